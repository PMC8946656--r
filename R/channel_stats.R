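#' Per-channel nonparametric group comparisons
#'
#' Two-tailed Mann-Whitney U comparisons of relative channel intensities
#' between tissue classes, with the significance annotation used throughout
#' the figures: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001. The U null
#' distribution is enumerated exactly for small tie-free samples
#' (`min(n_a, n_b) <= exact_threshold`), otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @name channel_stats
NULL

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Two-tailed Mann-Whitney U test
#'
#' @param a,b numeric samples
#' @param exact_threshold enumerate the exact null when `min(n_a, n_b)` is
#'   at most this and there are no ties (default 8)
#' @return list with `u` (U statistic of sample `a`), `p`, `method`
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 8L) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) afmi_stop("afmi_empty_group", "empty sample")
  pooled <- c(a, b)
  if (max(pooled) == min(pooled))
    return(list(u = na * nb / 2, p = 1, method = "degenerate",
                flagged = TRUE))
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(na, nb) <= exact_threshold && na + nb <= 20) {
    # exact: U is distribution-free; enumerate all C(na+nb, na) assignments
    cmb <- combn(na + nb, na)
    rr <- rank(pooled) # tie-free: ranks are a permutation
    u_all <- colSums(matrix(rr[cmb], nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    return(list(u = u, p = min(p, 1), method = "exact", flagged = FALSE))
  }
  mu <- na * nb / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / ((na + nb) * (na + nb - 1))
  sigma2 <- na * nb / 12 * ((na + nb + 1) - tie_term)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- min(2 * pnorm(z, lower.tail = FALSE), 1)
  if (u == mu) p <- 1
  list(u = u, p = p, method = "normal_approx", flagged = FALSE)
}

#' Compare one channel's relative intensities between two classes
#'
#' @param rss_table signature table with `rss_*` columns and labels
#' @param channel_index 1-based channel id
#' @param pair character vector of two class names, e.g.
#'   `c("normal", "OSSN")`
#' @param exact_threshold see [mann_whitney_u()]
#' @param per_patient aggregate sectors to per-patient medians before
#'   testing (avoids pooled-sector pseudo-replication)?
#' @return one-row data frame: channel, pair, n_a, n_b, U, p, stars, medians
#' @export
compare_channel_groups <- function(rss_table, channel_index, pair,
                                   exact_threshold = 8L,
                                   per_patient = FALSE) {
  col <- paste0("rss_", channel_index)
  if (!col %in% names(rss_table))
    afmi_stop("afmi_no_signature_columns", "column %s missing", col)
  pick <- function(cl) {
    v <- rss_table[rss_table$label == cl, c("patient_id", col)]
    if (!nrow(v)) afmi_stop("afmi_empty_group", "no sectors of class %s", cl)
    if (per_patient)
      tapply(v[[col]], v$patient_id, median)
    else v[[col]]
  }
  a <- as.numeric(pick(pair[1])); b <- as.numeric(pick(pair[2]))
  mw <- mann_whitney_u(a, b, exact_threshold)
  data.frame(channel = channel_index, group_a = pair[1], group_b = pair[2],
             n_a = length(a), n_b = length(b), u_statistic = mw$u,
             p_value = mw$p, median_a = median(a), median_b = median(b),
             stars = p_stars(mw$p), method = mw$method,
             stringsAsFactors = FALSE)
}

#' Channel comparison table over channels and class pairs
#'
#' @param rss_table signature table with `rss_*` columns
#' @param channels channel indices (default: the four fluorophore-hinted
#'   channels 3, 12, 30, 52)
#' @param pairs list of class pairs (default: all three)
#' @param adjust `"none"` (per-channel reporting) or `"BH"`
#' @inheritParams compare_channel_groups
#' @return data frame, one row per channel x pair
#' @export
channel_comparison_table <- function(rss_table, channels = c(3, 12, 30, 52),
                                     pairs = list(c("normal", "PTG"),
                                                  c("normal", "OSSN"),
                                                  c("PTG", "OSSN")),
                                     exact_threshold = 8L,
                                     per_patient = FALSE,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (ch in channels) for (pr in pairs)
    rows[[length(rows) + 1L]] <-
      compare_channel_groups(rss_table, ch, pr, exact_threshold, per_patient)
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- vapply(out$p_value, p_stars, character(1))
  }
  out
}
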