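#' Intra-patient boundary delineation and false-color maps
#'
#' For a single patient, a PCA+SVM classifier is trained on high-purity
#' annotated sectors of that patient only (relative signatures computed
#' against the same patient's normal reference) and applied to every other
#' tissue sector -- operationally the "region intersections" where classes
#' meet. Predictions are rendered as a red (OSSN) / orange (PTG) / green
#' (normal) overlay on a grayscale base channel (default channel 10).
#'
#' @name boundary_map
NULL

afmi_legend <- function() {
  rbind(OSSN = c(255, 0, 0), PTG = c(255, 165, 0), normal = c(0, 255, 0)) / 255
}

#' Select per-class training annotations from one patient's sectors
#'
#' Mimics an annotator outlining a patch of each region: picks
#' `round(frac * n)` pure sectors per class (at least `min_per_class`),
#' deterministically from the seed.
#'
#' @param table one patient's signature table rows
#' @param frac fraction of each class's pure sectors to annotate
#' @param min_per_class minimum annotated sectors per class
#' @param seed RNG seed
#' @return logical vector marking training rows
#' @export
select_annotations <- function(table, frac = 0.3, min_per_class = 20L,
                               seed = 1) {
  set.seed(derive_seed(seed, "annotations"))
  sel <- logical(nrow(table))
  for (cl in intersect(afmi_classes(), unique(table$label))) {
    idx <- which(table$label == cl)
    n <- max(min_per_class, round(frac * length(idx)))
    if (n > length(idx)) n <- length(idx)
    sel[sample(idx, n)] <- TRUE
  }
  sel
}

#' Detect tissue boundaries within one patient
#'
#' @param stack the patient's (preprocessed) `afmi_patient_stack`
#' @param annotations logical vector over the sector table marking training
#'   sectors (e.g. from [select_annotations()]); must cover >=
#'   `min_per_class` sectors of every class present and >= `min_normal`
#'   normal sectors for the normal reference
#' @param table optional precomputed signature table for `stack`
#' @param pca_k,kernel,cost passed to the classifier
#' @param min_per_class minimum annotated sectors per present class
#' @param min_normal minimum normal sectors for the reference
#' @param base_channel grayscale base for the overlay (default 10)
#' @return an `afmi_boundary_map`: predicted label `grid` (sector rows x
#'   cols), `agreement` (fraction of non-training tissue sectors matching
#'   the mask majority label), the sector `table` with predictions, and
#'   rendering metadata
#' @export
detect_boundaries <- function(stack, annotations = NULL, table = NULL,
                              pca_k = 5L, kernel = "rbf", cost = 1,
                              min_per_class = 20L, min_normal = 10L,
                              base_channel = 10L) {
  if (is.null(table)) table <- extract_signatures(stack)
  if (length(unique(table$patient_id)) != 1)
    afmi_stop("afmi_patient_mismatch", "sectors from more than one patient")
  if (is.null(annotations))
    annotations <- select_annotations(table, min_per_class = min_per_class)
  stopifnot(length(annotations) == nrow(table))
  train <- table[annotations, , drop = FALSE]
  present <- intersect(afmi_classes(), unique(train$label))
  if (length(present) < 2)
    afmi_stop("afmi_single_class",
              "annotations must cover >= 2 classes, got: %s",
              paste(present, collapse = ", "))
  cnt <- table(train$label[train$label %in% present])
  if (any(cnt < min_per_class))
    afmi_stop("afmi_too_few_annotations",
              "need >= %d annotated sectors per class", min_per_class)

  # normal reference from the annotated normal sectors of this patient
  rel <- relative_signatures(train, min_normal = min_normal)
  ref <- rel$references[[table$patient_id[1]]]
  sig <- signature_matrix(table, "ch_")
  rss <- sweep(sweep(sig, 2, ref$med), 2, ref$std, "/")
  colnames(rss) <- paste0("rss_", seq_len(ncol(rss)))
  table_rss <- cbind(table, as.data.frame(rss))

  bundle <- train_classifier(table_rss[annotations, , drop = FALSE],
                             framework = "intra_patient", pca_k = pca_k,
                             kernel = kernel, cost = cost)

  tissue <- table$label != "outside"
  pred <- rep(NA_character_, nrow(table))
  eval_rows <- tissue & !annotations
  pred[tissue] <- classifier_predict(bundle, table_rss[tissue, , drop = FALSE])
  nsr <- max(table$sector_row) + 1L; nsc <- max(table$sector_col) + 1L
  grid <- matrix("outside", nsr, nsc)
  grid[cbind(table$sector_row + 1L, table$sector_col + 1L)] <-
    ifelse(is.na(pred), "outside", pred)
  agree_rows <- eval_rows & table$majority %in% afmi_classes()
  agreement <- mean(pred[agree_rows] == table$majority[agree_rows])
  table_rss$predicted <- pred
  table_rss$training <- annotations
  structure(list(patient_id = table$patient_id[1], grid = grid,
                 base_channel = as.integer(base_channel),
                 agreement = agreement, table = table_rss,
                 stack = stack, bundle = bundle),
            class = "afmi_boundary_map")
}

#' @export
print.afmi_boundary_map <- function(x, ...) {
  cat(sprintf("<afmi_boundary_map> %s: %dx%d sectors, agreement %.3f\n",
              x$patient_id, nrow(x$grid), ncol(x$grid), x$agreement))
  invisible(x)
}

#' Majority-filter smoothing of a boundary map
#'
#' Modal filter over the `(2r+1)^2` sector neighborhood; ties keep the
#' center label; `outside` sectors never change and never vote as tissue.
#' @param map an `afmi_boundary_map` (or a plain label matrix)
#' @param radius neighborhood radius in sectors
#' @param iterations number of passes
#' @return same type as the input, smoothed
#' @export
smooth_map <- function(map, radius = 1L, iterations = 1L) {
  grid <- if (inherits(map, "afmi_boundary_map")) map$grid else map
  nr <- nrow(grid); nc <- ncol(grid)
  for (it in seq_len(iterations)) {
    out <- grid
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (grid[i, j] == "outside") next
      nb <- grid[max(1, i - radius):min(nr, i + radius),
                 max(1, j - radius):min(nc, j + radius)]
      nb <- nb[nb != "outside"]
      tab <- table(nb)
      best <- names(tab)[tab == max(tab)]
      out[i, j] <- if (grid[i, j] %in% best || length(best) > 1)
        grid[i, j] else best[1]
    }
    grid <- out
  }
  if (inherits(map, "afmi_boundary_map")) { map$grid <- grid; map } else grid
}

#' Render the red/orange/green overlay
#'
#' Base: the configured channel rescaled to its 1st-99th percentile; class
#' colors are blended at `opacity` over the grayscale base on tissue
#' sectors.
#' @param map an `afmi_boundary_map`
#' @param opacity overlay opacity in `[0,1]`
#' @return RGB array (rows x cols x 3, values in `[0,1]`)
#' @export
render_boundary_overlay <- function(map, opacity = 0.5) {
  base <- map$stack$stack[, , map$base_channel]
  q <- quantile(base, c(0.01, 0.99), names = FALSE)
  g <- pmin(pmax((base - q[1]) / max(q[2] - q[1], 1e-12), 0), 1)
  nr <- nrow(g); nc <- ncol(g)
  rgb <- array(rep(g, 3), c(nr, nc, 3))
  legend <- afmi_legend()
  sp <- map$table$r1[1] - map$table$r0[1]
  for (k in seq_len(nrow(map$table))) {
    lab <- map$table$predicted[k]
    if (is.na(lab) || !(lab %in% rownames(legend))) next
    rr <- map$table$r0[k]:(map$table$r1[k] - 1L)
    cc <- map$table$c0[k]:(map$table$c1[k] - 1L)
    for (ch in 1:3)
      rgb[rr, cc, ch] <- (1 - opacity) * rgb[rr, cc, ch] +
        opacity * legend[lab, ch]
  }
  rgb
}

#' PCA false-color visualization
#'
#' Per-sector top-3 PCA scores are linearly rescaled to `[0,1]` per score
#' over the image and mapped to (R, G, B), then upsampled to pixel
#' resolution by nearest neighbor. Colors are dataset-relative: no fixed
#' class-to-color correspondence is implied.
#' @param stack an `afmi_patient_stack`
#' @param pca fitted `afmi_pca` with `k >= 3`
#' @param table optional precomputed signature table
#' @param prefix feature columns to project (`"ch_"` or `"rss_"`)
#' @return RGB array (rows x cols x 3, values in `[0,1]`)
#' @export
render_pca_falsecolor <- function(stack, pca, table = NULL, prefix = "ch_") {
  if (pca$k < 3)
    afmi_stop("afmi_pca_too_few_components", "need k >= 3 for RGB mapping")
  if (is.null(table)) table <- extract_signatures(stack)
  sc <- pca_scores(pca, signature_matrix(table, prefix))[, 1:3, drop = FALSE]
  for (j in 1:3) {
    rng <- range(sc[, j])
    sc[, j] <- if (diff(rng) > 0) (sc[, j] - rng[1]) / diff(rng) else 0.5
  }
  nr <- dim(stack$stack)[1]; nc <- dim(stack$stack)[2]
  rgb <- array(0, c(nr, nc, 3))
  for (k in seq_len(nrow(table))) {
    rr <- table$r0[k]:(table$r1[k] - 1L)
    cc <- table$c0[k]:(table$c1[k] - 1L)
    for (ch in 1:3) rgb[rr, cc, ch] <- sc[k, ch]
  }
  rgb
}
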