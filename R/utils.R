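`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a global seed
#'
#' A fixed integer mixing of the global seed with the stage name so that
#' partial pipeline reruns reproduce the same per-stage random streams.
#' Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(seed) * 48271 + h * 9973 + 17) %% 2147483646 + 1)
}

afmi_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "afmi_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# class labels used throughout: integer codes in masks, names in tables
afmi_classes <- function() c("normal", "PTG", "OSSN")

class_code <- function(labels) {
  m <- match(labels, afmi_classes())
  if (anyNA(m)) afmi_stop("afmi_bad_label", "unknown class label(s): %s",
                          paste(unique(labels[is.na(m)]), collapse = ", "))
  m
}
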