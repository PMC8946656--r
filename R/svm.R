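#' Support vector machine (SMO)
#'
#' A compact soft-margin SVM trained by sequential minimal optimization,
#' with linear and RBF kernels, per-class weights, and a deterministic
#' working-set heuristic (no RNG: refits on identical data are identical).
#' Multiclass problems use one-vs-rest with decision values retained, so
#' ROC analysis always has continuous scores.
#'
#' @param x numeric matrix of features
#' @param y factor or character labels (2+ classes)
#' @param kernel `"rbf"` or `"linear"`
#' @param cost box constraint C (default 1)
#' @param gamma RBF width; default `1 / (ncol(x) * var(x))` ("scale")
#' @param class_weights `"balanced"` (default) scales C by inverse class
#'   frequency; or a named numeric vector
#' @param tol KKT tolerance
#' @param max_passes optimizer pass budget
#' @return an `afmi_svm` model
#' @export
svm_fit <- function(x, y, kernel = c("rbf", "linear"), cost = 1,
                    gamma = NULL, class_weights = "balanced",
                    tol = 1e-3, max_passes = 200L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    afmi_stop("afmi_single_class", "need >= 2 classes, got: %s", classes[1])
  if (is.null(gamma)) {
    v <- var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  kcode <- if (kernel == "linear") 0L else 1L
  weight_of <- function(cls) {
    if (identical(class_weights, "balanced"))
      length(y) / (length(classes) * sum(y == cls))
    else if (is.numeric(class_weights)) class_weights[[cls]] %||% 1
    else 1
  }
  fit_binary <- function(pos) {
    yy <- ifelse(y == pos, 1, -1)
    Cvec <- ifelse(yy > 0, cost * weight_of(pos),
                   cost * if (length(classes) == 2)
                     weight_of(setdiff(classes, pos)) else
                       mean(vapply(setdiff(classes, pos), weight_of,
                                   numeric(1))))
    res <- .smo_train(x, yy, Cvec, kcode, gamma, tol, as.integer(max_passes))
    sv <- which(res$alpha > 1e-8)
    list(coef = res$alpha[sv] * yy[sv], sv = x[sv, , drop = FALSE],
         b = res$b)
  }
  machines <- if (length(classes) == 2) {
    list(fit_binary(classes[2])) # decision > 0 means second class
  } else {
    lapply(classes, fit_binary)
  }
  structure(list(machines = machines, classes = classes, kernel = kernel,
                 gamma = gamma, cost = cost, dim = ncol(x)),
            class = "afmi_svm")
}

#' Decision values of an SVM
#'
#' Binary models return one column (positive favors the second class in
#' sorted order); multiclass models return one one-vs-rest column per class.
#' @param model an `afmi_svm`
#' @param x matrix of feature rows
#' @return numeric matrix of decision values
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    afmi_stop("afmi_dim_mismatch", "expected %d features, got %d",
              model$dim, ncol(x))
  kcode <- if (model$kernel == "linear") 0L else 1L
  out <- vapply(model$machines, function(m)
    .smo_decision(m$sv, m$coef, m$b, x, kcode, model$gamma),
    numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x))
  colnames(out) <- if (length(model$classes) == 2) model$classes[2] else
    model$classes
  out
}

#' Predict class labels
#' @inheritParams svm_decision
#' @return character vector of labels
#' @export
svm_predict <- function(model, x) {
  d <- svm_decision(model, x)
  if (length(model$classes) == 2) {
    ifelse(d[, 1] > 0, model$classes[2], model$classes[1])
  } else {
    model$classes[max.col(d, ties.method = "first")]
  }
}
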