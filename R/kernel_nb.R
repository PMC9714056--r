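# ---- helpers ---------------------------------------------------------------

.as_xy <- function(X, labels = NULL) {
  # Accept a labelled feature_matrix, or a plain matrix plus labels.
  if (inherits(X, "feature_matrix")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$x
  }
  stopifnot(is.matrix(X))
  if (!is.null(labels)) {
    labels <- .label_factor(labels)
    if (anyNA(labels)) stop("labels must be amyloid / non-amyloid")
    stopifnot(length(labels) == nrow(X))
  }
  list(x = X, y = labels)
}

# Normal-reference (Silverman) bandwidth per feature within one class,
# floored for zero-variance features so densities are never degenerate.
.silverman_bandwidth <- function(xc, feat_range) {
  n <- nrow(xc)
  sdev <- apply(xc, 2, stats::sd)
  iqr <- apply(xc, 2, stats::IQR) / 1.349
  spread <- pmin(sdev, ifelse(iqr > 0, iqr, sdev))
  h <- 0.9 * spread * n^(-1 / 5)
  floor_h <- 1e-6 * (feat_range + 1e-12)
  pmax(h, floor_h, na.rm = TRUE)
}

# ---- kernel naive Bayes ----------------------------------------------------

#' Fit a Gaussian-kernel naive Bayes classifier
#'
#' Per class and per feature, an independent kernel density estimate with a
#' Gaussian kernel supported on the whole real line ("unbounded support").
#' Bandwidths follow the normal-reference (Silverman) rule per class and
#' feature, `0.9 min(sd, IQR/1.349) n^(-1/5)`, floored at
#' `1e-6 * (feature range + 1e-12)` so zero-variance features never produce a
#' zero or undefined bandwidth. Priors are the class frequencies.
#'
#' @param X a labelled `feature_matrix`, or a numeric matrix.
#' @param labels class labels (needed when `X` is a plain matrix).
#' @return a `kernel_nb` model: priors, per-class training values and
#'   per-class/feature bandwidths.
#' @examples
#' x <- matrix(c(0, 0.2, 10, 10.3), ncol = 1)
#' m <- fit_kernel_nb(x, c("amyloid", "amyloid", "non-amyloid", "non-amyloid"))
#' predict_kernel_nb(m, matrix(1))$labels
#' @export
fit_kernel_nb <- function(X, labels = NULL) {
  d <- .as_xy(X, labels)
  if (is.null(d$y)) stop("labels are required to fit a classifier")
  if (anyNA(d$x)) stop("missing values in the feature matrix")
  cc <- table(d$y)
  if (any(cc < 1)) stop("at least one sample per class is required")
  feat_range <- apply(d$x, 2, function(v) diff(range(v)))
  per_class <- lapply(LABEL_LEVELS, function(cl) {
    xc <- d$x[d$y == cl, , drop = FALSE]
    list(values = xc, bandwidth = .silverman_bandwidth(xc, feat_range))
  })
  names(per_class) <- LABEL_LEVELS
  structure(list(classes = LABEL_LEVELS,
                 priors = as.numeric(cc[LABEL_LEVELS]) / sum(cc),
                 per_class = per_class,
                 n_features = ncol(d$x),
                 feature_names = colnames(d$x)),
            class = "kernel_nb")
}

#' Predict with a kernel naive Bayes model
#'
#' Accumulates per-feature log kernel densities plus the log prior in the log
#' domain (per-feature densities floored at 1e-300), normalises to class
#' posteriors, and assigns the arg-max label. A posterior tie resolves to the
#' negative (non-amyloid) class — the conservative choice for a screening
#' tool.
#'
#' @param model a `kernel_nb` model.
#' @param X feature matrix (plain matrix or `feature_matrix`) with the same
#'   number of columns as at training.
#' @return list with `labels` (factor), `posterior` (n x 2 matrix, columns
#'   non-amyloid / amyloid) and `score` (positive-class posterior).
#' @export
predict_kernel_nb <- function(model, X) {
  stopifnot(inherits(model, "kernel_nb"))
  d <- .as_xy(X)
  if (ncol(d$x) != model$n_features) {
    stop("feature count mismatch: model has ", model$n_features,
         ", input has ", ncol(d$x))
  }
  ll <- vapply(model$classes, function(cl) {
    pc <- model$per_class[[cl]]
    .nb_class_loglik(d$x, pc$values, pc$bandwidth)
  }, numeric(nrow(d$x)))
  ll <- matrix(ll, nrow = nrow(d$x),
               dimnames = list(NULL, model$classes))
  ll <- sweep(ll, 2, log(model$priors), "+")
  # normalise in the log domain
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  score <- post[, LABEL_POSITIVE]
  labels <- ifelse(score > post[, LABEL_NEGATIVE], LABEL_POSITIVE,
                   LABEL_NEGATIVE)  # tie -> negative
  list(labels = .label_factor(labels), posterior = post, score = score)
}

#' @export
print.kernel_nb <- function(x, ...) {
  cat(sprintf(
    "kernel naive Bayes: %d features; priors %s=%.3f %s=%.3f; n=(%d, %d)\n",
    x$n_features, x$classes[1], x$priors[1], x$classes[2], x$priors[2],
    nrow(x$per_class[[1]]$values), nrow(x$per_class[[2]]$values)))
  invisible(x)
}

# Density of one (class, feature) KDE on a grid; used by tests to verify the
# densities integrate to one.
#' Evaluate one per-class, per-feature kernel density of a fitted model
#'
#' @param model a `kernel_nb` model.
#' @param class class label.
#' @param feature feature index.
#' @param at numeric vector of evaluation points.
#' @return density values at `at`.
#' @export
kernel_nb_density <- function(model, class, feature, at) {
  pc <- model$per_class[[class]]
  v <- pc$values[, feature]
  h <- pc$bandwidth[feature]
  vapply(at, function(x) mean(stats::dnorm((x - v) / h)) / h, numeric(1))
}
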