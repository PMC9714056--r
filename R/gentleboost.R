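# ---- regression tree base learner ------------------------------------------

#' Fit a weighted least-squares regression tree
#'
#' Greedy best-first growth: at each step the leaf whose best split yields
#' the largest weighted SSE reduction is split, up to `max_split` internal
#' splits. Candidate thresholds lie midway between consecutive distinct
#' feature values within a leaf; leaf values are weighted means of their
#' targets. Degenerate data (constant targets, all candidates gainless)
#' yields a single leaf.
#'
#' @param X numeric matrix (samples x features).
#' @param targets real-valued responses.
#' @param weights non-negative sample weights with positive sum.
#' @param max_split maximum number of internal splits (1 = a stump).
#' @param orders optional precomputed column sort orders (as returned by the
#'   internal presorter); computed when missing.
#' @return a `regression_tree`: parallel node arrays `feature` (NA at
#'   leaves), `threshold`, `left`, `right`, `value`.
#' @export
fit_stump_tree <- function(X, targets, weights = rep(1, nrow(X)),
                           max_split = 1L, orders = NULL) {
  stopifnot(is.matrix(X), length(targets) == nrow(X),
            length(weights) == nrow(X), max_split >= 0)
  if (sum(weights) <= 0) stop("sum of weights must be positive")
  if (is.null(orders)) orders <- .column_orders(X)
  fit <- .fit_tree_cpp(X, as.numeric(targets), as.numeric(weights),
                       as.integer(max_split), orders)
  fit$feature[fit$feature == 0L] <- NA_integer_
  structure(fit, class = "regression_tree")
}

#' Predict from a regression tree
#'
#' @param tree a `regression_tree`.
#' @param X numeric matrix.
#' @return numeric vector of leaf values.
#' @export
predict_tree <- function(tree, X) {
  stopifnot(inherits(tree, "regression_tree"), is.matrix(X))
  feat <- tree$feature
  feat[is.na(feat)] <- 0L
  if (any(feat > ncol(X))) {
    stop("dimension mismatch: tree uses feature ", max(feat),
         " but matrix has ", ncol(X), " columns")
  }
  .predict_tree_cpp(feat, tree$threshold, tree$left, tree$right,
                    tree$value, X)
}

# ---- GentleBoost ------------------------------------------------------------

.labels_to_pm1 <- function(labels) {
  y <- .label_factor(labels)
  if (anyNA(y)) stop("labels must be binary amyloid / non-amyloid")
  ifelse(y == LABEL_POSITIVE, 1, -1)
}

#' Fit a GentleBoost ensemble of regression trees
#'
#' GentleBoost under exponential loss: sample weights start uniform; each
#' round fits a weighted least-squares regression tree to the +/-1 response,
#' adds `learning_rate * tree` to the additive score F, reweights
#' `w <- w * exp(-y * learning_rate * f(x))` and renormalises. Leaf outputs
#' are clamped to \[-4, 4\] as a numerical guard against extreme weights.
#'
#' @param X labelled `feature_matrix` or numeric matrix.
#' @param labels class labels (when `X` is a plain matrix).
#' @param num_learners number of boosting rounds (study configuration
#'   Exp 1: 67).
#' @param max_split maximum splits per tree (Exp 1: 26).
#' @param learning_rate shrinkage in (0, 1\] (Exp 1: 0.5915).
#' @return a `gentle_boost` model (ordered learners + learning rate).
#' @export
fit_gentleboost <- function(X, labels = NULL, num_learners = 67L,
                            max_split = 26L, learning_rate = 0.5915) {
  d <- .as_xy(X, labels)
  if (is.null(d$y)) stop("labels are required to fit a classifier")
  stopifnot(num_learners >= 1, max_split >= 1,
            learning_rate > 0, learning_rate <= 1)
  y <- .labels_to_pm1(d$y)
  n <- nrow(d$x)
  w <- rep(1 / n, n)
  orders <- .column_orders(d$x)
  learners <- vector("list", num_learners)
  loss_trace <- numeric(num_learners)
  Fx <- numeric(n)
  for (t in seq_len(num_learners)) {
    tree <- fit_stump_tree(d$x, y, w, max_split, orders = orders)
    tree$value <- pmin(4, pmax(-4, tree$value))
    f <- predict_tree(tree, d$x)
    Fx <- Fx + learning_rate * f
    w <- w * exp(-y * learning_rate * f)
    w <- w / sum(w)
    learners[[t]] <- tree
    loss_trace[t] <- mean(exp(-y * Fx))
  }
  structure(list(learners = learners,
                 learning_rate = learning_rate,
                 num_learners = as.integer(num_learners),
                 max_split = as.integer(max_split),
                 n_features = ncol(d$x),
                 feature_names = colnames(d$x),
                 classes = LABEL_LEVELS,
                 loss_trace = loss_trace),
            class = "gentle_boost")
}

#' Predict with a GentleBoost model
#'
#' `F(x) = sum_t rate * f_t(x)`; the label is the sign of F, with F = 0
#' (including the empty-ensemble case) resolving to the negative
#' (non-amyloid) class.
#'
#' @param model a `gentle_boost` model.
#' @param X feature matrix with the same column count as at training.
#' @return list with `labels` (factor) and `score` (the additive score F).
#' @export
predict_gentleboost <- function(model, X) {
  stopifnot(inherits(model, "gentle_boost"))
  d <- .as_xy(X)
  if (ncol(d$x) != model$n_features) {
    stop("feature count mismatch: model has ", model$n_features,
         ", input has ", ncol(d$x))
  }
  Fx <- numeric(nrow(d$x))
  for (tree in model$learners) {
    Fx <- Fx + model$learning_rate * predict_tree(tree, d$x)
  }
  labels <- ifelse(Fx > 0, LABEL_POSITIVE, LABEL_NEGATIVE)
  list(labels = .label_factor(labels), score = Fx)
}

#' @export
print.gentle_boost <- function(x, ...) {
  cat(sprintf(
    "GentleBoost ensemble: %d learners, max_split %d, learning rate %.4f, %d features\n",
    length(x$learners), x$max_split, x$learning_rate, x$n_features))
  invisible(x)
}

# ---- training configuration -------------------------------------------------

# The eight study configurations (Table-of-experiments presets). "auto"
# learner counts are exposed as an explicit integer (default 30).
.TRAIN_PRESETS <- list(
  exp1 = list(algorithm = "gentleboost", k = 5L, max_split = 26L,
              num_learners = 67L, learning_rate = 0.5915),
  exp2 = list(algorithm = "kernel_nb", k = 5L),
  exp3 = list(algorithm = "gentleboost", k = 10L, max_split = 22L,
              num_learners = 30L, learning_rate = 0.0011),
  exp4 = list(algorithm = "gentleboost", k = 10L, max_split = 40L,
              num_learners = 80L, learning_rate = 0.1),
  exp5 = list(algorithm = "kernel_nb", k = 10L),
  exp6 = list(algorithm = "gentleboost", k = 15L, max_split = 30L,
              num_learners = 30L, learning_rate = 0.1),
  exp7 = list(algorithm = "gentleboost", k = 15L, max_split = 20L,
              num_learners = 60L, learning_rate = 0.1),
  exp8 = list(algorithm = "kernel_nb", k = 15L))

#' Training configuration
#'
#' Either build a configuration field by field or load one of the eight named
#' study presets (`"exp1"` ... `"exp8"`): GentleBoost ensembles with the
#' published max-split / learner-count / learning-rate triples, or kernel
#' naive Bayes, each paired with its cross-validation fold count (5, 10, 15).
#' The preset with an unspecified ("auto") learner count exposes it as an
#' explicit integer, default 30.
#'
#' @param algorithm `"kernel_nb"` or `"gentleboost"`.
#' @param preset optional preset name; overrides the other arguments.
#' @param k cross-validation fold count.
#' @param max_split,num_learners,learning_rate GentleBoost hyperparameters.
#' @param seed integer seed for stochastic stages (CV shuffling).
#' @return a `train_config` list.
#' @export
train_config <- function(algorithm = c("kernel_nb", "gentleboost"),
                         preset = NULL, k = 5L, max_split = 26L,
                         num_learners = 67L, learning_rate = 0.5915,
                         seed = 1L) {
  if (!is.null(preset)) {
    if (!preset %in% names(.TRAIN_PRESETS)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(.TRAIN_PRESETS), collapse = ", "))
    }
    p <- .TRAIN_PRESETS[[preset]]
    cfg <- list(algorithm = p$algorithm, k = p$k,
                max_split = p$max_split %||% NA_integer_,
                num_learners = p$num_learners %||% NA_integer_,
                learning_rate = p$learning_rate %||% NA_real_,
                seed = as.integer(seed), preset = preset)
  } else {
    algorithm <- match.arg(algorithm)
    cfg <- list(algorithm = algorithm, k = as.integer(k),
                max_split = as.integer(max_split),
                num_learners = as.integer(num_learners),
                learning_rate = learning_rate,
                seed = as.integer(seed), preset = NA_character_)
  }
  structure(cfg, class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the classifier named by a training configuration
#'
#' @param X labelled `feature_matrix` or matrix.
#' @param labels labels when `X` is a plain matrix.
#' @param config a [train_config()].
#' @return a fitted `kernel_nb` or `gentle_boost` model.
#' @export
fit_classifier <- function(X, labels = NULL, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  switch(config$algorithm,
    kernel_nb = fit_kernel_nb(X, labels),
    gentleboost = fit_gentleboost(X, labels,
                                  num_learners = config$num_learners,
                                  max_split = config$max_split,
                                  learning_rate = config$learning_rate),
    stop("unknown algorithm: ", config$algorithm))
}

#' Predict labels and scores with either classifier
#'
#' @param model a `kernel_nb` or `gentle_boost` model.
#' @param X feature matrix.
#' @return list with `labels` and `score` (positive-class posterior for the
#'   kernel naive Bayes, additive score F for GentleBoost).
#' @export
predict_classifier <- function(model, X) {
  if (inherits(model, "kernel_nb")) {
    p <- predict_kernel_nb(model, X)
    list(labels = p$labels, score = p$score)
  } else if (inherits(model, "gentle_boost")) {
    predict_gentleboost(model, X)
  } else {
    stop("not a fitted amyloidhex model")
  }
}

# ---- serialization ----------------------------------------------------------

.MODEL_FORMAT_VERSION <- "1.0"

#' Save / load a fitted model (portable JSON)
#'
#' Models are serialized as versioned JSON with full numeric precision;
#' `load_model(save_model(m))` reproduces bit-identical predictions. A file
#' with a different format version, or a truncated/corrupt file, raises a
#' clean error without returning a partial model.
#'
#' @param model a `kernel_nb` or `gentle_boost` model.
#' @param path file path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  type <- if (inherits(model, "kernel_nb")) "kernel_nb"
          else if (inherits(model, "gentle_boost")) "gentle_boost"
          else stop("not a fitted amyloidhex model")
  body <- unclass(model)
  if (type == "gentle_boost") {
    body$learners <- lapply(body$learners, unclass)
  }
  payload <- list(format_version = .MODEL_FORMAT_VERSION,
                  model_type = type,
                  model = body)
  # 17 significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) stop("cannot read model file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(payload$format_version) || is.null(payload$model_type)) {
    stop("model file '", path, "' is missing its format header")
  }
  if (!identical(payload$format_version, .MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: file has ", payload$format_version,
         ", this package reads ", .MODEL_FORMAT_VERSION)
  }
  m <- payload$model
  if (payload$model_type == "kernel_nb") {
    m$per_class <- lapply(m$per_class, function(pc) {
      pc$values <- as.matrix(pc$values)
      pc
    })
    structure(m, class = "kernel_nb")
  } else if (payload$model_type == "gentle_boost") {
    m$learners <- lapply(payload$model$learners, function(tr) {
      structure(list(feature = as.integer(tr$feature),
                     threshold = as.numeric(tr$threshold),
                     left = as.integer(tr$left),
                     right = as.integer(tr$right),
                     value = as.numeric(tr$value),
                     n_splits = as.integer(tr$n_splits)),
                class = "regression_tree")
    })
    structure(m, class = "gentle_boost")
  } else {
    stop("unknown model type in file: ", payload$model_type)
  }
}
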