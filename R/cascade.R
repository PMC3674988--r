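#' @title Two-stage cascaded classifier
#' @name cascade
#' @description
#' First stage: up to 12 base classifiers (6 descriptors x 2 learning
#' schemes, feed-forward neural networks and support vector machines), each
#' auto-parameterized by grid search with inner 5-fold cross-validation on
#' the Matthews correlation coefficient. Second stage: a small "jury"
#' neural network over the base-classifier scores; all member subsets of the
#' base slots are enumerated, each jury is evaluated by cross-validated and
#' external-set MCC, the best compromise is selected and retrained on the
#' whole core set. Scores live in [0, 1); classification threshold 0.5.
NULL

SCHEME_IDS <- c("ANN", "SVM")
SCORE_EPS <- 1e-9

clamp_score <- function(s) pmin(pmax(as.numeric(s), 0), 1 - SCORE_EPS)

#' The base-classifier slots of the cascade
#'
#' @param descriptors Descriptor identifiers (default all six).
#' @param schemes Learning schemes (default ANN and SVM).
#' @return data.frame with columns `slot`, `descriptor`, `scheme`; one row
#'   per (descriptor, scheme) combination in fixed order.
#' @export
#' @examples
#' nrow(base_slots())  # 12
base_slots <- function(descriptors = DESCRIPTOR_IDS, schemes = SCHEME_IDS) {
  descriptors <- match.arg(descriptors, DESCRIPTOR_IDS, several.ok = TRUE)
  schemes <- match.arg(schemes, SCHEME_IDS, several.ok = TRUE)
  g <- expand.grid(scheme = schemes, descriptor = descriptors,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("descriptor", "scheme")]
  g$slot <- paste(g$descriptor, g$scheme, sep = ".")
  g[, c("slot", "descriptor", "scheme")]
}

#' Hyperparameter grid specification
#'
#' Defaults follow the published ranges: ANN hidden neurons h in [2, 10];
#' SVM cost C in [0.5, 8.0] over four kernels (linear, polynomial, radial,
#' sigmoid) with degree d in \{1,2,3\}, gamma in \{0.01, 0.05, 0.10\} and
#' coef0 in \{0, 3, 6\}. The neural networks are trained by quasi-Newton
#' optimization with weight decay (grid \{0.01, 0.1, 1\}) rather than
#' online backpropagation, so decay takes the role of the original
#' learning-rate/momentum pair. Hyperparameters are chosen by inner 5-fold
#' cross-validated MCC.
#'
#' @param ann_size Hidden-neuron counts for the ANN grid.
#' @param ann_decay Weight-decay values for the ANN grid.
#' @param svm_kernels Kernels searched.
#' @param svm_cost,svm_gamma,svm_degree,svm_coef0 SVM grid values.
#' @param inner_folds Inner cross-validation folds (default 5).
#' @param ann_maxit Optimizer iteration cap per network fit.
#' @return List of class `"grid_spec"` with data.frame components `ann` and
#'   `svm` (one row per configuration) and `inner_folds`.
#' @export
grid_spec <- function(ann_size = 2:10, ann_decay = c(0.01, 0.1, 1),
                      svm_kernels = c("linear", "polynomial", "radial",
                                      "sigmoid"),
                      svm_cost = c(0.5, 1, 2, 4, 8),
                      svm_gamma = c(0.01, 0.05, 0.10),
                      svm_degree = 1:3, svm_coef0 = c(0, 3, 6),
                      inner_folds = 5, ann_maxit = 200) {
  stopifnot(length(ann_size) > 0, length(svm_cost) > 0, inner_folds >= 2)
  ann <- expand.grid(size = ann_size, decay = ann_decay,
                     KEEP.OUT.ATTRS = FALSE)
  svm <- do.call(rbind, lapply(svm_kernels, function(k) {
    base <- switch(k,
      linear = expand.grid(cost = svm_cost, gamma = NA_real_,
                           degree = NA_real_, coef0 = NA_real_),
      radial = expand.grid(cost = svm_cost, gamma = svm_gamma,
                           degree = NA_real_, coef0 = NA_real_),
      sigmoid = expand.grid(cost = svm_cost, gamma = svm_gamma,
                            degree = NA_real_, coef0 = svm_coef0),
      polynomial = expand.grid(cost = svm_cost, gamma = svm_gamma,
                               degree = svm_degree, coef0 = svm_coef0),
      stop("unknown kernel: ", k))
    cbind(kernel = k, base, stringsAsFactors = FALSE)
  }))
  rownames(svm) <- NULL
  structure(list(ann = ann, svm = svm, inner_folds = inner_folds,
                 ann_maxit = ann_maxit),
            class = "grid_spec")
}

#' Reduced desk-scale hyperparameter grid
#'
#' A small grid (two network sizes, one decay; radial-kernel SVMs at two
#' costs and two gammas) for fast exploratory and test runs; same selection
#' machinery as [grid_spec()].
#'
#' @inheritParams grid_spec
#' @return A `"grid_spec"`.
#' @export
reduced_grid_spec <- function(inner_folds = 5) {
  grid_spec(ann_size = c(3, 6), ann_decay = 0.1,
            svm_kernels = "radial", svm_cost = c(1, 4),
            svm_gamma = c(0.01, 0.05), inner_folds = inner_folds,
            ann_maxit = 150)
}

# ---- confusion tables and MCC -------------------------------------------

#' Confusion table of a binary classification
#'
#' @param predicted,actual Logical vectors (TRUE = binder) or label vectors
#'   with values "binder"/"non-binder".
#' @return Named numeric vector with entries TP, FP, FN, TN.
#' @export
confusion_table <- function(predicted, actual) {
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x > 0.5)
    x == "binder"
  }
  p <- to_logical(predicted); a <- to_logical(actual)
  stopifnot(length(p) == length(a), length(p) > 0)
  c(TP = sum(p & a), FP = sum(p & !a), FN = sum(!p & a), TN = sum(!p & !a))
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the Pearson
#' phi coefficient of the predicted-vs-actual binary labels, in [-1, 1].
#' If any factor of the denominator is zero the coefficient is defined as 0.
#'
#' @param conf Named numeric with entries TP, FP, FN, TN (as produced by
#'   [confusion_table()]), or a list with those components.
#' @return Numeric scalar in [-1, 1].
#' @export
#' @examples
#' mcc(c(TP = 50, FP = 0, FN = 0, TN = 50))  # 1
mcc <- function(conf) {
  conf <- unlist(conf)
  if (!all(c("TP", "FP", "FN", "TN") %in% names(conf)))
    stop("'conf' must provide TP, FP, FN and TN")
  tp <- as.double(conf[["TP"]]); fp <- as.double(conf[["FP"]])
  fn <- as.double(conf[["FN"]]); tn <- as.double(conf[["TN"]])
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion table")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# ---- single model fits ---------------------------------------------------

stratified_fold_ids <- function(y, k, seed) {
  set.seed(as.integer(seed))
  ids <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    ids[idx] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

fit_ann <- function(X, y01, size, decay, maxit, seed) {
  set.seed(as.integer(seed))
  nnet::nnet(x = X, y = y01, size = size, decay = decay, maxit = maxit,
             trace = FALSE, MaxNWts = 50000)
}

fit_svm <- function(X, y01, config, seed) {
  args <- list(x = X, y = factor(y01, levels = c(0, 1)),
               kernel = config$kernel, cost = config$cost, scale = FALSE)
  if (!is.na(config$gamma)) args$gamma <- config$gamma
  if (!is.na(config$degree)) args$degree <- config$degree
  if (!is.na(config$coef0)) args$coef0 <- config$coef0
  model <- do.call(e1071::svm, args)
  dv <- as.numeric(attr(stats::predict(model, X, decision.values = TRUE),
                        "decision.values"))
  # Platt-style calibration of decision values into (0, 1); deterministic,
  # sign-agnostic (the GLM learns the orientation of the decision axis)
  platt <- suppressWarnings(
    stats::glm(y01 ~ dv, family = stats::binomial(),
               data = data.frame(y01 = y01, dv = dv)))
  list(svm = model, platt_coef = stats::coef(platt))
}

score_fit <- function(fit, scheme, X) {
  s <- if (scheme == "ANN") {
    as.numeric(stats::predict(fit, X))
  } else {
    dv <- as.numeric(attr(stats::predict(fit$svm, X,
                                         decision.values = TRUE),
                          "decision.values"))
    stats::plogis(fit$platt_coef[1] + fit$platt_coef[2] * dv)
  }
  clamp_score(s)
}

fit_config <- function(X, y01, scheme, config, grid, seed) {
  if (scheme == "ANN")
    fit_ann(X, y01, config$size, config$decay, grid$ann_maxit, seed)
  else
    fit_svm(X, y01, config, seed)
}

# inner k-fold CV MCC of one hyperparameter configuration
inner_cv_mcc <- function(X, y01, scheme, config, grid, seed) {
  ids <- stratified_fold_ids(y01, grid$inner_folds, child_seed(seed, 90))
  conf <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (f in seq_len(grid$inner_folds)) {
    tr <- ids != f
    fit <- tryCatch(
      fit_config(X[tr, , drop = FALSE], y01[tr], scheme, config, grid,
                 child_seed(seed, 100 + f)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    s <- score_fit(fit, scheme, X[!tr, , drop = FALSE])
    conf <- conf + confusion_table(s >= 0.5, y01[!tr] == 1)
  }
  mcc(conf)
}

# core trainer on a precomputed design matrix
train_base_matrix <- function(X, y01, scheme, grid, seed) {
  if (length(unique(y01)) < 2)
    stop("base-classifier training requires both classes")
  configs <- if (scheme == "ANN") grid$ann else grid$svm
  cv <- vapply(seq_len(nrow(configs)), function(i)
    inner_cv_mcc(X, y01, scheme, configs[i, , drop = FALSE], grid,
                 child_seed(seed, i)), numeric(1))
  if (all(is.na(cv))) stop("no ", scheme, " configuration converged")
  if (anyNA(cv))
    warning(sum(is.na(cv)), " non-converging ", scheme,
            " configuration(s) skipped")
  best <- which.max(cv)  # deterministic: first of ties in grid order
  fit <- fit_config(X, y01, scheme, configs[best, , drop = FALSE], grid,
                    child_seed(seed, 7000))
  structure(list(scheme = scheme,
                 config = as.list(configs[best, , drop = FALSE]),
                 inner_mcc = cv[best], fit = fit, n_train = nrow(X),
                 seed = seed),
            class = "base_fit")
}

#' Train one base classifier
#'
#' Encodes the training peptides with the requested descriptor, selects
#' hyperparameters by inner 5-fold cross-validated MCC over the grid, and
#' refits on all training records with the winning configuration.
#' Deterministic under `seed`. Configurations that fail to converge are
#' skipped with a warning.
#'
#' @param data Labeled peptide set (columns `sequence`, `label`), both
#'   classes present.
#' @param descriptor One of [DESCRIPTOR_IDS].
#' @param scheme `"ANN"` or `"SVM"`.
#' @param grid A `"grid_spec"`.
#' @param seed Integer seed.
#' @param context A `"descriptor_context"`.
#' @return Object of class `"base_classifier"` emitting scores in [0, 1)
#'   via [score_peptides()].
#' @export
train_base <- function(data, descriptor, scheme, grid = grid_spec(),
                       seed = 1, context = descriptor_context()) {
  check_peptide_set(data)
  descriptor <- match.arg(descriptor, DESCRIPTOR_IDS)
  scheme <- match.arg(scheme, SCHEME_IDS)
  lens <- unique(nchar(data$sequence))
  if (length(lens) != 1)
    stop("all training peptides must share one length")
  X <- encode_peptides(data$sequence, descriptor, context)
  y01 <- as.integer(data$label == "binder")
  fit <- train_base_matrix(X, y01, scheme, grid, seed)
  structure(c(fit, list(descriptor = descriptor, peptide_length = lens,
                        context = context)),
            class = c("base_classifier", "base_fit"))
}

#' Score peptides with a trained base classifier
#'
#' @param model A `"base_classifier"`.
#' @param sequences Character vector of peptides of the trained length.
#' @return Numeric scores in [0, 1).
#' @export
score_peptides <- function(model, sequences) {
  stopifnot(inherits(model, "base_classifier"))
  sequences <- validate_peptides(sequences, model$peptide_length)
  X <- encode_peptides(sequences, model$descriptor, model$context)
  score_fit(model$fit, model$scheme, X)
}

#' Score matrix of several base classifiers
#'
#' @param models List of `"base_classifier"` objects (fixed slot order).
#' @param data Labeled peptide set or character vector of sequences.
#' @return Numeric matrix, rows = instances, columns = models (named by
#'   `descriptor.scheme`), entries in [0, 1).
#' @export
base_score_matrix <- function(models, data) {
  if (is.data.frame(data)) data <- data$sequence
  if (any(!vapply(models, inherits, logical(1), "base_classifier")))
    stop("untrained or invalid base-classifier slot")
  S <- vapply(models, function(m) score_peptides(m, data),
              numeric(length(data)))
  S <- matrix(S, nrow = length(data))
  colnames(S) <- vapply(models, function(m)
    paste(m$descriptor, m$scheme, sep = "."), character(1))
  S
}
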