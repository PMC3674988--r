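#' @title Jury enumeration and the final cascaded model
#' @name jury
#' @description
#' The second stage of the cascade: a feed-forward "jury" network over the
#' base-classifier scores. [enumerate_juries()] iterates member subsets of
#' the base slots (all 2^k for an exhaustive run over k slots), scoring
#' each jury by cross-validated MCC and external-set MCC;
#' [select_and_retrain()] applies the compromise rule — rank by
#' min(MCC_cv, MCC_ext), tie-break by mean, then by fewer members — and
#' refits the winning jury on the entire core set. [cascade_fit()] runs the
#' whole workflow.
NULL

train_jury_net <- function(S, y01, hidden, seed, maxit = 300) {
  set.seed(as.integer(seed))
  nnet::nnet(x = S, y = y01, size = hidden, decay = 0.01, maxit = maxit,
             trace = FALSE, MaxNWts = 5000)
}

score_jury_net <- function(net, S) clamp_score(stats::predict(net, S))

# out-of-fold base scores for leak-free jury stacking
oof_scores <- function(X, y01, scheme, config, grid, seed, k = 5) {
  ids <- stratified_fold_ids(y01, k, child_seed(seed, 80))
  s <- numeric(length(y01))
  for (f in seq_len(k)) {
    tr <- ids != f
    fit <- fit_config(X[tr, , drop = FALSE], y01[tr], scheme, config, grid,
                      child_seed(seed, 81 + f))
    s[!tr] <- score_fit(fit, scheme, X[!tr, , drop = FALSE])
  }
  s
}

#' Train all base-classifier slots over the cross-validation folds
#'
#' Produces the internal state the jury search runs on: for every outer
#' fold, each slot's base classifier trained on the fold's training
#' portion, plus the jury-training score matrix (by default the bases'
#' scores on their own training data, as in the original workflow;
#' `stacking = "cv"` substitutes leak-free out-of-fold scores) and the
#' scores on the fold's test portion; additionally one set of bases trained
#' on the full cross-validation portion with scores on the external set.
#'
#' @param data Curated labeled peptide set.
#' @param split A `"peptide_split"` from [split_peptides()].
#' @param slots data.frame from [base_slots()].
#' @param grid A `"grid_spec"`.
#' @param seed Integer seed.
#' @param context A `"descriptor_context"`.
#' @param stacking `"faithful"` (default; jury inputs are base scores on
#'   the bases' own training data) or `"cv"` (out-of-fold scores).
#' @return Object of class `"cascade_state"`.
#' @export
train_base_stage <- function(data, split, slots, grid = grid_spec(),
                             seed = 1, context = descriptor_context(),
                             stacking = c("faithful", "cv")) {
  check_peptide_set(data)
  stacking <- match.arg(stacking)
  stopifnot(inherits(split, "peptide_split"))
  lens <- unique(nchar(data$sequence))
  if (length(lens) != 1) stop("all peptides must share one length")
  y01 <- as.integer(data$label == "binder")
  Xs <- lapply(stats::setNames(nm = unique(slots$descriptor)),
               function(d) encode_peptides(data$sequence, d, context))

  fit_slots <- function(train_idx, slot_seed_base) {
    lapply(seq_len(nrow(slots)), function(s) {
      X <- Xs[[slots$descriptor[s]]]
      train_base_matrix(X[train_idx, , drop = FALSE], y01[train_idx],
                        slots$scheme[s], grid,
                        child_seed(seed, slot_seed_base + s))
    })
  }
  slot_scores <- function(models, idx) {
    S <- vapply(seq_len(nrow(slots)), function(s)
      score_fit(models[[s]]$fit, slots$scheme[s],
                Xs[[slots$descriptor[s]]][idx, , drop = FALSE]),
      numeric(length(idx)))
    matrix(S, nrow = length(idx),
           dimnames = list(NULL, slots$slot))
  }
  jury_train_scores <- function(models, train_idx, seed_base) {
    if (stacking == "faithful") return(slot_scores(models, train_idx))
    S <- vapply(seq_len(nrow(slots)), function(s) {
      X <- Xs[[slots$descriptor[s]]]
      oof_scores(X[train_idx, , drop = FALSE], y01[train_idx],
                 slots$scheme[s], models[[s]]$config, grid,
                 child_seed(seed, seed_base + s))
    }, numeric(length(train_idx)))
    matrix(S, nrow = length(train_idx), dimnames = list(NULL, slots$slot))
  }

  folds <- lapply(seq_along(split$folds), function(f) {
    test_idx <- split$folds[[f]]
    train_idx <- setdiff(split$cv, test_idx)
    models <- fit_slots(train_idx, 1000 * f)
    list(train_idx = train_idx, test_idx = test_idx,
         scores_train = jury_train_scores(models, train_idx, 1000 * f + 500),
         scores_test = slot_scores(models, test_idx),
         y_train = y01[train_idx], y_test = y01[test_idx])
  })
  full_models <- fit_slots(split$cv, 0)
  full <- list(scores_cv = jury_train_scores(full_models, split$cv, 500),
               scores_ext = slot_scores(full_models, split$external),
               y_cv = y01[split$cv], y_ext = y01[split$external])
  # pooled per-slot MCC over the outer test folds (diagnostic)
  base_mcc <- vapply(seq_len(nrow(slots)), function(s) {
    conf <- Reduce(`+`, lapply(folds, function(fd)
      confusion_table(fd$scores_test[, s] >= 0.5, fd$y_test == 1)))
    mcc(conf)
  }, numeric(1))
  structure(list(slots = slots, folds = folds, full = full,
                 base_mcc_cv = stats::setNames(base_mcc, slots$slot),
                 grid = grid, seed = seed, stacking = stacking,
                 peptide_length = lens),
            class = "cascade_state")
}

mask_members <- function(mask, k) which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0)

eval_jury_subset <- function(state, members, jury_hidden, seed) {
  mask <- sum(2^(members - 1))
  conf <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (f in seq_along(state$folds)) {
    fd <- state$folds[[f]]
    net <- train_jury_net(fd$scores_train[, members, drop = FALSE],
                          fd$y_train, jury_hidden,
                          child_seed(seed, mask * 64 + f))
    s <- score_jury_net(net, fd$scores_test[, members, drop = FALSE])
    conf <- conf + confusion_table(s >= 0.5, fd$y_test == 1)
  }
  net_ext <- train_jury_net(state$full$scores_cv[, members, drop = FALSE],
                            state$full$y_cv, jury_hidden,
                            child_seed(seed, mask * 64))
  s_ext <- score_jury_net(net_ext,
                          state$full$scores_ext[, members, drop = FALSE])
  c(mcc_cv = mcc(conf),
    mcc_ext = mcc(confusion_table(s_ext >= 0.5, state$full$y_ext == 1)))
}

#' Rank enumerated juries by the compromise selection rule
#'
#' Orders juries by descending min(MCC_cv, MCC_ext), breaking ties by
#' descending mean of the two, then by fewer members. Degenerate rows
#' (empty subset, NA performance) sort last.
#'
#' @param jury_table data.frame with columns `mcc_cv`, `mcc_ext`,
#'   `n_members`.
#' @return The table, reordered, with helper columns `min_mcc` and
#'   `mean_mcc`.
#' @export
rank_juries <- function(jury_table) {
  jt <- jury_table
  jt$min_mcc <- pmin(jt$mcc_cv, jt$mcc_ext)
  jt$mean_mcc <- (jt$mcc_cv + jt$mcc_ext) / 2
  key_min <- ifelse(is.na(jt$min_mcc), -Inf, jt$min_mcc)
  key_mean <- ifelse(is.na(jt$mean_mcc), -Inf, jt$mean_mcc)
  jt[order(-key_min, -key_mean, jt$n_members), , drop = FALSE]
}

#' Enumerate jury networks over base-classifier subsets
#'
#' Iterates member subsets of the base slots — all 2^k subsets of k slots
#' in exhaustive mode (the empty subset is recorded as degenerate, not
#' trained), or a forward-selection path in greedy mode — training a jury
#' network per subset and scoring it by pooled cross-validated MCC and by
#' external-set MCC. An exhaustive run over the full 12 slots evaluates
#' 2^12 = 4096 subsets.
#'
#' @param state A `"cascade_state"` from [train_base_stage()].
#' @param jury_hidden Hidden neurons of each jury network (default 3).
#' @param search `"exhaustive"` or `"greedy"`.
#' @param seed Integer seed.
#' @return data.frame ranked by [rank_juries()], one row per evaluated
#'   subset, columns `mask`, `members` (comma-separated slot names),
#'   `n_members`, `mcc_cv`, `mcc_ext`, `min_mcc`, `mean_mcc`; attribute
#'   `"n_evaluated"` counts iterated subsets (including the degenerate
#'   empty one in exhaustive mode).
#' @export
enumerate_juries <- function(state, jury_hidden = 3,
                             search = c("exhaustive", "greedy"), seed = 1) {
  stopifnot(inherits(state, "cascade_state"))
  search <- match.arg(search)
  k <- nrow(state$slots)
  row_for <- function(members) {
    if (length(members) == 0)
      return(data.frame(mask = 0, members = "", n_members = 0L,
                        mcc_cv = NA_real_, mcc_ext = NA_real_,
                        stringsAsFactors = FALSE))
    perf <- eval_jury_subset(state, members, jury_hidden, seed)
    data.frame(mask = sum(2^(members - 1)),
               members = paste(state$slots$slot[members], collapse = ","),
               n_members = length(members),
               mcc_cv = perf[["mcc_cv"]], mcc_ext = perf[["mcc_ext"]],
               stringsAsFactors = FALSE)
  }
  if (search == "exhaustive") {
    masks <- 0:(2^k - 1)
    rows <- lapply(masks, function(m) row_for(mask_members(m, k)))
    n_evaluated <- length(masks)
  } else {
    rows <- list(row_for(integer(0)))
    current <- integer(0)
    best_min <- -Inf
    repeat {
      candidates <- setdiff(seq_len(k), current)
      if (length(candidates) == 0) break
      cand_rows <- lapply(candidates, function(s) row_for(c(current, s)))
      mins <- vapply(cand_rows, function(r) min(r$mcc_cv, r$mcc_ext),
                     numeric(1))
      rows <- c(rows, cand_rows)
      if (max(mins) <= best_min) break
      best <- which.max(mins)
      current <- sort(c(current, candidates[best]))
      best_min <- mins[best]
    }
    n_evaluated <- length(rows)
  }
  out <- rank_juries(do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- n_evaluated
  out
}

#' Select the best jury and retrain it on the entire core set
#'
#' Takes the top-ranked jury (see [rank_juries()]), refits its member base
#' classifiers on the whole core set, trains the jury network on their
#' outputs, and returns the deployable model. The selection-stage MCCs are
#' stored alongside.
#'
#' @param ranked Ranked jury table from [enumerate_juries()].
#' @param data The entire curated core set.
#' @param state The `"cascade_state"` used for enumeration.
#' @param jury_hidden Hidden neurons (default 3, the final architecture).
#' @param seed Integer seed.
#' @param context A `"descriptor_context"`.
#' @return Object of class `"jury_model"`.
#' @export
select_and_retrain <- function(ranked, data, state, jury_hidden = 3,
                               seed = 1, context = descriptor_context()) {
  stopifnot(nrow(ranked) > 0)
  top <- ranked[!is.na(ranked$mcc_cv), , drop = FALSE][1, ]
  members <- mask_members(top$mask, nrow(state$slots))
  slots <- state$slots[members, , drop = FALSE]
  base_models <- lapply(seq_len(nrow(slots)), function(s)
    train_base(data, slots$descriptor[s], slots$scheme[s], state$grid,
               child_seed(seed, 8000 + members[s]), context))
  S <- base_score_matrix(base_models, data)
  y01 <- as.integer(data$label == "binder")
  net <- train_jury_net(S, y01, jury_hidden, child_seed(seed, 9000))
  structure(list(slots = slots, base_models = base_models, jury_net = net,
                 jury_hidden = jury_hidden, threshold = 0.5,
                 mcc_cv = top$mcc_cv, mcc_ext = top$mcc_ext,
                 peptide_length = state$peptide_length,
                 jury_table = ranked, n_core = nrow(data), seed = seed),
            class = "jury_model")
}

#' Fit the full cascaded model
#'
#' End-to-end workflow: stratified 4:1 cross-validation/external split,
#' base-classifier training with inner 5-fold grid search per outer fold,
#' jury subset enumeration, compromise selection, and retraining on the
#' entire core set.
#'
#' @param data Curated labeled peptide set (one shared length, both
#'   classes).
#' @param descriptors,schemes Base-slot definition (default all 6 x 2).
#' @param grid A `"grid_spec"`.
#' @param n_folds Outer cross-validation folds (default 10).
#' @param external_fraction External-set fraction (default 1/5).
#' @param jury_hidden Jury hidden neurons (default 3).
#' @param search `"exhaustive"` or `"greedy"` jury search.
#' @param stacking `"faithful"` or `"cv"` (see [train_base_stage()]).
#' @param seed Single pipeline seed; all stage seeds derive from it.
#' @param context A `"descriptor_context"`; built once if missing.
#' @return A `"jury_model"` with the ranked `jury_table`, selection-stage
#'   `mcc_cv` / `mcc_ext`, and per-slot diagnostics in
#'   `attr(, "base_mcc_cv")`.
#' @export
cascade_fit <- function(data, descriptors = DESCRIPTOR_IDS,
                        schemes = SCHEME_IDS, grid = grid_spec(),
                        n_folds = 10, external_fraction = 1 / 5,
                        jury_hidden = 3,
                        search = c("exhaustive", "greedy"),
                        stacking = c("faithful", "cv"),
                        seed = 1, context = NULL) {
  search <- match.arg(search)
  stacking <- match.arg(stacking)
  if (is.null(context)) context <- descriptor_context()
  split <- split_peptides(data, external_fraction, n_folds,
                          child_seed(seed, 10))
  slots <- base_slots(descriptors, schemes)
  state <- train_base_stage(data, split, slots, grid,
                            child_seed(seed, 20), context, stacking)
  ranked <- enumerate_juries(state, jury_hidden, search,
                             child_seed(seed, 30))
  model <- select_and_retrain(ranked, data, state, jury_hidden,
                              child_seed(seed, 40), context)
  attr(model, "base_mcc_cv") <- state$base_mcc_cv
  attr(model, "split") <- split
  model
}

#' Score peptides with a trained jury model
#'
#' @param model A `"jury_model"`.
#' @param sequences Character vector of peptides of the trained length.
#' @return Numeric scores in [0, 1); values at or above the threshold
#'   (0.5) indicate predicted binders.
#' @export
jury_score <- function(model, sequences) {
  stopifnot(inherits(model, "jury_model"))
  sequences <- validate_peptides(sequences, model$peptide_length)
  S <- base_score_matrix(model$base_models, sequences)
  as.numeric(score_jury_net(model$jury_net, S))
}

#' @export
#' @rdname jury_score
#' @param object A `"jury_model"`.
#' @param newdata Character vector of sequences or data.frame with a
#'   `sequence` column.
#' @param ... Unused.
predict.jury_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$sequence
  s <- jury_score(object, newdata)
  data.frame(sequence = newdata, score = s,
             class = ifelse(s >= object$threshold, "binder", "non-binder"),
             stringsAsFactors = FALSE)
}

#' @export
print.jury_model <- function(x, ...) {
  cat("Cascaded jury model (", nrow(x$slots), " base classifiers, ",
      x$jury_hidden, " jury hidden neurons)\n", sep = "")
  cat("members:", paste(x$slots$slot, collapse = ", "), "\n")
  cat(sprintf("selection-stage MCC: cross-validated %.3f, external %.3f\n",
              x$mcc_cv, x$mcc_ext))
  cat("retrained on", x$n_core, "core peptides of length",
      x$peptide_length, "\n")
  invisible(x)
}

#' Persist / reload a trained jury model
#'
#' The archive stores the full model (descriptor context, base-classifier
#' fits, jury network, member slots, selection-stage MCCs) with a format
#' version; reloading reproduces predictions bit-for-bit.
#'
#' @param model A `"jury_model"`.
#' @param path Destination file.
#' @return `path` (save) / the model (load).
#' @export
save_jury_model <- function(model, path) {
  stopifnot(inherits(model, "jury_model"))
  saveRDS(list(format = "pepcascade-jury-1", model = model), path)
  invisible(path)
}

#' @rdname save_jury_model
#' @export
load_jury_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pepcascade-jury-1"))
    stop("not a pepcascade jury-model archive")
  obj$model
}
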