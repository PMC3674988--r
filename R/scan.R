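#' @title Wildcard fragment dissection and proteome scanning
#' @name scan
#' @description
#' Tools for dissecting a reference epitope in silico: enumerate the
#' wildcard octapeptide groups that contain each contiguous fragment of the
#' reference at its original register (e.g. `xIINFEKL` for the C-terminal
#' heptapeptide of SIINFEKL), score the groups with a trained jury model,
#' profile the per-position effect of randomization, and slide a scoring
#' window across protein sequences.
NULL

#' Wildcard fragment patterns of a reference peptide
#'
#' One pattern per contiguous substring of the reference with length in
#' `[min_len, L]`, pinned at its original register with `x` at every other
#' position. The full-length "pattern" (the reference itself) is included
#' only when `include_full = TRUE`. Ordered by fragment length descending,
#' then start position.
#'
#' @param reference Reference peptide (e.g. an octapeptide epitope).
#' @param min_len Minimum fragment length (default 3, a tripeptide).
#' @param include_full Include the full-length fragment (default FALSE).
#' @return data.frame with columns `template`, `fragment`, `start`,
#'   `length`; class `"fragment_patterns"`.
#' @export
#' @examples
#' fragment_patterns("SIINFEKL")  # 20 patterns, lengths 7 down to 3
fragment_patterns <- function(reference, min_len = 3, include_full = FALSE) {
  reference <- validate_peptides(reference)
  stopifnot(length(reference) == 1, min_len >= 1)
  L <- nchar(reference)
  if (min_len > L) stop("min_len exceeds the reference length (", L, ")")
  max_len <- if (include_full) L else L - 1L
  if (min_len > max_len)
    stop("no fragments in [", min_len, ", ", max_len, "]")
  rows <- list()
  for (len in seq(max_len, min_len)) {
    for (start in seq_len(L - len + 1)) {
      frag <- substr(reference, start, start + len - 1)
      tmpl <- paste(rep("x", L), collapse = "")
      substr(tmpl, start, start + len - 1) <- frag
      rows[[length(rows) + 1]] <- data.frame(template = tmpl,
                                             fragment = frag,
                                             start = start, length = len,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fragment_patterns", "data.frame")
  out
}

parse_pattern <- function(template) {
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  wild <- chars == "x"
  if (any(!wild & !chars %in% AA_ALPHABET))
    stop("pattern may contain only canonical residues and 'x'")
  list(chars = chars, wild = which(wild), fixed = which(!wild))
}

#' Enumerate the peptides matching a wildcard pattern
#'
#' Expands the `k` wildcard positions of the pattern over the 20 canonical
#' residues: exhaustively when `20^k <= cap`, otherwise as a uniform seeded
#' sample of `cap` peptides (the `"sampled"` attribute records which).
#' Fixed (non-`x`) positions are never altered.
#'
#' @param template Pattern string, e.g. `"xIINFEKL"`.
#' @param cap Enumeration cap (default 160000 = 20^4, so groups with up to
#'   four wildcards are exhaustive).
#' @param seed Seed for the sampled mode.
#' @return Character vector of peptides with attributes `sampled`
#'   (logical) and `group_size` (the exact group size `20^k`).
#' @export
#' @examples
#' length(enumerate_group("xIINFEKL"))  # 20
enumerate_group <- function(template, cap = 160000, seed = 1) {
  p <- parse_pattern(template)
  k <- length(p$wild)
  exact <- 20^k
  if (k == 0) {
    out <- paste(p$chars, collapse = "")
  } else if (exact <= cap) {
    combos <- expand.grid(rep(list(AA_ALPHABET), k),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- matrix(rep(p$chars, each = nrow(combos)), nrow = nrow(combos))
    for (j in seq_len(k)) m[, p$wild[j]] <- combos[[j]]
    out <- apply(m, 1, paste, collapse = "")
  } else {
    set.seed(as.integer(child_seed(seed, 2)))
    m <- matrix(rep(p$chars, each = cap), nrow = cap)
    for (j in seq_len(k))
      m[, p$wild[j]] <- sample(AA_ALPHABET, cap, replace = TRUE)
    out <- apply(m, 1, paste, collapse = "")
  }
  structure(out, sampled = k > 0 && exact > cap, group_size = exact)
}

#' Score distribution of one fragment group
#'
#' Scores every enumerated (or sampled) peptide of the pattern's group with
#' the jury model and summarizes the distribution by median and quartiles —
#' the group medians are the quantity the dissection analysis compares.
#'
#' @param model A `"jury_model"`.
#' @param template Pattern string of the model's peptide length.
#' @param cap,seed Passed to [enumerate_group()].
#' @return One-row data.frame: `template`, `n_peptides`, `median`, `q1`,
#'   `q3`, `sampled`, `seed`.
#' @export
group_score_summary <- function(model, template, cap = 160000, seed = 1) {
  stopifnot(inherits(model, "jury_model"))
  if (nchar(template) != model$peptide_length)
    stop("pattern length must be ", model$peptide_length)
  peps <- enumerate_group(template, cap, seed)
  s <- jury_score(model, peps)
  q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(template = template, n_peptides = length(peps),
             median = q[2], q1 = q[1], q3 = q[3],
             sampled = attr(peps, "sampled"), seed = seed,
             stringsAsFactors = FALSE)
}

#' Score all fragment groups of a reference epitope
#'
#' Convenience wrapper: [fragment_patterns()] + [group_score_summary()]
#' per pattern.
#'
#' @param model A `"jury_model"`.
#' @param reference Reference peptide of the model's length.
#' @param min_len,include_full Passed to [fragment_patterns()].
#' @param cap,seed Passed to [enumerate_group()].
#' @return data.frame, one row per pattern, with the pattern columns plus
#'   the score summary.
#' @export
dissect_epitope <- function(model, reference, min_len = 3,
                            include_full = FALSE, cap = 160000, seed = 1) {
  pats <- fragment_patterns(reference, min_len, include_full)
  summaries <- do.call(rbind, lapply(pats$template, function(t)
    group_score_summary(model, t, cap, seed)))
  cbind(pats, summaries[, setdiff(names(summaries), "template")])
}

#' Per-position randomization effect profile
#'
#' For each sequence position p of the reference, scores the group with
#' only position p randomized (the reference residue everywhere else) and
#' reports the median score of that group and its drop relative to the
#' reference's own score. Positions whose randomization drops the median
#' most are the putative anchor positions; the table is sorted by
#' descending drop.
#'
#' @param model A `"jury_model"`.
#' @param reference Reference peptide of the model's length.
#' @param cap,seed Passed to [enumerate_group()] (single-position groups
#'   have 20 members, so enumeration is always exhaustive in practice).
#' @return data.frame with columns `position`, `residue`, `group_median`,
#'   `drop` (reference score minus group median), sorted by `drop`
#'   descending; attribute `"reference_score"`.
#' @export
position_effect_profile <- function(model, reference, cap = 160000,
                                    seed = 1) {
  reference <- validate_peptides(reference, model$peptide_length)
  ref_score <- jury_score(model, reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  L <- length(chars)
  rows <- lapply(seq_len(L), function(p) {
    tmpl <- reference
    substr(tmpl, p, p) <- "x"
    gs <- group_score_summary(model, tmpl, cap, seed)
    data.frame(position = p, residue = chars[p],
               group_median = gs$median, drop = ref_score - gs$median,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_score") <- ref_score
  out
}

#' Slide a scoring window across protein sequences
#'
#' Scores every contiguous window of the model's peptide length in every
#' input protein (forward sequence only; 1-based inclusive coordinates).
#' Windows containing non-canonical residues are skipped and counted. The
#' summary reports the fraction of scored windows at or above the
#' confidence threshold.
#'
#' @param model A `"jury_model"`.
#' @param sequences Named character vector of protein sequences, or a path
#'   to a FASTA file.
#' @param threshold Confidence threshold on the prediction score (default
#'   0.99).
#' @return List of class `"proteome_scan"`: `windows` (data.frame
#'   `protein`, `start`, `end`, `peptide`, `score`) and `summary` (list
#'   `n_windows`, `n_scored`, `n_skipped`, `threshold`,
#'   `fraction_confident`).
#' @export
scan_proteome <- function(model, sequences, threshold = 0.99) {
  stopifnot(inherits(model, "jury_model"))
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- read_peptides(sequences)
  if (length(sequences) == 0) stop("no protein sequences supplied")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("protein", seq_along(sequences))
  w <- model$peptide_length
  all_rows <- list()
  n_windows <- 0L; n_skipped <- 0L
  for (id in names(sequences)) {
    seqc <- toupper(sequences[[id]])
    L <- nchar(seqc)
    if (L < w) next
    starts <- seq_len(L - w + 1)
    n_windows <- n_windows + length(starts)
    peps <- substring(seqc, starts, starts + w - 1)
    canonical <- !vapply(peptide_residues(peps),
                         function(r) any(!r %in% AA_ALPHABET), logical(1))
    n_skipped <- n_skipped + sum(!canonical)
    if (!any(canonical)) next
    all_rows[[id]] <- data.frame(protein = id, start = starts[canonical],
                                 end = starts[canonical] + w - 1,
                                 peptide = peps[canonical],
                                 stringsAsFactors = FALSE)
  }
  windows <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(protein = character(0), start = integer(0),
               end = integer(0), peptide = character(0))
  if (nrow(windows) > 0)
    windows$score <- jury_score(model, windows$peptide)
  else windows$score <- numeric(0)
  rownames(windows) <- NULL
  structure(list(windows = windows,
                 summary = list(n_windows = n_windows,
                                n_scored = nrow(windows),
                                n_skipped = n_skipped,
                                threshold = threshold,
                                fraction_confident =
                                  if (nrow(windows) > 0)
                                    mean(windows$score >= threshold)
                                  else NA_real_)),
            class = "proteome_scan")
}

#' @export
print.proteome_scan <- function(x, ...) {
  s <- x$summary
  cat("Proteome scan:", s$n_scored, "windows scored (", s$n_skipped,
      "skipped of", s$n_windows, "total )\n")
  cat(sprintf("fraction with score >= %.2f: %.4f\n", s$threshold,
              s$fraction_confident))
  invisible(x)
}
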