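#' @title Labeled peptide sets: curation, splitting, synthesis
#' @name datagen
#' @description
#' A labeled peptide set is a `data.frame` with columns `sequence` and
#' `label` (values `"binder"` / `"non-binder"`). [curate_peptides()] applies
#' the core-set filter (length, canonical alphabet, duplicate collapse,
#' ambiguity drop), [split_peptides()] produces the stratified
#' cross-validation / external-validation partition, and
#' [generate_peptides()] draws seeded synthetic sets with planted
#' anchor-position motifs for end-to-end testing.
NULL

PEPTIDE_LABELS <- c("binder", "non-binder")

check_peptide_set <- function(data) {
  if (!is.data.frame(data) || !all(c("sequence", "label") %in% names(data)))
    stop("expected a data.frame with columns 'sequence' and 'label'")
  if (!all(data$label %in% PEPTIDE_LABELS))
    stop("labels must be 'binder' or 'non-binder'")
  invisible(data)
}

#' Curate a raw labeled peptide table into a core set
#'
#' Applies, in order: (1) keep only sequences made of the 20 canonical
#' amino-acid codes; (2) keep only sequences of `target_length`;
#' (3) collapse exact duplicate records with a consistent label to one
#' record; (4) drop every record of any sequence observed with conflicting
#' labels (the ambiguity filter — both copies are removed, no majority
#' vote). Counts kept/dropped per rule are attached as the `"curation"`
#' attribute and printed.
#'
#' Curation is idempotent: re-curating a curated set changes nothing.
#'
#' @param records data.frame with columns `sequence`, `label`.
#' @param target_length Required peptide length (default 8).
#' @param quiet Suppress the count report.
#' @return Curated data.frame (columns `sequence`, `label`), attribute
#'   `"curation"` holding the per-rule counts.
#' @export
#' @examples
#' raw <- data.frame(sequence = c("SIINFEKL", "SIINFEKL", "AAAAAAAA"),
#'                   label = c("binder", "binder", "non-binder"))
#' curate_peptides(raw)
curate_peptides <- function(records, target_length = 8, quiet = FALSE) {
  check_peptide_set(records)
  if (nrow(records) == 0) stop("'records' is empty")
  seqs <- toupper(records$sequence)
  canonical <- !vapply(peptide_residues(seqs),
                       function(r) any(!r %in% AA_ALPHABET) || length(r) == 0,
                       logical(1))
  n_noncanonical <- sum(!canonical)
  records <- data.frame(sequence = seqs[canonical],
                        label = records$label[canonical],
                        stringsAsFactors = FALSE)
  right_len <- nchar(records$sequence) == target_length
  n_wrong_length <- sum(!right_len)
  records <- records[right_len, , drop = FALSE]
  n_before_dedup <- nrow(records)
  records <- unique(records)
  n_duplicates <- n_before_dedup - nrow(records)
  conflicted <- names(which(table(records$sequence) > 1))
  n_ambiguous <- sum(records$sequence %in% conflicted)
  records <- records[!records$sequence %in% conflicted, , drop = FALSE]
  if (nrow(records) == 0)
    stop("no records survive curation")
  rownames(records) <- NULL
  counts <- c(non_canonical = n_noncanonical, wrong_length = n_wrong_length,
              duplicates_collapsed = n_duplicates,
              ambiguous_dropped = n_ambiguous, kept = nrow(records))
  attr(records, "curation") <- counts
  if (!quiet)
    message("curated core set: ", counts[["kept"]], " peptides (",
            sum(records$label == "binder"), " binders, ",
            sum(records$label == "non-binder"), " non-binders); dropped ",
            n_noncanonical, " non-canonical, ", n_wrong_length,
            " wrong-length, ", n_duplicates, " duplicates, ",
            n_ambiguous, " ambiguous")
  records
}

#' Stratified cross-validation / external-validation split
#'
#' Splits a curated set into an external validation set (default one fifth,
#' i.e. a 4:1 ratio) and `n_folds` cross-validation folds, stratified by
#' label so class proportions are preserved everywhere. The external set is
#' never touched during model selection. Reproducible under `seed`.
#'
#' @param data Curated labeled peptide set.
#' @param external_fraction Fraction assigned to the external set (default
#'   1/5); must be strictly positive (the jury selection rule needs an
#'   external estimate).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return List with `folds` (list of integer row-index vectors into
#'   `data`), `external` (integer row indices), and `cv` (all
#'   non-external indices); class `"peptide_split"`.
#' @export
split_peptides <- function(data, external_fraction = 1 / 5, n_folds = 10,
                           seed = 1) {
  check_peptide_set(data)
  if (external_fraction <= 0 || external_fraction >= 1)
    stop("'external_fraction' must be in (0, 1): the selection rule ",
         "requires a non-empty external validation set")
  if (nrow(data) < 2 * n_folds) stop("too few records to split")
  rng <- local({ set.seed(as.integer(child_seed(seed, 0)));
                 sample.int(nrow(data)) })
  external <- integer(0)
  fold_of <- integer(nrow(data))
  for (lab in unique(data$label)) {
    idx <- rng[data$label[rng] == lab]  # shuffled indices of this class
    n_ext <- round(length(idx) * external_fraction)
    external <- c(external, idx[seq_len(n_ext)])
    rest <- idx[-seq_len(n_ext)]
    fold_of[rest] <- rep_len(seq_len(n_folds), length(rest))
  }
  cv <- setdiff(seq_len(nrow(data)), external)
  folds <- lapply(seq_len(n_folds), function(f) cv[fold_of[cv] == f])
  if (any(lengths(folds) == 0)) stop("empty fold; reduce n_folds")
  structure(list(folds = folds, external = sort(external), cv = sort(cv)),
            class = "peptide_split")
}

#' Specification of a planted-motif synthetic peptide set
#'
#' Describes the generative model for synthetic binder/non-binder sets:
#' binders draw each anchor position from its preferred residue set with
#' probability `enrichment` (and from the background otherwise); all other
#' positions, and every position of a non-binder, draw from `background`.
#' Non-binders accidentally matching *all* anchor sets are rejected and
#' redrawn. Finally each label is flipped with probability `label_noise`.
#'
#' The default anchors are the canonical H-2Kb octapeptide motif: tyrosine
#' at position 3 (secondary anchor), tyrosine/phenylalanine at position 5
#' and an aliphatic residue at position 8 (main anchors).
#'
#' @param length Peptide length (default 8).
#' @param anchors Named list: position (as character) -> preferred residue
#'   set.
#' @param enrichment Probability an anchor position is drawn from its
#'   preferred set (default 0.9).
#' @param background Residue sampling weights, named by amino acid (default
#'   uniform over the 20 canonical residues).
#' @param label_noise Label flip probability (default 0.05).
#' @param n_pos,n_neg Number of binders / non-binders (default 500 each).
#' @param seed Integer seed (mandatory for pipeline runs).
#' @return List of class `"motif_spec"`.
#' @export
motif_spec <- function(length = 8,
                       anchors = list(`3` = "Y",
                                      `5` = c("Y", "F"),
                                      `8` = c("L", "M", "I", "V")),
                       enrichment = 0.9,
                       background = NULL,
                       label_noise = 0.05,
                       n_pos = 500, n_neg = 500, seed = 1) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(length >= 1, enrichment >= 0, enrichment <= 1,
            label_noise >= 0, label_noise < 1, n_pos >= 0, n_neg >= 0)
  pos <- as.integer(names(anchors))
  if (any(is.na(pos)) || any(pos < 1) || any(pos > length))
    stop("anchor positions must lie in [1, length]")
  if (!all(unlist(anchors) %in% AA_ALPHABET))
    stop("anchor residues must be canonical amino acids")
  bg <- background[AA_ALPHABET]
  if (anyNA(bg) || any(bg < 0) || sum(bg) <= 0)
    stop("'background' must assign non-negative weight to all 20 residues")
  bg <- bg / sum(bg)
  # infeasible if the background excludes every residue of some anchor set
  for (p in names(anchors))
    if (all(bg[anchors[[p]]] == 0) && enrichment < 1)
      stop("background excludes all residues of the anchor set at position ",
           p)
  structure(list(length = length, anchors = anchors,
                 enrichment = enrichment, background = bg,
                 label_noise = label_noise, n_pos = n_pos, n_neg = n_neg,
                 seed = seed),
            class = "motif_spec")
}

#' A reference peptide matching every planted anchor
#'
#' Builds the motif consensus: the first preferred residue at each anchor
#' position and the most probable background residue elsewhere. Useful as
#' the reference for position-effect profiling on synthetic models.
#'
#' @param spec A `"motif_spec"`.
#' @return Peptide sequence string.
#' @export
motif_consensus <- function(spec) {
  stopifnot(inherits(spec, "motif_spec"))
  res <- rep(names(which.max(spec$background)), spec$length)
  for (p in names(spec$anchors))
    res[as.integer(p)] <- spec$anchors[[p]][1]
  paste(res, collapse = "")
}

matches_all_anchors <- function(residue_matrix, spec) {
  ok <- rep(TRUE, nrow(residue_matrix))
  for (p in names(spec$anchors))
    ok <- ok & residue_matrix[, as.integer(p)] %in% spec$anchors[[p]]
  ok
}

#' Generate a synthetic labeled peptide set
#'
#' Draws peptides under a planted-motif model (see [motif_spec()]); seeded
#' and reproducible.
#'
#' @param spec A `"motif_spec"`.
#' @return data.frame with columns `sequence`, `label`; attribute
#'   `"motif_spec"` carries the generating spec.
#' @export
#' @examples
#' d <- generate_peptides(motif_spec(n_pos = 20, n_neg = 20, seed = 7))
#' table(d$label)
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "motif_spec"))
  set.seed(as.integer(child_seed(spec$seed, 1)))
  L <- spec$length
  draw_bg <- function(n) matrix(sample(AA_ALPHABET, n * L, replace = TRUE,
                                       prob = spec$background),
                                nrow = n, ncol = L)
  # binders: anchor positions from preferred sets with prob `enrichment`
  pos_m <- draw_bg(spec$n_pos)
  if (spec$n_pos > 0) {
    for (p in names(spec$anchors)) {
      j <- as.integer(p)
      hit <- stats::runif(spec$n_pos) < spec$enrichment
      pos_m[hit, j] <- sample(spec$anchors[[p]], sum(hit), replace = TRUE)
    }
  }
  # non-binders: pure background, rejecting full-motif matches
  neg_m <- draw_bg(spec$n_neg)
  if (spec$n_neg > 0 && length(spec$anchors) > 0) {
    repeat {
      bad <- which(matches_all_anchors(neg_m, spec))
      if (length(bad) == 0) break
      neg_m[bad, ] <- draw_bg(length(bad))
    }
  }
  seqs <- c(apply(pos_m, 1, paste, collapse = ""),
            apply(neg_m, 1, paste, collapse = ""))
  labels <- rep(PEPTIDE_LABELS, c(spec$n_pos, spec$n_neg))
  if (spec$label_noise > 0) {
    flip <- stats::runif(length(labels)) < spec$label_noise
    labels[flip] <- ifelse(labels[flip] == "binder", "non-binder", "binder")
  }
  out <- data.frame(sequence = seqs, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "motif_spec") <- spec
  out
}

#' Read / write labeled peptide tables
#'
#' CSV or TSV with columns `sequence` and `label` (delimiter inferred from
#' the file extension).
#'
#' @param path File path.
#' @return data.frame with columns `sequence`, `label`.
#' @export
read_peptide_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  check_peptide_set(df)
  df[, c("sequence", "label")]
}

#' @rdname read_peptide_table
#' @param data Labeled peptide set to write.
#' @export
write_peptide_table <- function(data, path) {
  check_peptide_set(data)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Map an immune-epitope database export to a labeled peptide table
#'
#' Optional adapter for qualitative binding exports: give the column names
#' holding the sequence and the qualitative label, and the label values to
#' treat as positive/negative; everything else is dropped.
#'
#' @param df Raw export data.frame.
#' @param sequence_col,label_col Column names.
#' @param positive_values,negative_values Label values mapped to binder /
#'   non-binder.
#' @return data.frame with columns `sequence`, `label`.
#' @export
adapt_epitope_export <- function(df, sequence_col = "Description",
                                 label_col = "Qualitative Measure",
                                 positive_values = c("Positive",
                                                     "Positive-High",
                                                     "Positive-Intermediate",
                                                     "Positive-Low"),
                                 negative_values = "Negative") {
  if (!all(c(sequence_col, label_col) %in% names(df)))
    stop("columns '", sequence_col, "' / '", label_col, "' not found")
  lab <- rep(NA_character_, nrow(df))
  lab[df[[label_col]] %in% positive_values] <- "binder"
  lab[df[[label_col]] %in% negative_values] <- "non-binder"
  keep <- !is.na(lab)
  data.frame(sequence = toupper(df[[sequence_col]][keep]), label = lab[keep],
             stringsAsFactors = FALSE)
}
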