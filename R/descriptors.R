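#' @title Peptide sequence descriptors
#' @description
#' Six numeric encodings of peptide sequences used as base-classifier
#' inputs: AAFREQ (amino-acid frequencies, 20), BINAATYPE (per-residue
#' 6-bit pharmacophore feature flags, 6L), BINPEP (per-residue 5-bit
#' identity codes, 5L), PEPCATS (topological pharmacophore pair descriptor,
#' 21 pair types x 7 distance bins = 147, length-independent), PPCA
#' (per-residue 19 property principal-component scores, 19L), and PPCALI
#' (auto-correlated length-invariant variant of PPCA, 19 x (max_lag+1) =
#' 152 by default).
#' @name descriptors
NULL

#' Identifiers of the six peptide descriptors
#' @format Character vector of length 6.
#' @export
DESCRIPTOR_IDS <- c("AAFREQ", "BINAATYPE", "BINPEP", "PEPCATS", "PPCA",
                    "PPCALI")

# 21 unordered feature-pair names in fixed order (LL, LR, ..., NN)
pepcats_pair_names <- function() {
  f <- PHARMACOPHORE_FEATURES
  out <- character(0)
  for (i in seq_along(f))
    for (j in i:length(f))
      out <- c(out, paste0(f[i], f[j]))
  out
}

#' Amino-acid frequency descriptor (AAFREQ)
#'
#' Counts each of the 20 canonical amino acids in the peptide, reported as
#' integers in the fixed alphabet order A, R, N, D, C, Q, E, G, H, I, L, K,
#' M, F, P, S, T, W, Y, V. The counts sum to the peptide length.
#'
#' @param peptide A single peptide sequence.
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' encode_aafreq("SIINFEKL")
encode_aafreq <- function(peptide) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1)
  res <- peptide_residues(peptide)[[1]]
  counts <- table(factor(res, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts), AA_ALPHABET)
}

#' Binary identity descriptor (BINPEP)
#'
#' Encodes the identity of each residue as five bits: the binary
#' representation of the residue's index (0-19) in the fixed alphabet order.
#' Any injective 5-bit code suffices for a learner; the index code makes the
#' encoding trivially invertible. Dimension 5L.
#'
#' @param peptide A single peptide sequence.
#' @return Numeric 0/1 vector of length `5 * nchar(peptide)`, named
#'   `pos<i>.b<k>` with b1 the most significant bit.
#' @export
encode_binpep <- function(peptide) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1)
  res <- peptide_residues(peptide)[[1]]
  idx <- match(res, AA_ALPHABET) - 1L
  bits <- vapply(idx, function(v) as.numeric(bitwAnd(bitwShiftR(v, 4:0), 1L)),
                 numeric(5))
  out <- as.numeric(bits)
  names(out) <- paste0("pos", rep(seq_along(res), each = 5), ".b", 1:5)
  out
}

#' Decode a binary identity descriptor back to a sequence
#'
#' Inverse of [encode_binpep()]; mainly a consistency check.
#'
#' @param bits Numeric 0/1 vector of length divisible by 5.
#' @return Peptide sequence string.
#' @export
decode_binpep <- function(bits) {
  stopifnot(length(bits) %% 5 == 0, all(bits %in% c(0, 1)))
  m <- matrix(bits, nrow = 5)
  idx <- as.integer(crossprod(m, 2^(4:0))) + 1L
  if (any(idx > 20)) stop("invalid 5-bit code")
  paste(AA_ALPHABET[idx], collapse = "")
}

#' Binary pharmacophore-type descriptor (BINAATYPE)
#'
#' Represents each residue by six bits flagging the presence of each
#' pharmacophore feature (order L, R, A, D, P, N) on its side chain, per the
#' assignment table. Dimension 6L.
#'
#' @param peptide A single peptide sequence.
#' @param table Pharmacophore table (default packaged table).
#' @return Numeric 0/1 vector of length `6 * nchar(peptide)`.
#' @export
encode_binaatype <- function(peptide, table = default_pharmacophore_table()) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1)
  res <- peptide_residues(peptide)[[1]]
  out <- vapply(res,
                function(aa) as.numeric(PHARMACOPHORE_FEATURES %in% table[[aa]]),
                numeric(6))
  out <- as.numeric(out)
  names(out) <- paste0("pos", rep(seq_along(res), each = 6), ".",
                       PHARMACOPHORE_FEATURES)
  out
}

#' Topological pharmacophore pair descriptor (PEPCATS)
#'
#' Counts pharmacophore feature pairs at sequence-position separations
#' `min_dist .. max_dist`. For every residue pair (i, j) with separation
#' d = j - i in the range, each cross-product of a feature on residue i with
#' a feature on residue j increments the bin of the unordered feature-pair
#' type at distance d. Each bin is then divided by the total count of its
#' pair type over all distances; bins of an unseen pair type stay 0, so the
#' seven bins of every occupied pair type sum to 1. With the default range
#' 1..7 the descriptor has 21 x 7 = 147 dimensions, independent of peptide
#' length.
#'
#' @param peptide A single peptide sequence.
#' @param table Pharmacophore table.
#' @param max_dist Largest separation counted (default 7).
#' @param min_dist Smallest separation counted (default 1; set to 0 to also
#'   count intra-residue feature pairs).
#' @return Named numeric vector of length `21 * (max_dist - min_dist + 1)`.
#' @export
#' @examples
#' length(encode_pepcats("SIINFEKL"))  # 147
encode_pepcats <- function(peptide, table = default_pharmacophore_table(),
                           max_dist = 7, min_dist = 1) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1, max_dist >= min_dist, min_dist >= 0)
  res <- peptide_residues(peptide)[[1]]
  L <- length(res)
  pairs <- pepcats_pair_names()
  dists <- min_dist:max_dist
  counts <- matrix(0, nrow = length(pairs), ncol = length(dists),
                   dimnames = list(pairs, paste0("d", dists)))
  feats <- lapply(res, function(aa) table[[aa]])
  for (d in dists) {
    if (d > L - 1 && d > 0) next
    for (i in seq_len(L - d)) {
      f1 <- feats[[i]]; f2 <- feats[[i + d]]
      if (length(f1) == 0 || length(f2) == 0) next
      for (a in f1) for (b in f2) {
        key <- if (match(a, PHARMACOPHORE_FEATURES) <=
                   match(b, PHARMACOPHORE_FEATURES))
          paste0(a, b) else paste0(b, a)
        # self-pairs at d = 0 would otherwise be counted twice
        if (d == 0 && a != b && match(a, PHARMACOPHORE_FEATURES) >
              match(b, PHARMACOPHORE_FEATURES)) next
        counts[key, paste0("d", d)] <- counts[key, paste0("d", d)] + 1
      }
    }
  }
  totals <- rowSums(counts)
  occupied <- totals > 0
  counts[occupied, ] <- counts[occupied, , drop = FALSE] / totals[occupied]
  out <- as.numeric(t(counts))
  names(out) <- paste0(rep(pairs, each = length(dists)), ".",
                       rep(paste0("d", dists), times = length(pairs)))
  out
}

#' Property principal-component descriptor (PPCA)
#'
#' Represents each residue by its 19 principal-component scores from the
#' property-scale PCA, concatenated in sequence order. Dimension 19L.
#'
#' @param peptide A single peptide sequence.
#' @param scores A `"pca_scores"` object from [build_pca_scores()].
#' @return Numeric vector of length `19 * nchar(peptide)`.
#' @export
encode_ppca <- function(peptide, scores) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1, inherits(scores, "pca_scores"))
  res <- peptide_residues(peptide)[[1]]
  m <- scores$scores[res, , drop = FALSE]
  out <- as.numeric(t(m))
  names(out) <- paste0("pos", rep(seq_along(res), each = 19), ".PC", 1:19)
  out
}

#' Auto-correlated property descriptor (PPCALI)
#'
#' Length-invariant variant of the property principal-component encoding:
#' for each correlation distance d in 0..max_lag and each of the 19 score
#' dimensions k, the sum over positions i of `x[i,k] * x[i+d,k]` is emitted,
#' concatenated by lag. Lags with no valid position pair (d >= L) contribute
#' zeros. Default max_lag 7 gives 19 x 8 = 152 dimensions.
#'
#' @param peptide A single peptide sequence.
#' @param scores A `"pca_scores"` object.
#' @param max_lag Largest correlation distance (default 7).
#' @return Numeric vector of length `19 * (max_lag + 1)`.
#' @export
encode_ppcali <- function(peptide, scores, max_lag = 7) {
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1, inherits(scores, "pca_scores"),
            max_lag >= 0)
  res <- peptide_residues(peptide)[[1]]
  L <- length(res)
  m <- scores$scores[res, , drop = FALSE]  # L x 19
  out <- numeric(19 * (max_lag + 1))
  for (d in 0:max_lag) {
    if (d <= L - 1) {
      i <- seq_len(L - d)
      block <- colSums(m[i, , drop = FALSE] * m[i + d, , drop = FALSE])
    } else block <- numeric(19)
    out[(d * 19 + 1):(d * 19 + 19)] <- block
  }
  names(out) <- paste0("lag", rep(0:max_lag, each = 19), ".PC", 1:19)
  out
}

#' Descriptor context: the tables shared by all encoders
#'
#' Bundles the pharmacophore assignment table and the property PCA scores so
#' they are computed once per pipeline run.
#'
#' @param table Pharmacophore table.
#' @param scores `"pca_scores"` object; built from the default property
#'   scales if missing.
#' @return List with elements `table` and `scores`, class
#'   `"descriptor_context"`.
#' @export
descriptor_context <- function(table = default_pharmacophore_table(),
                               scores = NULL) {
  if (is.null(scores)) scores <- build_pca_scores()
  stopifnot(inherits(table, "pharmacophore_table"),
            inherits(scores, "pca_scores"))
  structure(list(table = table, scores = scores),
            class = "descriptor_context")
}

#' Encode a set of peptides into one descriptor space
#'
#' @param sequences Character vector of peptides (equal length required for
#'   the position-resolved descriptors used in one model).
#' @param descriptor One of [DESCRIPTOR_IDS].
#' @param context A `"descriptor_context"`.
#' @return Numeric matrix, one row per peptide, named descriptor columns.
#' @export
#' @examples
#' ctx <- descriptor_context()
#' dim(encode_peptides(c("SIINFEKL", "AAAAAAAA"), "PEPCATS", ctx))
encode_peptides <- function(sequences, descriptor,
                            context = descriptor_context()) {
  descriptor <- match.arg(descriptor, DESCRIPTOR_IDS)
  sequences <- validate_peptides(sequences)
  enc <- switch(descriptor,
    AAFREQ    = function(p) encode_aafreq(p),
    BINAATYPE = function(p) encode_binaatype(p, context$table),
    BINPEP    = function(p) encode_binpep(p),
    PEPCATS   = function(p) encode_pepcats(p, context$table),
    PPCA      = function(p) encode_ppca(p, context$scores),
    PPCALI    = function(p) encode_ppcali(p, context$scores))
  rows <- lapply(sequences, enc)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("peptides of differing length cannot share a ", descriptor,
         " design matrix")
  m <- do.call(rbind, rows)
  rownames(m) <- sequences
  m
}

#' Expected descriptor dimensionality
#'
#' @param descriptor One of [DESCRIPTOR_IDS].
#' @param length Peptide length (ignored by the length-independent
#'   descriptors).
#' @param max_dist,max_lag Range parameters of PEPCATS / PPCALI.
#' @return Integer dimension.
#' @export
descriptor_dim <- function(descriptor, length = 8, max_dist = 7,
                           max_lag = 7) {
  descriptor <- match.arg(descriptor, DESCRIPTOR_IDS)
  switch(descriptor,
         AAFREQ = 20L,
         BINAATYPE = 6L * length,
         BINPEP = 5L * length,
         PEPCATS = 21L * max_dist,
         PPCA = 19L * length,
         PPCALI = 19L * (max_lag + 1L))
}
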