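#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in the fixed order used throughout the
#' package (the order of the amino-acid frequency descriptor):
#' A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V.
#'
#' @format A length-20 character vector.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Pharmacophore feature codes
#'
#' The six side-chain pharmacophore feature types, in the fixed order used by
#' the binary type descriptor and the topological pharmacophore descriptor:
#' L (lipophilic), R (aromatic), A (H-bond acceptor), D (H-bond donor),
#' P (positively ionizable), N (negatively ionizable).
#'
#' @format A length-6 character vector.
#' @export
PHARMACOPHORE_FEATURES <- c("L", "R", "A", "D", "P", "N")

#' Validate peptide sequences
#'
#' Checks that every sequence consists solely of the 20 canonical one-letter
#' amino-acid codes. Non-canonical residues (X, B, Z, U, ...) are rejected,
#' not imputed: the modeling pipeline is defined on curated canonical
#' sequences only.
#'
#' @param sequences Character vector of peptide sequences.
#' @param length_required Optional integer; if given, every sequence must
#'   have exactly this length.
#' @return The input, upper-cased, invisibly usable downstream.
#' @export
#' @examples
#' validate_peptides(c("SIINFEKL", "AAAA"))
validate_peptides <- function(sequences, length_required = NULL) {
  if (!is.character(sequences) || length(sequences) == 0)
    stop("'sequences' must be a non-empty character vector")
  sequences <- toupper(sequences)
  chars <- strsplit(sequences, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    if (length(chars[[i]]) < 1L)
      stop("empty peptide sequence at position ", i)
    bad <- setdiff(unique(chars[[i]]), AA_ALPHABET)
    if (length(bad) > 0)
      stop("non-canonical residue code(s) '", paste(bad, collapse = "', '"),
           "' in peptide '", sequences[i], "'")
  }
  if (!is.null(length_required)) {
    nc <- nchar(sequences)
    if (any(nc != length_required))
      stop("peptide length must be ", length_required, "; offending: ",
           paste(utils::head(sequences[nc != length_required], 3),
                 collapse = ", "))
  }
  sequences
}

#' Split peptides into residue vectors
#'
#' @param sequences Validated peptide sequences.
#' @return List of character vectors, one residue per element.
#' @keywords internal
peptide_residues <- function(sequences) {
  strsplit(toupper(sequences), "", fixed = TRUE)
}

#' Deterministically derive a child seed from a pipeline seed
#'
#' Every stochastic stage of the pipeline draws its seed from the single
#' top-level seed through this counter-based map, so adding a stage never
#' reshuffles the randomness of earlier stages.
#'
#' @param seed Integer top-level seed.
#' @param k Integer stage counter (any non-negative integer).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k))
  ((as.double(seed) %% 2147483647) * 48271 + as.double(k) * 100003 + 12345) %%
    2147483647
}

#' Read peptides from FASTA or plain text
#'
#' Accepts either a FASTA file (header lines starting with '>') or a
#' one-sequence-per-line text file.
#'
#' @param path File path.
#' @return Named character vector of sequences (names empty for plain text).
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty input file: ", path)
  if (startsWith(first, ">")) {
    fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
    out <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
    names(out) <- names(fa)
  } else {
    out <- toupper(trimws(readLines(path, warn = FALSE)))
    out <- out[nzchar(out)]
  }
  out
}
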