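#' Default side-chain pharmacophore assignment table
#'
#' Maps each canonical amino acid to the subset of the six pharmacophore
#' feature types (L lipophilic, R aromatic, A acceptor, D donor, P positive,
#' N negative) carried by its side chain. The default assignment is:
#' aromatic F, W, Y, H; lipophilic A, V, L, I, M, F, W, P, C; donor
#' S, T, Y, N, Q, W, K, R, H; acceptor S, T, Y, N, Q, D, E, H; positive
#' K, R, H; negative D, E. Glycine carries no side-chain feature.
#'
#' The assignment is a package default, not a physical constant; it can be
#' replaced wholesale with [read_pharmacophore_table()].
#'
#' @return A named list of 20 character vectors (possibly empty), one per
#'   amino acid in [AA_ALPHABET] order, each a subset of
#'   [PHARMACOPHORE_FEATURES]; class `"pharmacophore_table"`.
#' @export
#' @examples
#' tab <- default_pharmacophore_table()
#' tab$K   # positive, donor
default_pharmacophore_table <- function() {
  path <- system.file("extdata", "pharmacophore_default.txt",
                      package = "pepcascade", mustWork = TRUE)
  read_pharmacophore_table(path)
}

#' Read a pharmacophore table from a plain-text config
#'
#' Format: one line per amino acid, `CODE: F1,F2,...` (features may be empty
#' after the colon); `#` starts a comment. The table must cover all 20
#' canonical amino acids and use only the six known feature codes.
#'
#' @param path File path.
#' @return A `"pharmacophore_table"` (see [default_pharmacophore_table()]).
#' @export
read_pharmacophore_table <- function(path) {
  if (!file.exists(path)) stop("pharmacophore table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tab <- stats::setNames(vector("list", length(AA_ALPHABET)), AA_ALPHABET)
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    aa <- trimws(parts[1])
    if (!aa %in% AA_ALPHABET)
      stop("unknown amino-acid code '", aa, "' in pharmacophore table")
    feats <- character(0)
    if (length(parts) > 1 && nzchar(trimws(parts[2]))) {
      feats <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
      bad <- setdiff(feats, PHARMACOPHORE_FEATURES)
      if (length(bad) > 0)
        stop("unknown feature code(s) '", paste(bad, collapse = "','"),
             "' for amino acid ", aa)
    }
    # keep fixed feature order regardless of file order
    tab[[aa]] <- PHARMACOPHORE_FEATURES[PHARMACOPHORE_FEATURES %in% feats]
  }
  missing <- names(tab)[vapply(tab, is.null, logical(1))]
  if (length(missing) > 0)
    stop("pharmacophore table incomplete; missing: ",
         paste(missing, collapse = ", "))
  structure(tab, class = "pharmacophore_table")
}

#' Pharmacophore features of a single amino acid
#'
#' @param aa One-letter canonical amino-acid code.
#' @param table A `"pharmacophore_table"`; default the packaged table.
#' @return Character vector (subset of [PHARMACOPHORE_FEATURES], possibly
#'   empty).
#' @export
#' @examples
#' assign_features("K")  # "D" "P"
#' assign_features("G")  # character(0)
assign_features <- function(aa, table = default_pharmacophore_table()) {
  stopifnot(inherits(table, "pharmacophore_table"))
  aa <- toupper(aa)
  if (length(aa) != 1 || !aa %in% AA_ALPHABET)
    stop("unknown residue code '", aa, "'")
  table[[aa]]
}
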