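#' Default amino-acid property-scale matrix
#'
#' Returns a 20-row (amino acids, in [AA_ALPHABET] order) by S-column matrix
#' of published amino-acid property scales, used as input for the
#' principal-component peptide encoding. The default draws every complete
#' (NA-free) scale from the AAindex collection bundled with \pkg{seqinr}
#' (531 scales), giving the PCA far more columns than the 20 rows so the
#' rank bound of 19 components is attained.
#'
#' A custom matrix can be supplied instead via [read_property_scales()].
#'
#' @return Numeric matrix, 20 x S (S >= 20), rownames = amino acids,
#'   colnames = scale identifiers.
#' @export
default_property_scales <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  complete <- Filter(function(a) !any(is.na(a$I)), aaindex)
  m <- vapply(complete, function(a) unname(a$I[three[AA_ALPHABET]]),
              numeric(20))
  rownames(m) <- AA_ALPHABET
  colnames(m) <- vapply(complete, function(a) a$H, character(1))
  m
}

#' Read an amino-acid property-scale matrix from CSV
#'
#' Expected format: a header row of scale names, one row per amino acid with
#' the one-letter code in the first column; exactly 20 rows covering the
#' canonical alphabet.
#'
#' @param path CSV file path.
#' @return Numeric 20 x S matrix with amino-acid rownames in [AA_ALPHABET]
#'   order.
#' @export
read_property_scales <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  aa <- toupper(df[[1]])
  if (!setequal(aa, AA_ALPHABET) || anyDuplicated(aa))
    stop("property-scale CSV must contain exactly one row per canonical ",
         "amino acid")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- aa
  m <- m[AA_ALPHABET, , drop = FALSE]
  if (anyNA(m)) stop("property-scale matrix contains missing values")
  m
}

#' Principal-component score matrix of amino-acid property scales
#'
#' Column-standardizes the 20 x S property matrix, performs a PCA, keeps the
#' first 19 principal components (a centered 20-row matrix has rank at most
#' 19, so 19 components carry essentially all variance), and rescales every
#' score column to unit variance. Each row of the result is a 19-dimensional
#' physicochemical description of one amino acid.
#'
#' Constant-valued scale columns carry no information and are dropped with a
#' warning before the PCA.
#'
#' @param scales 20 x S numeric matrix (S >= 20), e.g.
#'   [default_property_scales()].
#' @return Object of class `"pca_scores"`: list with `scores` (20 x 19
#'   unit-variance score matrix, amino-acid rownames), `explained_variance`
#'   (length-19, variance of each raw component), and
#'   `explained_fraction` (cumulative fraction of total variance).
#' @export
build_pca_scores <- function(scales = default_property_scales()) {
  stopifnot(is.matrix(scales))
  if (nrow(scales) != 20)
    stop("property-scale matrix must have exactly 20 rows")
  if (ncol(scales) < 20)
    stop("need at least 20 property scales (got ", ncol(scales), ")")
  if (anyNA(scales)) stop("property-scale matrix contains missing values")
  sds <- apply(scales, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant property scale(s) dropped before PCA")
    scales <- scales[, sds > 0, drop = FALSE]
    if (ncol(scales) < 20)
      stop("degenerate property matrix: fewer than 20 informative scales ",
           "remain")
  }
  std <- scale(scales, center = TRUE, scale = TRUE)
  pca <- stats::prcomp(std, center = FALSE, scale. = FALSE)
  if (length(pca$sdev) < 19 || pca$sdev[19] < 1e-10)
    stop("degenerate property matrix: fewer than 19 non-null components")
  raw <- pca$x[, 1:19, drop = FALSE]
  scores <- sweep(raw, 2, apply(raw, 2, stats::sd), "/")
  rownames(scores) <- rownames(scales)
  colnames(scores) <- paste0("PC", 1:19)
  ev <- pca$sdev^2
  structure(list(scores = scores,
                 explained_variance = ev[1:19],
                 explained_fraction = cumsum(ev)[1:19] / sum(ev),
                 rotation = pca$rotation[, 1:19, drop = FALSE],
                 n_scales = ncol(scales)),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("Amino-acid property PCA scores: 20 x 19 (from", x$n_scales,
      "scales)\n")
  cat(sprintf("cumulative variance of 19 components: %.4f%%\n",
              100 * x$explained_fraction[19]))
  invisible(x)
}
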