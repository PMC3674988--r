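# Brute-force feature-pair recount, independent of the production binning
# code: double loop over residue pairs, expanding feature cross-products,
# then the same per-pair-type normalization.
pepcats_oracle <- function(peptide, table, max_dist = 7) {
  res <- strsplit(peptide, "")[[1]]
  L <- length(res)
  feats <- lapply(res, function(aa) table[[aa]])
  pair_names <- character(0)
  for (i in 1:6) for (j in i:6)
    pair_names <- c(pair_names, paste0(PHARMACOPHORE_FEATURES[i],
                                       PHARMACOPHORE_FEATURES[j]))
  counts <- matrix(0, length(pair_names), max_dist,
                   dimnames = list(pair_names, NULL))
  if (L >= 2) {
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      d <- j - i
      if (d > max_dist) next
      for (a in feats[[i]]) for (b in feats[[j]]) {
        key <- paste0(sort(factor(c(a, b),
                                  levels = PHARMACOPHORE_FEATURES)),
                      collapse = "")
        counts[key, d] <- counts[key, d] + 1
      }
    }
  }
  tot <- rowSums(counts)
  counts[tot > 0, ] <- counts[tot > 0, , drop = FALSE] / tot[tot > 0]
  as.numeric(t(counts))
}
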