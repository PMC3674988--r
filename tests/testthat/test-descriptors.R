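test_that("descriptor dimensions follow the dimension table for lengths 1-15", {
  ctx <- get_context()
  for (L in c(1, 2, 5, 8, 12, 15)) {
    p <- random_peptides(1, L, seed = 100 + L)
    expect_length(encode_aafreq(p), 20)
    expect_length(encode_binaatype(p, ctx$table), 6 * L)
    expect_length(encode_binpep(p), 5 * L)
    expect_length(encode_pepcats(p, ctx$table), 147)
    expect_length(encode_ppca(p, ctx$scores), 19 * L)
    expect_length(encode_ppcali(p, ctx$scores), 152)
    expect_length(encode_ppcali(p, ctx$scores, max_lag = 3), 19 * 4)
  }
})

test_that("amino-acid frequencies count residues in fixed alphabet order", {
  v <- encode_aafreq("SIINFEKL")
  expect_equal(v[["I"]], 2)
  expect_equal(unname(v[c("S", "N", "F", "E", "K", "L")]), rep(1, 6))
  expect_equal(sum(v), 8)
  expect_equal(names(v), AA_ALPHABET)
  expect_equal(unname(encode_aafreq("AAAA")["A"]), 4)
  for (L in c(3, 9)) {
    p <- random_peptides(1, L, seed = L)
    expect_equal(sum(encode_aafreq(p)), L)
  }
})

test_that("pharmacophore assignment matches the packaged table", {
  expect_setequal(assign_features("K"), c("P", "D"))
  expect_length(assign_features("G"), 0)
  expect_true("R" %in% assign_features("F"))
  expect_error(assign_features("X"), "unknown residue code 'X'")
  expect_error(validate_peptides("SIINFEKX"), "non-canonical")
  expect_error(validate_peptides("PEPTIDEB"), "'B'")
})

test_that("binary type descriptor bits agree with assign_features", {
  ctx <- get_context()
  p <- "SIGNFEKW"
  v <- encode_binaatype(p, ctx$table)
  res <- strsplit(p, "")[[1]]
  for (i in seq_along(res)) {
    block <- v[((i - 1) * 6 + 1):(i * 6)]
    expect_equal(unname(block),
                 as.numeric(PHARMACOPHORE_FEATURES %in%
                              assign_features(res[i], ctx$table)))
  }
  # glycine has no side-chain feature: all-zero block
  expect_equal(unname(v[13:18]), rep(0, 6))
})

test_that("binary identity codes are injective, local, and decodable", {
  codes <- vapply(AA_ALPHABET, function(a) paste(encode_binpep(a),
                                                 collapse = ""),
                  character(1))
  expect_equal(length(unique(codes)), 20)
  a <- encode_binpep("SIINFEKL")
  b <- encode_binpep("SIINFEKV")  # differs at position 8 only
  diff_blocks <- which(vapply(1:8, function(i)
    any(a[((i - 1) * 5 + 1):(i * 5)] != b[((i - 1) * 5 + 1):(i * 5)]),
    logical(1)))
  expect_equal(diff_blocks, 8)
  for (p in random_peptides(5, 8, seed = 42))
    expect_equal(decode_binpep(encode_binpep(p)), p)
})

test_that("pair descriptor is 147-dimensional with per-pair-type bins summing to 1", {
  ctx <- get_context()
  expect_equal(sum(encode_pepcats("A", ctx$table)), 0)  # no pair exists
  set.seed(7)
  for (L in sample(c(5, 8, 10, 12), 100, replace = TRUE)) {
    p <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    v <- encode_pepcats(p, ctx$table)
    expect_length(v, 147)
    sums <- rowSums(matrix(v, nrow = 21, byrow = TRUE))
    occupied <- sums > 0
    expect_true(all(abs(sums[occupied] - 1) < 1e-9))
  }
})

test_that("pair descriptor agrees with a brute-force pair recount", {
  ctx <- get_context()
  for (p in random_peptides(100, 10, seed = 55))
    expect_equal(unname(encode_pepcats(p, ctx$table)),
                 pepcats_oracle(p, ctx$table), tolerance = 1e-12)
})

test_that("property PCA encoding concatenates score rows in sequence order", {
  ctx <- get_context()
  v <- encode_ppca("SIINFEKL", ctx$scores)
  expect_length(v, 152)
  expect_equal(unname(v[1:19]), unname(ctx$scores$scores["S", ]))
  v2 <- encode_ppca("AA", ctx$scores)
  expect_equal(unname(v2[1:19]), unname(v2[20:38]))
})

test_that("auto-correlated property descriptor matches its closed forms", {
  ctx <- get_context()
  p <- "SIINFEKL"
  v <- encode_ppcali(p, ctx$scores)
  m <- matrix(encode_ppca(p, ctx$scores), ncol = 19, byrow = TRUE)
  expect_equal(unname(v[1:19]), unname(colSums(m^2)))  # lag 0
  # lag d oracle
  for (d in c(1, 3, 7)) {
    i <- 1:(8 - d)
    expect_equal(unname(v[(d * 19 + 1):(d * 19 + 19)]),
                 unname(colSums(m[i, , drop = FALSE] *
                                  m[i + d, , drop = FALSE])))
  }
  v1 <- encode_ppcali("W", ctx$scores)
  expect_true(all(v1[20:152] == 0))  # only the lag-0 block is populated
  expect_true(all(v1[1:19] >= 0))
})

test_that("property-scale PCA yields 19 unit-variance components capturing all variance", {
  scores <- get_context()$scores
  expect_equal(dim(scores$scores), c(20, 19))
  expect_equal(unname(apply(scores$scores, 2, sd)), rep(1, 19),
               tolerance = 1e-8)
  # a centered 20-row matrix has rank <= 19
  expect_equal(scores$explained_fraction[19], 1, tolerance = 1e-8)
})

test_that("PCA reconstruction from 19 components recovers the standardized matrix", {
  m <- default_property_scales()
  expect_gte(ncol(m), 20)
  scores <- build_pca_scores(m)
  raw <- sweep(scores$scores, 2, sqrt(scores$explained_variance), "*")
  recon <- raw %*% t(scores$rotation)
  expect_equal(unname(recon), unname(scale(m)[, ]), tolerance = 1e-6)
})

test_that("degenerate property matrices are rejected or cleaned", {
  m <- default_property_scales()
  ident <- matrix(rep(m[1, ], each = 20), nrow = 20,
                  dimnames = dimnames(m))
  expect_error(suppressWarnings(build_pca_scores(ident)), "degenerate")
  m2 <- m
  m2[, 3] <- 5  # one constant scale: dropped with a warning
  expect_warning(s2 <- build_pca_scores(m2), "constant")
  expect_equal(ncol(s2$scores), 19)
  expect_error(build_pca_scores(m[, 1:10]), "at least 20")
})

test_that("encoders are deterministic and permutation-sensitive except AAFREQ", {
  ctx <- get_context()
  p <- "SIINFEKL"
  rev_p <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(encode_pepcats(p, ctx$table), encode_pepcats(p, ctx$table))
  expect_equal(encode_aafreq(p)[AA_ALPHABET],
               encode_aafreq(rev_p)[AA_ALPHABET])
  expect_false(all(encode_ppca(p, ctx$scores) ==
                     encode_ppca(rev_p, ctx$scores)))
  expect_false(all(encode_binpep(p) == encode_binpep(rev_p)))
  expect_false(all(encode_binaatype(p, ctx$table) ==
                     encode_binaatype(rev_p, ctx$table)))
})

test_that("set-level encoding yields one named row per peptide", {
  ctx <- get_context()
  peps <- random_peptides(10, 8, seed = 3)
  m <- encode_peptides(peps, "PEPCATS", ctx)
  expect_equal(dim(m), c(10, 147))
  expect_equal(rownames(m), peps)
  expect_error(encode_peptides(c("AAA", "AAAA"), "PPCA", ctx),
               "differing length")
})

test_that("a custom pharmacophore table round-trips through its text format", {
  ctx <- get_context()
  path <- tempfile(fileext = ".txt")
  writeLines(vapply(AA_ALPHABET, function(aa)
    paste0(aa, ": ", paste(ctx$table[[aa]], collapse = ",")),
    character(1)), path)
  tab2 <- read_pharmacophore_table(path)
  expect_equal(tab2[AA_ALPHABET], ctx$table[AA_ALPHABET],
               ignore_attr = TRUE)
  writeLines(c("A: L"), path)
  expect_error(read_pharmacophore_table(path), "incomplete")
})
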