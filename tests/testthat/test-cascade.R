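test_that("the architecture exposes 12 base slots in stable order", {
  slots <- base_slots()
  expect_equal(nrow(slots), 12)
  expect_equal(slots$slot[1:2], c("AAFREQ.ANN", "AAFREQ.SVM"))
  expect_equal(length(unique(slots$slot)), 12)
  expect_equal(nrow(base_slots("PPCA", "SVM")), 1)
})

test_that("MCC matches the phi-coefficient oracle and its conventions", {
  expect_equal(mcc(c(TP = 50, FP = 0, FN = 0, TN = 50)), 1)
  expect_equal(mcc(c(TP = 25, FP = 25, FN = 25, TN = 25)), 0)
  expect_equal(mcc(c(TP = 0, FP = 50, FN = 50, TN = 0)), -1)
  expect_equal(mcc(c(TP = 10, FP = 0, FN = 0, TN = 0)), 0)  # zero factor
  expect_error(mcc(c(TP = 0, FP = 0, FN = 0, TN = 0)), "empty")
  expect_error(mcc(c(TP = 1, FP = 1)), "must provide")

  set.seed(12)
  for (i in 1:1000) {
    conf <- c(TP = sample(1:30, 1), FP = sample(1:30, 1),
              FN = sample(1:30, 1), TN = sample(1:30, 1))
    pred <- rep(c(1, 1, 0, 0), conf[c("TP", "FP", "FN", "TN")])
    truth <- rep(c(1, 0, 1, 0), conf[c("TP", "FP", "FN", "TN")])
    expect_equal(mcc(conf), suppressWarnings(cor(pred, truth)),
                 tolerance = 1e-12)
  }
})

test_that("confusion tables account for every instance", {
  set.seed(3)
  pred <- runif(200)
  truth <- sample(c("binder", "non-binder"), 200, replace = TRUE)
  ct <- confusion_table(pred >= 0.5, truth)
  expect_equal(sum(ct), 200)
  # scores above threshold count as predicted binders
  expect_equal(ct[["TP"]] + ct[["FP"]], sum(pred >= 0.5))
})

test_that("base training selects hyperparameters deterministically", {
  d <- generate_peptides(motif_spec(n_pos = 80, n_neg = 80, seed = 51))
  m1 <- train_base(d, "BINPEP", "SVM", tiny_grid(), seed = 6,
                   context = get_context())
  m2 <- train_base(d, "BINPEP", "SVM", tiny_grid(), seed = 6,
                   context = get_context())
  expect_identical(m1$config, m2$config)
  peps <- random_peptides(30, 8, seed = 8)
  expect_identical(score_peptides(m1, peps), score_peptides(m2, peps))

  single <- d[d$label == "binder", ]
  expect_error(train_base(single, "AAFREQ", "ANN", tiny_grid(), seed = 1,
                          context = get_context()),
               "both classes")
})

test_that("base classifiers recover a noise-free planted motif", {
  d <- generate_peptides(motif_spec(label_noise = 0, seed = 61))
  m <- train_base(d, "BINAATYPE", "SVM", reduced_grid_spec(), seed = 9,
                  context = get_context())
  expect_gt(m$inner_mcc, 0.8)
})

test_that("base classifiers learn nothing from permuted labels", {
  d <- generate_peptides(motif_spec(seed = 67))
  set.seed(10)
  d$label <- sample(d$label)
  m <- train_base(d, "BINPEP", "SVM", tiny_grid(), seed = 12,
                  context = get_context())
  expect_lt(abs(m$inner_mcc), 0.2)
})

test_that("the base score matrix is [0,1)-valued with stable columns", {
  st <- get_tiny_state()
  models <- lapply(seq_len(3), function(s)
    train_base(st$data, st$state$slots$descriptor[s],
               st$state$slots$scheme[s], tiny_grid(),
               seed = 100 + s, context = get_context()))
  peps <- random_peptides(40, 8, seed = 14)
  S <- base_score_matrix(models, peps)
  expect_equal(dim(S), c(40, 3))
  expect_true(all(S >= 0 & S < 1))
  expect_identical(colnames(S), st$state$slots$slot)
  expect_identical(S, base_score_matrix(models, peps))
  expect_error(base_score_matrix(c(models[1], list("not a model")), peps),
               "untrained")
})

test_that("jury enumeration iterates 2^k subsets with a degenerate empty entry", {
  st <- get_tiny_state()$state
  jt <- enumerate_juries(st, jury_hidden = 2, seed = 19)
  expect_equal(attr(jt, "n_evaluated"), 8)        # 2^3 subsets
  expect_equal(nrow(jt), 8)
  expect_equal(sum(!is.na(jt$mcc_cv)), 7)          # 2^3 - 1 trainable
  empty <- jt[jt$n_members == 0, ]
  expect_true(is.na(empty$mcc_cv) && is.na(empty$mcc_ext))
  # full 12-slot subset space, combinatorially
  expect_equal(2^nrow(base_slots()), 4096)
  # determinism
  jt2 <- enumerate_juries(st, jury_hidden = 2, seed = 19)
  expect_identical(jt, jt2)
})

test_that("greedy search reproduces exhaustive per-subset estimates", {
  st <- get_tiny_state()$state
  ex <- enumerate_juries(st, jury_hidden = 2, search = "exhaustive",
                         seed = 19)
  gr <- enumerate_juries(st, jury_hidden = 2, search = "greedy", seed = 19)
  common <- intersect(ex$mask[ex$n_members > 0], gr$mask[gr$n_members > 0])
  expect_gt(length(common), 0)
  for (m in common) {
    expect_equal(ex$mcc_cv[ex$mask == m], gr$mcc_cv[gr$mask == m])
    expect_equal(ex$mcc_ext[ex$mask == m], gr$mcc_ext[gr$mask == m])
  }
})

test_that("the compromise rule ranks by min, then mean, then parsimony", {
  jt <- data.frame(mask = 1:4, members = letters[1:4],
                   n_members = c(2, 1, 3, 1),
                   mcc_cv = c(0.6, 0.6, 0.9, 0.5),
                   mcc_ext = c(0.7, 0.7, 0.55, 0.9))
  r <- rank_juries(jt)
  # masks 1 and 2 tie on min (0.6) and mean; fewer members wins
  expect_equal(r$mask, c(2, 1, 3, 4))
  st <- get_tiny_state()$state
  jt2 <- enumerate_juries(st, jury_hidden = 2, seed = 19)
  trained <- jt2[!is.na(jt2$min_mcc), ]
  expect_true(all(trained$min_mcc[1] >= trained$min_mcc))
})

test_that("a single-member jury cannot beat its member by more than noise", {
  st <- get_tiny_state()$state
  jt <- enumerate_juries(st, jury_hidden = 2, seed = 19)
  for (s in seq_len(nrow(st$slots))) {
    row <- jt[jt$mask == 2^(s - 1), ]
    expect_lte(row$mcc_cv, st$base_mcc_cv[[s]] + 0.15)
  }
})

test_that("prediction is a pure [0,1) function enforcing the trained length", {
  model <- get_recovery_model()
  peps <- random_peptides(50, 8, seed = 44)
  s1 <- jury_score(model, peps)
  expect_true(all(s1 >= 0 & s1 < 1))
  expect_identical(s1, jury_score(model, peps))
  pr <- predict(model, peps)
  expect_equal(pr$class, ifelse(pr$score >= 0.5, "binder", "non-binder"))
  expect_error(jury_score(model, "SIINF"), "8")
})

test_that("a persisted model reproduces predictions bit-for-bit", {
  model <- get_recovery_model()
  path <- tempfile(fileext = ".rds")
  save_jury_model(model, path)
  reloaded <- load_jury_model(path)
  peps <- random_peptides(30, 8, seed = 45)
  expect_identical(jury_score(model, peps), jury_score(reloaded, peps))
  expect_error(load_jury_model(system.file("extdata",
                                           "pharmacophore_default.txt",
                                           package = "pepcascade")))
})

test_that("external estimates do not depend on enumeration internals", {
  # per-subset seeds derive from the member mask, so the same subset gets
  # identical jury training whether it is reached exhaustively or greedily
  st <- get_tiny_state()$state
  full_mask <- 2^nrow(st$slots) - 1
  ex <- enumerate_juries(st, jury_hidden = 2, search = "exhaustive",
                         seed = 19)
  gr <- enumerate_juries(st, jury_hidden = 2, search = "greedy", seed = 19)
  if (full_mask %in% gr$mask)
    expect_identical(ex$mcc_ext[ex$mask == full_mask],
                     gr$mcc_ext[gr$mask == full_mask])
})
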