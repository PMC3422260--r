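test_that("cosine distance matches direct evaluation and its conventions", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - sqrt(2) / 2)
  expect_error(cosine_distance(1:3, 1:2), "length")
  expect_warning(d <- cosine_distance(c(0, 0), c(1, 2)), "zero-norm")
  expect_equal(d, 1)
})

test_that("cosine distance is symmetric, zero on self, scale-invariant", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(2:10, 1))
    y <- rnorm(length(x))
    expect_equal(cosine_distance(x, y), cosine_distance(y, x))
    expect_equal(cosine_distance(x, x), 0, tolerance = 1e-12)
    s <- runif(1, 0.1, 100)
    expect_equal(cosine_distance(s * x, y), cosine_distance(x, y),
                 tolerance = 1e-12)
    expect_gte(cosine_distance(x, y), 0)
    expect_lte(cosine_distance(x, y), 2)
  }
})

test_that("nearest-neighbor prediction follows the nearest label, ties to the earlier sample", {
  train <- omics_matrix(
    matrix(c(1, 1, -1, -1), 2, 2,
           dimnames = list(c("f1", "f2"), c("s1", "s2"))),
    labels = c("tumor", "normal"), level = "mRNA")
  expect_equal(nna_predict(train, c(1, 1)), "tumor")
  expect_equal(nna_predict(train, c(-2, -2)), "normal")
  # equidistant query: both training samples at cosine distance 1
  expect_equal(nna_predict(train, c(1, -1)), "tumor")
  expect_error(nna_predict(train, c(1, 2, 3)), "match")
})

test_that("LOOCV separates well-separated clusters and inverts with n=2", {
  om <- toy_matrix(n_tumor = 10, n_normal = 10, n_features = 3,
                   center = 1, noise = 0.01, seed = 2)
  cc <- loocv_confusion(om, rownames(om$values))
  expect_equal(unname(cc[c("TP", "TN", "FP", "FN")]), c(10, 10, 0, 0))
  expect_equal(mcc(cc), 1)

  # with one sample per class each held-out sample's only neighbor is the
  # other class
  two <- omics_matrix(
    matrix(c(1, 2, 5, 6), 2, 2, dimnames = list(c("f1", "f2"), c("a", "b"))),
    labels = c("tumor", "normal"), level = "mRNA")
  cc2 <- loocv_confusion(two, c("f1", "f2"))
  expect_equal(unname(cc2[c("TP", "TN", "FP", "FN")]), c(0, 0, 1, 1))
  expect_equal(mcc(cc2), -1)

  expect_error(loocv_confusion(om, c("nope1", "nope2")), "nope1")
})

test_that("LOOCV MCC is centered at zero under label permutation", {
  set.seed(7)
  vals <- replicate(500, {
    v <- matrix(rnorm(5 * 40), 5,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:40)))
    om <- omics_matrix(v, labels = sample(rep(c("tumor", "normal"), 20)),
                       level = "mRNA")
    mcc(loocv_confusion(om, paste0("f", 1:5)))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("MCC follows the direct formula, conventions included", {
  expect_equal(mcc(confusion_counts(10, 10, 0, 0)), 1)
  expect_equal(mcc(confusion_counts(0, 0, 10, 10)), -1)
  expect_equal(mcc(confusion_counts(6, 4, 1, 2)), 22 / sqrt(1680))
  expect_equal(mcc(confusion_counts(5, 0, 0, 5)), 0)  # zero factor
  expect_error(confusion_counts(-1, 0, 0, 2), "nonnegative")
  expect_error(mcc(confusion_counts(0, 0, 0, 0)), "no evaluated samples")
})

test_that("full LOOCV-NNA-MCC path agrees with the brute-force oracle", {
  set.seed(11)
  for (rep in 1:200) {
    nf <- sample(1:10, 1)
    nt <- sample(1:10, 1)
    nn <- sample(1:10, 1)
    if (nt + nn < 2) nn <- nn + 1
    v <- matrix(rnorm(nf * (nt + nn)), nf,
                dimnames = list(paste0("f", seq_len(nf)),
                                paste0("s", seq_len(nt + nn))))
    labels <- rep(c("tumor", "normal"), c(nt, nn))
    om <- omics_matrix(v, labels = labels, level = "mRNA")
    cc <- loocv_confusion(om, rownames(v))
    oracle <- bf_loocv(v, labels)
    expect_identical(unname(cc[c("TP", "TN", "FP", "FN")]),
                     as.numeric(oracle[c("TP", "TN", "FP", "FN")]))
    expect_equal(mcc(cc),
                 bf_mcc(oracle["TP"], oracle["TN"], oracle["FP"],
                        oracle["FN"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("per-term scoring recovers a planted single-level effect", {
  cfg <- simulation_config(
    n_genes = 150, n_mirnas = 30, n_terms = 10,
    planted = data.frame(term = 1, level = "mRNA", delta = 3),
    seed = 31)
  study <- simulate_study(cfg)
  targets <- consensus_targets(study$predictions)
  sets <- filter_terms(build_term_sets(
    study$annotation, rownames(study$meth$values),
    rownames(study$mirna$values), rownames(study$mrna$values), targets))
  tab <- score_term_sets(study$meth, study$mirna, study$mrna, sets)
  planted <- tab[tab$term_id == "T0001", ]
  expect_gte(planted$mcc_mRNA, 0.9)
  expect_gt(planted$mcc_mRNA, planted$mcc_methylation)
  expect_gt(planted$mcc_mRNA, planted$mcc_microRNA)

  # duplicate term ids are refused
  expect_error(score_term_sets(study$meth, study$mirna, study$mrna,
                               c(sets[1], sets[1])), "duplicated")
})

test_that("scoring is invariant to sample-column permutation (tie-free case)", {
  om <- toy_matrix(n_tumor = 8, n_normal = 8, n_features = 4,
                   center = 0.5, noise = 0.4, seed = 13)
  base <- mcc(loocv_confusion(om, rownames(om$values)))
  set.seed(14)
  for (i in 1:5) {
    p <- sample(ncol(om$values))
    shuffled <- omics_matrix(om$values[, p],
                             labels = as.character(om$labels)[p],
                             level = om$level)
    expect_equal(mcc(loocv_confusion(shuffled, rownames(om$values))), base)
  }
})
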