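test_that("identical seeds reproduce the study bitwise", {
  cfg <- simulation_config(n_genes = 80, n_mirnas = 20, n_terms = 8,
                           n_tumor = 8, n_normal = 8, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$independent$values, b$independent$values)
  expect_identical(a$annotation$sets, b$annotation$sets)
  expect_identical(a$predictions, b$predictions)

  other <- simulate_study(simulation_config(n_genes = 80, n_mirnas = 20,
                                            n_terms = 8, n_tumor = 8,
                                            n_normal = 8, seed = 100))
  expect_false(identical(a$mrna$values, other$mrna$values))
})

test_that("a full methylation fraction covers the whole gene universe", {
  study <- simulate_study(simulation_config(n_genes = 50, n_mirnas = 10,
                                            n_terms = 5, n_tumor = 5,
                                            n_normal = 5,
                                            meth_fraction = 1, seed = 3))
  expect_setequal(rownames(study$meth$values), rownames(study$mrna$values))
})

test_that("with nothing planted, per-feature t statistics follow the null", {
  study <- simulate_study(simulation_config(
    n_genes = 10000, n_mirnas = 2, n_terms = 2, term_size = c(2, 4),
    n_tumor = 30, n_normal = 30, meth_fraction = 0.01, seed = 17))
  v <- study$mrna$values
  tum <- v[, study$mrna$labels == "tumor", drop = FALSE]
  nor <- v[, study$mrna$labels == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  sp <- sqrt(((n1 - 1) * apply(tum, 1, var) +
                (n2 - 1) * apply(nor, 1, var)) / (n1 + n2 - 2))
  tstat <- (rowMeans(tum) - rowMeans(nor)) / (sp * sqrt(1 / n1 + 1 / n2))
  frac <- mean(abs(tstat) > 3)
  # P(|t_58| > 3) ~ 0.004; allow generous Monte-Carlo slack around it
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.01)
  expect_lt(abs(mean(rowMeans(tum) - rowMeans(nor))), 0.02)
})

test_that("planted standardized effects are recovered empirically at large n", {
  delta <- 1.5
  study <- simulate_study(simulation_config(
    n_genes = 200, n_mirnas = 20, n_terms = 10,
    n_tumor = 500, n_normal = 500,
    planted = data.frame(term = 2, level = "mRNA", delta = delta),
    seed = 21))
  members <- study$truth$membership$mRNA[[2]]
  v <- study$mrna$values[members, , drop = FALSE]
  tum <- v[, study$mrna$labels == "tumor", drop = FALSE]
  nor <- v[, study$mrna$labels == "normal", drop = FALSE]
  sp <- sqrt((apply(tum, 1, var) + apply(nor, 1, var)) / 2)
  smd <- (rowMeans(tum) - rowMeans(nor)) / sp
  # each feature dysregulates up or down; the magnitude converges to delta
  expect_lt(max(abs(abs(smd) - delta)), 0.1 + 3 * sqrt(2 / 500))
  expect_lt(abs(mean(abs(smd)) - delta), 0.1)
  # recorded signs match the realized directions
  expect_identical(sign(smd), study$truth$signs$mRNA[members])
  # unplanted features stay null
  rest <- setdiff(rownames(study$mrna$values), members)
  smd0 <- (rowMeans(study$mrna$values[rest, study$mrna$labels == "tumor"]) -
             rowMeans(study$mrna$values[rest, study$mrna$labels == "normal"]))
  expect_lt(abs(mean(smd0)), 0.05)
})

test_that("planting on a level with no members is an error", {
  cfg <- simulation_config(
    n_genes = 30, n_mirnas = 5, n_terms = 3, term_size = c(2, 3),
    n_tumor = 4, n_normal = 4, meth_fraction = 0.05,
    targets_per_mirna = c(1, 1),
    planted = data.frame(term = 1, level = "methylation", delta = 2),
    seed = 8)
  # with only ~1-2 methylation-measured genes, some seed/term combination
  # leaves the planted term without methylation members
  res <- tryCatch(simulate_study(cfg), error = identity)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no members")
  } else {
    expect_gt(length(res$truth$membership$methylation[[1]]), 0)
  }
})

test_that("truth_group orders levels by descending planted effect", {
  study <- simulate_study(simulation_config(
    n_genes = 80, n_mirnas = 20, n_terms = 6, n_tumor = 5, n_normal = 5,
    planted = data.frame(term = c(1, 1, 1, 2),
                         level = c("methylation", "microRNA", "mRNA",
                                   "mRNA"),
                         delta = c(2.0, 1.0, 0.5, 1.5)),
    seed = 5))
  g1 <- truth_group(study$truth, "T0001")
  expect_equal(g1$order, c("methylation", "microRNA", "mRNA"))
  expect_false(any(g1$tied))

  g2 <- truth_group(study$truth, "T0002")  # mRNA only: other two tied at 0
  expect_equal(g2$order[1], "mRNA")
  expect_true(all(g2$tied[c("methylation", "microRNA")]))
  expect_false(g2$tied["mRNA"][[1]])

  g3 <- truth_group(study$truth, "T0003")  # nothing planted: all tied
  expect_true(all(g3$tied))

  expect_error(truth_group(study$truth, "T9999"), "unknown term")
})

test_that("a written study reloads into the same analysis inputs", {
  study <- simulate_study(simulation_config(
    n_genes = 60, n_mirnas = 15, n_terms = 6, n_tumor = 6, n_normal = 6,
    seed = 44))
  dir <- tempfile("study")
  write_study(study, dir)
  meth <- read_omics_matrix(file.path(dir, "methylation.tsv"),
                            "methylation",
                            file.path(dir, "methylation_labels.tsv"))
  expect_identical(rownames(meth$values), rownames(study$meth$values))
  expect_identical(meth$labels, study$meth$labels)
  expect_lt(max(abs(meth$values - study$meth$values)), 1e-12)
  ann <- read_gmt(file.path(dir, "annotation.gmt"))
  expect_identical(ann$sets, study$annotation$sets)
  preds <- read_target_predictions(file.path(dir, "predictions.tsv"))
  expect_identical(preds$mirna, study$predictions$mirna)
  expect_identical(preds$tool, study$predictions$tool)
})
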