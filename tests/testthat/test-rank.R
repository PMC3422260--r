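test_that("descending ranks use mean ranks for ties", {
  expect_equal(rank_with_ties(c(0.9, 0.7, 0.5)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(0.9, 0.7, 0.7, 0.5)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_with_ties(c(0.4, 0.4, 0.4)), c(2, 2, 2))
  expect_error(rank_with_ties(c(1, NA)), "non-finite")
  expect_error(rank_with_ties(numeric(0)), "empty")
})

test_that("ranks always sum to T(T+1)/2, ties or not", {
  set.seed(19)
  for (i in 1:1000) {
    t_len <- sample(1:40, 1)
    v <- sample(round(runif(t_len), sample(0:2, 1)))  # engineered ties
    expect_equal(sum(rank_with_ties(v)), t_len * (t_len + 1) / 2)
  }
})

mcc_tab <- function(...) {
  rows <- list(...)
  data.frame(term_id = vapply(rows, `[[`, character(1), 1),
             mcc_methylation = vapply(rows, `[[`, numeric(1), 2),
             mcc_microRNA = vapply(rows, `[[`, numeric(1), 3),
             mcc_mRNA = vapply(rows, `[[`, numeric(1), 4),
             stringsAsFactors = FALSE)
}

test_that("terms are assigned the ordering of their three level ranks", {
  tab <- mcc_tab(list("A", 0.9, 0.5, 0.1),
                 list("B", 0.1, 0.9, 0.5),
                 list("C", 0.5, 0.1, 0.9))
  dt <- classify_groups(tab)
  expect_equal(dt$group[dt$term_id == "A"], "methylation<microRNA<mRNA")
  expect_equal(dt$group[dt$term_id == "B"], "microRNA<mRNA<methylation")
  expect_equal(dt$group[dt$term_id == "C"], "mRNA<methylation<microRNA")
  expect_false(any(dt$tie_flag))
  expect_equal(dt$summed_rank, rep(6, 3))  # 1+2+3 per term
  # per-level ranks sum to T(T+1)/2
  expect_equal(sum(dt$rank_methylation), 6)
  expect_equal(sum(dt$rank_mRNA), 6)
})

test_that("within-term rank ties resolve by level priority and are flagged", {
  # term X: methylation and microRNA MCC tie within their levels
  tab <- mcc_tab(list("X", 0.8, 0.8, 0.2),
                 list("Y", 0.4, 0.4, 0.9))
  dt <- classify_groups(tab)
  x <- dt[dt$term_id == "X", ]
  expect_equal(x$rank_methylation, x$rank_microRNA)  # both rank 1 vs Y
  expect_equal(x$group, "methylation<microRNA<mRNA")
  expect_true(x$tie_flag)
  y <- dt[dt$term_id == "Y", ]
  expect_equal(y$group, "mRNA<methylation<microRNA")
  expect_true(y$tie_flag)
  expect_error(classify_groups(mcc_tab(list("Z", NA, 1, 0))), "Z")
})

test_that("six-group counts always partition the terms", {
  set.seed(23)
  for (rep in 1:20) {
    t_len <- sample(2:60, 1)
    tab <- data.frame(term_id = paste0("T", seq_len(t_len)),
                      mcc_methylation = round(runif(t_len), 1),
                      mcc_microRNA = round(runif(t_len), 1),
                      mcc_mRNA = round(runif(t_len), 1),
                      stringsAsFactors = FALSE)
    dt <- classify_groups(tab)
    expect_equal(sum(table(dt$group)), t_len)
    expect_true(all(grepl("^(methylation|microRNA|mRNA)<", dt$group)))
    for (lv in c("rank_methylation", "rank_microRNA", "rank_mRNA"))
      expect_equal(sum(dt[[lv]]), t_len * (t_len + 1) / 2)
    expect_equal(dt$summed_rank,
                 dt$rank_methylation + dt$rank_microRNA + dt$rank_mRNA)
  }
})

test_that("overall ranking sorts by summed rank with term-id tie-break", {
  tab <- mcc_tab(list("B", 0.5, 0.5, 0.5),
                 list("A", 0.5, 0.5, 0.5),
                 list("C", 0.9, 0.9, 0.9))
  ord <- overall_ranking(classify_groups(tab))
  expect_equal(ord$term_id, c("C", "A", "B"))  # C wins, A/B tie by id
  expect_equal(ord$overall_rank, 1:3)
  expect_false(ord$sum_tie[1])
  expect_true(all(ord$sum_tie[2:3]))
  # minimum possible summed rank is 3 (rank 1 at all levels)
  expect_gte(min(ord$summed_rank), 3)

  # invariant to input order up to the documented tie-break
  perm <- overall_ranking(classify_groups(tab[c(3, 1, 2), ]))
  expect_equal(perm$term_id, ord$term_id)
  expect_equal(perm$summed_rank, ord$summed_rank)
})

test_that("top_terms slices the ordered list and validates k", {
  tab <- mcc_tab(list("A", 0.9, 0.8, 0.7), list("B", 0.1, 0.2, 0.3),
                 list("C", 0.5, 0.5, 0.5))
  ord <- overall_ranking(classify_groups(tab))
  expect_equal(top_terms(ord, 3), ord$term_id)
  expect_equal(top_terms(ord, 1), "A")
  k2 <- top_terms(ord, 2)
  expect_lte(max(ord$summed_rank[match(k2, ord$term_id)]),
             ord$summed_rank[3])
  expect_error(top_terms(ord, 0), "between")
  expect_error(top_terms(ord, 4), "between")
})

test_that("level comparison reports one-sided Welch tests with symmetry", {
  set.seed(29)
  tab <- data.frame(term_id = paste0("T", 1:30),
                    mcc_methylation = rnorm(30, 0.3, 0.1),
                    mcc_microRNA = rnorm(30, 0.5, 0.1),
                    mcc_mRNA = rnorm(30, 0.8, 0.1),
                    stringsAsFactors = FALSE)
  comp <- compare_levels(tab)
  g <- function(a, b) comp[comp$greater == a & comp$lesser == b, ]
  expect_lt(g("mRNA", "microRNA")$p_value, 0.05)
  expect_lt(g("microRNA", "methylation")$p_value, 0.05)
  # swapping the pair maps p to 1 - p in the continuous case
  expect_equal(g("mRNA", "microRNA")$p_value +
                 g("microRNA", "mRNA")$p_value, 1)

  # identical distributions: t = 0, p = 0.5 exactly
  same <- tab
  same$mcc_microRNA <- same$mcc_mRNA
  expect_equal(compare_levels(same)[
    compare_levels(same)$greater == "mRNA" &
      compare_levels(same)$lesser == "microRNA", ]$p_value, 0.5)

  # zero variance in both groups is flagged, p by sign of the difference
  flat <- data.frame(term_id = c("a", "b"),
                     mcc_methylation = c(0.2, 0.2),
                     mcc_microRNA = c(0.2, 0.2),
                     mcc_mRNA = c(0.9, 0.9), stringsAsFactors = FALSE)
  fc <- compare_levels(flat)
  row <- fc[fc$greater == "mRNA" & fc$lesser == "methylation", ]
  expect_true(row$degenerate)
  expect_equal(row$p_value, 0)
  row2 <- fc[fc$greater == "methylation" & fc$lesser == "mRNA", ]
  expect_equal(row2$p_value, 1)
  row3 <- fc[fc$greater == "methylation" & fc$lesser == "microRNA", ]
  expect_equal(row3$p_value, 0.5)
})

test_that("strong single-level planting drives the group assignment", {
  planted <- data.frame(term = 1:6,
                        level = rep(c("methylation", "microRNA", "mRNA"),
                                    2),
                        delta = 2.5)
  study <- simulate_study(simulation_config(
    n_terms = 20, planted = planted, seed = 37))
  fit <- dgsa(study$meth, study$mirna, study$mrna, study$annotation,
              study$predictions)
  idx <- match(planted$term_id <- paste0("T000", 1:6), fit$table$term_id)
  lead <- sub("<.*", "", fit$table$group[idx])
  expect_gte(sum(lead == planted$level), 5)  # >= 80% of 6
})
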