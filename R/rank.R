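#' Rank values in descending order with mean ranks for ties
#'
#' Rank 1 goes to the largest value (the most discriminating set); tied
#' values share the mean of the positions they span, so ranks always sum to
#' T(T+1)/2 for T values.
#'
#' @param values numeric vector, all finite.
#' @return numeric vector of ranks (mean ranks may be fractional).
#' @export
#' @examples
#' rank_with_ties(c(0.9, 0.7, 0.7, 0.5))  # 1, 2.5, 2.5, 4
rank_with_ties <- function(values) {
  if (!length(values)) stop("empty value vector", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite values cannot be ranked", call. = FALSE)
  rank(-values, ties.method = "average")
}

# canonical level order used for labels and for within-term tie priority
.levels3 <- c("methylation", "microRNA", "mRNA")

#' Classify terms into the six rank orderings
#'
#' MCCs are ranked within each level across all terms (rank 1 = highest
#' MCC), and each term is assigned the ordering of its three level ranks:
#' one of the 3! = 6 possible strict orderings, the level with the best
#' (smallest) rank listed first.  The level listed first is the term's most
#' dysfunctional level — the one whose signal separates tumor from normal
#' best relative to other terms.
#'
#' Every term is forced into one of the six groups: when two or three of a
#' term's level ranks are exactly equal the tie is resolved by the fixed
#' level priority methylation, then microRNA, then mRNA, and `tie_flag` is
#' set so the forced assignments remain identifiable.
#'
#' @param mcc_table `data.frame` from [score_term_sets()] with columns
#'   `term_id`, `mcc_methylation`, `mcc_microRNA`, `mcc_mRNA`.
#' @return a `dysfunction_table`: a `data.frame` with the three MCCs, the
#'   three within-level ranks (`rank_*`), the `group` label (e.g.
#'   `"methylation<microRNA<mRNA"`), `tie_flag` and `summed_rank`.
#' @export
classify_groups <- function(mcc_table) {
  need <- c("term_id", paste0("mcc_", .levels3))
  miss <- setdiff(need, colnames(mcc_table))
  if (length(miss))
    stop("mcc table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(mcc_table) < 1L) stop("no terms to classify", call. = FALSE)
  for (lv in .levels3) {
    bad <- !is.finite(mcc_table[[paste0("mcc_", lv)]])
    if (any(bad))
      stop("missing ", lv, " MCC for term(s): ",
           paste(mcc_table$term_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- mcc_table[, need]
  ranks <- sapply(.levels3, function(lv)
    rank_with_ties(mcc_table[[paste0("mcc_", lv)]]))
  ranks <- matrix(ranks, ncol = 3,
                  dimnames = list(NULL, paste0("rank_", .levels3)))
  out <- cbind(out, as.data.frame(ranks))
  cls <- apply(ranks, 1, function(r) {
    o <- order(r, seq_len(3L))  # ties fall back to level priority
    c(group = paste(.levels3[o], collapse = "<"),
      tie = anyDuplicated(r) > 0L)
  })
  out$group <- cls["group", ]
  out$tie_flag <- as.logical(cls["tie", ])
  out$summed_rank <- rowSums(ranks)
  class(out) <- c("dysfunction_table", "data.frame")
  out
}

#' Order terms by summed rank
#'
#' The dysfunction ranking: terms sorted by the sum of their three level
#' ranks, smallest sum first (most dysfunctional overall).  Equal sums are
#' broken lexicographically by term id for reproducibility, with `sum_tie`
#' marking the affected terms.
#'
#' @param table a `dysfunction_table` from [classify_groups()].
#' @return the table reordered, with columns `overall_rank` (1-based
#'   position) and `sum_tie` appended.
#' @export
overall_ranking <- function(table) {
  need <- c("term_id", "summed_rank")
  if (!all(need %in% colnames(table)))
    stop("expected a dysfunction table with term_id and summed_rank",
         call. = FALSE)
  o <- order(table$summed_rank, table$term_id)
  out <- table[o, , drop = FALSE]
  out$overall_rank <- seq_len(nrow(out))
  dup <- duplicated(out$summed_rank) | duplicated(out$summed_rank,
                                                  fromLast = TRUE)
  out$sum_tie <- dup
  rownames(out) <- NULL
  out
}

#' Top k dysfunctional terms
#'
#' @param ordered a table from [overall_ranking()] (or any term-ordered
#'   data frame / character vector of term ids).
#' @param k how many leading terms to keep; must lie in \[1, T\].
#' @return character vector of the first `k` term ids.
#' @export
top_terms <- function(ordered, k) {
  ids <- if (is.character(ordered)) ordered else ordered$term_id
  if (is.null(ids)) stop("cannot find term ids in 'ordered'", call. = FALSE)
  if (k < 1L || k > length(ids))
    stop("'k' must be between 1 and ", length(ids), call. = FALSE)
  ids[seq_len(k)]
}

#' Compare MCC distributions between levels
#'
#' For every ordered pair of levels, a Welch (unequal-variance) one-sided
#' t-test of whether the first level's MCCs are greater, over the term-wise
#' MCC distributions.  With a mean difference of exactly zero and no
#' variance in either group the p-value is reported as 0.5; with zero
#' variance and a nonzero difference it is 0 or 1 by the sign of the
#' difference — such degenerate cases are flagged.
#'
#' @param mcc_table `data.frame` from [score_term_sets()].
#' @return `data.frame` with one row per ordered level pair: the two level
#'   names, their mean MCCs, the one-sided p-value and a `degenerate` flag.
#' @export
compare_levels <- function(mcc_table) {
  if (nrow(mcc_table) < 2L)
    stop("need at least two terms to compare levels", call. = FALSE)
  cols <- stats::setNames(paste0("mcc_", .levels3), .levels3)
  pairs <- expand.grid(greater = .levels3, lesser = .levels3,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$greater != pairs$lesser, ]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- mcc_table[[cols[pairs$greater[i]]]]
    y <- mcc_table[[cols[pairs$lesser[i]]]]
    degen <- stats::sd(x) == 0 && stats::sd(y) == 0
    if (degen) {
      d <- mean(x) - mean(y)
      p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    } else {
      p <- stats::t.test(x, y, alternative = "greater",
                         var.equal = FALSE)$p.value
    }
    data.frame(greater = pairs$greater[i], lesser = pairs$lesser[i],
               mean_greater = mean(x), mean_lesser = mean(y),
               p_value = p, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
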