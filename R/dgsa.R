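#' Dysfunctional gene set analysis
#'
#' The central analysis: given tumor-versus-normal matrices from three
#' platforms, a term annotation and multi-tool microRNA target predictions,
#' build the three member sets per term, score each set's tumor/normal
#' discriminating ability (leave-one-out nearest-neighbor classification
#' under cosine distance, summarized as an MCC), rank the MCCs within each
#' level, classify every term into one of the six possible rank orderings of
#' its methylation/microRNA/mRNA ranks, and order terms by summed rank —
#' smallest sum first, the most dysfunctional terms overall.
#'
#' @param meth,mirna,mrna the three [omics_matrix()] objects.
#' @param annotation an [annotation_map()] of term -> annotated genes.
#' @param predictions target prediction `data.frame` (columns `mirna`,
#'   `gene`, `tool`), e.g. from [read_target_predictions()].
#' @param min_tools consensus threshold for target predictions (default 3).
#' @param min_size minimum members per level for a term to be analyzed
#'   (default 1, i.e. data at all three levels).
#' @return an object of class `dgsa`: a list with `table` (the ordered
#'   dysfunction table: MCCs, ranks, group, tie flags, summed rank, overall
#'   rank), `mcc` (the raw term-by-level MCC table), `comparison`
#'   (level-wise mean MCCs and one-sided Welch p-values), `sets` (the
#'   filtered term-level sets), `targets` (the consensus target map),
#'   `n_terms`, and the `call`.
#' @seealso [top_terms()], [member_frequency()], [high_frequency()],
#'   [hypergeom_enrichment()], [validate_independent()] for the downstream
#'   steps; [simulate_study()] for synthetic input.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(
#'   n_genes = 80, n_mirnas = 20, n_terms = 8, term_size = c(5, 10),
#'   n_tumor = 10, n_normal = 10,
#'   planted = data.frame(term = 1, level = "mRNA", delta = 2.5),
#'   seed = 7))
#' fit <- dgsa(study$meth, study$mirna, study$mrna,
#'             study$annotation, study$predictions)
#' head(fit$table)
dgsa <- function(meth, mirna, mrna, annotation, predictions,
                 min_tools = 3L, min_size = 1L) {
  cl <- match.call()
  for (m in list(meth, mirna, mrna))
    if (!inherits(m, "omics_matrix"))
      stop("matrices must be omics_matrix objects; see read_omics_matrix()",
           call. = FALSE)
  targets <- consensus_targets(predictions, min_tools = min_tools)
  sets <- build_term_sets(annotation,
                          meth_features = rownames(meth$values),
                          mirna_features = rownames(mirna$values),
                          mrna_features = rownames(mrna$values),
                          targets = targets)
  sets <- filter_terms(sets, min_size = min_size)
  mcc_table <- score_term_sets(meth, mirna, mrna, sets)
  table <- overall_ranking(classify_groups(mcc_table))
  structure(list(table = table, mcc = mcc_table,
                 comparison = compare_levels(mcc_table),
                 sets = sets, targets = targets,
                 n_terms = nrow(table), call = cl),
            class = "dgsa")
}

#' @export
print.dgsa <- function(x, n = 6L, ...) {
  cat("Dysfunctional gene set analysis\n")
  cat(sprintf("  %d terms with data at all three levels\n", x$n_terms))
  means <- colMeans(x$mcc[, paste0("mcc_", .levels3)])
  cat(sprintf("  mean MCC: methylation %.3f, microRNA %.3f, mRNA %.3f\n",
              means[1], means[2], means[3]))
  cat(sprintf("\nTop %d dysfunctional terms (by summed rank):\n",
              min(n, x$n_terms)))
  cols <- c("term_id", "summed_rank", "group")
  print(utils::head(x$table[, cols], n), row.names = FALSE)
  invisible(x)
}

#' Summarize a dysfunction analysis
#'
#' Reports the six-group partition of the terms, the mean MCC per level with
#' the one-sided Welch t-test comparisons between consecutive levels, and
#' the leading terms of the summed-rank ordering.
#'
#' @param object a [dgsa()] fit.
#' @param n how many top terms to show.
#' @param ... unused.
#' @return an object of class `summary.dgsa`, printed with its own method.
#' @export
summary.dgsa <- function(object, n = 10L, ...) {
  group_levels <- apply(.perms3(), 1, function(o)
    paste(.levels3[o], collapse = "<"))
  counts <- table(factor(object$table$group, levels = group_levels))
  structure(list(n_terms = object$n_terms,
                 group_counts = counts,
                 n_rank_ties = sum(object$table$tie_flag),
                 mean_mcc = colMeans(
                   object$mcc[, paste0("mcc_", .levels3)]),
                 comparison = object$comparison,
                 top = utils::head(object$table, n)),
            class = "summary.dgsa")
}

# the 6 permutations of 3 elements, rows in lexicographic order
.perms3 <- function() {
  m <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  m <- as.matrix(m[m$a != m$b & m$a != m$c & m$b != m$c,
                   c("a", "b", "c")])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @export
print.summary.dgsa <- function(x, ...) {
  cat("Dysfunctional gene set analysis —", x$n_terms, "terms\n\n")
  cat("Six-group partition (level with best rank listed first):\n")
  for (g in names(x$group_counts))
    cat(sprintf("  %-34s %d\n", g, x$group_counts[g]))
  cat(sprintf("  (%d terms carried a within-term rank tie)\n\n",
              x$n_rank_ties))
  cat("Mean MCC per level:\n")
  cat(sprintf("  methylation %.3f, microRNA %.3f, mRNA %.3f\n\n",
              x$mean_mcc[1], x$mean_mcc[2], x$mean_mcc[3]))
  comp <- x$comparison
  for (pair in list(c("mRNA", "microRNA"), c("microRNA", "methylation"))) {
    row <- comp[comp$greater == pair[1] & comp$lesser == pair[2], ]
    cat(sprintf("  one-sided Welch t-test %s > %s: p = %.3g\n",
                pair[1], pair[2], row$p_value))
  }
  cat("\nTop terms by summed rank:\n")
  print(x$top[, c("term_id", "summed_rank", "group", "overall_rank")],
        row.names = FALSE)
  invisible(x)
}

#' Boxplot of MCC distributions by level
#'
#' One box per molecular level over the per-term MCCs, the standard view of
#' how discriminating the three levels are overall.
#'
#' @param x a [dgsa()] fit.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.dgsa <- function(x, ...) {
  vals <- list(methylation = x$mcc$mcc_methylation,
               microRNA = x$mcc$mcc_microRNA,
               mRNA = x$mcc$mcc_mRNA)
  graphics::boxplot(vals, ylab = "MCC (LOOCV, nearest neighbor)",
                    xlab = "molecular level", ...)
  invisible(x)
}

#' @export
coef.dgsa <- function(object, ...) {
  m <- as.matrix(object$mcc[, paste0("mcc_", .levels3)])
  rownames(m) <- object$mcc$term_id
  colnames(m) <- .levels3
  m
}
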