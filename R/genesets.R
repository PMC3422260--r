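#' Consensus microRNA targets across prediction tools
#'
#' MicroRNA target predictions are noisy and tool-specific, so a
#' (microRNA, gene) pair is accepted only when at least `min_tools` distinct
#' tools predict it (default 3, out of a tool universe of typically 6).
#' Duplicate records from one tool count once: tools are counted, not
#' records.
#'
#' @param predictions a `data.frame` with columns `mirna`, `gene`, `tool`,
#'   e.g. from [read_target_predictions()].
#' @param min_tools minimum number of distinct predicting tools, at least 1
#'   and no more than the tool universe size.
#' @return named list mapping each retained microRNA id to the character
#'   vector of its consensus target genes.
#' @export
#' @examples
#' preds <- data.frame(mirna = "miR-1", gene = "KRAS",
#'                     tool = c("A", "B", "C"))
#' consensus_targets(preds, min_tools = 3)
consensus_targets <- function(predictions, min_tools = 3L) {
  tools <- attr(predictions, "tool_universe")
  if (is.null(tools)) tools <- unique(predictions$tool)
  if (min_tools < 1L)
    stop("'min_tools' must be at least 1", call. = FALSE)
  if (nrow(predictions) == 0L) {
    warning("empty prediction table: no consensus targets", call. = FALSE)
    return(stats::setNames(list(), character(0)))
  }
  if (min_tools > length(tools))
    stop("'min_tools' (", min_tools, ") exceeds the tool universe size (",
         length(tools), ")", call. = FALSE)
  # distinct tools per (mirna, gene) pair
  pair <- paste(predictions$mirna, predictions$gene, sep = "\r")
  uniq <- !duplicated(paste(pair, predictions$tool, sep = "\r"))
  n_tools <- table(pair[uniq])
  keep <- names(n_tools)[n_tools >= min_tools]
  if (!length(keep)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  mir <- vapply(parts, `[`, character(1), 1L)
  gene <- vapply(parts, `[`, character(1), 2L)
  out <- split(gene, mir)
  lapply(out, function(g) sort(unique(g)))
}

#' Build the three member sets for every annotation term
#'
#' Each functional term is represented at three molecular levels:
#' \itemize{
#'   \item methylation genes: annotated genes whose methylation was measured
#'     (annotation intersected with the methylation feature universe);
#'   \item microRNAs: measured microRNAs with at least one consensus target
#'     gene annotated to the term;
#'   \item mRNA genes: annotated genes measured on the mRNA platform.
#' }
#' The output is invariant to the order of the prediction records and to the
#' order of the universes.  Empty sets are allowed here; [filter_terms()]
#' removes terms lacking data at any level.
#'
#' @param annotation an [annotation_map()] of term -> annotated genes.
#' @param meth_features,mirna_features,mrna_features character vectors of the
#'   measured feature universes (genes, microRNA ids, genes).
#' @param targets named list microRNA -> consensus target genes, from
#'   [consensus_targets()].
#' @return list of term-level sets; each element is a list with `term_id`,
#'   `methylation_genes`, `mirnas`, `mrna_genes`.
#' @export
build_term_sets <- function(annotation, meth_features, mirna_features,
                            mrna_features, targets) {
  stopifnot(inherits(annotation, "annotation_map"))
  if (!length(meth_features) || !length(mirna_features) ||
      !length(mrna_features))
    stop("all three measured feature universes must be nonempty",
         call. = FALSE)
  targets <- targets[names(targets) %in% mirna_features]
  lapply(names(annotation$sets), function(id) {
    ann <- annotation$sets[[id]]
    hit <- vapply(targets, function(g) any(g %in% ann), logical(1))
    list(term_id = id,
         methylation_genes = sort(intersect(ann, meth_features)),
         mirnas = sort(names(targets)[hit]),
         mrna_genes = sort(intersect(ann, mrna_features)))
  })
}

#' Keep terms with data at every level
#'
#' A term can only be compared across levels when all three of its member
#' sets are populated; terms failing the size threshold at any level are
#' dropped.  Output order follows input order.
#'
#' @param sets list of term-level sets from [build_term_sets()].
#' @param min_size minimum members required in each of the three sets
#'   (default 1, i.e. plain three-level availability).
#' @return the retained subset of `sets`, in stable order.
#' @export
filter_terms <- function(sets, min_size = 1L) {
  if (min_size < 1L) stop("'min_size' must be at least 1", call. = FALSE)
  ok <- vapply(sets, function(s) {
    length(s$methylation_genes) >= min_size &&
      length(s$mirnas) >= min_size &&
      length(s$mrna_genes) >= min_size
  }, logical(1))
  if (!any(ok))
    stop("no term has >= ", min_size, " members at all three levels; ",
         "loosen 'min_size' or check the annotation and universes",
         call. = FALSE)
  sets[ok]
}

#' Export the three per-level gene set collections as GMT files
#'
#' Writes one GMT file per level (term, member count, members), microRNA set
#' members being microRNA ids.
#'
#' @param sets list of term-level sets from [build_term_sets()].
#' @param dir output directory (created if needed).
#' @return character vector of the three paths, invisibly.
#' @export
write_term_sets <- function(sets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(sets, `[[`, character(1), "term_id")
  paths <- file.path(dir, c("sets_methylation.gmt", "sets_microRNA.gmt",
                            "sets_mRNA.gmt"))
  write_gmt(stats::setNames(lapply(sets, `[[`, "methylation_genes"), ids),
            paths[1])
  write_gmt(stats::setNames(lapply(sets, `[[`, "mirnas"), ids), paths[2])
  write_gmt(stats::setNames(lapply(sets, `[[`, "mrna_genes"), ids), paths[3])
  invisible(paths)
}
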