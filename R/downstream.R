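#' Member frequency in the top dysfunctional sets
#'
#' Counts, for every gene or microRNA, how many of the top dysfunctional
#' terms contain it at the requested level.  Gene frequency is computed
#' separately for mRNA-level and methylation-level membership, since a gene
#' can be a high-frequency member at one level only.
#'
#' @param top_terms character vector of term ids (e.g. from [top_terms()]).
#' @param sets list of term-level sets from [build_term_sets()], covering at
#'   least `top_terms`.
#' @param level_class which membership to count: `"gene_mrna"`,
#'   `"gene_methylation"` or `"microRNA"`.
#' @return `data.frame` with columns `member` and `count` (count in
#'   \[1, K\] for K top terms; members in no top set are simply absent),
#'   sorted by decreasing count then member id.
#' @export
member_frequency <- function(top_terms, sets,
                             level_class = c("gene_mrna",
                                             "gene_methylation",
                                             "microRNA")) {
  level_class <- match.arg(level_class)
  ids <- vapply(sets, `[[`, character(1), "term_id")
  unknown <- setdiff(top_terms, ids)
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  field <- switch(level_class, gene_mrna = "mrna_genes",
                  gene_methylation = "methylation_genes",
                  microRNA = "mirnas")
  members <- unlist(lapply(sets[match(top_terms, ids)], `[[`, field),
                    use.names = FALSE)
  if (!length(members))
    return(data.frame(member = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  counts <- table(members)
  out <- data.frame(member = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$member), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-frequency members
#'
#' Members whose frequency in the top dysfunctional sets strictly exceeds
#' the threshold (frequency *higher than* the threshold, default 50).
#'
#' @param freq `data.frame` from [member_frequency()].
#' @param threshold nonnegative count cutoff; strictly-greater comparison.
#' @return character vector of member ids.
#' @export
high_frequency <- function(freq, threshold = 50L) {
  if (threshold < 0) stop("'threshold' must be >= 0", call. = FALSE)
  freq$member[freq$count > threshold]
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability that at least the observed number of hits fall in
#' the reference set when `|hits|` members are drawn without replacement
#' from the universe: P(X >= overlap) for X hypergeometric with universe
#' size N and reference size K.  Used to ask whether high-frequency genes
#' are significantly over-represented in a known pathway.
#'
#' @param hits character vector, e.g. the high-frequency genes; must be a
#'   subset of `universe`.
#' @param reference character vector, the pathway gene set; subset of
#'   `universe`.
#' @param universe character vector of all candidate members (typically all
#'   genes measured on the mRNA platform).
#' @return the p-value, in (0, 1\].
#' @export
#' @examples
#' hypergeom_enrichment(letters[1:5], letters[1:5], letters[1:10])
#' # = 1 / choose(10, 5)
hypergeom_enrichment <- function(hits, reference, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  reference <- unique(reference)
  out <- setdiff(c(hits, reference), universe)
  if (length(out))
    stop("hits/reference contain id(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  n_overlap <- length(intersect(hits, reference))
  stats::phyper(n_overlap - 1L, length(reference),
                length(universe) - length(reference), length(hits),
                lower.tail = FALSE)
}

#' Validate a marker gene set in an independent cohort
#'
#' Scores the discriminating ability of a gene set — typically the
#' high-frequency genes — in an independent labeled cohort, by the same
#' machinery used throughout: leave-one-out nearest-neighbor classification
#' under cosine distance, summarized as an MCC.  An MCC of 1 means every
#' independent sample was assigned its true class.
#'
#' @param high_freq_genes character vector of gene ids; must intersect the
#'   cohort's features.
#' @param independent an [omics_matrix()] for the validation cohort.
#' @return the MCC, in \[-1, 1\].
#' @export
validate_independent <- function(high_freq_genes, independent) {
  stopifnot(inherits(independent, "omics_matrix"))
  present <- intersect(high_freq_genes, rownames(independent$values))
  if (!length(present))
    stop("none of the genes are measured in the independent cohort; ",
         "missing: ",
         paste(utils::head(high_freq_genes, 5), collapse = ", "),
         if (length(high_freq_genes) > 5) ", ..." else "", call. = FALSE)
  mcc(loocv_confusion(independent, present))
}
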