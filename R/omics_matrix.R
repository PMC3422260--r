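#' Construct a labeled omics matrix
#'
#' An `omics_matrix` bundles one platform's feature-by-sample value matrix
#' with a two-class (tumor/normal) label for every sample.  It is the unit of
#' data the discrimination machinery operates on: columns are sample vectors,
#' rows are features (genes, CpG-profiled genes, or microRNAs, depending on
#' `level`).
#'
#' Validation is strict: dimensions must match the identifier vectors,
#' identifiers must be unique, no value may be missing or non-numeric, and
#' both classes must be present.  Missing values are rejected rather than
#' imputed.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique row identifiers.  Defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique column identifiers.  Defaults
#'   to `colnames(values)`.
#' @param labels character or factor, one of `"tumor"`/`"normal"` per sample.
#' @param level one of `"methylation"`, `"microRNA"`, `"mRNA"`.
#'
#' @return an object of class `omics_matrix`: a list with elements `values`
#'   (the matrix, dimnames set), `labels` (factor with levels tumor/normal)
#'   and `level`.
#' @seealso [read_omics_matrix()] to build one from tab-separated files.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' om <- omics_matrix(m, labels = c("tumor", "tumor", "normal", "normal"),
#'                    level = "mRNA")
#' dim(om$values)
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values), labels,
                         level = c("mRNA", "methylation", "microRNA")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) ||
      ncol(values) != length(sample_ids))
    stop(sprintf("value matrix is %d x %d but %d feature and %d sample ids were given",
                 nrow(values), ncol(values),
                 length(feature_ids), length(sample_ids)), call. = FALSE)
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicated feature id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 feature_ids[idx[1]], sample_ids[idx[2]]), call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids))
    stop("one label per sample is required", call. = FALSE)
  bad <- setdiff(unique(labels), c("tumor", "normal"))
  if (length(bad))
    stop("labels must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  labels <- factor(labels, levels = c("tumor", "normal"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes (tumor and normal) must be present", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, labels = labels, level = level),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%d tumor, %d normal)\n",
              x$level, nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Restrict an omics_matrix to a feature subset, preserving matrix row order.
# Internal; errors when the subset misses the matrix entirely.
restrict_features <- function(x, feature_set) {
  stopifnot(inherits(x, "omics_matrix"))
  keep <- rownames(x$values) %in% feature_set
  if (!any(keep))
    stop("feature set shares no features with the ", x$level,
         " matrix (first requested: ",
         paste(utils::head(feature_set, 3), collapse = ", "), ")",
         call. = FALSE)
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Construct an annotation map
#'
#' A named list mapping term identifiers to their annotated member
#' identifiers, as read from a GMT-style file.  Every member set must be
#' nonempty and term ids must be unique.
#'
#' @param sets named list of character vectors (term id -> members).
#' @param descriptions optional character vector of term descriptions, one
#'   per term.
#' @return an object of class `annotation_map`.
#' @export
annotation_map <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list of member vectors", call. = FALSE)
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicated term id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty member set for term(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (!is.null(descriptions)) {
    if (length(descriptions) != length(sets))
      stop("need one description per term", call. = FALSE)
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms, member set sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Confusion counts from a two-class evaluation
#'
#' Tallies of true/false tumor and control calls, with tumor as the positive
#' class.  The four counts must be nonnegative and their total equals the
#' number of evaluated samples.
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return an object of class `confusion_counts` (named numeric vector).
#' @seealso [mcc()]
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  structure(as.numeric(counts), names = names(counts),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%g TN=%g FP=%g FN=%g (n=%g)\n",
              x["TP"], x["TN"], x["FP"], x["FN"], sum(x)))
  invisible(x)
}
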