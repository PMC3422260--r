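#' Read a feature-by-sample matrix and its sample labels
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' feature id in the first column; the label file is a two-column
#' tab-separated table (header `sample_id`, `class`) mapping every sample id
#' to `tumor` or `normal`.  This mirrors the series-matrix convention of
#' public repositories while keeping labels out of the matrix header, so
#' matrices stay platform-agnostic.
#'
#' Row and column order are preserved from the file.  Identifiers are
#' case-sensitive exact strings; no aliasing is attempted.  Duplicate ids,
#' unlabeled samples, missing or non-numeric cells all raise an error naming
#' the file and the offending row or column.
#'
#' @param path path to the tab-separated matrix file.
#' @param level platform of the matrix: `"methylation"`, `"microRNA"` or
#'   `"mRNA"`.
#' @param labels_path path to the two-column label file.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, level, labels_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("'", path, "': expected a feature id column plus sample columns",
         call. = FALSE)
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("'%s': non-numeric or missing value '%s' at feature '%s' (row %d), sample '%s'",
                 path, cells[idx[1], idx[2]], feature_ids[idx[1]],
                 idx[1] + 1L, sample_ids[idx[2]]), call. = FALSE)
  }
  labels <- read_labels(labels_path)
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("'", labels_path, "': no label for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  tryCatch(
    omics_matrix(values, labels = labels[sample_ids], level = level),
    error = function(e) stop("'", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
}

#' Read a sample label file
#'
#' @param path two-column tab-separated file with header `sample_id`,
#'   `class`; classes must be `tumor` or `normal`.
#' @return named character vector of classes, names are sample ids.
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L)
    stop("'", path, "': expected columns sample_id and class", call. = FALSE)
  dup <- unique(lab[[1]][duplicated(lab[[1]])])
  if (length(dup))
    stop("'", path, "': duplicated sample id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(lab[[2]]), c("tumor", "normal"))
  if (length(bad))
    stop("'", path, "': classes must be tumor/normal; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  stats::setNames(lab[[2]], lab[[1]])
}

#' Read a GMT-style gene set file
#'
#' Each line holds a term id, a second field (either a free-text description
#' or the declared member count), then the tab-separated member ids.  When
#' the second field parses as an integer it is checked against the actual
#' member count; a mismatch, an empty member list or a repeated term id is an
#' error naming the term.
#'
#' @param path path to the GMT file.
#' @return an [annotation_map()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("GO:0001525\t3\tVEGFA\tKDR\tFLT1", f)
#' am <- read_gmt(f)
#' lengths(am$sets)
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("'", path, "': empty file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("'", path, "': duplicated term id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  sets <- vector("list", length(fields))
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("'", path, "': term '", ids[i], "' has no members", call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop("'", path, "': term '", ids[i], "' has no members", call. = FALSE)
    declared <- suppressWarnings(as.integer(f[2]))
    if (!is.na(declared) && grepl("^[0-9]+$", f[2]) &&
        declared != length(members))
      stop(sprintf("'%s': term '%s' declares %d members but lists %d",
                   path, ids[i], declared, length(members)), call. = FALSE)
    sets[[i]] <- members
    desc[i] <- f[2]
  }
  names(sets) <- ids
  annotation_map(sets, descriptions = desc)
}

#' Write an annotation map (or plain named list of sets) as GMT
#'
#' Lines are `term <tab> member-count <tab> members...`, the layout used for
#' the per-level gene set exports.
#'
#' @param x an [annotation_map()] or a named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  sets <- if (inherits(x, "annotation_map")) x$sets else x
  if (!length(sets)) stop("nothing to write: no gene sets", call. = FALSE)
  lines <- vapply(names(sets), function(id) {
    paste(c(id, length(sets[[id]]), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read microRNA target prediction records
#'
#' A tab-separated table with header columns `mirna`, `gene`, `tool`.
#' Duplicate (microRNA, gene, tool) triples are an error: a tool either
#' predicts a pair or it does not.
#'
#' @param path path to the prediction table.
#' @param tool_universe optional character vector of all tool names; defaults
#'   to the tools observed in the file.  Unknown tool names in the file are
#'   an error when a universe is supplied.
#' @return a `data.frame` with columns `mirna`, `gene`, `tool` and attribute
#'   `tool_universe`.
#' @export
read_target_predictions <- function(path, tool_universe = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "tool")
  if (!all(need %in% colnames(tab)))
    stop("'", path, "': expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[, need]
  key <- do.call(paste, c(tab, sep = "\r"))
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("'%s': duplicated prediction record (%s, %s, %s)",
                 path, d$mirna, d$gene, d$tool), call. = FALSE)
  }
  if (is.null(tool_universe)) {
    tool_universe <- sort(unique(tab$tool))
  } else {
    unknown <- setdiff(unique(tab$tool), tool_universe)
    if (length(unknown))
      stop("'", path, "': tool(s) outside the declared universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(tab, "tool_universe") <- tool_universe
  tab
}

#' Write a tabular result as tab-separated text
#'
#' Plain TSV with a header row; numeric columns round-trip through
#' [read_tsv_table()] to within 1e-12.  Writing an empty table is an error.
#'
#' @param table a nonempty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("refusing to write an empty table", call. = FALSE)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an omics matrix and its labels to tab-separated files
#'
#' @param x an [omics_matrix()].
#' @param path output path for the matrix (first column `feature_id`).
#' @param labels_path output path for the two-column label table.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, labels_path) {
  stopifnot(inherits(x, "omics_matrix"))
  tab <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  lab <- data.frame(sample_id = colnames(x$values),
                    class = as.character(x$labels),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
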