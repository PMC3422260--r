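#' Cosine distance between two sample vectors
#'
#' The distance between two samples restricted to a feature set is one minus
#' the cosine similarity of the two value vectors,
#' \deqn{d(x, y) = 1 - \frac{x \cdot y}{\|x\|\,\|y\|},}
#' which lies in \[0, 2\].  Values are used as measured; no standardization
#' is applied before the distance computation.
#'
#' A zero-norm vector has no direction, so the distance is defined as 1
#' (maximal indifference) with a warning rather than failing: constant-zero
#' sample slices must not abort a scan over thousands of feature sets.
#'
#' @param x,y numeric vectors of equal positive length.
#' @return the cosine distance, a single number in \[0, 2\].
#' @export
#' @examples
#' cosine_distance(c(1, 2, 3), c(1, 2, 3))  # 0
#' cosine_distance(c(1, 0), c(0, 1))        # 1
#' cosine_distance(c(1, 1), c(1, 0))        # 1 - sqrt(2)/2
cosine_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  if (length(x) == 0L) stop("zero-length sample vectors", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm sample vector; cosine distance defined as 1",
            call. = FALSE)
    return(1)
  }
  1 - sum(x * y) / (nx * ny)
}

# Pairwise cosine distance between columns of v (features x samples) and
# columns of w.  Zero-norm columns get distance 1 to everything, with one
# warning.  Internal workhorse shared by prediction and LOOCV.
cosine_distance_matrix <- function(v, w = v) {
  nv <- sqrt(colSums(v^2))
  nw <- sqrt(colSums(w^2))
  zv <- nv == 0
  zw <- nw == 0
  if (any(zv) || any(zw))
    warning("zero-norm sample vector(s); cosine distance defined as 1",
            call. = FALSE)
  nv[zv] <- 1
  nw[zw] <- 1
  sim <- crossprod(v, w) / outer(nv, nw)
  sim[zv, ] <- 0
  sim[, zw] <- 0
  1 - sim
}

#' Nearest-neighbor class prediction
#'
#' A query sample is predicted to have the class of its nearest training
#' sample under cosine distance (a 1-nearest-neighbor rule).  Distance ties
#' are broken deterministically in favor of the smallest training-sample
#' position, so predictions are reproducible and permutation-testable.
#'
#' @param train an [omics_matrix()], already restricted to the feature set of
#'   interest.
#' @param query numeric vector with one value per training feature (same
#'   order as `rownames(train$values)`).
#' @return the predicted class, `"tumor"` or `"normal"`.
#' @export
nna_predict <- function(train, query) {
  stopifnot(inherits(train, "omics_matrix"))
  if (nrow(train$values) == 0L)
    stop("empty feature set: no rows in training matrix", call. = FALSE)
  if (length(query) != nrow(train$values))
    stop("query length ", length(query), " does not match ",
         nrow(train$values), " training features", call. = FALSE)
  d <- cosine_distance_matrix(train$values, matrix(query, ncol = 1))
  as.character(train$labels[which.min(d)])
}

#' Leave-one-out confusion counts for a feature set
#'
#' Every sample is held out once and predicted by the nearest-neighbor rule
#' trained on all remaining samples, using only the rows of `matrix` named in
#' `feature_set`.  Tumor is the positive class: TP counts tumor samples
#' called tumor, TN normal samples called normal, FP normal samples called
#' tumor, FN tumor samples called normal.
#'
#' @param matrix an [omics_matrix()] with at least two samples.
#' @param feature_set character vector of feature ids; must intersect the
#'   matrix rows.
#' @return a [confusion_counts()] object totalling the sample count.
#' @seealso [mcc()] to summarize the counts.
#' @export
loocv_confusion <- function(matrix, feature_set) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (ncol(matrix$values) < 2L)
    stop("LOOCV needs at least two samples", call. = FALSE)
  sub <- restrict_features(matrix, feature_set)
  d <- cosine_distance_matrix(sub$values)
  diag(d) <- Inf
  nn <- apply(d, 2, which.min)  # first minimum = smallest training position
  pred <- sub$labels[nn]
  truth <- sub$labels
  confusion_counts(tp = sum(truth == "tumor" & pred == "tumor"),
                   tn = sum(truth == "normal" & pred == "normal"),
                   fp = sum(truth == "normal" & pred == "tumor"),
                   fn = sum(truth == "tumor" & pred == "normal"))
}

#' Matthews correlation coefficient
#'
#' A balanced summary of two-class prediction performance,
#' \deqn{\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' in \[-1, 1\]: 1 for perfect prediction, 0 for performance no better than
#' chance, -1 for total disagreement.  When any factor of the denominator is
#' zero the coefficient is defined as 0, the standard convention.
#'
#' @param c a [confusion_counts()] object, or anything coercible to a named
#'   numeric vector with elements TP, TN, FP, FN.
#' @return the coefficient, a single number in \[-1, 1\].
#' @export
#' @examples
#' mcc(confusion_counts(10, 10, 0, 0))  # 1
#' mcc(confusion_counts(6, 4, 1, 2))    # 22 / sqrt(1680)
mcc <- function(c) {
  if (!inherits(c, "confusion_counts"))
    c <- confusion_counts(c[["TP"]], c[["TN"]], c[["FP"]], c[["FN"]])
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  if (tp + tn + fp + fn == 0)
    stop("no evaluated samples: all counts are zero", call. = FALSE)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Score every term's three member sets
#'
#' For each term, the methylation, microRNA and mRNA member sets are scored
#' on their respective matrices by leave-one-out nearest-neighbor
#' classification summarized as an MCC.  The computation is deterministic.
#'
#' @param meth,mirna,mrna the three [omics_matrix()] objects
#'   (levels methylation, microRNA and mRNA respectively).
#' @param sets a list of term-level sets as produced by
#'   [build_term_sets()] (each element a list with `term_id`,
#'   `methylation_genes`, `mirnas`, `mrna_genes`).
#' @return a `data.frame` with columns `term_id`, `mcc_methylation`,
#'   `mcc_microRNA`, `mcc_mRNA`, one row per term.
#' @export
score_term_sets <- function(meth, mirna, mrna, sets) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(mirna, "omics_matrix"),
            inherits(mrna, "omics_matrix"))
  ids <- vapply(sets, `[[`, character(1), "term_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated term id(s) in input sets: ",
         paste(dup, collapse = ", "), call. = FALSE)
  score1 <- function(m, members) mcc(loocv_confusion(m, members))
  data.frame(
    term_id = ids,
    mcc_methylation = vapply(sets, function(s)
      score1(meth, s$methylation_genes), numeric(1)),
    mcc_microRNA = vapply(sets, function(s)
      score1(mirna, s$mirnas), numeric(1)),
    mcc_mRNA = vapply(sets, function(s)
      score1(mrna, s$mrna_genes), numeric(1)),
    stringsAsFactors = FALSE
  )
}
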