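# Independent brute-force re-implementations used as oracles.  These share
# no code with the package: plain loops and direct formulas only.

# cosine distance by explicit sums
bf_cosine <- function(x, y) {
  num <- 0; nx <- 0; ny <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    nx <- nx + x[i]^2
    ny <- ny + y[i]^2
  }
  if (nx == 0 || ny == 0) return(1)
  1 - num / (sqrt(nx) * sqrt(ny))
}

# LOOCV 1-NN with cosine distance, tumor positive; values: features x
# samples, labels: character vector.  Ties go to the smallest sample index.
bf_loocv <- function(values, labels) {
  n <- ncol(values)
  pred <- character(n)
  for (j in seq_len(n)) {
    best_d <- Inf
    best_i <- NA_integer_
    for (i in seq_len(n)) {
      if (i == j) next
      d <- bf_cosine(values[, i], values[, j])
      if (d < best_d) {
        best_d <- d
        best_i <- i
      }
    }
    pred[j] <- labels[best_i]
  }
  c(TP = sum(labels == "tumor" & pred == "tumor"),
    TN = sum(labels == "normal" & pred == "normal"),
    FP = sum(labels == "normal" & pred == "tumor"),
    FN = sum(labels == "tumor" & pred == "normal"))
}

# direct MCC formula with the zero-denominator convention
bf_mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# exact upper-tail hypergeometric by enumerating every draw of size n_hits
# from the universe (feasible for universes up to ~12)
bf_hypergeom <- function(n_universe, n_reference, n_hits, overlap) {
  draws <- utils::combn(n_universe, n_hits)
  in_ref <- colSums(draws <= n_reference)  # wlog reference = first K items
  mean(in_ref >= overlap)
}

# a small labeled omics matrix with separated classes, for direct tests
toy_matrix <- function(n_tumor = 10, n_normal = 10, n_features = 3,
                       center = 1, noise = 0.01, level = "mRNA",
                       seed = 1) {
  set.seed(seed)
  tum <- matrix(rnorm(n_features * n_tumor, center, noise), n_features)
  nor <- matrix(rnorm(n_features * n_normal, -center, noise), n_features)
  values <- cbind(tum, nor)
  dimnames(values) <- list(paste0("f", seq_len(n_features)),
                           paste0("s", seq_len(n_tumor + n_normal)))
  omics_matrix(values,
               labels = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
               level = level)
}
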