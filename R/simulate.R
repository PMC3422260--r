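#' Configuration for a synthetic multi-omics study
#'
#' Collects every knob of the generator: universe sizes, annotation shape,
#' per-platform sample counts, the planted per-(term, level) effect sizes,
#' the noise scale, and the target-prediction mechanism.  Defaults are sized
#' for desk-scale runs (300 genes, 60 microRNAs, 40 terms, 30 + 30 samples)
#' while keeping the statistical structure of a three-platform
#' tumor-versus-normal study: two-class labels, overlapping but
#' non-identical gene universes across platforms, and level-specific
#' differential signal concentrated in chosen terms.
#'
#' @param n_genes,n_mirnas,n_terms sizes of the gene universe, microRNA
#'   universe and annotation.
#' @param term_size integer range `c(min, max)` of annotated genes per term.
#' @param n_tumor,n_normal samples per class; a single value applies to all
#'   platforms, or give a length-3 vector ordered methylation, microRNA,
#'   mRNA.
#' @param n_independent samples per class in the independent validation
#'   cohort (mRNA platform).
#' @param meth_fraction fraction of the gene universe with methylation
#'   measured, in (0, 1].
#' @param planted `data.frame` with columns `term` (1-based term index),
#'   `level` (`"methylation"`, `"microRNA"` or `"mRNA"`) and `delta`
#'   (standardized effect size, in units of the within-class SD).  `NULL`
#'   plants nothing.
#' @param noise_sd within-class standard deviation of every feature.
#' @param baseline_mean,baseline_sd every feature carries a fixed baseline
#'   level drawn once from Normal(`baseline_mean`, `baseline_sd`), shared by
#'   both classes (and, for genes, by the main and independent mRNA
#'   cohorts).  Nonzero baselines emulate measured array intensities, whose
#'   positive shared profile gives every class a coherent direction under
#'   cosine distance; class differences then ride on the planted shifts.
#'   With a zero baseline the normal class has no direction of its own and
#'   cosine-distance classification of normals degenerates to chance tails,
#'   regardless of effect size.
#' @param n_tools number of target-prediction tools.
#' @param targets_per_mirna integer range of true target genes per microRNA.
#' @param p_tool_bg per-tool probability that a non-target pair is
#'   (spuriously) predicted.
#' @param enrichment factor by which a true regulator's per-tool prediction
#'   probability exceeds `p_tool_bg` (capped at 1), so true pairs pass the
#'   three-tool consensus and background pairs rarely do.
#' @param seed integer seed; the recorded seed reproduces the exact study.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300L, n_mirnas = 60L, n_terms = 40L,
                              term_size = c(8L, 15L),
                              n_tumor = 30L, n_normal = 30L,
                              n_independent = 20L,
                              meth_fraction = 0.6,
                              planted = NULL,
                              noise_sd = 1,
                              baseline_mean = 6,
                              baseline_sd = 1,
                              n_tools = 6L,
                              targets_per_mirna = c(2L, 5L),
                              p_tool_bg = 0.02,
                              enrichment = 35,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_mirnas >= 1, n_terms >= 1,
            length(term_size) == 2, term_size[1] >= 1,
            term_size[2] >= term_size[1], term_size[2] <= n_genes,
            meth_fraction > 0, meth_fraction <= 1,
            noise_sd > 0, baseline_sd >= 0, n_tools >= 1,
            p_tool_bg >= 0, p_tool_bg <= 1, enrichment >= 1)
  n_tumor <- rep_len(as.integer(n_tumor), 3L)
  n_normal <- rep_len(as.integer(n_normal), 3L)
  stopifnot(all(n_tumor >= 1), all(n_normal >= 1), n_independent >= 2)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("term", "level", "delta") %in% colnames(planted)))
    if (any(planted$term < 1 | planted$term > n_terms))
      stop("planted term indices must lie in [1, n_terms]", call. = FALSE)
    if (!all(planted$level %in% .levels3))
      stop("planted levels must be one of: ",
           paste(.levels3, collapse = ", "), call. = FALSE)
    if (any(planted$delta < 0))
      stop("planted effect sizes must be >= 0", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_terms = as.integer(n_terms),
                 term_size = as.integer(term_size),
                 n_tumor = n_tumor, n_normal = n_normal,
                 n_independent = as.integer(n_independent),
                 meth_fraction = meth_fraction,
                 planted = planted, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_tools = as.integer(n_tools),
                 targets_per_mirna = as.integer(targets_per_mirna),
                 p_tool_bg = p_tool_bg, enrichment = enrichment,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# draw one platform matrix: per-feature baseline plus Normal(0, sd) noise,
# tumor columns additionally shifted by delta * sd on the shifted features
.draw_platform <- function(features, baseline, n_tumor, n_normal, noise_sd,
                           shifts, level, prefix) {
  n <- n_tumor + n_normal
  values <- baseline + matrix(stats::rnorm(length(features) * n, 0,
                                           noise_sd),
                              nrow = length(features))
  dimnames(values) <- list(features,
                           c(sprintf("%s_T%03d", prefix, seq_len(n_tumor)),
                             sprintf("%s_N%03d", prefix,
                                     seq_len(n_normal))))
  labels <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  sh <- shifts[features]
  sh[is.na(sh)] <- 0
  values[, seq_len(n_tumor)] <- values[, seq_len(n_tumor)] + sh * noise_sd
  omics_matrix(values, labels = labels, level = level)
}

#' Generate a complete synthetic study
#'
#' Draws the three omics matrices, the annotation map, the multi-tool target
#' prediction table, an independent mRNA validation cohort and a ground
#' truth record, all from one seed.
#'
#' The generative model: every feature carries a fixed per-feature baseline
#' (drawn once from Normal(`baseline_mean`, `baseline_sd`); gene baselines
#' are shared between the main and independent mRNA cohorts) plus
#' within-class Normal(0, `noise_sd`) noise; for each planted (term, level,
#' delta) entry, every member feature of that term at that level has its
#' tumor-class mean additionally shifted by `delta * noise_sd`, upward or
#' downward with equal probability (the direction is drawn once per feature
#' and recorded in the truth), since dysregulation in tumors goes both
#' ways — and because a purely one-directional shift would be almost
#' parallel to the shared baseline profile and hence nearly invisible to a
#' scale-invariant cosine distance.  Term membership at generation time is the annotation
#' for the gene levels (intersected with the methylation universe for the
#' methylation platform) and, for the microRNA level, the microRNAs whose
#' *true* target genes intersect the term — the analysis side has to recover
#' that membership through the tool-consensus filter.  When a feature
#' belongs to several planted pairs the largest delta wins; shifts do not
#' stack.  Tool predictions are conditionally independent given true-target
#' status: a true pair is predicted per tool with probability
#' `min(1, enrichment * p_tool_bg)`, a background pair with `p_tool_bg`.
#'
#' Identical seeds give identical output, bitwise.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_study` with elements `meth`, `mirna`,
#'   `mrna` (omics matrices), `annotation` ([annotation_map()]),
#'   `predictions` (prediction `data.frame` with a `tool_universe`
#'   attribute), `independent` (mRNA [omics_matrix()]), and `truth` (class
#'   `synthetic_truth`: the planted table, per-level membership and shifts,
#'   the true target map, config and seed).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(config$n_mirnas))
  terms <- sprintf("T%04d", seq_len(config$n_terms))
  tools <- sprintf("tool%d", seq_len(config$n_tools))

  sizes <- sample(config$term_size[1]:config$term_size[2],
                  config$n_terms, replace = TRUE)
  ann_sets <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(ann_sets) <- terms
  annotation <- annotation_map(ann_sets)

  n_meth <- max(1L, round(config$meth_fraction * config$n_genes))
  meth_features <- sort(sample(genes, n_meth))

  true_targets <- lapply(mirnas, function(m)
    sort(sample(genes, sample(config$targets_per_mirna[1]:
                                config$targets_per_mirna[2], 1L))))
  names(true_targets) <- mirnas

  # per-level membership as the generator defines it
  membership <- list(
    methylation = lapply(ann_sets, intersect, x = meth_features),
    microRNA = lapply(ann_sets, function(ann) {
      hit <- vapply(true_targets, function(g) any(g %in% ann), logical(1))
      mirnas[hit]
    }),
    mRNA = ann_sets
  )

  # resolve planted effects into per-feature shifts: magnitudes combine by
  # "largest delta wins"; each feature dysregulates in a fixed direction
  # (up or down with equal probability, drawn once per feature and level),
  # as real tumors both gain and lose signal
  magnitudes <- list(
    methylation = stats::setNames(numeric(length(meth_features)),
                                  meth_features),
    microRNA = stats::setNames(numeric(length(mirnas)), mirnas),
    mRNA = stats::setNames(numeric(length(genes)), genes)
  )
  signs <- lapply(magnitudes, function(m)
    stats::setNames(sample(c(-1, 1), length(m), replace = TRUE), names(m)))
  planted <- config$planted
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      lv <- planted$level[i]
      members <- membership[[lv]][[planted$term[i]]]
      if (!length(members))
        stop("planted term ", terms[planted$term[i]],
             " has no members at the ", lv, " level", call. = FALSE)
      magnitudes[[lv]][members] <- pmax(magnitudes[[lv]][members],
                                        planted$delta[i])
    }
    planted$term_id <- terms[planted$term]
  }
  shifts <- Map(function(m, s) m * s, magnitudes, signs)

  base_meth <- stats::rnorm(length(meth_features), config$baseline_mean,
                            config$baseline_sd)
  base_mirna <- stats::rnorm(length(mirnas), config$baseline_mean,
                             config$baseline_sd)
  base_gene <- stats::rnorm(length(genes), config$baseline_mean,
                            config$baseline_sd)
  meth <- .draw_platform(meth_features, base_meth, config$n_tumor[1],
                         config$n_normal[1], config$noise_sd,
                         shifts$methylation, "methylation", "me")
  mirna <- .draw_platform(mirnas, base_mirna, config$n_tumor[2],
                          config$n_normal[2], config$noise_sd,
                          shifts$microRNA, "microRNA", "mi")
  mrna <- .draw_platform(genes, base_gene, config$n_tumor[3],
                         config$n_normal[3], config$noise_sd,
                         shifts$mRNA, "mRNA", "mr")
  independent <- .draw_platform(genes, base_gene, config$n_independent,
                                config$n_independent, config$noise_sd,
                                shifts$mRNA, "mRNA", "iv")

  # tool predictions: all pairs at background rate, true pairs enriched
  p_true <- min(1, config$enrichment * config$p_tool_bg)
  is_true <- matrix(FALSE, config$n_mirnas, config$n_genes,
                    dimnames = list(mirnas, genes))
  for (m in mirnas) is_true[m, true_targets[[m]]] <- TRUE
  recs <- vector("list", config$n_tools)
  for (t in seq_len(config$n_tools)) {
    p <- ifelse(is_true, p_true, config$p_tool_bg)
    hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p,
                 arr.ind = TRUE)
    recs[[t]] <- data.frame(mirna = mirnas[hit[, 1]],
                            gene = genes[hit[, 2]],
                            tool = tools[t], stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, recs)
  predictions <- predictions[order(predictions$mirna, predictions$gene,
                                   predictions$tool), ]
  rownames(predictions) <- NULL
  attr(predictions, "tool_universe") <- tools

  truth <- structure(list(planted = planted, membership = membership,
                          shifts = shifts, magnitudes = magnitudes,
                          signs = signs, true_targets = true_targets,
                          meth_features = meth_features,
                          term_ids = terms, config = config,
                          seed = config$seed),
                     class = "synthetic_truth")
  structure(list(meth = meth, mirna = mirna, mrna = mrna,
                 annotation = annotation, predictions = predictions,
                 independent = independent, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("synthetic_study: %d genes, %d microRNAs, %d terms (seed %d)\n",
              cfg$n_genes, cfg$n_mirnas, cfg$n_terms, cfg$seed))
  np <- if (is.null(x$truth$planted)) 0L else nrow(x$truth$planted)
  cat(sprintf("  planted effects: %d; platforms: meth %dx%d, miRNA %dx%d, mRNA %dx%d\n",
              np, nrow(x$meth$values), ncol(x$meth$values),
              nrow(x$mirna$values), ncol(x$mirna$values),
              nrow(x$mrna$values), ncol(x$mrna$values)))
  invisible(x)
}

#' Expected level ordering for a planted term
#'
#' Reads the ground-truth record and returns the term's levels sorted by
#' descending planted effect size — the rank ordering the analysis is
#' expected to recover.  Levels with no planted entry count as effect 0.
#'
#' @param truth the `synthetic_truth` component of a [simulate_study()]
#'   result.
#' @param term_id a term id present in the study.
#' @return list with `order` (the three level names, strongest effect
#'   first; exact ties broken by the canonical level order), `effects`
#'   (named numeric vector) and `tied` (logical per level in `order`,
#'   `TRUE` where the level's effect equals another level's).
#' @export
truth_group <- function(truth, term_id) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!term_id %in% truth$term_ids)
    stop("unknown term id: ", term_id, call. = FALSE)
  effects <- stats::setNames(numeric(3), .levels3)
  p <- truth$planted
  if (!is.null(p)) {
    p <- p[p$term_id == term_id, , drop = FALSE]
    if (nrow(p)) {
      agg <- tapply(p$delta, p$level, max)
      effects[names(agg)] <- agg
    }
  }
  o <- order(-effects, seq_len(3L))
  ord <- .levels3[o]
  eff_sorted <- effects[ord]
  tied <- duplicated(eff_sorted) | duplicated(eff_sorted, fromLast = TRUE)
  list(order = ord, effects = effects,
       tied = stats::setNames(tied, ord))
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the three matrices and label files, the annotation GMT, the
#' prediction TSV, the independent cohort, and a TSV of the planted truth —
#' the full input bundle for a file-based pipeline run.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_omics_matrix(study$meth, fp("methylation.tsv"),
                     fp("methylation_labels.tsv"))
  write_omics_matrix(study$mirna, fp("microRNA.tsv"),
                     fp("microRNA_labels.tsv"))
  write_omics_matrix(study$mrna, fp("mRNA.tsv"), fp("mRNA_labels.tsv"))
  write_omics_matrix(study$independent, fp("independent.tsv"),
                     fp("independent_labels.tsv"))
  write_gmt(study$annotation, fp("annotation.gmt"))
  write_tsv_table(study$predictions, fp("predictions.tsv"))
  pl <- study$truth$planted
  if (!is.null(pl) && nrow(pl)) write_tsv_table(pl, fp("truth_planted.tsv"))
  invisible(dir)
}
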