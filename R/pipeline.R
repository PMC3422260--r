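#' Run configuration for the file-based pipeline
#'
#' Paths to every input, the analysis thresholds, and run metadata.  The
#' defaults are the method's canonical settings: a 3-of-6 tool consensus for
#' microRNA targets, the top 300 dysfunctional sets for frequency counting,
#' and a strict frequency cutoff of 50.  Either supply the input paths or
#' set `simulate` to a [simulation_config()] to generate the study first.
#'
#' @param meth_path,meth_labels,mirna_path,mirna_labels,mrna_path,mrna_labels
#'   matrix and label file paths for the three platforms.
#' @param annotation_path GMT annotation file.
#' @param predictions_path target prediction TSV.
#' @param independent_path,independent_labels optional independent
#'   validation cohort.
#' @param reference_path optional one-column file of reference pathway gene
#'   ids for the enrichment test.
#' @param simulate optional [simulation_config()]; when set, a synthetic
#'   study is generated into `out_dir/input/` and its files are used as the
#'   inputs above.
#' @param min_tools,min_size,top_k,freq_threshold analysis settings
#'   (defaults 3, 1, 300, 50).
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation when `simulate` carries no explicit seed change).
#' @param out_dir output directory.
#' @param verbose log stage boundaries with term/sample counts.
#' @return a list of class `run_config`.
#' @export
run_config <- function(meth_path = NULL, meth_labels = NULL,
                       mirna_path = NULL, mirna_labels = NULL,
                       mrna_path = NULL, mrna_labels = NULL,
                       annotation_path = NULL, predictions_path = NULL,
                       independent_path = NULL, independent_labels = NULL,
                       reference_path = NULL, simulate = NULL,
                       min_tools = 3L, min_size = 1L, top_k = 300L,
                       freq_threshold = 50L, seed = 1L,
                       out_dir = "dgsa_out", verbose = TRUE) {
  if (is.null(simulate)) {
    need <- list(meth_path = meth_path, meth_labels = meth_labels,
                 mirna_path = mirna_path, mirna_labels = mirna_labels,
                 mrna_path = mrna_path, mrna_labels = mrna_labels,
                 annotation_path = annotation_path,
                 predictions_path = predictions_path)
    missing <- names(need)[vapply(need, is.null, logical(1))]
    if (length(missing))
      stop("without 'simulate', these inputs are required: ",
           paste(missing, collapse = ", "), call. = FALSE)
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
  }
  structure(list(meth_path = meth_path, meth_labels = meth_labels,
                 mirna_path = mirna_path, mirna_labels = mirna_labels,
                 mrna_path = mrna_path, mrna_labels = mrna_labels,
                 annotation_path = annotation_path,
                 predictions_path = predictions_path,
                 independent_path = independent_path,
                 independent_labels = independent_labels,
                 reference_path = reference_path, simulate = simulate,
                 min_tools = as.integer(min_tools),
                 min_size = as.integer(min_size),
                 top_k = as.integer(top_k),
                 freq_threshold = as.integer(freq_threshold),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used to
# fingerprint the configuration in the run manifest
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32, split to stay inside exact double range
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stage <- function(verbose, name, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full dysfunction analysis workflow
#'
#' Chains every stage — simulate (optional), read inputs, build term sets,
#' score, rank and classify, frequency, enrichment (when a reference is
#' available) and independent validation (when a cohort is available) —
#' writing every intermediate table under `out_dir` and a manifest
#' recording the package version, seed and a configuration fingerprint.
#' A rerun with the same configuration reproduces identical outputs.
#' Any stage failure aborts with the stage name and the offending input.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the [dgsa()] fit, the top term ids, the
#'   per-class frequency tables, the high-frequency members, the enrichment
#'   p-value (or NA), the validation MCC (or NA), and the output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  vb <- config$verbose
  paths <- character(0)
  keep <- function(p) { paths <<- c(paths, p); p }

  if (!is.null(config$simulate)) {
    study <- .run_stage("simulate", simulate_study(config$simulate))
    ind <- file.path(config$out_dir, "input")
    .run_stage("simulate", write_study(study, ind))
    config$meth_path <- file.path(ind, "methylation.tsv")
    config$meth_labels <- file.path(ind, "methylation_labels.tsv")
    config$mirna_path <- file.path(ind, "microRNA.tsv")
    config$mirna_labels <- file.path(ind, "microRNA_labels.tsv")
    config$mrna_path <- file.path(ind, "mRNA.tsv")
    config$mrna_labels <- file.path(ind, "mRNA_labels.tsv")
    config$annotation_path <- file.path(ind, "annotation.gmt")
    config$predictions_path <- file.path(ind, "predictions.tsv")
    if (is.null(config$independent_path)) {
      config$independent_path <- file.path(ind, "independent.tsv")
      config$independent_labels <- file.path(ind, "independent_labels.tsv")
    }
    .stage(vb, "simulate", "wrote synthetic study to %s", ind)
  }

  meth <- .run_stage("read", read_omics_matrix(config$meth_path,
                                               "methylation",
                                               config$meth_labels))
  mirna <- .run_stage("read", read_omics_matrix(config$mirna_path,
                                                "microRNA",
                                                config$mirna_labels))
  mrna <- .run_stage("read", read_omics_matrix(config$mrna_path, "mRNA",
                                               config$mrna_labels))
  annotation <- .run_stage("read", read_gmt(config$annotation_path))
  predictions <- .run_stage(
    "read", read_target_predictions(config$predictions_path))
  .stage(vb, "read", "%d/%d/%d features; %d terms; %d prediction records",
         nrow(meth$values), nrow(mirna$values), nrow(mrna$values),
         length(annotation$sets), nrow(predictions))

  fit <- .run_stage("analyse",
                    dgsa(meth, mirna, mrna, annotation, predictions,
                         min_tools = config$min_tools,
                         min_size = config$min_size))
  .stage(vb, "analyse", "%d terms scored at all three levels", fit$n_terms)

  fp <- function(f) keep(file.path(config$out_dir, f))
  .run_stage("write", write_term_sets(fit$sets, config$out_dir))
  paths <- c(paths, file.path(config$out_dir,
                              c("sets_methylation.gmt", "sets_microRNA.gmt",
                                "sets_mRNA.gmt")))
  write_tsv_table(fit$mcc, fp("mcc.tsv"))
  write_tsv_table(as.data.frame(fit$table), fp("dysfunction.tsv"))
  write_tsv_table(fit$comparison, fp("level_comparison.tsv"))

  k <- min(config$top_k, fit$n_terms)
  if (k < config$top_k)
    .stage(vb, "rank", "top_k %d exceeds %d terms; using all terms",
           config$top_k, fit$n_terms)
  top <- top_terms(fit$table, k)
  write_tsv_table(data.frame(term_id = top, position = seq_along(top)),
                  fp("top_terms.tsv"))

  freq <- list(
    gene_mrna = member_frequency(top, fit$sets, "gene_mrna"),
    gene_methylation = member_frequency(top, fit$sets, "gene_methylation"),
    microRNA = member_frequency(top, fit$sets, "microRNA"))
  for (cls in names(freq))
    if (nrow(freq[[cls]]))
      write_tsv_table(freq[[cls]], fp(paste0("frequency_", cls, ".tsv")))
  hi <- lapply(freq, high_frequency, threshold = config$freq_threshold)
  hi_tab <- data.frame(
    member = unlist(hi, use.names = FALSE),
    level_class = rep(names(hi), lengths(hi)), stringsAsFactors = FALSE)
  if (nrow(hi_tab)) write_tsv_table(hi_tab, fp("high_frequency.tsv"))
  .stage(vb, "frequency",
         "top %d sets; high-frequency members: %d mRNA, %d methylation, %d microRNA",
         k, length(hi$gene_mrna), length(hi$gene_methylation),
         length(hi$microRNA))

  enrich_p <- NA_real_
  if (!is.null(config$reference_path)) {
    reference <- .run_stage("enrich", readLines(config$reference_path))
    reference <- reference[nzchar(reference)]
    universe <- rownames(mrna$values)
    enrich_p <- .run_stage(
      "enrich",
      hypergeom_enrichment(intersect(hi$gene_mrna, universe),
                           intersect(reference, universe), universe))
    write_tsv_table(data.frame(n_high_frequency = length(hi$gene_mrna),
                               n_reference = length(reference),
                               p_value = enrich_p),
                    fp("enrichment.tsv"))
    .stage(vb, "enrich", "hypergeometric p = %.3g", enrich_p)
  }

  val_mcc <- NA_real_
  if (!is.null(config$independent_path) && length(hi$gene_mrna)) {
    independent <- .run_stage(
      "validate", read_omics_matrix(config$independent_path, "mRNA",
                                    config$independent_labels))
    val_mcc <- .run_stage("validate",
                          validate_independent(hi$gene_mrna, independent))
    write_tsv_table(data.frame(n_genes = length(hi$gene_mrna),
                               mcc = val_mcc), fp("validation.tsv"))
    .stage(vb, "validate", "independent-cohort MCC = %.3f", val_mcc)
  }

  cfg_string <- paste(vapply(config[c("min_tools", "min_size", "top_k",
                                      "freq_threshold", "seed")],
                             as.character, character(1)),
                      collapse = "|")
  manifest <- c(
    sprintf("package\tdgsa %s",
            as.character(utils::packageVersion("dgsa"))),
    sprintf("r_version\t%s", R.version.string),
    sprintf("seed\t%d", config$seed),
    sprintf("min_tools\t%d", config$min_tools),
    sprintf("min_size\t%d", config$min_size),
    sprintf("top_k\t%d", config$top_k),
    sprintf("freq_threshold\t%d", config$freq_threshold),
    sprintf("n_terms\t%d", fit$n_terms),
    sprintf("config_hash\t%s", fnv1a32(cfg_string)))
  writeLines(manifest, keep(file.path(config$out_dir, "manifest.tsv")))

  invisible(list(fit = fit, top = top, frequency = freq,
                 high_frequency = hi, enrichment_p = enrich_p,
                 validation_mcc = val_mcc, paths = unique(paths)))
}
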