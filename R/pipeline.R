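#' Configuration for an end-to-end pipeline run
#'
#' A run is either self-contained (a [sim_config()] supplies everything) or
#' driven by files/tables: counts + sample sheet + annotation (+ optional TE
#' table). Paths and in-memory tibbles are both accepted.
#'
#' @param counts counts tibble or TSV path.
#' @param samples sample sheet tibble or TSV path.
#' @param annotation gene-model tibble or GFF3/BED path.
#' @param te_table optional TE table (tibble or TSV path).
#' @param sim optional [sim_config()] for a self-contained simulated run.
#' @param params an [analysis_params()].
#' @param bin_size bin width (bp) for the TE chromosomal distribution.
#' @param seed integer seed; per-stage seeds are derived deterministically
#'   from it (simulation: seed; counts: seed + 1; pseudo-split: seed + 2).
#' @param outdir optional directory; when given, every stage's table is
#'   written there as TSV along with a `run_summary.tsv`.
#' @return A list of class `meio_pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, samples = NULL, annotation = NULL,
                            te_table = NULL, sim = NULL,
                            params = analysis_params(), bin_size = 1e5,
                            seed = 1, outdir = NULL) {
  if (is.null(sim) && (is.null(counts) || is.null(samples) ||
                       is.null(annotation))) {
    abort(paste0("pipeline needs either a sim config or counts + samples",
                 " + annotation inputs"))
  }
  structure(list(counts = counts, samples = samples, annotation = annotation,
                 te_table = te_table, sim = sim, params = params,
                 bin_size = bin_size, seed = seed, outdir = outdir),
            class = "meio_pipeline_config")
}

#' Run the full meiocyte RNA-Seq analysis pipeline
#'
#' Executes every stage in order: (1) load or simulate inputs; (2) RPM
#' normalization of the real libraries and the analysis-inclusion filter
#' (at least `detect_low` RPM in at least one real sample); (3) binomial
#' pseudo-replicate split of any tissue with a single library; (4) RPM
#' normalization of the final columns, replicate correlation QC, per-gene
#' ANOVA contrasts with BH adjustment and fold changes; (5) significant sets
#' and their Venn partition; (6) tissue means, specificity classification and
#' the candidate meiosis-specific pool; (7) MGI-interval summary,
#' TE differential summaries against both anther and seedling baselines, and
#' the binned chromosomal distribution of meiocyte-up TE genes. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `meio_pipeline`: a list with the inputs, all
#'   intermediate tables (`rpm`, `qc`, `de`, `sig`, `venn`, `means`,
#'   `calls`, `pool`, `mgi`, `te_anther`, `te_seedling`, `te_bins`), a long
#'   `summary` tibble, and (for simulated runs) the planted `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "meio_pipeline_config"))
  params <- config$params
  seed <- config$seed
  truth <- NULL

  # --- stage: inputs ---
  if (!is.null(config$sim)) {
    sim <- simulate_experiment(config$sim, seed = seed)
    counts <- sim$counts; samples <- sim$samples
    annotation <- sim$annotation; truth <- sim$truth
    annotation_te <- sim$annotation
  } else {
    samples <- if (is.character(config$samples))
      read_sample_sheet(config$samples) else
        validate_sample_sheet(config$samples)
    counts <- if (is.character(config$counts))
      read_counts(config$counts, samples) else
        validate_counts(config$counts, samples)
    annotation <- if (is.character(config$annotation))
      read_annotation(config$annotation, config$te_table) else {
        ann <- as_tibble(config$annotation)
        if (!is.null(config$te_table)) {
          te <- if (is.character(config$te_table))
            read_te_table(config$te_table) else config$te_table
          idx <- match(intersect(te$gene_id, ann$gene_id), ann$gene_id)
          ann$biotype[idx] <- "te"
          ann$te_superfamily[idx] <-
            te$superfamily[match(ann$gene_id[idx], te$gene_id)]
        }
        ann
      }
    annotation_te <- annotation
  }

  # --- stage: detection filter on the real libraries ---
  rpm_real <- rpm_normalize(counts, samples)
  flags <- detection_flags(rpm_real, samples, cutoff = params$detect_low,
                           scope = "any_sample")
  keep <- flags$gene_id[flags$expressed]

  # --- stage: pseudo-replicates for single-library tissues ---
  singles <- samples |>
    group_by(.data$tissue) |>
    filter(n() == 1) |>
    pull("sample_id")
  for (sid in singles) {
    split <- split_pseudoreplicates(counts, samples, sid, seed = seed + 2)
    counts <- split$counts
    samples <- split$samples
  }

  # --- stage: normalization, QC, differential expression ---
  rpm <- rpm_normalize(counts, samples)
  qc <- replicate_correlation(rpm)
  rpm_de <- filter(rpm, .data$gene_id %in% keep)
  attr(rpm_de, "log2p1") <- FALSE
  de <- de_results(rpm_de, samples, params)

  # --- stage: significant sets and Venn partition ---
  sig <- significant_sets(de, rpm_de, samples, params)
  venn <- venn_partition(sig)

  # --- stage: classification and candidate pool ---
  means <- tissue_means(rpm, samples)
  calls <- classify_specificity(means, params)
  pool <- candidate_pool(calls, sig)

  # --- stage: region and TE summaries ---
  mgi_ids <- genes_in_interval(annotation, params$mgi_chrom,
                               params$mgi_start, params$mgi_end)
  mgi <- mgi_summary(means, mgi_ids, params)
  te_anther <- te_differential_summary(means, annotation_te, "anther", params)
  te_seedling <- te_differential_summary(means, annotation_te, "seedling",
                                         params)
  up_te <- te_anther$genes$gene_id[te_anther$genes$direction == "up"]
  te_bins <- chromosome_bin_distribution(annotation, up_te,
                                         bin_size = config$bin_size)

  summary <- bind_rows(
    tibble(section = "params", metric = c("detect_low", "detect_high",
                                          "fold_pref", "fold_exclude",
                                          "alpha", "seed"),
           value = c(params$detect_low, params$detect_high, params$fold_pref,
                     params$fold_exclude, params$alpha, seed)),
    tibble(section = "filter", metric = c("n_genes_total", "n_genes_kept"),
           value = c(nrow(rpm), length(keep))),
    calls |>
      dplyr::count(.data$category, .drop = FALSE) |>
      mutate(section = "category", metric = as.character(.data$category),
             value = as.numeric(.data$n)) |>
      select("section", "metric", "value"),
    tidy(venn) |>
      mutate(section = "venn", metric = .data$region,
             value = as.numeric(.data$n)) |>
      select("section", "metric", "value"),
    tibble(section = "venn", metric = "union",
           value = as.numeric(venn$n_union)),
    tibble(section = "pool", metric = "n_candidates",
           value = as.numeric(nrow(pool))),
    mgi |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                          values_to = "value") |>
      mutate(section = "mgi", value = as.numeric(.data$value)) |>
      select("section", "metric", "value"),
    te_anther$counts |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                          values_to = "value") |>
      mutate(section = "te_vs_anther", value = as.numeric(.data$value)) |>
      select("section", "metric", "value"),
    te_seedling$counts |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                          values_to = "value") |>
      mutate(section = "te_vs_seedling", value = as.numeric(.data$value)) |>
      select("section", "metric", "value")
  )

  result <- structure(
    list(counts = counts, samples = samples, annotation = annotation,
         truth = truth, rpm = rpm, qc = qc, keep = keep, de = de, sig = sig,
         venn = venn, means = means, calls = calls, pool = pool,
         mgi_gene_ids = mgi_ids, mgi = mgi, te_anther = te_anther,
         te_seedling = te_seedling, te_bins = te_bins, summary = summary,
         params = params, seed = seed),
    class = "meio_pipeline"
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(config$outdir, f))
    w(samples, "sample_sheet.tsv")
    w(rpm, "rpm.tsv")
    w(qc, "qc_correlation.tsv")
    w(de, "de_results.tsv")
    w(sig, "significant_sets.tsv")
    w(tidy(venn), "venn_regions.tsv")
    w(calls, "specificity_calls.tsv")
    w(pool, "candidate_pool.tsv")
    w(mgi, "mgi_summary.tsv")
    w(te_anther$counts, "te_counts_vs_anther.tsv")
    w(te_anther$superfamily, "te_superfamily_vs_anther.tsv")
    w(te_seedling$counts, "te_counts_vs_seedling.tsv")
    w(te_bins, "te_bins.tsv")
    w(summary, "run_summary.tsv")
  }
  result
}

#' @export
print.meio_pipeline <- function(x, ...) {
  cat("meiocyte RNA-Seq pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  %d genes, %d kept by the detection filter\n",
              nrow(x$rpm), length(x$keep)))
  cat(sprintf("  significant-set union: %d genes; candidate pool: %d genes\n",
              x$venn$n_union, nrow(x$pool)))
  invisible(x)
}

#' @describeIn run_pipeline the long section/metric/value summary table.
#' @param x a `meio_pipeline` object.
#' @param ... unused.
#' @method tidy meio_pipeline
#' @export
tidy.meio_pipeline <- function(x, ...) x$summary

#' @describeIn run_pipeline one-row overview of the run.
#' @method glance meio_pipeline
#' @export
glance.meio_pipeline <- function(x, ...) {
  tibble(
    n_genes = nrow(x$rpm),
    n_kept = length(x$keep),
    n_significant_union = x$venn$n_union,
    n_candidates = nrow(x$pool),
    n_mgi_genes = x$mgi$n_genes_in_region,
    n_te_differential = x$te_anther$counts$n_te_differential,
    n_te_up = x$te_anther$counts$n_up_in_meiocyte
  )
}
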