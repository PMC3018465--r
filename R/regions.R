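#' Genes overlapping a genomic interval
#'
#' Returns the ids of all genes whose span overlaps the query interval by at
#' least 1 bp (1-based inclusive coordinates), ordered by start position.
#' Overlap — rather than full containment — is used so loci straddling the
#' interval boundary are kept.
#'
#' @param annotation a gene-model tibble (see [read_annotation()]).
#' @param chrom chromosome name.
#' @param start,end interval bounds, 1-based inclusive.
#' @return A character vector of gene ids.
#' @export
genes_in_interval <- function(annotation, chrom, start, end) {
  if (start > end) abort("interval start must not exceed end")
  annotation |>
    filter(.data$chrom == !!chrom, .data$start <= !!end, .data$end >= !!start) |>
    arrange(.data$start) |>
    pull("gene_id")
}

#' Expression summary of a genomic region (the MGI block)
#'
#' Counts, over the genes of a region, how many are detected in meiocytes
#' (meiocyte mean at least `detect_low` RPM), how many are meiocyte-only
#' (detected in meiocytes with the anther mean below detection), how many are
#' meiocyte-preferential (anther detected and meiocyte at least `fold_pref`
#' times anther), and how many of the preferential genes reach
#' `fold_exclude`-fold meiocyte excess. Designed for the
#' mitochondrial-genomic-insertion block on chromosome II but applicable to
#' any interval.
#'
#' @param means a tissue-mean tibble ([tissue_means()]) covering every gene
#'   of the region; a missing gene is an error naming it.
#' @param gene_ids the region's gene ids, e.g. from [genes_in_interval()].
#' @param params an [analysis_params()].
#' @return A one-row tibble: `n_genes_in_region`, `n_detected_in_meiocyte`,
#'   `n_meiocyte_only`, `n_meiocyte_preferential`, `n_fourfold`.
#' @export
mgi_summary <- function(means, gene_ids, params = analysis_params()) {
  missing <- setdiff(gene_ids, means$gene_id)
  if (length(missing) > 0) {
    abort(paste0("gene(s) absent from the RPM table: ",
                 paste(missing, collapse = ", ")))
  }
  d <- means[match(gene_ids, means$gene_id), ]
  lo <- params$detect_low
  det <- d$meiocyte >= lo
  only <- det & d$anther < lo
  pref <- d$anther >= lo & d$meiocyte >= params$fold_pref * d$anther
  four <- pref & d$meiocyte >= params$fold_exclude * d$anther
  tibble(
    n_genes_in_region = length(gene_ids),
    n_detected_in_meiocyte = sum(det),
    n_meiocyte_only = sum(only),
    n_meiocyte_preferential = sum(pref),
    n_fourfold = sum(four)
  )
}

# Percentage shares rounded to 2 decimals by largest remainder, so they sum
# to exactly 100.00 (an empty denominator yields zeros).
round_pct <- function(n) {
  total <- sum(n)
  if (total == 0) return(rep(0, length(n)))
  raw <- 100 * n / total
  base <- floor(raw * 100) / 100
  short <- round((100 - sum(base)) * 100)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 0.01
  }
  base
}

#' Differential transposable-element expression summary
#'
#' Summarises TE-gene expression in meiocytes against a baseline tissue
#' (anther or seedling). The differential set contains the TE genes (biotype
#' `te`) with at least a `fold_pref`-fold difference between the meiocyte and
#' baseline tissue means and detection (`>= detect_low` RPM) in at least one
#' of the two tissues; this is a threshold construction on tissue means — a
#' q-value gate is deliberately not applied by default, matching how such TE
#' tables are built. The set is partitioned into meiocyte-only (baseline mean
#' below detection), baseline-only, and shared up/down; up-regulated =
#' meiocyte-only + shared-up. Superfamily shares are reported against two
#' denominators — the full differential set and the up-regulated subset —
#' with TE genes lacking a superfamily pooled as `unassigned`; percentages
#' are rounded to 2 decimals and sum to 100 within 0.01.
#'
#' @param means a tissue-mean tibble covering the TE genes.
#' @param annotation a gene-model tibble with `biotype` and
#'   `te_superfamily`.
#' @param baseline `"anther"` or `"seedling"`.
#' @param params an [analysis_params()].
#' @return An object of class `meio_te_summary`: a list with `counts`
#'   (one-row tibble), `superfamily` (tibble `superfamily`,
#'   `n_differential`, `pct_differential`, `n_up`, `pct_up`) and `genes`
#'   (per-TE-gene tibble with `status` and `direction`).
#' @export
te_differential_summary <- function(means, annotation,
                                    baseline = c("anther", "seedling"),
                                    params = analysis_params()) {
  baseline <- match.arg(baseline)
  if (all(is.na(means[[baseline]]))) {
    abort(paste0("baseline tissue '", baseline, "' has no expression values"))
  }
  te_ann <- filter(annotation, .data$biotype == "te")
  d <- means |>
    inner_join(select(te_ann, "gene_id", "te_superfamily"), by = "gene_id") |>
    mutate(m = .data$meiocyte, b = .data[[baseline]])
  lo <- params$detect_low
  f <- fold_change(d$m, d$b, params)
  d <- d |>
    mutate(
      detected = pmax(.data$m, .data$b) >= lo,
      differential = .data$detected & !is.na(f$ratio) &
        f$ratio >= params$fold_pref,
      status = case_when(
        !.data$differential ~ NA_character_,
        .data$b < lo ~ "meiocyte_only",
        .data$m < lo ~ paste0(baseline, "_only"),
        .data$m > .data$b ~ "shared_up",
        TRUE ~ "shared_down"
      ),
      direction = case_when(
        !.data$differential ~ NA_character_,
        .data$m > .data$b ~ "up",
        TRUE ~ "down"
      ),
      superfamily = dplyr::coalesce(.data$te_superfamily, "unassigned")
    )
  diff <- filter(d, .data$differential)
  counts <- tibble(
    n_te_annotated = nrow(d),
    n_te_differential = nrow(diff),
    n_up_in_meiocyte = sum(diff$direction == "up"),
    n_down_in_meiocyte = sum(diff$direction == "down"),
    n_meiocyte_only = sum(diff$status == "meiocyte_only"),
    n_other_only = sum(diff$status == paste0(baseline, "_only")),
    n_shared_up = sum(diff$status == "shared_up"),
    n_shared_down = sum(diff$status == "shared_down")
  )
  sf <- diff |>
    group_by(.data$superfamily) |>
    summarise(n_differential = n(),
              n_up = sum(.data$direction == "up"), .groups = "drop") |>
    arrange(desc(.data$n_differential)) |>
    mutate(
      pct_differential = round_pct(.data$n_differential),
      pct_up = round_pct(.data$n_up)
    ) |>
    select("superfamily", "n_differential", "pct_differential",
           "n_up", "pct_up")
  structure(
    list(counts = counts, superfamily = sf,
         genes = select(diff, "gene_id", "superfamily", "m", "b",
                        "status", "direction"),
         baseline = baseline),
    class = "meio_te_summary"
  )
}

#' @export
print.meio_te_summary <- function(x, ...) {
  cat("TE differential expression summary (meiocyte vs", x$baseline, ")\n")
  print(x$counts)
  cat("By superfamily:\n")
  print(x$superfamily, n = Inf)
  invisible(x)
}

#' @describeIn te_differential_summary superfamily share table.
#' @param x a `meio_te_summary`.
#' @param ... unused.
#' @method tidy meio_te_summary
#' @export
tidy.meio_te_summary <- function(x, ...) x$superfamily

#' @describeIn te_differential_summary one-row count summary.
#' @method glance meio_te_summary
#' @export
glance.meio_te_summary <- function(x, ...) x$counts

#' Binned chromosomal distribution of a gene set
#'
#' Counts the members of a gene set in fixed-width bins along each
#' chromosome, keyed by gene start: bin k covers positions
#' `[k * bin_size + 1, (k + 1) * bin_size]` (k from 0). All bins up to the
#' last annotated position of each chromosome are emitted, zeros included,
#' as a tidy table ready for plotting.
#'
#' @param annotation a gene-model tibble.
#' @param gene_ids the gene set to bin.
#' @param bin_size bin width in bp (> 0).
#' @return A tibble `chrom`, `bin`, `start`, `end`, `n`.
#' @export
chromosome_bin_distribution <- function(annotation, gene_ids,
                                        bin_size = 1e5) {
  if (bin_size <= 0) abort("bin_size must be > 0")
  chroms <- annotation |>
    group_by(.data$chrom) |>
    summarise(max_end = max(.data$end), .groups = "drop")
  grid <- chroms |>
    mutate(bin = purrr::map(.data$max_end,
                            ~ seq(0, (. - 1) %/% bin_size))) |>
    tidyr::unnest("bin") |>
    mutate(start = .data$bin * bin_size + 1, end = (.data$bin + 1) * bin_size) |>
    select("chrom", "bin", "start", "end")
  hits <- annotation |>
    filter(.data$gene_id %in% gene_ids) |>
    mutate(bin = (.data$start - 1) %/% bin_size) |>
    dplyr::count(.data$chrom, .data$bin, name = "n")
  grid |>
    left_join(hits, by = c("chrom", "bin")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Plot a binned chromosomal distribution
#'
#' Column plot of [chromosome_bin_distribution()] output, one facet per
#' chromosome, with optional centromere midpoints marked.
#'
#' @param bins a tibble from [chromosome_bin_distribution()].
#' @param centromeres optional tibble `chrom`, `mid` for dashed centromere
#'   lines.
#' @return A ggplot object.
#' @export
plot_te_distribution <- function(bins, centromeres = NULL) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$start / 1e6, y = .data$n)) +
    ggplot2::geom_col(width = diff(range(bins$start)) / 1e6 / 100,
                      fill = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "genes per bin",
                  title = "Chromosomal distribution") +
    ggplot2::theme_minimal()
  if (!is.null(centromeres)) {
    p <- p + ggplot2::geom_vline(
      data = centromeres,
      ggplot2::aes(xintercept = .data$mid / 1e6), linetype = "dashed")
  }
  p
}

#' Heatmap of pairwise replicate correlations
#'
#' @param cor_tbl a long correlation tibble from [replicate_correlation()].
#' @return A ggplot object.
#' @export
plot_replicate_correlation <- function(cor_tbl) {
  ggplot2::ggplot(cor_tbl,
                  ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise sample correlation") +
    ggplot2::theme_minimal()
}
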