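#' Reads-per-million normalization
#'
#' Scales each sample column by its library total: `rpm = count /
#' library_total * 1e6`. The library total is the total genome-aligned reads
#' for the library (the `library_total` column of the sample sheet), not a
#' column sum; pseudo-replicate totals are their shares of the parent
#' library total (see [split_pseudoreplicates()]).
#'
#' @param counts a counts tibble (`gene_id` + one column per sample).
#' @param samples the matching sample sheet.
#' @return An RPM tibble of the same shape (untransformed).
#' @export
rpm_normalize <- function(counts, samples) {
  counts <- validate_counts(counts, samples)
  samples <- validate_sample_sheet(samples)
  if (any(samples$library_total == 0)) {
    abort(paste0("library_total is zero for sample ",
                 samples$sample_id[samples$library_total == 0][1]))
  }
  rpm <- counts
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    rpm[[sid]] <- counts[[sid]] / samples$library_total[j] * 1e6
  }
  attr(rpm, "log2p1") <- FALSE
  rpm
}

#' log2(x + 1) transform of an RPM table
#'
#' Applies `log2(rpm + 1)` to every expression column and marks the result as
#' transformed. Transforming an already-transformed table is an error. The
#' transform is strictly monotone, so within-sample gene ordering is
#' preserved.
#'
#' @param rpm an untransformed RPM tibble from [rpm_normalize()].
#' @return The transformed tibble (attribute `log2p1` set).
#' @export
log2p1 <- function(rpm) {
  if (is_log2p1(rpm)) {
    abort("input is already log2+1 transformed; refusing to transform twice")
  }
  out <- mutate(rpm, across(-"gene_id", ~ log2(.x + 1)))
  attr(out, "log2p1") <- TRUE
  out
}

#' @rdname log2p1
#' @param x an expression tibble.
#' @export
is_log2p1 <- function(x) isTRUE(attr(x, "log2p1"))

#' Split one library into two binomial pseudo-replicates
#'
#' When a tissue has a single library (here the seedling control), a
#' technical-replicate stand-in is created by randomly halving its reads:
#' each gene's count n is split as `Binomial(n, 1/2)` versus the remainder,
#' mimicking a random partition of the flow-cell reads. The two pseudo
#' columns replace the original (named `<id>_1`, `<id>_2`), are flagged
#' `is_pseudo`, and each is individually normalized per million: its
#' `library_total` is its proportional share of the parent library total
#' (parent total times the pseudo column sum over the parent column sum).
#' When the counts table spans the whole read universe — the parent column
#' sum equals the parent library total, as with fully aligned real data —
#' this equals the pseudo column's own column sum; the proportional form
#' keeps normalization consistent when the table covers only part of the
#' transcriptome. The split conserves every gene's total exactly.
#' Deterministic given `seed`.
#'
#' @param counts a counts tibble.
#' @param samples the matching sample sheet.
#' @param sample_id the library to split (must not already be a pseudo
#'   column).
#' @param seed integer seed.
#' @return A list with the updated `counts` and `samples`.
#' @export
split_pseudoreplicates <- function(counts, samples, sample_id, seed = 1) {
  samples <- validate_sample_sheet(samples)
  counts <- validate_counts(counts, samples)
  j <- match(sample_id, samples$sample_id)
  if (is.na(j)) abort(paste0("unknown sample_id: ", sample_id))
  if (samples$is_pseudo[j]) {
    abort(paste0(sample_id, " is already a pseudo-replicate"))
  }
  n <- counts[[sample_id]]
  half1 <- withr::with_seed(seed, rbinom(length(n), n, 0.5))
  half2 <- n - half1
  ids <- paste0(sample_id, "_", 1:2)

  counts[[ids[1]]] <- half1
  counts[[ids[2]]] <- half2
  counts <- counts |>
    relocate(dplyr::all_of(ids), .after = dplyr::all_of(sample_id)) |>
    select(-dplyr::all_of(sample_id))

  parent_sum <- sum(n)
  shares <- if (parent_sum > 0) c(sum(half1), sum(half2)) / parent_sum else
    c(0.5, 0.5)
  row <- samples[j, ]
  new_rows <- bind_rows(row, row) |>
    mutate(sample_id = ids, replicate = 1:2, is_pseudo = TRUE,
           library_total = samples$library_total[j] * shares)
  samples <- bind_rows(
    samples[seq_len(j - 1), ], new_rows,
    if (j < nrow(samples)) samples[(j + 1):nrow(samples), ]
  )
  list(counts = counts, samples = samples)
}

#' Detection flags at an RPM cutoff
#'
#' Flags genes as expressed at a cutoff, inclusively (a value exactly at the
#' cutoff counts as detected). Two scopes:
#' * `any_sample` — expressed iff the maximum RPM over the *non-pseudo*
#'   samples is at least the cutoff (the analysis-inclusion filter applied to
#'   the real libraries before pseudo-splitting);
#' * `per_tissue_mean` — per tissue, detected iff the mean RPM over that
#'   tissue's replicates (pseudo included) is at least the cutoff.
#'
#' @param rpm an untransformed RPM tibble.
#' @param samples the matching sample sheet.
#' @param cutoff RPM threshold (> 0).
#' @param scope `"any_sample"` or `"per_tissue_mean"`.
#' @return For `any_sample`, a tibble `gene_id`, `expressed`; for
#'   `per_tissue_mean`, a long tibble `gene_id`, `tissue`, `detected`.
#' @export
detection_flags <- function(rpm, samples, cutoff = 1,
                            scope = c("any_sample", "per_tissue_mean")) {
  scope <- match.arg(scope)
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (is_log2p1(rpm)) abort("detection flags need untransformed RPM values")
  samples <- validate_sample_sheet(samples)
  if (scope == "any_sample") {
    real <- samples$sample_id[!samples$is_pseudo]
    m <- as.matrix(rpm[, real, drop = FALSE])
    tibble(gene_id = rpm$gene_id,
           expressed = apply(m, 1, max) >= cutoff)
  } else {
    out <- lapply(unique(samples$tissue), function(t) {
      sid <- samples$sample_id[samples$tissue == t]
      tibble(gene_id = rpm$gene_id, tissue = t,
             detected = rowMeans(as.matrix(rpm[, sid, drop = FALSE])) >= cutoff)
    })
    bind_rows(out)
  }
}

#' Pairwise Pearson correlation of samples on the log2+1 scale
#'
#' Replicate-quality check: Pearson correlation between every pair of sample
#' columns, computed on log2(rpm + 1) values (applied internally if the input
#' is untransformed). A zero-variance column yields `NA` correlations with a
#' warning.
#'
#' @param rpm an RPM tibble (transformed or not).
#' @return A long tibble `sample_a`, `sample_b`, `r` covering all ordered
#'   pairs (diagonal r = 1).
#' @export
replicate_correlation <- function(rpm) {
  m <- as.matrix(rpm[, setdiff(names(rpm), "gene_id"), drop = FALSE])
  if (ncol(m) < 2) abort("need at least two samples")
  if (!is_log2p1(rpm)) m <- log2(m + 1)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("zero-variance sample column(s): ",
                paste(colnames(m)[sds == 0], collapse = ", "),
                "; correlations reported as NA"))
  }
  r <- suppressWarnings(cor(m))
  as_tibble(as.data.frame.table(r, responseName = "r")) |>
    rename(sample_a = "Var1", sample_b = "Var2") |>
    mutate(across(c("sample_a", "sample_b"), as.character))
}
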