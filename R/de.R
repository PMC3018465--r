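#' Per-gene one-way ANOVA with pooled pairwise contrasts
#'
#' For every gene, fits a fixed-effects one-way ANOVA of the log2(rpm + 1)
#' values across the three tissues and forms the three pairwise contrasts
#' seedling-vs-anther (`SvA`), seedling-vs-meiocyte (`SvM`) and
#' anther-vs-meiocyte (`AvM`). Each contrast uses the pooled residual mean
#' square: `t = (ybar_i - ybar_j) / sqrt(MSE * (1/n_i + 1/n_j))`, with
#' two-sided p-values from a Student t on `N - k` degrees of freedom.
#'
#' Degenerate variance is resolved deterministically per contrast: if the
#' pooled MSE is (numerically) zero, a contrast with equal group means gets
#' p = 1 and one with unequal means gets p = 0; a gene whose values are all
#' identical therefore gets p = 1 everywhere and F = 0.
#'
#' @param log2rpm a transformed RPM tibble (from [log2p1()]).
#' @param samples the matching sample sheet; each tissue needs at least two
#'   replicate columns (pseudo-replicates count).
#' @return A long tibble: `gene_id`, `contrast`, `estimate` (log2 mean
#'   difference, first tissue minus second), `statistic` (t), `p_value`,
#'   plus gene-level `f_statistic`, `mse` and `df_residual` repeated across
#'   the gene's three rows.
#' @export
anova_contrasts <- function(log2rpm, samples) {
  if (!is_log2p1(log2rpm)) {
    abort("anova_contrasts needs log2+1-transformed values; see log2p1()")
  }
  samples <- validate_sample_sheet(samples)
  tab <- table(samples$tissue)
  if (!setequal(names(tab), TISSUES)) {
    abort("samples must cover meiocyte, anther and seedling")
  }
  if (any(tab < 2)) {
    abort(paste0("each tissue needs >= 2 replicates; short: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  y <- as.matrix(log2rpm[, samples$sample_id, drop = FALSE])
  k <- 3L
  N <- ncol(y)
  df <- N - k

  grp <- lapply(TISSUES, function(t) which(samples$tissue == t))
  names(grp) <- TISSUES
  means <- vapply(grp, function(i) rowMeans(y[, i, drop = FALSE]),
                  numeric(nrow(y)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1, dimnames = list(NULL, names(grp)))
  }
  ssw <- Reduce(`+`, lapply(TISSUES, function(t) {
    rowSums((y[, grp[[t]], drop = FALSE] - means[, t])^2)
  }))
  n_i <- vapply(grp, length, integer(1))
  grand <- rowSums(y) / N
  ssb <- Reduce(`+`, lapply(TISSUES, function(t) {
    n_i[[t]] * (means[, t] - grand)^2
  }))
  mse <- ssw / df
  eps <- 1e-12
  f_stat <- ifelse(mse > eps, (ssb / (k - 1)) / mse,
                   ifelse(ssb > eps, Inf, 0))

  pair <- list(SvA = c("seedling", "anther"),
               SvM = c("seedling", "meiocyte"),
               AvM = c("anther", "meiocyte"))
  rows <- lapply(CONTRASTS, function(cn) {
    ij <- pair[[cn]]
    diff <- means[, ij[1]] - means[, ij[2]]
    se <- sqrt(mse * (1 / n_i[[ij[1]]] + 1 / n_i[[ij[2]]]))
    t_stat <- ifelse(mse > eps, diff / se,
                     ifelse(abs(diff) > eps, sign(diff) * Inf, 0))
    p <- ifelse(mse > eps, 2 * pt(-abs(t_stat), df),
                ifelse(abs(diff) > eps, 0, 1))
    tibble(gene_id = log2rpm$gene_id, contrast = cn,
           estimate = unname(diff), statistic = unname(t_stat),
           p_value = unname(p))
  })
  bind_rows(rows) |>
    left_join(tibble(gene_id = log2rpm$gene_id, f_statistic = f_stat,
                     mse = mse, df_residual = df),
              by = "gene_id") |>
    arrange(match(.data$gene_id, log2rpm$gene_id),
            match(.data$contrast, CONTRASTS))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values with the Benjamini-Hochberg step-up
#' procedure (`q_i = min over p_(j) >= p_(i) of p_(j) * m / j`) and flags
#' rejections at level `alpha`. Rejections are monotone in `alpha`, and
#' `q >= p` always.
#'
#' @param p a vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A tibble `p_value`, `q_value`, `reject`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  tibble(p_value = p, q_value = q, reject = q <= alpha)
}

#' Fold change between two tissue-mean RPM values
#'
#' The ratio is computed on the untransformed RPM scale as larger/smaller,
#' with `higher` naming the side with the larger mean (`"first"`/`"second"`,
#' `NA` on a tie). If the smaller value is 0, the ratio is `Inf` when the
#' larger is at least `detect_low`, and `NA` (undefined; fails any fold
#' filter) otherwise.
#'
#' @param x,y non-negative tissue-mean RPM vectors.
#' @param params an [analysis_params()].
#' @return A tibble `ratio`, `higher`.
#' @export
fold_change <- function(x, y, params = analysis_params()) {
  if (any(x < 0 | y < 0, na.rm = TRUE)) abort("tissue means must be non-negative")
  lo <- pmin(x, y)
  hi <- pmax(x, y)
  ratio <- ifelse(lo > 0, hi / lo,
                  ifelse(hi >= params$detect_low, Inf, NA_real_))
  ratio[which(x == y & x > 0)] <- 1
  higher <- case_when(x > y ~ "first", y > x ~ "second", TRUE ~ NA_character_)
  tibble(ratio = ratio, higher = higher)
}

#' Per-gene tissue-mean RPM
#'
#' Mean RPM per tissue over that tissue's replicate columns
#' (pseudo-replicates included).
#'
#' @param rpm an untransformed RPM tibble.
#' @param samples the matching sample sheet.
#' @return A tibble `gene_id`, `meiocyte`, `anther`, `seedling` (a tissue
#'   absent from the sheet yields an `NA` column).
#' @export
tissue_means <- function(rpm, samples) {
  if (is_log2p1(rpm)) abort("tissue_means needs untransformed RPM values")
  samples <- validate_sample_sheet(samples)
  out <- tibble(gene_id = rpm$gene_id)
  for (t in TISSUES) {
    sid <- samples$sample_id[samples$tissue == t]
    out[[t]] <- if (length(sid) == 0) NA_real_ else
      rowMeans(as.matrix(rpm[, sid, drop = FALSE]))
  }
  out
}

#' Full per-gene differential-expression table
#'
#' Runs [anova_contrasts()] on the log2+1 transform of `rpm`, adjusts
#' p-values per contrast with Benjamini-Hochberg across genes, computes RPM
#' fold changes between the contrasted tissue means, and flags significance
#' as `q <= alpha` AND `fold_change >= fold_pref` (an `NA` fold fails; an
#' infinite fold passes).
#'
#' @param rpm an untransformed RPM tibble.
#' @param samples the matching sample sheet.
#' @param params an [analysis_params()].
#' @return A long tibble with one row per gene and contrast: `gene_id`,
#'   `contrast`, `estimate`, `statistic`, `p_value`, `q_value`,
#'   `fold_change`, `direction` (tissue with the larger mean RPM, `NA` on a
#'   tie), `significant`, `f_statistic`, `mse`, `df_residual`.
#' @export
de_results <- function(rpm, samples, params = analysis_params()) {
  if (is_log2p1(rpm)) abort("de_results expects untransformed RPM values")
  de <- anova_contrasts(log2p1(rpm), samples)
  means <- tissue_means(rpm, samples)
  pair <- list(SvA = c("seedling", "anther"),
               SvM = c("seedling", "meiocyte"),
               AvM = c("anther", "meiocyte"))
  de <- de |>
    group_by(.data$contrast) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup()
  fc <- lapply(CONTRASTS, function(cn) {
    ij <- pair[[cn]]
    f <- fold_change(means[[ij[1]]], means[[ij[2]]], params)
    tibble(gene_id = means$gene_id, contrast = cn,
           fold_change = f$ratio,
           direction = case_when(f$higher == "first" ~ ij[1],
                                 f$higher == "second" ~ ij[2],
                                 TRUE ~ NA_character_))
  }) |> bind_rows()
  de |>
    left_join(fc, by = c("gene_id", "contrast")) |>
    mutate(significant = .data$q_value <= params$alpha &
             !is.na(.data$fold_change) &
             .data$fold_change >= params$fold_pref) |>
    relocate("q_value", .after = "p_value")
}

#' Significant gene sets per contrast
#'
#' The Venn-diagram input: for each pairwise contrast, the genes with
#' `q <= alpha`, fold change at least `fold_pref`, and expression passing the
#' `detect_high` gate (at least `detect_high` RPM in at least one sample,
#' pseudo-replicates included).
#'
#' @param de a [de_results()] table.
#' @param rpm the untransformed RPM tibble the table was computed from.
#' @param samples the matching sample sheet.
#' @param params an [analysis_params()].
#' @return A tibble `contrast`, `gene_id`, `direction`.
#' @export
significant_sets <- function(de, rpm, samples, params = analysis_params()) {
  samples <- validate_sample_sheet(samples)
  m <- as.matrix(rpm[, samples$sample_id, drop = FALSE])
  gate <- tibble(gene_id = rpm$gene_id,
                 gate = apply(m, 1, max) >= params$detect_high)
  de |>
    filter(.data$significant) |>
    inner_join(gate, by = "gene_id") |>
    filter(.data$gate) |>
    select("contrast", "gene_id", "direction")
}
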