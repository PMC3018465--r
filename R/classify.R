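#' Two-criterion meiosis-specificity classifier
#'
#' Assigns every gene exactly one tissue-specificity category from its
#' tissue-mean RPM values, implementing the two identification criteria —
#' (1) at least `fold_pref`-fold meiocyte-over-anther enrichment (or meiocyte
#' detection with the anther below detection), and (2) at least
#' `fold_pref`-fold enrichment of both meiocyte and anther over seedling —
#' together with the anther-wall exclusion: a gene expressed `fold_exclude`
#' times or more in anthers versus meiocytes is called an anther-wall
#' candidate regardless of its seedling level, since whole anthers contain
#' only ~1% meiocytes and such genes (the DYT1/ATA1 pattern) function in the
#' anther wall, not in meiosis.
#'
#' The decision ladder, first match wins:
#' 1. every available mean below `detect_low` — `not_expressed`;
#' 2. anther at least `detect_low` and at least `fold_exclude` times the
#'    meiocyte mean — `anther_wall_candidate` (`excluded_fourfold`);
#' 3. meiocyte detected, anther below detection — `meiocyte_specific`;
#' 4. meiocyte at least `fold_pref` times anther — `meiocyte_preferential`;
#' 5. seedling available and both meiocyte and anther at least `fold_pref`
#'    times seedling — `meiosis_anther_shared` (criterion 2);
#' 6. anther at least `fold_pref` times meiocyte — `anther_preferential`;
#' 7. seedling available and at least `fold_pref` times both others —
#'    `seedling_enriched`;
#' 8. otherwise `not_specific`.
#'
#' Ratios against a zero denominator are treated as infinite when the
#' numerator is at least `detect_low` and as failing otherwise, so genes
#' undetected in seedlings can still satisfy criterion 2.
#'
#' @param means a tibble with columns `gene_id`, `meiocyte`, `anther` and
#'   optionally `seedling` (`NA` allowed: criterion 2 and the
#'   seedling-enriched rung are skipped for those genes), e.g. from
#'   [tissue_means()].
#' @param params an [analysis_params()].
#' @return A tibble `gene_id`, `category`, `criterion1`, `criterion2`,
#'   `excluded_fourfold`, `m_rpm`, `a_rpm`, `s_rpm`.
#' @export
classify_specificity <- function(means, params = analysis_params()) {
  m <- means$meiocyte
  a <- means$anther
  s <- if ("seedling" %in% names(means)) means$seedling else
    rep(NA_real_, length(m))
  if (any(c(m, a, s) < 0, na.rm = TRUE)) {
    abort("tissue means must be non-negative")
  }
  lo <- params$detect_low
  # ratio x/y >= f, with x/0 infinite iff x >= detect_low
  ge_fold <- function(x, y, f) {
    ifelse(y > 0, x >= f * y, x >= lo)
  }
  has_s <- !is.na(s)
  top <- pmax(m, a, ifelse(has_s, s, 0))

  r_not_expressed <- top < lo
  r_wall <- a >= lo & ge_fold(a, m, params$fold_exclude)
  r_spec <- m >= lo & a < lo
  r_pref <- ge_fold(m, a, params$fold_pref)
  r_shared <- has_s & ge_fold(m, s, params$fold_pref) &
    ge_fold(a, s, params$fold_pref)
  r_anther <- ge_fold(a, m, params$fold_pref)
  r_seedling <- has_s & ge_fold(s, pmax(m, a), params$fold_pref)

  category <- case_when(
    r_not_expressed ~ "not_expressed",
    r_wall ~ "anther_wall_candidate",
    r_spec ~ "meiocyte_specific",
    r_pref ~ "meiocyte_preferential",
    r_shared ~ "meiosis_anther_shared",
    r_anther ~ "anther_preferential",
    r_seedling ~ "seedling_enriched",
    TRUE ~ "not_specific"
  )
  tibble(
    gene_id = means$gene_id,
    category = factor(category, levels = CATEGORIES),
    criterion1 = category %in% c("meiocyte_specific", "meiocyte_preferential"),
    criterion2 = r_shared & !r_not_expressed & !r_wall,
    excluded_fourfold = category == "anther_wall_candidate",
    m_rpm = m, a_rpm = a, s_rpm = s
  )
}

#' Venn partition of the three significant gene sets
#'
#' Partitions the union of the SvA, SvM and AvM significant sets into the
#' seven disjoint Venn regions. The AvM-only region — the analogue of the
#' genes uniquely differential between meiocytes and anthers — is
#' additionally split by direction (meiocyte-up versus anther-up).
#'
#' @param sig a tibble `contrast`, `gene_id`, `direction` from
#'   [significant_sets()].
#' @return An object of class `meio_venn`: a list with `regions` (tibble
#'   `region`, `SvA`, `SvM`, `AvM`, `n`, `gene_ids` list-column), `n_union`,
#'   and `avm_only_direction` (tibble `direction`, `n`).
#' @export
venn_partition <- function(sig) {
  genes <- sort(unique(sig$gene_id))
  members <- lapply(CONTRASTS, function(cn) {
    genes %in% sig$gene_id[sig$contrast == cn]
  })
  names(members) <- CONTRASTS
  key <- paste0(ifelse(members$SvA, "SvA", ""),
                ifelse(members$SvM, "+SvM", ""),
                ifelse(members$AvM, "+AvM", ""))
  key <- sub("^\\+", "", key)
  combos <- tibble(
    region = c("SvA_only", "SvM_only", "AvM_only", "SvA_SvM", "SvA_AvM",
               "SvM_AvM", "all_three"),
    SvA = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    SvM = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    AvM = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  combo_key <- with(combos, sub("^\\+", "", paste0(
    ifelse(SvA, "SvA", ""), ifelse(SvM, "+SvM", ""), ifelse(AvM, "+AvM", ""))))
  combos$gene_ids <- lapply(combo_key, function(k) genes[key == k])
  combos$n <- lengths(combos$gene_ids)
  combos <- relocate(combos, "n", .before = "gene_ids")

  avm_only <- combos$gene_ids[[match("AvM_only", combos$region)]]
  dir_tab <- sig |>
    filter(.data$contrast == "AvM", .data$gene_id %in% avm_only) |>
    dplyr::count(.data$direction, name = "n") |>
    rename(direction = "direction")
  structure(
    list(regions = combos, n_union = length(genes),
         avm_only_direction = dir_tab),
    class = "meio_venn"
  )
}

#' @export
print.meio_venn <- function(x, ...) {
  cat("Venn partition of significant sets (union:", x$n_union, "genes)\n")
  print(select(x$regions, "region", "n"))
  if (nrow(x$avm_only_direction) > 0) {
    cat("AvM-only region by direction:\n")
    print(x$avm_only_direction)
  }
  invisible(x)
}

#' @describeIn venn_partition region counts as a tibble.
#' @param x a `meio_venn` object.
#' @param ... unused.
#' @method tidy meio_venn
#' @export
tidy.meio_venn <- function(x, ...) {
  select(x$regions, "region", "SvA", "SvM", "AvM", "n")
}

#' @describeIn venn_partition one-row summary (union size, per-set sizes).
#' @method glance meio_venn
#' @export
glance.meio_venn <- function(x, ...) {
  r <- x$regions
  tibble(
    n_union = x$n_union,
    n_SvA = sum(r$n[r$SvA]), n_SvM = sum(r$n[r$SvM]), n_AvM = sum(r$n[r$AvM]),
    n_AvM_only = r$n[r$region == "AvM_only"],
    n_AvM_only_meiocyte_up = sum(
      x$avm_only_direction$n[x$avm_only_direction$direction == "meiocyte"])
  )
}

#' @describeIn venn_partition bar chart of the seven region counts.
#' @param object a `meio_venn` object.
#' @method autoplot meio_venn
#' @export
autoplot.meio_venn <- function(object, ...) {
  d <- tidy(object)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Significant-set Venn regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Candidate meiosis-specific gene pool
#'
#' The final candidate list: genes significant in at least one pairwise
#' contrast whose specificity category is `meiocyte_specific`,
#' `meiocyte_preferential` or `meiosis_anther_shared`. Anther-wall candidates
#' never enter the pool, whatever their q-values. Sorted by meiocyte RPM
#' descending, ties broken by `gene_id`.
#'
#' @param calls a [classify_specificity()] table.
#' @param sig a [significant_sets()] table.
#' @return A tibble `gene_id`, `category`, `m_rpm`, `a_rpm`, `s_rpm`.
#' @export
candidate_pool <- function(calls, sig) {
  keep <- c("meiocyte_specific", "meiocyte_preferential",
            "meiosis_anther_shared")
  calls |>
    filter(.data$category %in% keep,
           .data$gene_id %in% unique(sig$gene_id)) |>
    arrange(desc(.data$m_rpm), .data$gene_id) |>
    select("gene_id", "category", "m_rpm", "a_rpm", "s_rpm")
}
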