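#' Configuration for the synthetic three-tissue experiment
#'
#' The generator emulates the study design this pipeline targets: three
#' tissues (meiocyte, anther, seedling) with two technical replicates for
#' meiocyte and anther, one seedling library (later split into
#' pseudo-replicates), library sizes around 21/17/13 million aligned reads,
#' planted expression classes, a contiguous block of mitochondrial-insertion
#' (MGI) genes in the chromosome II pericentromeric interval, and
#' transposable-element (TE) genes concentrated around centromere midpoints.
#'
#' Expression classes and their planted geometry (RPM means per tissue):
#' * `housekeeping` — identical mean in all three tissues.
#' * `meiocyte_specific` — expressed in meiocytes only; anther and seedling
#'   means below the detection threshold.
#' * `meiocyte_preferential` — meiocyte mean at least `fold_pref` times the
#'   anther mean, both detected.
#' * `anther_wall` — anther mean at least `fold_exclude` times the meiocyte
#'   mean (the DYT1/ATA1 pattern; seedling silent).
#' * `seedling_enriched` — seedling mean well above both others.
#' * `silent` — all means below detection.
#'
#' TE genes are placed with a truncated Laplace (double-exponential) kernel
#' centred on the centromere midpoint with scale `te_concentration` times the
#' chromosome length, so the probability mass in any pericentromeric window is
#' available in closed form from [pericentromeric_mass()].
#'
#' @param n_genes total number of genes (MGI block included).
#' @param class_props named class proportions for non-MGI genes; must sum
#'   to 1 (tolerance 1e-9).
#' @param chrom_names,chrom_lengths,centromere_mid the simulated karyotype;
#'   defaults patterned on Arabidopsis Col-0 (5 chromosomes).
#' @param mgi_chrom,mgi_start,mgi_end,mgi_n_genes the planted MGI block:
#'   `mgi_n_genes` contiguous genes inside the interval.
#' @param mgi_class_props class proportions used for MGI-block genes
#'   (meiocyte-biased by default).
#' @param te_fraction fraction of non-MGI genes that are TE genes.
#' @param te_superfamily_weights named sampling weights for TE superfamilies
#'   (normalised internally); `NA` names are reported as unassigned.
#' @param te_concentration Laplace scale for TE placement, as a fraction of
#'   chromosome length.
#' @param library_totals aligned-read totals for the five libraries
#'   (meiocyte x2, anther x2, seedling x1).
#' @param expr_range RPM range (log-uniform) for expressed tissue means.
#' @param base_range RPM range (log-uniform) for the lower tissue of
#'   preferential/excluded classes.
#' @param off_max upper bound for sub-detection means (uniform on 0..off_max).
#' @param pref_fold_range,exclude_fold_range,seedling_fold_range log-uniform
#'   fold ranges for the preferential, anther-wall and seedling-enriched
#'   classes.
#' @param dispersion_range per-gene negative-binomial dispersion range
#'   (uniform); 0 gives Poisson counts.
#' @param anther_mix optional mixture weight w: anther mean is replaced by
#'   `w * meiocyte + (1 - w) * anther`, modelling the ~1% meiocyte content of
#'   whole anthers. Default 0 (off).
#' @return A list of class `meio_sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       class_props = c(housekeeping = 0.50, silent = 0.15,
                                       meiocyte_specific = 0.08,
                                       meiocyte_preferential = 0.08,
                                       anther_wall = 0.10,
                                       seedling_enriched = 0.09),
                       chrom_names = c("I", "II", "III", "IV", "V"),
                       chrom_lengths = c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6),
                       centromere_mid = c(15.1e6, 3.6e6, 13.8e6, 3.95e6, 11.85e6),
                       mgi_chrom = "II", mgi_start = 3222935,
                       mgi_end = 3626460, mgi_n_genes = 150,
                       mgi_class_props = c(meiocyte_specific = 0.30,
                                           meiocyte_preferential = 0.36,
                                           housekeeping = 0.12, silent = 0.22),
                       te_fraction = 0.15,
                       te_superfamily_weights = c(
                         "LTR/Gypsy" = 0.36, "DNA/MuDR" = 0.21,
                         "LTR/Copia" = 0.10, "DNA/En-Spm" = 0.08,
                         "RC/Helitron" = 0.07, "LINE/L1" = 0.06,
                         "DNA/HAT" = 0.04, "DNA/Harbinger" = 0.03,
                         "DNA/Tc1" = 0.02, "SINE" = 0.0127,
                         "unassigned" = 0.0373),
                       te_concentration = 0.04,
                       library_totals = c(21e6, 21e6, 17e6, 17e6, 13e6),
                       expr_range = c(10, 500), base_range = c(1, 50),
                       off_max = 0.5,
                       pref_fold_range = c(3, 16),
                       exclude_fold_range = c(5, 40),
                       seedling_fold_range = c(3, 16),
                       dispersion_range = c(0.005, 0.05),
                       anther_mix = 0) {
  stopifnot(
    n_genes > 0,
    abs(sum(class_props) - 1) < 1e-9,
    all(class_props >= 0), all(class_props <= 1),
    abs(sum(mgi_class_props) - 1) < 1e-9,
    length(chrom_lengths) == length(chrom_names),
    length(centromere_mid) == length(chrom_names),
    mgi_chrom %in% chrom_names,
    mgi_start <= mgi_end,
    te_fraction >= 0, te_fraction < 1,
    te_concentration > 0,
    length(library_totals) == 5, all(library_totals > 0),
    all(dispersion_range >= 0),
    anther_mix >= 0, anther_mix <= 1
  )
  if (!all(names(class_props) %in% GENE_CLASSES)) {
    abort("class_props names must be gene classes")
  }
  structure(as.list(environment()), class = "meio_sim_config")
}

#' Default five-library sample sheet for a simulated experiment
#'
#' @param library_totals aligned-read totals for M1, M2, A1, A2, S1.
#' @return A sample-sheet tibble.
#' @export
default_samples <- function(library_totals = c(21e6, 21e6, 17e6, 17e6, 13e6)) {
  tibble(
    sample_id = c("M1", "M2", "A1", "A2", "S1"),
    tissue = c("meiocyte", "meiocyte", "anther", "anther", "seedling"),
    replicate = c(1L, 2L, 1L, 2L, 1L),
    library_total = as.numeric(library_totals),
    is_pseudo = FALSE
  )
}

# log-uniform draw on [lo, hi]
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# inverse-CDF sampler for a Laplace(centre, scale) truncated to [lo, hi]
rtrunc_laplace <- function(n, centre, scale, lo, hi) {
  F <- function(x) ifelse(x < centre,
                          0.5 * exp((x - centre) / scale),
                          1 - 0.5 * exp(-(x - centre) / scale))
  u <- runif(n, F(lo), F(hi))
  ifelse(u < 0.5,
         centre + scale * log(2 * u),
         centre - scale * log(2 * (1 - u)))
}

#' Analytic pericentromeric mass of the TE placement kernel
#'
#' Probability that a TE gene start drawn from the truncated Laplace placement
#' kernel falls within `window` bp of the centromere midpoint. Used to check
#' the generator's placement empirically.
#'
#' @param window half-width of the window around the centromere midpoint (bp).
#' @param centromere centromere midpoint (bp).
#' @param chrom_length chromosome length (bp); the kernel is truncated to
#'   `[1, chrom_length]`.
#' @param scale Laplace scale in bp (for [sim_config()] defaults this is
#'   `te_concentration * chrom_length`).
#' @return The window probability, a number in (0, 1].
#' @export
pericentromeric_mass <- function(window, centromere, chrom_length, scale) {
  F <- function(x) ifelse(x < centromere,
                          0.5 * exp((x - centromere) / scale),
                          1 - 0.5 * exp(-(x - centromere) / scale))
  z <- F(chrom_length) - F(1)
  (F(min(centromere + window, chrom_length)) -
      F(max(centromere - window, 1))) / z
}

#' Generate planted truth and gene models
#'
#' Assigns every gene a class, per-tissue expected RPM means honouring the
#' class geometry (see [sim_config()]), a negative-binomial dispersion, and a
#' genomic position: MGI genes contiguous in the configured interval, TE genes
#' drawn from the truncated Laplace kernel around centromere midpoints, other
#' genes uniform along the genome. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with `truth` (tibble: `gene_id`, `true_class`, `mu_m`,
#'   `mu_a`, `mu_s`, `dispersion`) and `annotation` (gene-model tibble as in
#'   [read_annotation()], plus `transposon_id` for TE genes).
#' @export
simulate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "meio_sim_config"))
  cfg <- config
  span <- cfg$mgi_end - cfg$mgi_start + 1
  if (cfg$mgi_n_genes * 600 > span) {
    abort("MGI block does not fit its interval (too many genes for the span)")
  }
  if (cfg$mgi_n_genes > cfg$n_genes) {
    abort("mgi_n_genes exceeds n_genes")
  }
  withr::with_seed(seed, {
    n <- cfg$n_genes
    n_mgi <- cfg$mgi_n_genes
    n_rest <- n - n_mgi
    gene_id <- sprintf("SIM%06d", seq_len(n))

    cls <- character(n)
    is_mgi <- c(rep(TRUE, n_mgi), rep(FALSE, n_rest))
    if (n_mgi > 0) {
      cls[is_mgi] <- sample(names(cfg$mgi_class_props), n_mgi, replace = TRUE,
                            prob = cfg$mgi_class_props)
    }
    cls[!is_mgi] <- sample(names(cfg$class_props), n_rest, replace = TRUE,
                           prob = cfg$class_props)

    mu_m <- mu_a <- mu_s <- numeric(n)
    draw <- function(k, rng) runif_log(k, rng[1], rng[2])
    for (cl in unique(cls)) {
      i <- which(cls == cl)
      k <- length(i)
      if (cl == "housekeeping") {
        mu <- draw(k, cfg$expr_range)
        mu_m[i] <- mu; mu_a[i] <- mu; mu_s[i] <- mu
      } else if (cl == "silent") {
        mu_m[i] <- runif(k, 0, 0.3)
        mu_a[i] <- runif(k, 0, 0.3)
        mu_s[i] <- runif(k, 0, 0.3)
      } else if (cl == "meiocyte_specific") {
        mu_m[i] <- draw(k, cfg$expr_range)
        mu_a[i] <- runif(k, 0, cfg$off_max)
        mu_s[i] <- runif(k, 0, cfg$off_max)
      } else if (cl == "meiocyte_preferential") {
        base <- draw(k, cfg$base_range)
        mu_a[i] <- base
        mu_m[i] <- base * draw(k, cfg$pref_fold_range)
        mu_s[i] <- base * runif(k, 0, 1)
      } else if (cl == "anther_wall") {
        base <- draw(k, cfg$base_range)
        mu_m[i] <- base
        mu_a[i] <- base * draw(k, cfg$exclude_fold_range)
        mu_s[i] <- runif(k, 0, cfg$off_max)
      } else if (cl == "seedling_enriched") {
        # meiocyte and anther within 2x of each other so no other rung fires
        base <- draw(k, cfg$base_range)
        mu_m[i] <- base
        mu_a[i] <- base * 2^runif(k, -1, 1)
        mu_s[i] <- pmax(mu_m[i], mu_a[i]) * draw(k, cfg$seedling_fold_range)
      }
    }
    if (cfg$anther_mix > 0) {
      mu_a <- cfg$anther_mix * mu_m + (1 - cfg$anther_mix) * mu_a
    }
    dispersion <- runif(n, cfg$dispersion_range[1], cfg$dispersion_range[2])

    # --- genomic placement ---
    biotype <- rep("nuclear", n)
    biotype[is_mgi] <- "mgi"
    n_te <- floor(cfg$te_fraction * n_rest)
    te_idx <- if (n_te > 0) sample(which(!is_mgi), n_te) else integer(0)
    biotype[te_idx] <- "te"

    len <- round(runif(n, 500, 5000))
    chrom <- character(n)
    start <- numeric(n)

    # MGI block: contiguous, evenly spaced inside the interval
    if (n_mgi > 0) {
      step <- (span - 5000) / n_mgi
      start[is_mgi] <- round(cfg$mgi_start + (seq_len(n_mgi) - 1) * step)
      chrom[is_mgi] <- cfg$mgi_chrom
      len[is_mgi] <- pmin(len[is_mgi], floor(step))
    }

    # the MGI interval is reserved for the block: other genes are resampled
    # out of it so the planted block is exactly the interval's gene content
    in_mgi_interval <- function(ch, st) {
      ch == cfg$mgi_chrom & st >= cfg$mgi_start - 5000 & st <= cfg$mgi_end
    }

    # TE genes: Laplace kernel around the centromere of a length-weighted chromosome
    if (n_te > 0) {
      ci <- sample(seq_along(cfg$chrom_names), n_te, replace = TRUE,
                   prob = cfg$chrom_lengths)
      chrom[te_idx] <- cfg$chrom_names[ci]
      pos <- round(rtrunc_laplace(
        n_te, cfg$centromere_mid[ci],
        cfg$te_concentration * cfg$chrom_lengths[ci],
        1, cfg$chrom_lengths[ci]))
      for (iter in 1:100) {
        bad <- which(in_mgi_interval(chrom[te_idx], pos))
        if (length(bad) == 0) break
        pos[bad] <- round(rtrunc_laplace(
          length(bad), cfg$centromere_mid[ci[bad]],
          cfg$te_concentration * cfg$chrom_lengths[ci[bad]],
          1, cfg$chrom_lengths[ci[bad]]))
      }
      start[te_idx] <- pos
    }

    # remaining genes: uniform over the genome
    plain <- which(!is_mgi & biotype != "te")
    if (length(plain) > 0) {
      ci <- sample(seq_along(cfg$chrom_names), length(plain), replace = TRUE,
                   prob = cfg$chrom_lengths)
      chrom[plain] <- cfg$chrom_names[ci]
      pos <- ceiling(runif(length(plain), 0, cfg$chrom_lengths[ci] - 5000))
      for (iter in 1:100) {
        bad <- which(in_mgi_interval(chrom[plain], pos))
        if (length(bad) == 0) break
        pos[bad] <- ceiling(runif(length(bad),
                                  0, cfg$chrom_lengths[ci[bad]] - 5000))
      }
      start[plain] <- pos
    }
    start <- pmax(start, 1)
    end <- start + len - 1
    clen <- cfg$chrom_lengths[match(chrom, cfg$chrom_names)]
    end <- pmin(end, clen)

    te_superfamily <- rep(NA_character_, n)
    te_family <- rep(NA_character_, n)
    transposon_id <- rep(NA_character_, n)
    if (n_te > 0) {
      w <- cfg$te_superfamily_weights / sum(cfg$te_superfamily_weights)
      sf <- sample(names(w), n_te, replace = TRUE, prob = w)
      te_superfamily[te_idx] <- sf
      te_family[te_idx] <- paste0(sub(".*/", "", sf), "-like")
      transposon_id[te_idx] <- sprintf("TE%06d", seq_len(n_te))
    }

    truth <- tibble(gene_id = gene_id, true_class = cls,
                    mu_m = mu_m, mu_a = mu_a, mu_s = mu_s,
                    dispersion = dispersion)
    annotation <- tibble(
      gene_id = gene_id, chrom = chrom, start = as.integer(start),
      end = as.integer(end),
      strand = sample(c("+", "-"), n, replace = TRUE),
      biotype = biotype, te_family = te_family,
      te_superfamily = te_superfamily, transposon_id = transposon_id
    ) |>
      arrange(.data$chrom, .data$start)
    list(truth = truth, annotation = annotation)
  })
}

#' Draw counts for a planted truth table
#'
#' Counts for gene g in sample j are negative binomial with mean
#' `mu[g, tissue(j)] * library_total_j / 1e6` and the gene's dispersion
#' (variance `mu + dispersion * mu^2`); dispersion 0 gives Poisson counts.
#' Technical replicates of a tissue share the same mean and differ only
#' through counting noise and library size. Deterministic given `seed`.
#'
#' @param truth a truth tibble (`gene_id`, `mu_m`, `mu_a`, `mu_s`,
#'   `dispersion`).
#' @param samples a sample sheet covering the tissues in `truth`.
#' @param seed integer seed.
#' @return A counts tibble (`gene_id` + one column per sample).
#' @export
simulate_counts <- function(truth, samples, seed = 1) {
  samples <- validate_sample_sheet(samples)
  mu_col <- c(meiocyte = "mu_m", anther = "mu_a", seedling = "mu_s")
  missing <- setdiff(mu_col[unique(samples$tissue)], names(truth))
  if (length(missing) > 0) {
    abort(paste0("truth table lacks mean column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(truth)
  size <- ifelse(truth$dispersion > 0, 1 / truth$dispersion, Inf)
  withr::with_seed(seed, {
    cols <- lapply(seq_len(nrow(samples)), function(j) {
      mu <- truth[[mu_col[[samples$tissue[j]]]]] *
        samples$library_total[j] / 1e6
      pois <- !is.finite(size)
      out <- integer(n)
      if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        out[!pois] <- as.integer(
          rnbinom(sum(!pois), mu = mu[!pois], size = size[!pois]))
      }
      out
    })
    names(cols) <- samples$sample_id
    bind_cols(tibble(gene_id = truth$gene_id), as_tibble(cols))
  })
}

#' Simulate a complete three-tissue experiment
#'
#' Convenience wrapper: planted truth and gene models from
#' [simulate_truth()], the five-library design from [default_samples()], and
#' counts from [simulate_counts()] (seeded with `seed + 1`).
#'
#' @inheritParams simulate_truth
#' @return A list with `counts`, `samples`, `annotation`, `te_table`,
#'   `truth` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1) {
  sim <- simulate_truth(config, seed = seed)
  samples <- default_samples(config$library_totals)
  counts <- simulate_counts(sim$truth, samples, seed = seed + 1)
  te <- sim$annotation |>
    filter(.data$biotype == "te") |>
    select("gene_id", "transposon_id",
           family = "te_family", superfamily = "te_superfamily")
  list(counts = counts, samples = samples,
       annotation = select(sim$annotation, -"transposon_id"),
       te_table = te, truth = sim$truth, config = config)
}
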