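make_log2_tbl <- function(m) {
  # m: genes x 6 matrix of log2 values in sample order M1 M2 A1 A2 S1 S2
  x <- tibble::as_tibble(as.data.frame(m))
  names(x) <- six_samples()$sample_id
  x <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m)))), x)
  attr(x, "log2p1") <- TRUE
  x
}

test_that("ANOVA contrasts reproduce the hand-computed textbook example", {
  # M = (5.0, 5.2), A = (3.1, 2.9), S = (3.0, 3.2); frozen from an
  # independent lm/emmeans computation
  y <- make_log2_tbl(matrix(c(5.0, 5.2, 3.1, 2.9, 3.0, 3.2), nrow = 1))
  out <- anova_contrasts(y, six_samples())
  expect_equal(unique(out$f_statistic), 140.33333, tolerance = 1e-6)
  expect_equal(unique(out$mse), 0.02)
  expect_equal(unique(out$df_residual), 3)
  avm <- out[out$contrast == "AvM", ]
  expect_equal(avm$estimate, -2.1)
  expect_equal(avm$statistic, -14.849242, tolerance = 1e-6)
  expect_equal(avm$p_value, 0.000663, tolerance = 1e-3)
  sva <- out[out$contrast == "SvA", ]
  expect_equal(sva$statistic, 0.7071068, tolerance = 1e-6)
  expect_equal(sva$p_value, 0.530447, tolerance = 1e-4)
})

test_that("ANOVA agrees with an independent lm/emmeans oracle on random fixtures", {
  skip_if_not_installed("emmeans")
  samples <- six_samples()
  withr::with_seed(42, {
    for (rep in 1:20) {
      vals <- round(rnorm(6, mean = 5, sd = 2), 3)
      y <- make_log2_tbl(matrix(vals, nrow = 1))
      out <- anova_contrasts(y, samples)
      fit <- stats::lm(vals ~ g,
                       data = data.frame(vals = vals,
                                         g = factor(samples$tissue)))
      a <- stats::anova(fit)
      expect_equal(unique(out$f_statistic), a$`F value`[1], tolerance = 1e-8)
      expect_equal(unique(out$mse), a$`Mean Sq`[2], tolerance = 1e-8)
      em <- summary(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                      "pairwise", adjust = "none"))
      # emmeans orders levels alphabetically: anther, meiocyte, seedling
      avm <- out$statistic[out$contrast == "AvM"]
      expect_equal(avm, em$t.ratio[em$contrast == "anther - meiocyte"],
                   tolerance = 1e-8)
      expect_equal(out$p_value[out$contrast == "AvM"],
                   em$p.value[em$contrast == "anther - meiocyte"],
                   tolerance = 1e-8)
      svm <- out$statistic[out$contrast == "SvM"]
      expect_equal(-svm, em$t.ratio[em$contrast == "meiocyte - seedling"],
                   tolerance = 1e-8)
    }
  })
})

test_that("degenerate variance resolves deterministically", {
  # identical group means with zero within-group variance: F = 0, p = 1
  flat <- make_log2_tbl(matrix(c(1, 2, 1, 2, 1, 2), nrow = 1))
  out <- anova_contrasts(flat, six_samples())
  expect_equal(unique(out$f_statistic), 0)
  expect_equal(out$p_value, rep(1, 3))

  # all six identical: p = 1 everywhere
  same <- make_log2_tbl(matrix(rep(3, 6), nrow = 1))
  expect_equal(anova_contrasts(same, six_samples())$p_value, rep(1, 3))

  # zero MSE with unequal means: p = 0 on the separated contrasts
  sep <- make_log2_tbl(matrix(c(5, 5, 1, 1, 1, 1), nrow = 1))
  out <- anova_contrasts(sep, six_samples())
  expect_equal(out$p_value[out$contrast == "AvM"], 0)
  expect_equal(out$p_value[out$contrast == "SvM"], 0)
  expect_equal(out$p_value[out$contrast == "SvA"], 1)

  # untransformed input and missing replicates are contract errors
  raw <- tiny_counts()
  expect_error(anova_contrasts(rpm_normalize(raw, six_samples()),
                               six_samples()), "transform")
  expect_error(anova_contrasts(
    log2p1(rpm_normalize(raw[, 1:6], six_samples()[1:5, ])),
    six_samples()[1:5, ]), ">= 2 replicates")
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(0.03)$q_value, 0.03)
  expect_true(bh_adjust(0.03)$reject)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5))$q_value,
               c(0.04, 0.04, 0.04, 0.5))
  expect_false(any(bh_adjust(rep(1, 20), alpha = 0.99)$reject))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(7, {
    for (rep in 1:50) {
      p <- runif(sample(1:12, 1))
      got <- bh_adjust(p)
      expect_equal(got$q_value, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(got$q_value >= got$p_value))
    }
  })
})

test_that("fold change follows the larger/smaller convention with zero rules", {
  p <- analysis_params()
  fc <- fold_change(7.8, 89.3, p)
  expect_equal(fc$ratio, 89.3 / 7.8)
  expect_equal(fc$higher, "second")
  expect_true(fc$ratio >= p$fold_pref && fc$ratio >= p$fold_exclude)
  expect_equal(fold_change(5, 0, p)$ratio, Inf)
  expect_true(is.na(fold_change(0.4, 0, p)$ratio))
  expect_equal(fold_change(3, 3, p)$ratio, 1)
  expect_true(is.na(fold_change(3, 3, p)$higher))
  expect_error(fold_change(-1, 2, p), "non-negative")
})

test_that("significant sets apply the q, fold and 5-RPM gates conjointly", {
  samples <- six_samples(1e6)
  counts <- tibble::tibble(
    gene_id = c("big", "small_fold", "low_expr"),
    M1 = c(400L, 40L, 4L), M2 = c(420L, 42L, 4L),
    A1 = c(40L, 30L, 1L), A2 = c(38L, 29L, 1L),
    S1 = c(41L, 30L, 1L), S2 = c(39L, 31L, 1L))
  rpm <- rpm_normalize(counts, samples)
  de <- de_results(rpm, samples)
  sig <- significant_sets(de, rpm, samples)
  # big: 10-fold meiocyte excess, >5 RPM -> in SvM and AvM, toward meiocyte
  expect_true(all(c("SvM", "AvM") %in% sig$contrast[sig$gene_id == "big"]))
  expect_true(all(sig$direction[sig$gene_id == "big"] == "meiocyte"))
  # small_fold: significant q but < 2-fold -> excluded
  expect_false("small_fold" %in% sig$gene_id)
  # low_expr: 4-fold but never reaches 5 RPM -> gated out
  expect_false("low_expr" %in% sig$gene_id)
  # empty input gives empty sets
  expect_equal(nrow(significant_sets(de[de$significant == FALSE & FALSE, ],
                                     rpm, samples)), 0)
})

test_that("housekeeping genes are rejected at about the FDR level", {
  # null behaviour: one simulation, 90% null genes
  n <- 4000
  withr::with_seed(5, base <- exp(runif(n, log(2), log(100))))
  truth <- manual_truth(mu_m = base * c(rep(1, 3600), rep(4, 400)),
                        mu_a = base, mu_s = base, dispersion = 0.01)
  samples <- six_samples(1.5e7)
  counts <- simulate_counts(truth, samples, seed = 6)
  de <- de_results(rpm_normalize(counts, samples), samples)
  nulls <- truth$gene_id[1:3600]
  hit <- de$gene_id[de$q_value <= 0.05] # any contrast
  fp_rate <- mean(nulls %in% hit)
  se <- sqrt(0.05 * 0.95 / 3600)
  expect_lt(fp_rate, 3 * 0.05 + 3 * se) # three contrasts, each BH-controlled
})

test_that("significant sets grow monotonically with alpha and shrink with fold", {
  sim <- simulate_experiment(small_sim(n_genes = 800), seed = 17)
  s5 <- split_pseudoreplicates(sim$counts, sim$samples, "S1", seed = 1)
  rpm <- rpm_normalize(s5$counts, s5$samples)
  loose <- analysis_params(alpha = 0.10, fold_pref = 1.5)
  strict <- analysis_params(alpha = 0.01, fold_pref = 3)
  de_l <- de_results(rpm, s5$samples, loose)
  de_s <- de_results(rpm, s5$samples, strict)
  sig_l <- significant_sets(de_l, rpm, s5$samples, loose)
  sig_s <- significant_sets(de_s, rpm, s5$samples, strict)
  for (cn in c("SvA", "SvM", "AvM")) {
    expect_true(all(sig_s$gene_id[sig_s$contrast == cn] %in%
                      sig_l$gene_id[sig_l$contrast == cn]))
  }
})
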