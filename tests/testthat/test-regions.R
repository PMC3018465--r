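region_ann <- function(n, chrom = "II", start0 = 1000, step = 1000, len = 500) {
  tibble::tibble(
    gene_id = sprintf("r%03d", seq_len(n)), chrom = chrom,
    start = as.integer(start0 + (seq_len(n) - 1) * step),
    end = as.integer(start0 + (seq_len(n) - 1) * step + len - 1),
    strand = "+", biotype = "nuclear",
    te_family = NA_character_, te_superfamily = NA_character_)
}

test_that("interval queries use >= 1 bp overlap on 1-based coordinates", {
  expect_equal(genes_in_interval(region_ann(0), "II", 1, 100), character(0))
  ann <- tibble::tibble(gene_id = "g", chrom = "II", start = 100L, end = 200L,
                        strand = "+", biotype = "nuclear",
                        te_family = NA_character_,
                        te_superfamily = NA_character_)
  expect_equal(genes_in_interval(ann, "II", 200, 300), "g") # 1-bp overlap
  expect_equal(genes_in_interval(ann, "II", 201, 300), character(0))
  expect_equal(genes_in_interval(ann, "I", 100, 200), character(0))
  expect_error(genes_in_interval(ann, "II", 300, 200), "start")
})

test_that("the planted MGI block is exactly the interval's gene content", {
  cfg <- small_sim(n_genes = 1200)
  sim <- simulate_truth(cfg, seed = 4)
  ids <- genes_in_interval(sim$annotation, cfg$mgi_chrom,
                           cfg$mgi_start, cfg$mgi_end)
  planted <- sim$annotation$gene_id[sim$annotation$biotype == "mgi"]
  expect_setequal(ids, planted)
  expect_equal(length(ids), cfg$mgi_n_genes)
  # returned in start order
  expect_equal(ids, sim$annotation$gene_id[match(ids, sim$annotation$gene_id)][
    order(sim$annotation$start[match(ids, sim$annotation$gene_id)])])
})

test_that("MGI summary counts follow the detection and fold definitions", {
  # planted: 10 genes with m = 8a, 5 with m = 3a, 5 with a < 1 < m
  means <- tibble::tibble(
    gene_id = sprintf("r%03d", 1:22),
    meiocyte = c(rep(16, 10), rep(6, 5), rep(4, 5), 0.2, 3),
    anther = c(rep(2, 10), rep(2, 5), rep(0.5, 5), 0.1, 2.9),
    seedling = 1)
  out <- mgi_summary(means, means$gene_id)
  expect_equal(out$n_genes_in_region, 22)
  expect_equal(out$n_fourfold, 10)
  expect_equal(out$n_meiocyte_preferential, 15)
  expect_equal(out$n_meiocyte_only, 5)
  expect_equal(out$n_detected_in_meiocyte, 21)
  # the AGO8-style pattern lands in meiocyte-only
  ago8 <- mgi_summary(tibble::tibble(gene_id = "x", meiocyte = 3.03,
                                     anther = 0.71, seedling = NA), "x")
  expect_equal(ago8$n_meiocyte_only, 1)
  # internal inequalities
  expect_lte(out$n_fourfold, out$n_meiocyte_preferential)
  expect_lte(out$n_meiocyte_only + out$n_meiocyte_preferential,
             out$n_detected_in_meiocyte)
  # all-silent region
  silent <- mgi_summary(tibble::tibble(gene_id = c("a", "b"),
                                       meiocyte = c(0.1, 0), anther = c(0, 0.4),
                                       seedling = 0), c("a", "b"))
  expect_equal(silent$n_detected_in_meiocyte, 0)
  expect_equal(silent$n_genes_in_region, 2)
  # missing gene errors by name
  expect_error(mgi_summary(means, c("r001", "ghost")), "ghost")
})

test_that("TE differential summary partitions and superfamily shares add up", {
  # 100 differential TEs, 36 of them LTR/Gypsy -> 36.00%
  ann <- region_ann(120)
  ann$biotype <- "te"
  ann$te_superfamily <- c(rep("LTR/Gypsy", 36), rep("DNA/MuDR", 30),
                          rep("LTR/Copia", 24), rep(NA, 30))
  means <- tibble::tibble(
    gene_id = ann$gene_id,
    meiocyte = c(rep(12, 80), rep(0.3, 10), rep(2, 10), rep(3, 20)),
    anther = c(rep(0.3, 80), rep(9, 10), rep(8, 10), rep(2.9, 20)),
    seedling = 0.1)
  out <- te_differential_summary(means, ann, baseline = "anther")
  expect_equal(out$counts$n_te_differential, 100)
  expect_equal(out$counts$n_meiocyte_only, 80)
  expect_equal(out$counts$n_other_only, 10)
  expect_equal(out$counts$n_shared_down, 10)
  expect_equal(out$counts$n_up_in_meiocyte, 80)
  expect_equal(out$counts$n_down_in_meiocyte, 20)
  expect_equal(out$counts$n_up_in_meiocyte + out$counts$n_down_in_meiocyte,
               out$counts$n_te_differential)
  sf <- out$superfamily
  expect_equal(sf$pct_differential[sf$superfamily == "LTR/Gypsy"], 36)
  expect_equal(sum(sf$pct_differential), 100, tolerance = 0.01)
  expect_equal(sum(sf$pct_up), 100, tolerance = 0.01)
  # no TE genes at all -> zero summary
  none <- region_ann(5)
  z <- te_differential_summary(means[1:5, ] |>
                                 dplyr::mutate(gene_id = none$gene_id),
                               none, "anther")
  expect_equal(z$counts$n_te_differential, 0)
  # m = 12, a = 0.3 is meiocyte-only and up-regulated
  one <- ann[1, ]
  m1 <- tibble::tibble(gene_id = one$gene_id, meiocyte = 12, anther = 0.3,
                       seedling = 0)
  o1 <- te_differential_summary(m1, one, "anther")
  expect_equal(o1$genes$status, "meiocyte_only")
  expect_equal(o1$genes$direction, "up")
})

test_that("meiocyte-only TEs against seedling contain those against anther when seedling is lower", {
  cfg <- small_sim(n_genes = 2500)
  sim <- simulate_experiment(cfg, seed = 19)
  rpm <- rpm_normalize(sim$counts, sim$samples)
  means <- tissue_means(rpm, sim$samples)
  vs_a <- te_differential_summary(means, sim$annotation, "anther")
  vs_s <- te_differential_summary(means, sim$annotation, "seedling")
  only_a <- vs_a$genes$gene_id[vs_a$genes$status == "meiocyte_only"]
  only_s <- vs_s$genes$gene_id[vs_s$genes$status == "meiocyte_only"]
  # planted seedling expression sits at or below anther for meiocyte classes,
  # so the seedling-baseline meiocyte-only set should not be the smaller one
  expect_gte(length(only_s), length(only_a) * 0.9)
})

test_that("chromosome binning is keyed by start and conserves the set size", {
  ann <- region_ann(3, chrom = "I", start0 = 150000, step = 250000)
  bins <- chromosome_bin_distribution(ann, ann$gene_id, bin_size = 1e5)
  expect_equal(sum(bins$n), 3)
  # a gene at 150,000 with 100-kb bins sits in bin index 1
  expect_equal(bins$n[bins$bin == 1], 1)
  expect_equal(bins$start[bins$bin == 1], 100001)
  # empty set: all bins present, all zero
  empty <- chromosome_bin_distribution(ann, character(0), bin_size = 1e5)
  expect_true(all(empty$n == 0))
  expect_gt(nrow(empty), 0)
  expect_error(chromosome_bin_distribution(ann, ann$gene_id, bin_size = 0),
               "bin_size")
})

test_that("meiocyte-up TEs concentrate near centromeres above genome average", {
  cfg <- sim_config(n_genes = 4000, te_fraction = 0.25, mgi_n_genes = 0)
  sim <- simulate_experiment(cfg, seed = 29)
  rpm <- rpm_normalize(sim$counts, sim$samples)
  means <- tissue_means(rpm, sim$samples)
  te <- te_differential_summary(means, sim$annotation, "anther")
  up <- te$genes$gene_id[te$genes$direction == "up"]
  ann_up <- sim$annotation[sim$annotation$gene_id %in% up, ]
  ci <- match(ann_up$chrom, cfg$chrom_names)
  w <- 0.10 * cfg$chrom_lengths[ci]
  frac_near <- mean(abs(ann_up$start - cfg$centromere_mid[ci]) <= w)
  # the same +-10% window under a uniform layout holds ~20% of genes
  expect_gt(frac_near, 2 * 0.2)
})
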