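test_that("simulation is deterministic and motif density matches expectation", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 1e5,
                    motif = "TTAA", n_genes = 10,
                    gene_length = c(2000, 4000), insertions_per_sample = 200)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_identical(sim1$true_rates, sim2$true_rates)
  s1 <- simulate_screen(sim1, seed = 2)
  s2 <- simulate_screen(sim2, seed = 2)
  expect_identical(s1[, 1:3], s2[, 1:3])

  # uniform base composition: P(TTAA at an offset) = 4^-4, ~100000/256 sites
  n_sites <- length(sim1$index$positions$chr1)
  expected <- 1e5 / 256
  expect_lt(abs(n_sites - expected) / sqrt(expected), 4)

  # the genome-wide neutral rate sums to the configured expectation
  expect_equal(sum(sim1$true_rates$lambda), 200)
})

test_that("null screens distribute insertions proportionally to motif counts", {
  cfg <- sim_config(seed = 8, n_chroms = 1, chrom_length = 2e5, n_genes = 10,
                    gene_length = c(3000, 6000),
                    bias_weights = c(gene = 0, tss = 0, atac = 0, dnase = 0),
                    depth_factors = rep(1, 10), chrom_factors = 1,
                    insertions_per_sample = 400)
  sim <- simulate_genome(cfg)
  expect_true(all(abs(sim$true_rates$lambda -
                        sim$true_rates$lambda[1]) < 1e-12))
  scr <- simulate_screen(sim, seed = 9)
  tiles <- make_window_regions(chrom_lengths(sim$genome), 50000L)
  k <- colSums(build_count_matrix(scr, tiles))
  n_motif <- aggregate_region_rates(sim$index, tiles)$n_motif_sites
  # chi-squared goodness of fit of counts against motif-count proportions
  p <- stats::chisq.test(k, p = n_motif / sum(n_motif))$p.value
  expect_gt(p, 1e-3)
})

test_that("depth factors scale expected unique-site counts linearly", {
  cfg <- sim_config(seed = 13, n_chroms = 1, chrom_length = 2e5,
                    n_genes = 10, gene_length = c(3000, 6000),
                    depth_factors = c(rep(1, 5), rep(2, 5)),
                    chrom_factors = 1, insertions_per_sample = 300)
  sim <- simulate_genome(cfg)
  totals <- rowSums(vapply(1:30, function(i) {
    scr <- simulate_screen(sim, seed = 100 + i)
    tab <- table(factor(scr$sample_id, names(cfg$depth_factors)))
    as.numeric(tab)
  }, numeric(10)))
  lo <- sum(totals[1:5]); hi <- sum(totals[6:10])
  # Poisson thinning at low per-site rates: doubling sigma ~doubles counts
  expect_equal(hi / lo, 2, tolerance = 0.1)
})

test_that("a planted selection coefficient shows as fold-enrichment of counts", {
  gene <- "gene_chr1_003"
  cfg <- calibration_config(
    seed = 19,
    selected_regions = data.frame(region_id = gene, beta = log(5)))
  sim <- simulate_genome(cfg)
  rates <- aggregate_region_rates(sim$true_rates, sim$regions, "mutagenesis")
  Lambda <- rates$Lambda[rates$region_id == gene]
  neutral_expected <- Lambda *
    sum(outer(cfg$depth_factors, cfg$chrom_factors)[,
      rates$chrom[rates$region_id == gene]])
  obs <- vapply(1:40, function(i) {
    scr <- simulate_screen(sim, seed = 300 + i)
    sum(build_count_matrix(scr, sim$regions)[, gene])
  }, numeric(1))
  expect_equal(mean(obs) / neutral_expected, 5, tolerance = 0.15)
})

test_that("written simulations round-trip through the standard formats", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 5e4, n_genes = 5,
                    gene_length = c(2000, 4000), n_peaks = 5,
                    insertions_per_sample = 100)
  sim <- simulate_genome(cfg)
  scr <- simulate_screen(sim, seed = 4)
  dir <- tempfile()
  paths <- write_simulation(sim, scr, dir)
  g <- read_genome(paths[["genome"]])
  expect_identical(as.character(g), as.character(sim$genome))
  ann <- read_annotation(paths[["annotation"]],
                         dnase = read_peaks(paths[["dnase"]]),
                         atac = read_peaks(paths[["atac"]]))
  expect_setequal(ann$gene_table$gene_id, sim$annotation$gene_table$gene_id)
  gt1 <- ann$gene_table[order(ann$gene_table$gene_id), ]
  gt2 <- sim$annotation$gene_table[order(sim$annotation$gene_table$gene_id), ]
  expect_equal(gt1$start, gt2$start)
  expect_equal(gt1$end, gt2$end)
  back <- read_insertions(paths[["insertions"]])
  expect_equal(back[, c("chrom", "pos", "sample_id")],
               scr[, c("chrom", "pos", "sample_id")])
  # peaks survive BED 0-based round trip
  pk <- read_peaks(paths[["atac"]])
  merged <- ciscall:::.split_intervals(pk$chrom, pk$start, pk$end)$chr1
  expect_equal(merged, sim$annotation$atac$chr1)
})
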