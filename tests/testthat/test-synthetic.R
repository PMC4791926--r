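test_that("generators are deterministic and write byte-identical files", {
  cfg <- synthetic_config(seed = 99, n_genes = 60,
                          chrom_lengths = c(chr1 = 10e6),
                          n_peaks_mc = 200, n_peaks_hmc = 200,
                          n_cpg = 500)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("written datasets pass read-back validation and round-trip", {
  cfg <- synthetic_config(seed = 5, n_genes = 60,
                          chrom_lengths = c(chr1 = 10e6),
                          n_peaks_mc = 150, n_peaks_hmc = 150, n_cpg = 500)
  ds <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- load_dataset(d)
  expect_equal(length(back$genome$genes), length(ds$genome$genes))
  expect_equal(granges(back$genome$cgi), granges(ds$genome$cgi),
               ignore_attr = TRUE)
  r1 <- back$marks$replicates$normal$mc[[1]]
  expect_equal(granges(r1), granges(ds$marks$replicates$normal$mc[[1]]),
               ignore_attr = TRUE)
  expect_true(all(width(r1) > 0))
  expect_equal(back$expression$normal$gene, ds$expression$normal$gene)
  expect_equal(back$gene_sets[[1]], ds$gene_sets[[1]])
})

test_that("the default genome populates every feature label", {
  ds <- shared_dataset()
  idx <- build_feature_index(ds$genome$genes, ds$genome$cgi, ds$genome$dhs)
  all_peaks <- c(ds$marks$base$normal$mc, ds$marks$base$normal$hmc)
  fd <- feature_distribution(all_peaks, idx)
  expect_true(all(fd$count > 0))
  # peak widths stay inside the configured range
  expect_true(all(width(ds$marks$base$normal$hmc) <=
                    ds$config$peak_width_range[2] + 1))
  expect_true(all(width(ds$marks$base$normal$hmc) >=
                    ds$config$peak_width_range[1] - 1))
})

test_that("cancer 5hmC loss and replicate structure follow the config", {
  ds <- shared_dataset()
  cfg <- ds$config
  expect_equal(length(ds$marks$base$cancer$hmc),
               round(length(ds$marks$base$normal$hmc) * cfg$hmc_loss))
  expect_length(ds$marks$replicates$normal$mc, 3)
  expect_length(ds$marks$replicates$normal$hmc, 1)
  # dropout keeps roughly (1 - dropout) of peaks per replicate
  kept <- length(ds$marks$replicates$normal$mc[[1]]) /
    length(ds$marks$base$normal$mc)
  expect_gt(kept, 1 - cfg$dropout - 3 * sqrt(cfg$dropout / 2000))
  expect_lt(kept, 1 - cfg$dropout + 3 * sqrt(cfg$dropout / 2000))
})

test_that("zero jitter and dropout make consensus(k=3) the base set", {
  cfg <- synthetic_config(seed = 8, n_genes = 60,
                          chrom_lengths = c(chr1 = 10e6),
                          n_peaks_mc = 150, n_peaks_hmc = 100,
                          jitter_sd_bp = 0, dropout = 0)
  g <- generate_genome(cfg)
  m <- generate_marks(cfg, g)
  cons <- consensus_peaks(m$replicates$normal$mc, 3)
  expect_equal(granges(cons), granges(merge_intervals(m$base$normal$mc)))
  expect_true(all(mcols(cons)$support == 3))
})

test_that("degenerate configurations behave: no CGIs, zero weights", {
  cfg <- synthetic_config(seed = 3, n_genes = 30,
                          chrom_lengths = c(chr1 = 6e6),
                          n_cgi = 0, n_cpg = 200, cpg_in_cgi_frac = 0.5,
                          n_peaks_mc = 80, n_peaks_hmc = 80)
  g <- generate_genome(cfg)
  expect_equal(length(g$cgi), 0)
  m <- generate_marks(cfg, g)  # cgi weight silently dropped (empty zone)
  expect_gt(length(m$base$normal$mc), 0)
  expect_error(synthetic_config(seed = 3,
                                weights_mc = c(promoter = 0, genic = 0,
                                               cgi = 0, dhs = 0,
                                               intergenic = 0)),
               "weights")
  # genome too small for the requested genes
  tiny <- synthetic_config(seed = 3, n_genes = 500,
                           chrom_lengths = c(chr1 = 2e5))
  expect_error(generate_genome(tiny), "too small")
})

test_that("expression effects shift marked genes by the configured odds", {
  cfg <- synthetic_config(seed = 13, n_genes = 120,
                          chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                          n_peaks_mc = 300, n_peaks_hmc = 300,
                          expr_noise_sd = 0,
                          effects = list(list(mark = "hmc", feature = "genic",
                                              odds = 50)))
  g <- generate_genome(cfg)
  idx <- build_feature_index(g$genes, g$cgi, g$dhs)
  m <- generate_marks(cfg, g, index = idx)
  e <- generate_expression(cfg, g, m, "normal", index = idx)
  ann <- annotate_peaks(m$base$normal$hmc, idx)
  nt <- nearest_tss(m$base$normal$hmc, g$genes)
  marked <- unique(nt$gene[ann[, "genic"] & !is.na(nt$gene)])
  expr <- rowMeans(e[, -1, drop = FALSE])
  # an odds-50 latent shift separates the group means clearly
  expect_gt(mean(expr[e$gene %in% marked]) - mean(expr[!e$gene %in% marked]),
            2)
  # replicate columns identical when noise is zero
  expect_equal(e$rep_1, e$rep_2)
})
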