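test_that("fate classes match the brute-force pairwise oracle", {
  withr::local_seed(808)
  for (rep in 1:10) {
    hmc_n <- random_gr(50); mc_n <- random_gr(50)
    hmc_c <- random_gr(50); mc_c <- random_gr(50)
    cl <- classify_dynamics(hmc_n, mc_n, hmc_c, mc_c)
    expect_equal(cl$absent$pairs[, c("a", "b", "overlap_bp")],
                 bf_pairs(hmc_n, mc_c), ignore_attr = TRUE)
    expect_equal(cl$retained$pairs[, c("a", "b", "overlap_bp")],
                 bf_pairs(hmc_n, hmc_c), ignore_attr = TRUE)
    expect_equal(cl$gained$pairs[, c("a", "b", "overlap_bp")],
                 bf_pairs(mc_n, hmc_c), ignore_attr = TRUE)
    # bookkeeping: pair total equals the sum of per-source partner counts
    expect_equal(nrow(cl$retained$pairs),
                 sum(table(cl$retained$pairs$a)))
  }
  # disjoint genomes: all classes empty
  cl0 <- classify_dynamics(gr0("chr1", 0, 10), gr0("chr2", 0, 10),
                           gr0("chr3", 0, 10), gr0("chr4", 0, 10))
  expect_equal(nrow(cl0$absent$pairs), 0)
  expect_equal(nrow(cl0$gained$pairs), 0)
})

test_that("a normal 5hmC peak can be both retained and absent", {
  hmc_n <- gr0("chr1", 100, 300)
  mc_c <- gr0("chr1", 150, 400)
  hmc_c <- gr0("chr1", 90, 200)
  cl <- classify_dynamics(hmc_n, GRanges(), hmc_c, mc_c)
  expect_equal(nrow(cl$absent$pairs), 1)
  expect_equal(nrow(cl$retained$pairs), 1)
})

test_that("dual-null chi-square arithmetic and Bonferroni flags are exact", {
  # O = E: chi2 0, p 1; O != E: textbook two-cell statistic
  g <- hmcdyn:::gof_2cell(80, 200, 0.4)
  expect_equal(unname(g["chi2"]), 0)
  expect_equal(unname(g["p"]), 1)
  g2 <- hmcdyn:::gof_2cell(120, 200, 0.4)
  expect_equal(unname(g2["chi2"]), (120 - 80)^2 / 80 + (80 - 120)^2 / 120)
  expect_equal(unname(g2["p"]),
               pchisq((120 - 80)^2 / 80 + (80 - 120)^2 / 120, 1,
                      lower.tail = FALSE))
  # Bonferroni with m = 7: raw p significant iff p < alpha / 7
  expect_true(0.004 < 0.05 / 7 + 1e-12)
  genes <- ten_gene_fixture()
  idx <- build_feature_index(genes)
  hmc_n <- gr0("chr1", c(10500, 810000, 811000, 36000),
               c(10700, 810200, 811200, 36200))
  mc_c <- gr0("chr1", c(10550, 810050, 811050, 500000),
              c(10750, 810250, 811250, 500200))
  cl <- classify_dynamics(hmc_n, GRanges(), GRanges(), mc_c)
  res <- dual_null_test(cl$absent, idx)
  n_row <- res[res$null == "normal" & res$feature == "intergenic", ]
  # 2 of 3 participating normal peaks are intergenic; marginal 2/4
  expect_equal(n_row$observed, 2)
  expect_equal(n_row$total, 3)
  expect_equal(n_row$expected, 3 * 2 / 4)
  expect_equal(n_row$direction, 1)
})

test_that("dual-null statistic agrees with a multinomial simulation null", {
  withr::local_seed(909)
  B <- 100000
  total <- 200; p_f <- 0.4; obs <- 120
  g <- hmcdyn:::gof_2cell(obs, total, p_f)
  draws <- rbinom(B, total, p_f)
  stats_sim <- (draws - total * p_f)^2 / (total * p_f) +
    ((total - draws) - total * (1 - p_f))^2 / (total * (1 - p_f))
  p_sim <- mean(stats_sim >= g[["chi2"]] - 1e-9)
  se <- sqrt(max(p_sim, 1 / B) * (1 - p_sim) / B)
  expect_lt(abs(p_sim - g[["p"]]), max(3 * se, 2e-4))
})

test_that("class comparison detects unequal feature proportions", {
  counts <- matrix(c(50, 10, 10), nrow = 1,
                   dimnames = list("intergenic", NULL))
  res <- compare_dynamic_classes(counts, c(100, 100, 100), alpha = 0.05)
  expect_lt(res$p, 1e-6)
  # identical proportions: p = 1
  eq <- compare_dynamic_classes(matrix(c(20, 20, 20), nrow = 1,
                                       dimnames = list("f", NULL)),
                                c(100, 100, 100))
  expect_equal(eq$p, 1)
  expect_error(compare_dynamic_classes(counts, c(100, 0, 100)), "zero")
  # permutation cross-check of the 2x3 chi-square
  withr::local_seed(111)
  B <- 20000
  tab_in <- c(50, 10, 10); tot <- c(100, 100, 100)
  obs <- suppressWarnings(chisq.test(rbind(tab_in, tot - tab_in),
                                     correct = FALSE)$statistic)
  perms <- stats::r2dtable(B, tot, c(sum(tab_in), sum(tot) - sum(tab_in)))
  stats_perm <- vapply(perms, function(x) {
    suppressWarnings(chisq.test(t(x), correct = FALSE)$statistic)
  }, 0)
  p_perm <- mean(stats_perm >= obs - 1e-9)
  expect_lt(abs(p_perm - res$p), 0.005)
})

test_that("co-incident spans equal the pairwise intersection oracle", {
  genes <- ten_gene_fixture()
  idx <- build_feature_index(genes)
  mc <- gr0("chr1", 0, 100)
  hmc <- gr0("chr1", 50, 150)
  co <- coincidence_regions(mc, hmc, idx)
  expect_equal(start(co$spans) - 1, 50)
  expect_equal(end(co$spans), 100)
  # abutting: no co-incidence
  expect_equal(coincidence_regions(gr0("chr1", 0, 100),
                                   gr0("chr1", 100, 200), idx)$n, 0)
  withr::local_seed(222)
  for (rep in 1:8) {
    a <- random_gr(40, chroms = "chr1", max_pos = 1e6)
    b <- random_gr(40, chroms = "chr1", max_pos = 1e6)
    co <- coincidence_regions(a, b, idx)
    pr <- bf_pairs(a, b)
    expect_equal(co$n, nrow(pr))
    expect_equal(width(co$spans), pr$overlap_bp)
  }
})

test_that("method concordance fractions follow their set arithmetic", {
  genes <- ten_gene_fixture()
  # tech1 peaks at the TSSs of FG01..FG04; tech2 redetects FG02/FG03, with
  # a same-region overlap only at FG02
  t1 <- gr0("chr1", c(9900, 37900, 51900, 94900),
            c(10100, 38100, 52100, 95100))
  t2 <- gr0("chr1", c(38000, 52500), c(38200, 52700))
  r <- method_concordance(t1, t2, genes)
  expect_equal(r$n_genes_tech1, 4)
  expect_equal(r$gene_fraction, 0.5)
  expect_equal(r$n_strict_genes, 1)
  expect_equal(r$strict_fraction, 0.25)
  expect_equal(r$strict_fraction_within, 0.5)
  # identity: both fractions 1
  rid <- method_concordance(t1, t1, genes)
  expect_equal(rid$gene_fraction, 1)
  expect_equal(rid$strict_fraction, 1)
  expect_error(method_concordance(gr0("chrZ", 0, 10), t2, genes),
               "no genes")
  # invariant: strict <= gene-level on random synthetic pairs
  withr::local_seed(333)
  ds <- shared_dataset()
  idx <- build_feature_index(ds$genome$genes, ds$genome$cgi, ds$genome$dhs)
  rc <- method_concordance(ds$marks$base$normal$hmc[1:400],
                           ds$marks$hmedip, ds$genome$genes, idx)
  expect_lte(rc$strict_fraction, rc$gene_fraction)
  expect_equal(nrow(rc$feature_comparison), 7)
})

test_that("CpG-random expectation matches per-CpG counting", {
  genes <- ten_gene_fixture()
  idx <- build_feature_index(genes)
  withr::local_seed(444)
  cpg_pos <- sort(sample(0:1100000, 3000))
  cpg <- gr0("chr1", cpg_pos, cpg_pos + 1)
  peaks <- random_gr(150, chroms = "chr1", max_pos = 1090000,
                     max_width = 300)
  res <- random_background_expectation(peaks, cpg, idx)
  ann_cpg <- annotate_peaks(cpg, idx)
  for (f in c("promoter", "intergenic", "genic")) {
    expect_equal(res$expected_proportion[res$feature == f],
                 sum(ann_cpg[, f]) / length(cpg))
  }
  # peaks placed only in promoters, CpGs everywhere: strong enrichment
  prom_peaks <- gr0("chr1", c(8000, 8400, 37600, 38000, 50000, 95000),
                    c(8200, 8600, 37800, 38200, 50200, 95200))
  res2 <- random_background_expectation(prom_peaks, cpg, idx)
  row <- res2[res2$feature == "promoter", ]
  expect_equal(row$direction, 1)
  expect_lt(row$p, 0.01)
  expect_error(random_background_expectation(peaks, GRanges(), idx),
               "empty CpG")
})
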