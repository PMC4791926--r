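test_that("tier_split orders, balances and breaks ties deterministically", {
  e9 <- data.frame(gene = sprintf("g%d", 1:9), expr = c(5, 1, 9, 3, 7, 2, 8,
                                                        4, 6))
  t9 <- tier_split(e9)
  expect_equal(attr(t9, "tier_sizes"), c(low = 3, medium = 3, high = 3))
  expect_equal(sort(t9$gene[t9$tier == "low"]), c("g2", "g4", "g6"))
  # 10 genes: remainder goes to the lower tier (4/3/3)
  e10 <- data.frame(gene = sprintf("g%02d", 1:10), expr = 1:10)
  expect_equal(unname(attr(tier_split(e10), "tier_sizes")), c(4, 3, 3))
  # all-equal values: deterministic assignment by gene name
  eq <- data.frame(gene = sprintf("g%02d", 10:1), expr = rep(1, 10))
  tq <- tier_split(eq)
  expect_equal(tq$gene, sort(eq$gene))
  expect_error(tier_split(e9[1:2, ]), "at least 3")
})

test_that("peak-to-tier assignment equals the exhaustive per-peak loop", {
  ds <- shared_dataset()
  idx <- build_feature_index(ds$genome$genes, ds$genome$cgi, ds$genome$dhs)
  peaks <- ds$marks$base$normal$hmc[1:200]
  expr <- data.frame(gene = ds$expression$normal$gene,
                     expr = rowMeans(ds$expression$normal[, -1]))
  # drop some genes to exercise the exclusion tally
  expr <- expr[-seq(1, nrow(expr), by = 11), ]
  tiers <- tier_split(expr)
  tc <- assign_peaks_to_tiers(peaks, ds$genome$genes, tiers, idx)
  ann <- annotate_peaks(peaks, idx)
  nt <- nearest_tss(peaks, ds$genome$genes)
  pk_oracle <- tc$peak_counts * 0
  gene_oracle <- lapply(hmcdyn:::FEATURES_ALL, function(f) {
    list(low = character(), medium = character(), high = character())
  })
  names(gene_oracle) <- hmcdyn:::FEATURES_ALL
  excl <- 0
  for (i in seq_along(peaks)) {
    tier <- as.character(tiers$tier[match(nt$gene[i], tiers$gene)])
    if (is.na(tier)) { excl <- excl + 1; next }
    for (f in hmcdyn:::FEATURES_ALL[ann[i, ]]) {
      pk_oracle[f, tier] <- pk_oracle[f, tier] + 1
      gene_oracle[[f]][[tier]] <- union(gene_oracle[[f]][[tier]], nt$gene[i])
    }
  }
  expect_equal(tc$peak_counts, pk_oracle)
  expect_equal(tc$n_excluded, excl)
  for (f in hmcdyn:::FEATURES_ALL) {
    for (l in c("low", "medium", "high")) {
      expect_equal(tc$marked_genes[[f]][[l]], sort(gene_oracle[[f]][[l]]))
    }
  }
  # two peaks nearest the same gene: counted once in genes, twice in peaks
  expect_true(any(tc$peak_counts > tc$gene_counts))
  # marked genes per tier never exceed the tier size
  expect_true(all(t(tc$gene_counts) <= as.numeric(tc$tier_sizes)))
})

test_that("trend test matches its closed form, base R, and symmetry", {
  # no trend: statistic 0, p 1
  r <- trend_test(c(10, 10, 10), c(100, 100, 100))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # agreement with the independent base-R implementation
  for (tab in list(list(m = c(5, 10, 15), n = c(100, 100, 100)),
                   list(m = c(30, 22, 11), n = c(60, 55, 50)),
                   list(m = c(1, 2, 30), n = c(40, 40, 40)))) {
    got <- trend_test(tab$m, tab$n)
    ref <- suppressWarnings(stats::prop.trend.test(tab$m, tab$n))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
  # reversing tier order flips the sign, keeps p
  a <- trend_test(c(5, 10, 15), c(100, 100, 100))
  b <- trend_test(c(15, 10, 5), c(100, 100, 100))
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$z, -b$z)
  expect_gt(a$z, 0)
  # degenerate: nothing marked
  expect_equal(trend_test(c(0, 0, 0), c(10, 10, 10))$p.value, 1)
})

test_that("trend test p agrees with a permutation null", {
  withr::local_seed(606)
  tables <- list(list(m = c(5, 10, 15), n = c(100, 100, 100)),
                 list(m = c(20, 28, 35), n = c(80, 80, 80)),
                 list(m = c(12, 9, 4), n = c(30, 30, 30)))
  B <- 20000
  for (tab in tables) {
    got <- trend_test(tab$m, tab$n)
    # permutation: condition on margins, redistribute marked genes; the
    # permutation distribution is a lattice, so the chi-square p is compared
    # to the permutation mid-p (half weight on ties)
    perms <- stats::r2dtable(B, tab$n, c(sum(tab$m), sum(tab$n) - sum(tab$m)))
    stats_perm <- vapply(perms, function(x) {
      trend_test(x[, 1], tab$n)$statistic
    }, 0)
    p_perm <- mean(stats_perm > got$statistic + 1e-9) +
      0.5 * mean(abs(stats_perm - got$statistic) <= 1e-9)
    se <- sqrt(max(p_perm, 1 / B) * (1 - p_perm) / B)
    expect_lt(abs(p_perm - got$p.value), max(3 * se, 0.003))
  }
})

test_that("fisher_low_vs_high matches enumeration and is row-symmetric", {
  expect_equal(fisher_low_vs_high(5, 100, 5, 100), 1)
  expect_equal(fisher_low_vs_high(1, 10, 9, 10),
               bf_fisher2(1, 9, 9, 1), tolerance = 1e-9)
  expect_equal(fisher_low_vs_high(3, 20, 11, 25),
               fisher_low_vs_high(11, 25, 3, 20))
  expect_equal(fisher_low_vs_high(0, 10, 0, 10), 1)  # zero margin
  withr::local_seed(707)
  for (rep in 1:25) {
    tl <- sample(5:25, 1); th <- sample(5:25, 1)
    ml <- sample(0:tl, 1); mh <- sample(0:th, 1)
    expect_equal(fisher_low_vs_high(ml, tl, mh, th),
                 bf_fisher2(ml, tl - ml, mh, th - mh), tolerance = 1e-9)
  }
})

test_that("pearson tier correlation hits the exact anchor cases", {
  expect_equal(pearson_tier_correlation(c(1, 2, 3))$r, 1)
  expect_equal(pearson_tier_correlation(c(3, 2, 1))$r, -1)
  expect_equal(pearson_tier_correlation(c(1, 3, 1))$r, 0)
  cst <- pearson_tier_correlation(c(4, 4, 4))
  expect_equal(cst$r, 0)
  expect_true(cst$constant)
})
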