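test_that("promoter/genic windows match hand-computed extents", {
  genes <- gene_models(c("chr1", "chr1"), c(10000, 0), c(30000, 5000),
                       c("PLUS", "MINUS"), c("+", "-"),
                       list(10000, 0), list(30000, 5000))
  idx <- build_feature_index(genes)
  prom <- idx$windows$promoter
  # + strand, TSS 10000: [7500, 10500)
  expect_equal(start(prom)[mcols(prom)$gene_name == "PLUS"] - 1, 7500)
  expect_equal(end(prom)[mcols(prom)$gene_name == "PLUS"], 10500)
  # - strand, span (0, 5000): TSS 5000, promoter [4500, 7500)
  expect_equal(start(prom)[mcols(prom)$gene_name == "MINUS"] - 1, 4500)
  expect_equal(end(prom)[mcols(prom)$gene_name == "MINUS"], 7500)
  gen <- idx$windows$genic
  # + strand genic: [TSS+500, end) = [10500, 30000)
  expect_equal(start(gen)[mcols(gen)$gene_name == "PLUS"] - 1, 10500)
  expect_equal(end(gen)[mcols(gen)$gene_name == "PLUS"], 30000)
  # - strand genic: [start, TSS-500) = [0, 4500)
  expect_equal(start(gen)[mcols(gen)$gene_name == "MINUS"] - 1, 0)
  expect_equal(end(gen)[mcols(gen)$gene_name == "MINUS"], 4500)
})

test_that("DHS windows expand by the radius and clip at zero", {
  genes <- gene_models("chr1", 0, 5000, "G", "+", list(0), list(5000))
  dhs <- gr0("chr1", c(10000, 2000), c(10200, 2100))
  # gene at 0 clips its promoter window, with the documented warning
  expect_warning(idx <- build_feature_index(genes, dhs = dhs), "clipped")
  w <- sort(idx$windows$dhs)
  expect_equal(start(w)[2] - 1, 5000)   # 10000 - 5000
  expect_equal(end(w)[2], 15200)        # 10200 + 5000
  expect_equal(start(w)[1], 1)          # clipped at the chromosome start
})

test_that("classify_peak multi-labels and the intergenic rule behave", {
  genes <- ten_gene_fixture()
  cgi <- gr0("chr1", c(11000, 37600), c(11600, 38200))
  dhs <- gr0("chr1", 52000, 52200)
  idx <- build_feature_index(genes, cgi, dhs)
  # inside the first exon of FG01 ([10000,13000)) and inside a CGI
  lab <- classify_peak(gr0("chr1", 11100, 11300), idx)
  expect_true(all(c("genic", "exonic", "cgi") %in% lab))
  expect_false("intergenic" %in% lab)
  # FG02 is minus strand with TSS 38000, promoter [37500, 40500); the CGI at
  # [37600,38200) lies inside it, so a peak in that CGI gets cgi_promoter
  lab2 <- classify_peak(gr0("chr1", 37700, 38000), idx)
  expect_true(all(c("cgi", "cgi_promoter", "promoter") %in% lab2))
  # peak straddling the exon/intron boundary of FG01 (intron [13000,14000))
  lab3 <- classify_peak(gr0("chr1", 12900, 13100), idx)
  expect_true(all(c("genic", "exonic", "intronic") %in% lab3))
  # desert between FG08 (TSS 620000) and FG09 (TSS 1009000): midpoint
  # 810100 is >100 kb from both
  lab4 <- classify_peak(gr0("chr1", 810000, 810200), idx)
  expect_equal(lab4, "intergenic")
  # 50 kb from the nearest TSS, outside promoter/genic: no label at all
  lab5 <- classify_peak(gr0("chr1", 145000, 145200), idx)
  expect_equal(length(lab5), 0)
  # unknown chromosome: intergenic only, with a warning
  expect_warning(lab6 <- classify_peak(gr0("chrZ", 0, 100), idx),
                 "without genes")
  expect_equal(lab6, "intergenic")
})

test_that("strand mirroring reflects promoter windows", {
  # same gene on opposite strands at mirrored coordinates gives mirrored
  # promoter windows around the reflection point
  L <- 100000
  gp <- gene_models("chr1", 40000, 50000, "G", "+", list(40000), list(50000))
  gm <- gene_models("chr1", L - 50000, L - 40000, "G", "-",
                    list(L - 50000), list(L - 40000))
  pp <- build_feature_index(gp)$windows$promoter
  pm <- build_feature_index(gm)$windows$promoter
  expect_equal(start(pm) - 1, L - end(pp))
  expect_equal(end(pm), L - (start(pp) - 1))
})

test_that("feature_distribution equals the per-peak classify_peak loop", {
  ds <- shared_dataset()
  idx <- build_feature_index(ds$genome$genes, ds$genome$cgi, ds$genome$dhs)
  peaks <- ds$marks$base$normal$hmc[1:150]
  fd <- feature_distribution(peaks, idx)
  counts <- setNames(numeric(length(hmcdyn:::FEATURES_ALL)),
                     hmcdyn:::FEATURES_ALL)
  for (i in seq_along(peaks)) {
    for (l in classify_peak(peaks[i], idx)) counts[l] <- counts[l] + 1
  }
  expect_equal(setNames(fd$count, fd$feature), counts)
  expect_equal(fd$proportion, fd$count / 150)
  # no peak inside a transcript body beyond TSS+500 is intergenic
  ann <- annotate_peaks(peaks, idx)
  expect_false(any(ann[, "genic"] & ann[, "intergenic"]))
  # classify is pure: a second call is identical
  expect_identical(ann, annotate_peaks(peaks, idx))
  # empty peak set gives all zeros
  fd0 <- feature_distribution(GRanges(), idx)
  expect_true(all(fd0$count == 0))
})
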