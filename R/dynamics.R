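#' Classify cross-cell-line 5hmC fate by peak overlap
#'
#' Three overlap-defined classes: `absent` = normal 5hmC peaks overlapping
#' cancer 5mC peaks; `retained` = normal 5hmC overlapping cancer 5hmC;
#' `gained` = normal 5mC overlapping cancer 5hmC. Classes are not mutually
#' exclusive; a source peak overlapping several partners counts once per
#' class (deduplicated by source peak).
#'
#' @param hmc_normal,mc_normal,hmc_cancer,mc_cancer peak sets
#'   ([GenomicRanges::GRanges]); typically consensus sets.
#' @param min_overlap_bp minimum overlap (default 1 bp, "at least partial
#'   overlap").
#' @return a `dynamics_classes` object: per class a list with `pairs` (the
#'   [intersect_sets()] data.frame), `source_normal` and `source_cancer`
#'   (full source peak sets) and `marks` (which mark each side carries).
#' @export
classify_dynamics <- function(hmc_normal, mc_normal, hmc_cancer, mc_cancer,
                              min_overlap_bp = 1) {
  mk <- function(sn, sc, mn, mc_) {
    list(pairs = intersect_sets(sn, sc, min_overlap_bp),
         source_normal = sn, source_cancer = sc,
         marks = c(normal = mn, cancer = mc_))
  }
  structure(list(absent = mk(hmc_normal, mc_cancer, "5hmC", "5mC"),
                 retained = mk(hmc_normal, hmc_cancer, "5hmC", "5hmC"),
                 gained = mk(mc_normal, hmc_cancer, "5mC", "5hmC")),
            class = "dynamics_classes")
}

# 1-df two-cell goodness-of-fit of an observed in-feature count against an
# expected proportion; returns chi2 and upper-tail p.
gof_2cell <- function(observed, total, p_expected) {
  e1 <- total * p_expected
  e2 <- total - e1
  if (total == 0) return(c(chi2 = NA_real_, p = NA_real_))
  if (e1 == 0) {
    if (observed == 0) return(c(chi2 = 0, p = 1))
    return(c(chi2 = Inf, p = .Machine$double.xmin))
  }
  if (e2 == 0) {
    if (observed == total) return(c(chi2 = 0, p = 1))
    return(c(chi2 = Inf, p = .Machine$double.xmin))
  }
  chi2 <- (observed - e1)^2 / e1 + ((total - observed) - e2)^2 / e2
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Test a fate class against dual marginal-distribution nulls
#'
#' For each genomic feature the observed count of class-participating source
#' peaks carrying that feature is compared, by a 1-df two-cell chi-square
#' goodness-of-fit, against the expectation under (i) the normal cell line's
#' marginal feature distribution of the relevant source mark and (ii) the
#' cancer cell line's. Bonferroni correction uses the number of features
#' tested per (class, null) row.
#'
#' @param cls one element of a `dynamics_classes` object (e.g. `x$absent`).
#' @param index a `feature_index`.
#' @param alpha family-wise significance level (default 0.05).
#' @param features features tested (default the seven-feature dynamics set).
#' @return a `dynamics_result` data.frame with one row per (null, feature):
#'   observed, total, expected, chi2, p, Bonferroni-corrected significance
#'   flag and direction (+1 more than expected, -1 less).
#' @export
dual_null_test <- function(cls, index, alpha = 0.05,
                           features = FEATURES_DYNAMICS) {
  m <- length(features)
  sides <- list(normal = list(source = cls$source_normal,
                              part = unique(cls$pairs$a),
                              mark = cls$marks[["normal"]]),
                cancer = list(source = cls$source_cancer,
                              part = unique(cls$pairs$b),
                              mark = cls$marks[["cancer"]]))
  rows <- list()
  for (side in names(sides)) {
    s <- sides[[side]]
    total <- length(s$part)
    ann_full <- annotate_peaks(s$source, index)
    marginal <- colSums(ann_full) / max(length(s$source), 1)
    ann_part <- ann_full[s$part, , drop = FALSE]
    for (f in features) {
      if (total == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          null = side, mark = s$mark, feature = f, observed = 0, total = 0,
          expected = NA_real_, chi2 = NA_real_, p = NA_real_,
          significant = NA, direction = NA_real_, stringsAsFactors = FALSE)
        next
      }
      obs <- sum(ann_part[, f])
      g <- gof_2cell(obs, total, marginal[[f]])
      rows[[length(rows) + 1]] <- data.frame(
        null = side, mark = s$mark, feature = f, observed = obs,
        total = total, expected = total * marginal[[f]],
        chi2 = g[["chi2"]], p = g[["p"]],
        significant = !is.na(g[["p"]]) && g[["p"]] < alpha / m,
        direction = sign(obs - total * marginal[[f]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dynamics_result", "data.frame")
  out
}

#' Dynamics table for all three fate classes
#'
#' Runs [dual_null_test()] on each class of a `dynamics_classes` object and
#' binds the results into one table shaped like a per-feature fate summary
#' (class x null x feature).
#'
#' @inheritParams dual_null_test
#' @param classes a `dynamics_classes` object from [classify_dynamics()].
#' @return a `dynamics_result` data.frame with a leading `class` column.
#' @export
dynamics_table <- function(classes, index, alpha = 0.05,
                           features = FEATURES_DYNAMICS) {
  stopifnot(inherits(classes, "dynamics_classes"))
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    res <- dual_null_test(classes[[cl]], index, alpha, features)
    cbind(class = cl, res, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dynamics_result", "data.frame")
  out
}

#' Compare the three fate classes per feature
#'
#' For each feature, a chi-square test on the 2x3 table of (in-feature,
#' not-in-feature) x (absent, retained, gained). When any expected cell falls
#' below 1 the test falls back to the exact Fiser-Freeman-Halton test and the
#' row is flagged. Bonferroni correction over features.
#'
#' @param counts matrix of in-feature counts, rows = features, columns =
#'   classes.
#' @param totals per-class totals (all > 0).
#' @param alpha family-wise significance level.
#' @return a data.frame with per-feature statistic, p, corrected flag and the
#'   method used.
#' @export
compare_dynamic_classes <- function(counts, totals, alpha = 0.05) {
  stopifnot(is.matrix(counts), length(totals) == ncol(counts))
  if (any(totals == 0)) {
    stop("class total is zero for: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  m <- nrow(counts)
  rows <- lapply(seq_len(m), function(i) {
    tab <- rbind(in_feature = counts[i, ],
                 out_feature = totals - counts[i, ])
    if (any(rowSums(tab) == 0)) {
      return(data.frame(feature = rownames(counts)[i], statistic = 0,
                        p = 1, significant = FALSE, method = "degenerate",
                        stringsAsFactors = FALSE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      p <- stats::fisher.test(tab)$p.value
      stat <- NA_real_
      method <- "fisher"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      p <- ct$p.value
      stat <- unname(ct$statistic)
      method <- "chisq"
    }
    data.frame(feature = rownames(counts)[i], statistic = stat, p = p,
               significant = p < alpha / m, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' In-feature counts of fate-class overlap regions
#'
#' Annotates the overlap spans of each class and returns the in-feature count
#' matrix and class totals consumed by [compare_dynamic_classes()].
#'
#' @param classes a `dynamics_classes` object.
#' @param index a `feature_index`.
#' @param features feature set (default seven-feature dynamics set).
#' @return a list with `counts` (features x classes) and `totals`.
#' @export
dynamics_feature_counts <- function(classes, index,
                                    features = FEATURES_DYNAMICS) {
  counts <- sapply(names(classes), function(cl) {
    spans <- overlap_spans(classes[[cl]]$pairs)
    ann <- annotate_peaks(spans, index)
    colSums(ann[, features, drop = FALSE])
  })
  totals <- vapply(classes, function(cl) nrow(cl$pairs), 0)
  list(counts = as.matrix(counts), totals = totals)
}

# GRanges of the overlap spans recorded in an intersect_sets() data.frame.
overlap_spans <- function(pairs) {
  if (nrow(pairs) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(pairs$chrom,
                               IRanges::IRanges(pairs$start0 + 1, pairs$end0))
  S4Vectors::mcols(gr)$a <- pairs$a
  S4Vectors::mcols(gr)$b <- pairs$b
  gr
}

#' Same-cell-line 5mC/5hmC co-incident regions
#'
#' Regions where a 5mC peak and a 5hmC peak of the same cell line overlap by
#' at least `min_overlap_bp`; the overlap span is recorded and its feature
#' distribution computed.
#'
#' @param mc_set,hmc_set peak sets from the same cell line.
#' @param index a `feature_index`.
#' @param min_overlap_bp minimum overlap (default 1).
#' @return a `coincidence_set` list: `spans` (GRanges with source indices),
#'   `distribution` (feature distribution of the spans) and `n`.
#' @export
coincidence_regions <- function(mc_set, hmc_set, index, min_overlap_bp = 1) {
  pairs <- intersect_sets(mc_set, hmc_set, min_overlap_bp)
  spans <- overlap_spans(pairs)
  structure(list(spans = spans,
                 distribution = feature_distribution(spans, index),
                 n = length(spans)),
            class = "coincidence_set")
}

#' Concordance between two 5hmC enrichment techniques
#'
#' Gene-level fraction: of the genes hydroxymethylated by technique 1 (by
#' nearest-TSS assignment of its peaks), the fraction also detected by
#' technique 2. Strict concordance: genes among those concordant whose
#' technique-1 peaks additionally overlap a technique-2 peak by >= 1 bp in
#' the same region. The strict count is reported both as a fraction of all
#' technique-1 genes (`strict_fraction`, always <= `gene_fraction`) and as a
#' fraction of the concordant genes (`strict_fraction_within`). Per-feature
#' distributions are compared by a 2x2 chi-square per feature.
#'
#' @param peaks_tech1,peaks_tech2 peak sets of the two techniques.
#' @param genes a `gene_models` object.
#' @param index optional `feature_index` for the per-feature comparison.
#' @return a `concordance_result` list with `gene_fraction`,
#'   `strict_fraction`, `strict_fraction_within`, gene counts and
#'   (optionally) `feature_comparison`.
#' @export
method_concordance <- function(peaks_tech1, peaks_tech2, genes,
                               index = NULL) {
  g1 <- nearest_tss(peaks_tech1, genes)$gene
  g2 <- nearest_tss(peaks_tech2, genes)$gene
  u1 <- unique(g1[!is.na(g1)])
  if (length(u1) == 0) stop("technique-1 peaks map to no genes")
  shared <- intersect(u1, unique(g2[!is.na(g2)]))
  gene_fraction <- length(shared) / length(u1)
  ov <- quiet_overlaps_any(peaks_tech1, peaks_tech2)
  strict_genes <- intersect(shared, unique(g1[ov & !is.na(g1)]))
  feature_comparison <- NULL
  if (!is.null(index)) {
    a1 <- annotate_peaks(peaks_tech1, index)
    a2 <- annotate_peaks(peaks_tech2, index)
    feature_comparison <- do.call(rbind, lapply(FEATURES_DYNAMICS,
                                                function(f) {
      tab <- rbind(c(sum(a1[, f]), nrow(a1) - sum(a1[, f])),
                   c(sum(a2[, f]), nrow(a2) - sum(a2[, f])))
      p <- if (any(colSums(tab) == 0)) 1 else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(feature = f, prop_tech1 = mean(a1[, f]),
                 prop_tech2 = mean(a2[, f]), p = p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(gene_fraction = gene_fraction,
                 strict_fraction = length(strict_genes) / length(u1),
                 strict_fraction_within = if (length(shared) > 0)
                   length(strict_genes) / length(shared) else NA_real_,
                 n_genes_tech1 = length(u1), n_shared_genes = length(shared),
                 n_strict_genes = length(strict_genes),
                 feature_comparison = feature_comparison),
            class = "concordance_result")
}

#' Observed versus CpG-random expected feature proportions
#'
#' The expected proportion of peaks in each feature under random placement
#' across CpG positions is the fraction of CpGs falling in that feature; the
#' observed peak proportions are tested feature-wise with the 1-df two-cell
#' goodness-of-fit.
#'
#' @param peaks a peak set.
#' @param cpg a width-1 [GenomicRanges::GRanges] of CpG positions.
#' @param index a `feature_index`.
#' @param alpha family-wise level for the Bonferroni flag.
#' @param features feature set tested.
#' @return a data.frame per feature: observed/expected proportions, chi2, p,
#'   corrected flag, direction.
#' @export
random_background_expectation <- function(peaks, cpg, index, alpha = 0.05,
                                          features = FEATURES_DYNAMICS) {
  if (length(cpg) == 0) stop("empty CpG track")
  ann_cpg <- annotate_peaks(cpg, index)
  ann_pk <- annotate_peaks(peaks, index)
  total <- length(peaks)
  m <- length(features)
  out <- do.call(rbind, lapply(features, function(f) {
    p_exp <- mean(ann_cpg[, f])
    obs <- sum(ann_pk[, f])
    g <- gof_2cell(obs, total, p_exp)
    data.frame(feature = f, observed = obs, total = total,
               expected_proportion = p_exp,
               observed_proportion = if (total > 0) obs / total else NA_real_,
               chi2 = g[["chi2"]], p = g[["p"]],
               significant = !is.na(g[["p"]]) && g[["p"]] < alpha / m,
               direction = sign(obs - total * p_exp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
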