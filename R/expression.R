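#' Split genes into ordered expression tiers
#'
#' Genes are sorted ascending by expression (ties broken by gene name, so the
#' split is deterministic) and cut into `n_tiers` contiguous blocks of equal
#' size; when the gene count is not divisible the remainder goes to the lower
#' tiers, so e.g. 10 genes give tier sizes 4/3/3.
#'
#' @param expr a data.frame with columns `gene` and `expr` (e.g. from
#'   [read_expression()]), or a named numeric vector.
#' @param n_tiers number of tiers (default 3: low/medium/high).
#' @return a `tier_table` data.frame with columns `gene`, `expr`, `tier`
#'   (ordered factor) and a `tier_sizes` attribute.
#' @export
tier_split <- function(expr, n_tiers = 3) {
  if (is.numeric(expr) && !is.null(names(expr))) {
    expr <- data.frame(gene = names(expr), expr = as.numeric(expr),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "expr") %in% names(expr)))
  expr <- expr[is.finite(expr$expr), , drop = FALSE]
  n <- nrow(expr)
  if (n < n_tiers) stop("need at least ", n_tiers, " genes, got ", n)
  o <- order(expr$expr, expr$gene)
  expr <- expr[o, , drop = FALSE]
  base <- n %/% n_tiers
  rem <- n %% n_tiers
  sizes <- rep(base, n_tiers) + c(rep(1L, rem), rep(0L, n_tiers - rem))
  labels <- if (n_tiers == 3) c("low", "medium", "high") else
    paste0("tier", seq_len(n_tiers))
  tier <- factor(rep(labels, times = sizes), levels = labels, ordered = TRUE)
  out <- data.frame(gene = expr$gene, expr = expr$expr, tier = tier,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tier_sizes") <- stats::setNames(sizes, labels)
  class(out) <- c("tier_table", "data.frame")
  out
}

#' Assign peaks to expression tiers via nearest gene
#'
#' Each peak is mapped to its nearest-TSS gene and counted, under every
#' feature label it carries, in that gene's expression tier. Peaks whose
#' nearest gene has no expression data are excluded and tallied. Distinct
#' marked genes per (feature, tier) are recorded alongside raw peak counts.
#'
#' @param peaks a [GenomicRanges::GRanges] (typically differential regions of
#'   one mark).
#' @param genes a `gene_models` object.
#' @param tiers a `tier_table` from [tier_split()].
#' @param index a `feature_index`.
#' @return a `tier_counts` object: list with `peak_counts` and `gene_counts`
#'   (feature x tier matrices), `marked_genes` (nested list of gene-name
#'   vectors), `tier_sizes`, and `n_excluded`.
#' @export
assign_peaks_to_tiers <- function(peaks, genes, tiers, index) {
  stopifnot(inherits(tiers, "tier_table"))
  labels <- levels(tiers$tier)
  ann <- annotate_peaks(peaks, index)
  nt <- nearest_tss(peaks, genes)
  tier_of <- tiers$tier[match(nt$gene, tiers$gene)]
  included <- !is.na(tier_of)
  n_excluded <- sum(!included)
  peak_counts <- matrix(0, nrow = length(FEATURES_ALL), ncol = length(labels),
                        dimnames = list(FEATURES_ALL, labels))
  gene_counts <- peak_counts
  marked <- lapply(FEATURES_ALL, function(f) {
    stats::setNames(vector("list", length(labels)), labels)
  })
  names(marked) <- FEATURES_ALL
  for (f in FEATURES_ALL) {
    sel <- ann[, f] & included
    if (!any(sel)) {
      for (l in labels) marked[[f]][[l]] <- character()
      next
    }
    tt <- table(tier_of[sel])
    peak_counts[f, names(tt)] <- as.numeric(tt)
    for (l in labels) {
      g <- unique(nt$gene[sel][tier_of[sel] == l])
      marked[[f]][[l]] <- sort(g)
      gene_counts[f, l] <- length(g)
    }
  }
  structure(list(peak_counts = peak_counts, gene_counts = gene_counts,
                 marked_genes = marked,
                 tier_sizes = attr(tiers, "tier_sizes"),
                 n_excluded = n_excluded),
            class = "tier_counts")
}

#' Cochran-Armitage chi-square test for trend
#'
#' Tests for a linear trend in the proportion of marked genes across ordered
#' tiers, with equally spaced scores (0, 1, 2, ...) and no continuity
#' correction; 1 degree of freedom, upper-tail p. The signed statistic `z`
#' is positive when the marked proportion increases with tier.
#'
#' @param marked marked counts per tier.
#' @param totals tier sizes (totals >= marked >= 0).
#' @param scores tier scores (default equally spaced from 0).
#' @return a list with `statistic` (chi-square), `p.value`, `z` (signed
#'   normal deviate) and `slope_sign`.
#' @export
trend_test <- function(marked, totals, scores = seq_along(marked) - 1) {
  stopifnot(length(marked) == length(totals),
            all(marked >= 0), all(totals >= marked))
  N <- sum(totals)
  M <- sum(marked)
  if (M == 0 || M == N || N == 0) {
    return(list(statistic = 0, p.value = 1, z = 0, slope_sign = 0))
  }
  pbar <- M / N
  sbar <- sum(totals * scores) / N
  num <- sum(marked * scores) - pbar * sum(totals * scores)
  den <- pbar * (1 - pbar) * (sum(totals * scores^2) -
                                sum(totals * scores)^2 / N)
  if (den <= 0) return(list(statistic = 0, p.value = 1, z = 0,
                            slope_sign = 0))
  z <- num / sqrt(den)
  stat <- z^2
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       z = z, slope_sign = sign(num))
}

#' Fisher exact test: lowest versus highest tier
#'
#' Two-tailed exact p for the 2x2 table of marked/unmarked genes in the low
#' and high tiers, by summation of hypergeometric probabilities no larger
#' than the observed table's. Zero-margin tables give p = 1.
#'
#' @param marked_low,total_low,marked_high,total_high 2x2 table entries.
#' @return the two-tailed p-value.
#' @export
fisher_low_vs_high <- function(marked_low, total_low, marked_high,
                               total_high) {
  stopifnot(marked_low >= 0, marked_high >= 0, total_low >= marked_low,
            total_high >= marked_high)
  tab <- matrix(c(marked_low, total_low - marked_low,
                  marked_high, total_high - marked_high),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Pearson correlation between tier index and counts
#'
#' @param counts per-tier counts (length >= 3).
#' @param scores tier scores (default equally spaced from 0).
#' @return a list with `r` (0, flagged, for constant counts) and `constant`.
#' @export
pearson_tier_correlation <- function(counts, scores = seq_along(counts) - 1) {
  if (stats::sd(counts) == 0) return(list(r = 0, constant = TRUE))
  list(r = stats::cor(scores, counts), constant = FALSE)
}

#' Per-feature association statistics between marks and expression tiers
#'
#' For every genomic feature computes the trend test on marked-gene
#' proportions, the Pearson correlation of peak counts against tier index,
#' and the two-tailed Fisher exact test comparing the lowest and highest
#' tiers. Direction is `positive`/`negative` by the sign of the trend when
#' significant at `alpha`, `nonlinear` otherwise.
#'
#' @param tc a `tier_counts` object from [assign_peaks_to_tiers()].
#' @param alpha significance level for the direction call (default 0.05).
#' @return a data.frame, one row per feature.
#' @export
association_stats <- function(tc, alpha = 0.05) {
  stopifnot(inherits(tc, "tier_counts"))
  labels <- colnames(tc$gene_counts)
  lo <- labels[1]; hi <- labels[length(labels)]
  rows <- lapply(FEATURES_ALL, function(f) {
    marked <- tc$gene_counts[f, ]
    totals <- as.numeric(tc$tier_sizes)
    tr <- trend_test(marked, totals)
    pr <- pearson_tier_correlation(tc$peak_counts[f, ])
    fp <- fisher_low_vs_high(marked[lo], totals[1], marked[hi],
                             totals[length(totals)])
    direction <- if (tr$p.value < alpha) {
      if (tr$z > 0) "positive" else "negative"
    } else "nonlinear"
    data.frame(feature = f,
               n_low = marked[lo], n_medium = marked["medium"],
               n_high = marked[hi],
               peaks_low = tc$peak_counts[f, lo],
               peaks_medium = tc$peak_counts[f, "medium"],
               peaks_high = tc$peak_counts[f, hi],
               chi2_trend = tr$statistic, p_trend = tr$p.value,
               trend_z = tr$z, pearson_r = pr$r, fisher_p = fp,
               direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
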