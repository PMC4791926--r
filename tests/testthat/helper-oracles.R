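# Brute-force oracles and fixture builders shared across the suite. The
# oracles deliberately avoid the package's interval machinery: plain loops
# and per-base arithmetic only.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

gr0 <- function(chrom, start0, end0, score = NULL) {
  g <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (!is.null(score)) mcols(g)$score <- score
  g
}

random_gr <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000,
                      max_width = 120) {
  s0 <- floor(runif(n, 0, max_pos))
  w <- 1 + floor(runif(n, 0, max_width))
  hmcdyn:::sort_peaks(gr0(sample(chroms, n, replace = TRUE), s0, s0 + w))
}

# O(n^2) all-pairs overlap oracle on 0-based half-open intervals;
# plain-vector loops, no interval machinery
bf_pairs <- function(a, b, min_overlap = 1) {
  ac <- as.character(seqnames(a)); as0 <- start(a) - 1; ae0 <- end(a)
  bc <- as.character(seqnames(b)); bs0 <- start(b) - 1; be0 <- end(b)
  out <- list()
  for (i in seq_along(as0)) {
    for (j in seq_along(bs0)) {
      if (ac[i] != bc[j]) next
      ov <- min(ae0[i], be0[j]) - max(as0[i], bs0[j])
      if (ov >= min_overlap) out[[length(out) + 1]] <- c(i, j, ov)
    }
  }
  if (length(out) == 0) {
    return(data.frame(a = integer(), b = integer(), overlap_bp = numeric()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(a = m[, 1], b = m[, 2], overlap_bp = m[, 3])
  df[order(df$a, df$b), ]
}

# per-base occupancy oracle: total covered bp across chromosomes
bf_covered_bp <- function(gr) {
  chrom <- as.character(seqnames(gr)); s <- start(gr); e <- end(gr)
  total <- 0
  for (chr in unique(chrom)) {
    i <- chrom == chr
    occ <- logical(max(e[i]))
    for (k in which(i)) occ[s[k]:e[k]] <- TRUE
    total <- total + sum(occ)
  }
  total
}

# exhaustive nearest-TSS scan with the package's tie rules
bf_nearest <- function(peaks, genes) {
  tss <- gene_tss(genes)
  chrom <- as.character(seqnames(peaks))
  mid <- floor((start(peaks) - 1 + end(peaks)) / 2)
  res <- data.frame(gene = rep(NA_character_, length(peaks)),
                    abs_distance = rep(NA_real_, length(peaks)))
  for (i in seq_along(mid)) {
    cand <- which(tss$chrom == chrom[i])
    if (length(cand) == 0) next
    d <- abs(mid[i] - tss$pos0[cand])
    best <- cand[d == min(d)]
    best <- best[order(tss$gene[best])][1]
    res$gene[i] <- tss$gene[best]
    res$abs_distance[i] <- min(d)
  }
  res
}

# exact two-tailed Fisher p by hypergeometric enumeration over all tables
# with the observed margins
bf_fisher2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact upper-tail hypergeometric by enumeration
bf_hyper_upper <- function(k, K, N, n) {
  if (k == 0) return(1)
  xs <- k:min(K, n)
  sum(vapply(xs, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, 0))
}

# ten-gene fixture with hand-computed windows, including minus-strand genes;
# expected values below were derived by hand from the window definitions
ten_gene_fixture <- function() {
  tab <- data.frame(
    chrom = rep("chr1", 10),
    start0 = c(10000, 30000, 52000, 80000, 240000,
               400000, 430000, 620000, 1001000, 1030000),
    end0 = c(18000, 38000, 60000, 95000, 252000,
             410000, 442000, 640000, 1009000, 1042000),
    strand = c("+", "-", "+", "-", "+", "-", "+", "+", "-", "+"),
    name = sprintf("FG%02d", 1:10))
  ex_s <- lapply(seq_len(10), function(i) {
    s <- tab$start0[i]; e <- tab$end0[i]; mid <- floor((s + e) / 2)
    c(s, mid)
  })
  ex_e <- lapply(seq_len(10), function(i) {
    s <- tab$start0[i]; e <- tab$end0[i]; mid <- floor((s + e) / 2)
    c(mid - 1000, e)
  })
  gene_models(tab$chrom, tab$start0, tab$end0, tab$name, tab$strand,
              ex_s, ex_e)
}

# default-condition dataset shared by slower tests (built once per run)
shared_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- simulate_dataset(synthetic_config(seed = 20260927))
    ds
  }
})
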