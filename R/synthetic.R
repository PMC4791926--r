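#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the assay design being analysed: two cell-line
#' conditions ("normal", "cancer"), three MBD-seq (5mC) replicates and one
#' hMeSeal-seq (5hmC) replicate per condition, peak widths of 100-300 bp
#' (sheared-fragment scale), global cancer 5hmC loss with an intergenic
#' placement excess plus a coincident-with-normal-5mC fraction (planting the
#' "gained in intergenic regions" signal), and expression coupled to mark
#' presence through proportional tier-odds effects on a logistic latent
#' scale. Genes are laid out in clusters separated by >200-kb deserts so
#' every genomic feature, including the >100-kb intergenic stratum, is
#' populated.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_genes total gene count.
#' @param gene_length_range,exon_count_range per-gene ranges.
#' @param cluster_size genes per cluster.
#' @param desert_bp,desert_jitter_bp inter-cluster desert length and its
#'   uniform jitter.
#' @param n_cgi,cgi_width_range,cgi_tss_frac CpG-island count, width range
#'   and fraction placed at a TSS.
#' @param n_dhs,dhs_width_range,dhs_tss_frac DNase-site count, width range
#'   and fraction placed near a TSS.
#' @param n_cpg,cpg_in_cgi_frac CpG positions and fraction inside CGIs.
#' @param peak_width_range peak width range (bp).
#' @param n_peaks_mc,n_peaks_hmc peaks per base set.
#' @param mc_cancer_factor scaling of the cancer 5mC peak count.
#' @param hmc_loss scaling of the cancer 5hmC peak count (global loss).
#' @param weights_mc,weights_hmc feature-placement weights (normal cells).
#' @param mc_cancer_cgi_boost multiplier on the CGI weight for cancer 5mC
#'   (CpG-island hypermethylation).
#' @param hmc_cancer_intergenic_boost multiplier on the intergenic weight for
#'   cancer 5hmC.
#' @param gained_coincident_frac fraction of cancer 5hmC peaks placed on top
#'   of intergenic normal 5mC peaks (drives the gained/intergenic excess).
#' @param n_replicates named vector: replicates per mark.
#' @param jitter_sd_bp,dropout replicate positional jitter SD and per-peak
#'   dropout probability.
#' @param hmedip_frac,hmedip_jitter_sd_bp,hmedip_width_range,hmedip_novel_frac
#'   second-technique (antibody-based) emulation of the normal 5hmC set:
#'   fraction of base peaks redetected, their positional jitter, fragment
#'   width range, and fraction of novel (technique-specific) peaks.
#' @param expr_mean,expr_scale location and scale of the logistic expression
#'   latent (log2 units).
#' @param expr_noise_sd,n_expr_replicates replicate noise SD and replicate
#'   count of the expression table.
#' @param effects list of `list(mark, feature, odds)` proportional tier-odds
#'   effects; odds > 1 raises the expression tier of marked genes. The
#'   default plants positive genic/DHS 5hmC effects and a negative
#'   intergenic 5hmC effect, plus conventional 5mC effects (negative in
#'   CGIs, positive in gene bodies).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1,
    chrom_lengths = stats::setNames(rep(10e6, 6), paste0("chr", 1:6)),
    n_genes = 900,
    gene_length_range = c(5e3, 2e4),
    exon_count_range = c(2, 8),
    cluster_size = 6,
    desert_bp = 2.5e5,
    desert_jitter_bp = 5e4,
    n_cgi = 200, cgi_width_range = c(500, 2000), cgi_tss_frac = 0.6,
    n_dhs = 200, dhs_width_range = c(150, 500), dhs_tss_frac = 0.5,
    n_cpg = 20000, cpg_in_cgi_frac = 0.5,
    peak_width_range = c(100, 300),
    n_peaks_mc = 2000, n_peaks_hmc = 2000,
    mc_cancer_factor = 1.25,
    hmc_loss = 0.5,
    weights_mc = c(promoter = 0.15, genic = 0.35, cgi = 0.15, dhs = 0.10,
                   intergenic = 0.25),
    weights_hmc = c(promoter = 0.15, genic = 0.35, cgi = 0.10, dhs = 0.10,
                    intergenic = 0.30),
    mc_cancer_cgi_boost = 2,
    hmc_cancer_intergenic_boost = 2,
    gained_coincident_frac = 0.06,
    n_replicates = c(mc = 3, hmc = 1),
    jitter_sd_bp = 30, dropout = 0.1,
    hmedip_frac = 0.7, hmedip_jitter_sd_bp = 150,
    hmedip_width_range = c(200, 600), hmedip_novel_frac = 0.3,
    expr_mean = 6, expr_scale = 1,
    expr_noise_sd = 0.25, n_expr_replicates = 3,
    effects = list(list(mark = "hmc", feature = "genic", odds = 2),
                   list(mark = "hmc", feature = "dhs", odds = 2),
                   list(mark = "hmc", feature = "intergenic", odds = 0.5),
                   list(mark = "mc", feature = "cgi", odds = 0.5),
                   list(mark = "mc", feature = "genic", odds = 2))) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$chrom_lengths > 0), cfg$n_genes > 0,
            all(cfg$weights_mc >= 0), all(cfg$weights_hmc >= 0),
            sum(cfg$weights_mc) > 0, sum(cfg$weights_hmc) > 0,
            cfg$hmc_loss > 0, cfg$dropout >= 0, cfg$dropout < 1,
            diff(cfg$peak_width_range) >= 0)
  structure(cfg, class = "synthetic_config")
}

#' Generate a toy genome: gene models, CGI, DHS and CpG tracks
#'
#' Genes are placed left to right in clusters separated by deserts so that a
#' populated intergenic stratum (> 100 kb from every TSS) exists; CGIs are
#' preferentially placed at TSSs and CpG positions are denser inside CGIs.
#' Deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed seed (default derived from `config$seed`).
#' @return a `synthetic_genome` list: `genes` (gene models), `cgi`, `dhs`,
#'   `cpg` (width-1 positions), `chrom_lengths`.
#' @export
generate_genome <- function(config, seed = config$seed + 1) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    chroms <- names(config$chrom_lengths)
    per_chrom <- table(factor(
      rep(chroms, length.out = config$n_genes), levels = chroms))
    g_chrom <- character(0); g_start <- numeric(0); g_end <- numeric(0)
    g_strand <- character(0)
    for (chr in chroms) {
      L <- config$chrom_lengths[[chr]]
      pos <- 5e4
      placed <- 0
      target <- per_chrom[[chr]]
      while (placed < target) {
        for (j in seq_len(min(config$cluster_size, target - placed))) {
          len <- round(runif(1, config$gene_length_range[1],
                             config$gene_length_range[2]))
          if (pos + len > L - 5e4) {
            stop("genome too small to place requested genes on ", chr)
          }
          g_chrom <- c(g_chrom, chr)
          g_start <- c(g_start, pos)
          g_end <- c(g_end, pos + len)
          g_strand <- c(g_strand, sample(c("+", "-"), 1))
          placed <- placed + 1
          pos <- pos + len + round(runif(1, 2e3, 8e3))
        }
        pos <- pos + config$desert_bp + round(runif(1, 0,
                                                    config$desert_jitter_bp))
      }
    }
    n <- length(g_start)
    name <- sprintf("G%04d", seq_len(n))
    ex_start <- vector("list", n); ex_end <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]),
                  1)
      w <- runif(2 * k - 1, 0.5, 1.5)
      seg <- round(cumsum(w / sum(w)) * (g_end[i] - g_start[i]))
      bounds <- g_start[i] + c(0, seg)
      bounds[length(bounds)] <- g_end[i]
      es <- bounds[seq(1, 2 * k - 1, by = 2)]
      ee <- bounds[seq(2, 2 * k, by = 2)]
      ok <- ee > es
      ex_start[[i]] <- es[ok]; ex_end[[i]] <- ee[ok]
    }
    genes <- gene_models(g_chrom, g_start, g_end, name, g_strand,
                         ex_start, ex_end)
    tss <- gene_tss(genes)

    rand_pos <- function(k) {
      chr <- sample(chroms, k, replace = TRUE,
                    prob = config$chrom_lengths / sum(config$chrom_lengths))
      data.frame(chrom = chr,
                 pos = floor(runif(k) * config$chrom_lengths[chr]))
    }
    make_track <- function(k, width_range, tss_frac, tss_radius = 0) {
      if (k == 0) return(GenomicRanges::GRanges())
      at_tss <- runif(k) < tss_frac
      n_tss <- sum(at_tss)
      centers <- rand_pos(k)
      if (n_tss > 0) {
        pick <- sample(nrow(tss), n_tss, replace = TRUE)
        centers$chrom[at_tss] <- tss$chrom[pick]
        centers$pos[at_tss] <- tss$pos0[pick] +
          round(runif(n_tss, -tss_radius, tss_radius))
      }
      w <- round(runif(k, width_range[1], width_range[2]))
      s0 <- pmax(centers$pos - floor(w / 2), 0)
      L <- config$chrom_lengths[centers$chrom]
      s0 <- pmin(s0, L - 1)
      sort_peaks(GenomicRanges::GRanges(centers$chrom,
                                        IRanges::IRanges(s0 + 1,
                                                         pmin(s0 + w, L))))
    }
    cgi <- make_track(config$n_cgi, config$cgi_width_range,
                      config$cgi_tss_frac)
    dhs <- make_track(config$n_dhs, config$dhs_width_range,
                      config$dhs_tss_frac, tss_radius = 3000)

    n_in <- round(config$n_cpg * config$cpg_in_cgi_frac)
    if (length(cgi) == 0) n_in <- 0
    cpg_bg <- rand_pos(config$n_cpg - n_in)
    cpg_chrom <- cpg_bg$chrom; cpg_pos <- cpg_bg$pos
    if (n_in > 0) {
      ci <- sample(length(cgi), n_in, replace = TRUE,
                   prob = BiocGenerics::width(cgi))
      off <- floor(runif(n_in) * BiocGenerics::width(cgi)[ci])
      cpg_chrom <- c(cpg_chrom,
                     as.character(GenomicRanges::seqnames(cgi))[ci])
      cpg_pos <- c(cpg_pos, BiocGenerics::start(cgi)[ci] - 1 + off)
    }
    cpg <- sort_peaks(GenomicRanges::GRanges(cpg_chrom,
                                             IRanges::IRanges(cpg_pos + 1,
                                                              cpg_pos + 1)))
    structure(list(genes = genes, cgi = cgi, dhs = dhs, cpg = cpg,
                   chrom_lengths = config$chrom_lengths),
              class = "synthetic_genome")
  })
}

# Regions whose every position is > intergenic_bp + margin from all TSSs;
# peaks whose midpoint falls here are guaranteed the intergenic label.
intergenic_zones <- function(genome, intergenic_bp = 100000, margin = 1000) {
  tss <- gene_tss(genome$genes)
  pad <- intergenic_bp + margin
  blocked <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pmax(tss$pos0 - pad, 0) + 1, tss$pos0 + pad))
  chrom_gr <- GenomicRanges::GRanges(
    names(genome$chrom_lengths),
    IRanges::IRanges(1, genome$chrom_lengths))
  GenomicRanges::setdiff(chrom_gr, GenomicRanges::reduce(blocked),
                        ignore.strand = TRUE)
}

# Draw n peaks with feature-biased placement: a feature is drawn per peak
# from `weights`, a window of that feature is drawn proportional to width,
# and the peak midpoint is uniform within the window.
draw_peaks <- function(n, weights, zones, width_range, chrom_lengths) {
  if (sum(weights) <= 0) stop("bias weights all zero")
  weights <- weights[names(weights) %in% names(zones)]
  avail <- vapply(zones[names(weights)], length, 0L) > 0
  weights <- weights[avail]
  if (length(weights) == 0 || sum(weights) == 0) {
    stop("bias weights all zero after dropping empty placement zones")
  }
  feat <- sample(names(weights), n, replace = TRUE,
                 prob = weights / sum(weights))
  chrom <- character(n); mid <- numeric(n)
  for (f in unique(feat)) {
    idx <- which(feat == f)
    z <- zones[[f]]
    zi <- sample(length(z), length(idx), replace = TRUE,
                 prob = BiocGenerics::width(z))
    chrom[idx] <- as.character(GenomicRanges::seqnames(z))[zi]
    mid[idx] <- BiocGenerics::start(z)[zi] - 1 +
      floor(runif(length(idx)) * BiocGenerics::width(z)[zi])
  }
  w <- round(runif(n, width_range[1], width_range[2]))
  mid <- pmin(mid, chrom_lengths[chrom] - 1)
  s0 <- pmax(pmin(mid - floor(w / 2), chrom_lengths[chrom] - 1), 0)
  e0 <- pmin(s0 + w, chrom_lengths[chrom])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
  S4Vectors::mcols(gr)$score <- round(runif(n, 20, 300), 1)
  sort_peaks(gr)
}

# One replicate realisation of a base peak set: per-peak dropout then
# positional jitter.
realize_replicate <- function(base, jitter_sd, dropout, chrom_lengths) {
  keep <- runif(length(base)) >= dropout
  r <- base[keep]
  if (length(r) == 0) return(r)
  shift <- round(rnorm(length(r), 0, jitter_sd))
  chrom <- as.character(GenomicRanges::seqnames(r))
  s0 <- pmax(BiocGenerics::start(r) - 1 + shift, 0)
  e0 <- pmin(BiocGenerics::end(r) + shift, chrom_lengths[chrom])
  ok <- e0 > s0
  out <- GenomicRanges::GRanges(chrom[ok], IRanges::IRanges(s0[ok] + 1,
                                                            e0[ok]))
  S4Vectors::mcols(out)$score <- S4Vectors::mcols(r)$score[ok]
  sort_peaks(out)
}

#' Generate per-(mark, condition, replicate) peak sets
#'
#' Base sets are drawn feature-biased; the cancer 5hmC set is globally
#' scaled down by `hmc_loss`, its intergenic placement weight boosted, and a
#' `gained_coincident_frac` fraction of its peaks placed directly over
#' intergenic normal 5mC peaks (the planted gained/intergenic excess). The
#' cancer 5mC set has its CGI weight boosted. Replicates are dropout+jitter
#' realisations of the base sets; an hMeDIP-like second technique of the
#' normal 5hmC set is also emitted.
#'
#' @param config a [synthetic_config()].
#' @param genome a `synthetic_genome`.
#' @param seed seed (default derived from `config$seed`).
#' @param index optional prebuilt `feature_index` for `genome` (rebuilt when
#'   omitted).
#' @return a `synthetic_marks` list with `base`, `replicates` and `hmedip`.
#' @export
generate_marks <- function(config, genome, seed = config$seed + 2,
                           index = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(index)) {
    index <- build_feature_index(genome$genes, genome$cgi, genome$dhs)
  }
  zones <- list(promoter = index$windows$promoter,
                genic = index$windows$genic,
                cgi = genome$cgi, dhs = genome$dhs,
                intergenic = intergenic_zones(genome))
  cl <- genome$chrom_lengths
  withr::with_seed(seed, {
    w_mc_c <- config$weights_mc
    w_mc_c["cgi"] <- w_mc_c["cgi"] * config$mc_cancer_cgi_boost
    w_hmc_c <- config$weights_hmc
    w_hmc_c["intergenic"] <- w_hmc_c["intergenic"] *
      config$hmc_cancer_intergenic_boost

    mc_n <- draw_peaks(config$n_peaks_mc, config$weights_mc, zones,
                       config$peak_width_range, cl)
    mc_c <- draw_peaks(round(config$n_peaks_mc * config$mc_cancer_factor),
                       w_mc_c, zones, config$peak_width_range, cl)
    hmc_n <- draw_peaks(config$n_peaks_hmc, config$weights_hmc, zones,
                        config$peak_width_range, cl)

    n_hmc_c <- round(config$n_peaks_hmc * config$hmc_loss)
    n_coin <- round(n_hmc_c * config$gained_coincident_frac)
    ann_mc_n <- annotate_peaks(mc_n, index)
    ig_idx <- which(ann_mc_n[, "intergenic"])
    n_coin <- min(n_coin, length(ig_idx))
    hmc_c <- draw_peaks(n_hmc_c - n_coin, w_hmc_c, zones,
                        config$peak_width_range, cl)
    if (n_coin > 0) {
      host <- mc_n[sample(ig_idx, n_coin, replace = TRUE)]
      hmid <- floor((BiocGenerics::start(host) - 1 +
                       BiocGenerics::end(host)) / 2) +
        round(runif(n_coin, -50, 50))
      w <- round(runif(n_coin, config$peak_width_range[1],
                       config$peak_width_range[2]))
      hostL <- cl[as.character(GenomicRanges::seqnames(host))]
      s0 <- pmax(pmin(hmid - floor(w / 2), hostL - 1), 0)
      coin <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(host),
        IRanges::IRanges(s0 + 1, pmin(
          s0 + w, cl[as.character(GenomicRanges::seqnames(host))])))
      S4Vectors::mcols(coin)$score <- round(runif(n_coin, 20, 300), 1)
      hmc_c <- sort_peaks(c(hmc_c, coin))
    }

    base <- list(normal = list(mc = mc_n, hmc = hmc_n),
                 cancer = list(mc = mc_c, hmc = hmc_c))
    replicates <- lapply(base, function(cond) {
      list(mc = lapply(seq_len(config$n_replicates[["mc"]]), function(i) {
        realize_replicate(cond$mc, config$jitter_sd_bp, config$dropout, cl)
      }),
      hmc = lapply(seq_len(config$n_replicates[["hmc"]]), function(i) {
        realize_replicate(cond$hmc, config$jitter_sd_bp, config$dropout, cl)
      }))
    })

    n1 <- length(hmc_n)
    redetect <- hmc_n[runif(n1) < config$hmedip_frac]
    rmid <- floor((BiocGenerics::start(redetect) - 1 +
                     BiocGenerics::end(redetect)) / 2) +
      round(rnorm(length(redetect), 0, config$hmedip_jitter_sd_bp))
    rw <- round(runif(length(redetect), config$hmedip_width_range[1],
                      config$hmedip_width_range[2]))
    rchrom <- as.character(GenomicRanges::seqnames(redetect))
    # clamp jittered midpoints into the chromosome
    rs0 <- pmax(pmin(rmid - floor(rw / 2), cl[rchrom] - 1), 0)
    hmedip <- GenomicRanges::GRanges(
      rchrom, IRanges::IRanges(rs0 + 1, pmin(rs0 + rw, cl[rchrom])))
    S4Vectors::mcols(hmedip)$score <- round(runif(length(hmedip), 20, 300), 1)
    novel <- draw_peaks(round(n1 * config$hmedip_novel_frac),
                        config$weights_hmc, zones,
                        config$hmedip_width_range, cl)
    hmedip <- sort_peaks(c(hmedip, novel))

    structure(list(base = base, replicates = replicates, hmedip = hmedip),
              class = "synthetic_marks")
  })
}

#' Generate per-condition expression tables coupled to mark presence
#'
#' Baseline log2 expression is a logistic latent; for each configured effect,
#' genes that are the nearest-TSS target of at least one base peak of the
#' effect's mark carrying the effect's feature label receive a latent shift
#' of `scale * log(odds)`, which is exactly a proportional odds multiplier of
#' `odds` per expression-tier threshold. Replicate columns add Gaussian
#' noise.
#'
#' @param config a [synthetic_config()].
#' @param genome a `synthetic_genome`.
#' @param marks a `synthetic_marks`.
#' @param condition `"normal"` or `"cancer"`.
#' @param seed seed (default derived from `config$seed`).
#' @param index optional prebuilt `feature_index` for `genome`.
#' @return a data.frame with a `gene` column and one column per replicate.
#' @export
generate_expression <- function(config, genome, marks,
                                condition = c("normal", "cancer"),
                                seed = config$seed + 3, index = NULL) {
  condition <- match.arg(condition)
  if (is.null(index)) {
    index <- build_feature_index(genome$genes, genome$cgi, genome$dhs)
  }
  gene_names <- S4Vectors::mcols(genome$genes)$gene_name
  shift <- stats::setNames(numeric(length(gene_names)), gene_names)
  marks_used <- unique(vapply(config$effects, `[[`, "", "mark"))
  ann_cache <- lapply(stats::setNames(marks_used, marks_used), function(mk) {
    peaks <- marks$base[[condition]][[mk]]
    list(ann = annotate_peaks(peaks, index),
         gene = nearest_tss(peaks, genome$genes)$gene)
  })
  for (e in config$effects) {
    ac <- ann_cache[[e$mark]]
    hit <- unique(ac$gene[ac$ann[, e$feature] & !is.na(ac$gene)])
    shift[hit] <- shift[hit] + config$expr_scale * log(e$odds)
  }
  withr::with_seed(seed, {
    latent <- stats::rlogis(length(gene_names), location = config$expr_mean,
                            scale = config$expr_scale) + shift
    reps <- vapply(seq_len(config$n_expr_replicates), function(i) {
      latent + stats::rnorm(length(latent), 0, config$expr_noise_sd)
    }, numeric(length(latent)))
    out <- data.frame(gene = gene_names, round(reps, 4),
                      stringsAsFactors = FALSE)
    names(out)[-1] <- paste0("rep_", seq_len(config$n_expr_replicates))
    out
  })
}

#' Generate a synthetic gene-set collection
#'
#' Random gene sets over the gene universe; a few "planted" sets are sampled
#' preferentially from desert-flanking genes (the genes assignable to
#' intergenic peaks), so region enrichment has true signal to find.
#'
#' @param config a [synthetic_config()].
#' @param genome a `synthetic_genome`.
#' @param n_sets number of sets (default 25, of which 5 planted).
#' @param seed seed (default derived from `config$seed`).
#' @return a named list of gene-name vectors (GMT-shaped; see [read_gmt()]).
#' @export
generate_gene_sets <- function(config, genome, n_sets = 25,
                               seed = config$seed + 5) {
  gene_names <- S4Vectors::mcols(genome$genes)$gene_name
  zones <- intergenic_zones(genome)
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(zones),
    IRanges::IRanges(floor((BiocGenerics::start(zones) +
                              BiocGenerics::end(zones)) / 2), width = 1))
  flanking <- unique(nearest_tss(mids, genome$genes)$gene)
  wts <- ifelse(gene_names %in% flanking, 5, 1)
  withr::with_seed(seed, {
    n_planted <- min(5, n_sets)
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- sample(10:40, 1)
      p <- if (i <= n_planted) wts else rep(1, length(gene_names))
      sort(sample(gene_names, size, prob = p))
    })
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    attr(sets, "description") <- stats::setNames(
      c(rep("synthetic planted (desert-flanking biased)", n_planted),
        rep("synthetic random", n_sets - n_planted)), names(sets))
    sets
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators with sub-seeds derived from `config$seed`, so the
#' whole dataset is reproducible from one integer.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list: `config`, `genome`, `marks`,
#'   `expression` (per condition), `gene_sets`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  genome <- generate_genome(config)
  index <- build_feature_index(genome$genes, genome$cgi, genome$dhs)
  marks <- generate_marks(config, genome, index = index)
  expression <- list(
    normal = generate_expression(config, genome, marks, "normal",
                                 seed = config$seed + 3, index = index),
    cancer = generate_expression(config, genome, marks, "cancer",
                                 seed = config$seed + 4, index = index))
  gene_sets <- generate_gene_sets(config, genome)
  structure(list(config = config, genome = genome, marks = marks,
                 expression = expression, gene_sets = gene_sets),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to standard formats
#'
#' Emits the gene models (exon-structure TSV), CGI/DHS/CpG BED tracks, one
#' BED per (mark, condition, replicate) plus the second-technique set, one
#' expression TSV per condition and a GMT file. Output is deterministic.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$genome$genes
  exl <- S4Vectors::mcols(g)$exons
  gene_tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = BiocGenerics::start(g) - 1L,
    end = BiocGenerics::end(g),
    name = S4Vectors::mcols(g)$gene_name,
    strand = as.character(BiocGenerics::strand(g)),
    exon_starts = vapply(seq_along(g), function(i) {
      paste(BiocGenerics::start(exl[[i]]) - 1L, collapse = ",")
    }, ""),
    exon_ends = vapply(seq_along(g), function(i) {
      paste(BiocGenerics::end(exl[[i]]), collapse = ",")
    }, ""))
  utils::write.table(gene_tab, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(dataset$genome$cgi, file.path(dir, "cgi.bed"))
  write_bed(dataset$genome$dhs, file.path(dir, "dhs.bed"))
  write_bed(dataset$genome$cpg, file.path(dir, "cpg.bed"))
  for (cond in names(dataset$marks$replicates)) {
    for (mark in names(dataset$marks$replicates[[cond]])) {
      reps <- dataset$marks$replicates[[cond]][[mark]]
      for (i in seq_along(reps)) {
        write_bed(reps[[i]],
                  file.path(dir, sprintf("%s_%s_rep%d.bed", mark, cond, i)))
      }
    }
  }
  write_bed(dataset$marks$hmedip, file.path(dir, "hmedip_normal.bed"))
  for (cond in names(dataset$expression)) {
    utils::write.table(dataset$expression[[cond]],
                file.path(dir, sprintf("expression_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
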