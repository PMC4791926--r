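#' Feature-window parameters
#'
#' Defaults encode the annotation windows used throughout: promoters span
#' 2.5 kb upstream to 500 bp downstream of the TSS, genic regions run from
#' 500 bp downstream of the TSS to the transcript end, intergenic peaks lie
#' more than 100 kb from the nearest TSS (midpoint distance), and
#' DHS-proximal means within 5 kb of a DNase hypersensitive site.
#'
#' @param upstream_bp promoter extent upstream of the TSS (bp).
#' @param downstream_bp promoter extent downstream of the TSS (bp); also the
#'   offset at which the genic window begins.
#' @param intergenic_bp minimum midpoint-to-TSS distance for the intergenic
#'   label (bp).
#' @param dhs_radius_bp expansion of DHS intervals on each side (bp).
#' @return a named list of class `feature_params`.
#' @export
feature_params <- function(upstream_bp = 2500, downstream_bp = 500,
                           intergenic_bp = 100000, dhs_radius_bp = 5000) {
  stopifnot(upstream_bp > 0, downstream_bp > 0, intergenic_bp > 0,
            dhs_radius_bp > 0)
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 intergenic_bp = intergenic_bp, dhs_radius_bp = dhs_radius_bp),
            class = "feature_params")
}

#' Build a genomic-feature index
#'
#' Precomputes strand-aware promoter windows, genic windows (TSS + 500 bp
#' downstream through the transcript end), exon and intron intervals, CpG
#' islands, CpG islands overlapping a promoter window, and DHS-proximal
#' windows. Windows falling below coordinate 0 are clipped with a warning.
#'
#' @param genes a `gene_models` object.
#' @param cgi,dhs optional [GenomicRanges::GRanges] tracks (may be `NULL` or
#'   empty).
#' @param params a [feature_params()] list.
#' @return a `feature_index` object.
#' @export
build_feature_index <- function(genes, cgi = NULL, dhs = NULL,
                                params = feature_params()) {
  stopifnot(inherits(params, "feature_params"))
  if (is.null(cgi)) cgi <- GenomicRanges::GRanges()
  if (is.null(dhs)) dhs <- GenomicRanges::GRanges()
  tss <- gene_tss(genes)
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  up <- params$upstream_bp; down <- params$downstream_bp

  # promoter: [tss - up, tss + down) on + strand, mirrored on - strand
  prom_s0 <- ifelse(plus, tss$pos0 - up, tss$pos0 - down)
  prom_e0 <- ifelse(plus, tss$pos0 + down, tss$pos0 + up)
  if (any(prom_s0 < 0)) {
    warning("promoter window(s) clipped at coordinate 0")
    prom_s0 <- pmax(prom_s0, 0)
  }
  promoter <- GenomicRanges::GRanges(tss$chrom,
                                     IRanges::IRanges(prom_s0 + 1, prom_e0))
  S4Vectors::mcols(promoter)$gene_name <- tss$gene

  # genic: from tss + down (gene orientation) to the transcript end
  gs0 <- BiocGenerics::start(genes) - 1
  ge0 <- BiocGenerics::end(genes)
  gen_s0 <- ifelse(plus, tss$pos0 + down, gs0)
  gen_e0 <- ifelse(plus, ge0, tss$pos0 - down)
  ok <- gen_e0 > gen_s0
  genic <- GenomicRanges::GRanges(tss$chrom[ok],
                                  IRanges::IRanges(gen_s0[ok] + 1, gen_e0[ok]))
  S4Vectors::mcols(genic)$gene_name <- tss$gene[ok]

  exl <- S4Vectors::mcols(genes)$exons
  ex_flat <- unlist(exl, use.names = FALSE)
  BiocGenerics::strand(ex_flat) <- "*"
  exonic <- ex_flat
  spans <- GenomicRanges::granges(genes)
  BiocGenerics::strand(spans) <- "*"
  intronic <- unlist(GenomicRanges::psetdiff(
    spans, S4Vectors::split(ex_flat, factor(rep(seq_along(exl),
                                               lengths(exl)),
                                            seq_along(exl)))),
    use.names = FALSE)

  dhs_prox <- if (length(dhs)) {
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(dhs),
      IRanges::IRanges(pmax(BiocGenerics::start(dhs) - params$dhs_radius_bp, 1),
                       BiocGenerics::end(dhs) + params$dhs_radius_bp))
  } else GenomicRanges::GRanges()

  cgi_prom <- if (length(cgi)) {
    cgi[IRanges::overlapsAny(cgi, promoter, ignore.strand = TRUE)]
  } else GenomicRanges::GRanges()

  structure(list(windows = list(promoter = promoter, genic = genic,
                                exonic = exonic, intronic = intronic,
                                cgi = cgi, cgi_promoter = cgi_prom,
                                dhs = dhs_prox),
                 tss = tss, genes = genes, params = params),
            class = "feature_index")
}

#' Annotate peaks with genomic-feature labels
#'
#' A window label is assigned when the peak overlaps the window by >= 1 bp;
#' `intergenic` is assigned when the peak midpoint lies more than
#' `intergenic_bp` from the nearest TSS. Labels are not exclusive: one peak
#' may carry several. Peaks on chromosomes absent from the index are labelled
#' intergenic only, with a warning.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param index a `feature_index`.
#' @return a logical matrix, one row per peak, one column per feature in
#'   `FEATURES_ALL` order.
#' @export
annotate_peaks <- function(peaks, index) {
  stopifnot(inherits(index, "feature_index"))
  m <- matrix(FALSE, nrow = length(peaks), ncol = length(FEATURES_ALL),
              dimnames = list(NULL, FEATURES_ALL))
  if (length(peaks) == 0) return(m)
  for (f in names(index$windows)) {
    w <- index$windows[[f]]
    if (length(w)) {
      m[, f] <- quiet_overlaps_any(peaks, w)
    }
  }
  # peak must itself overlap the CGI for the promoter-CGI label
  m[, "cgi_promoter"] <- m[, "cgi_promoter"] & m[, "cgi"]
  nt <- nearest_tss(peaks, index$genes)
  orphan <- is.na(nt$abs_distance)
  if (any(orphan)) {
    warning(sum(orphan), " peak(s) on chromosomes without genes: ",
            "labelled intergenic only")
  }
  m[, "intergenic"] <- orphan |
    (!is.na(nt$abs_distance) & nt$abs_distance > index$params$intergenic_bp)
  m[orphan, setdiff(FEATURES_ALL, "intergenic")] <- FALSE
  m
}

#' Feature labels of a single peak
#'
#' @param peak a length-1 [GenomicRanges::GRanges].
#' @param index a `feature_index`.
#' @return a character vector of labels (possibly empty: peaks between the
#'   promoter/genic windows and the intergenic distance threshold carry no
#'   label).
#' @export
classify_peak <- function(peak, index) {
  stopifnot(length(peak) == 1)
  m <- annotate_peaks(peak, index)
  FEATURES_ALL[m[1, ]]
}

#' Per-feature peak counts and proportions
#'
#' Proportions use the total peak count as denominator; because one peak may
#' carry several labels the proportions need not sum to 1.
#'
#' @param peaks a [GenomicRanges::GRanges] (empty gives all-zero counts).
#' @param index a `feature_index`.
#' @return a data.frame with columns `feature`, `count`, `proportion`, plus
#'   an `n_peaks` attribute.
#' @export
feature_distribution <- function(peaks, index) {
  m <- annotate_peaks(peaks, index)
  counts <- colSums(m)
  n <- length(peaks)
  out <- data.frame(feature = FEATURES_ALL, count = as.numeric(counts),
                    proportion = if (n > 0) as.numeric(counts) / n else 0,
                    stringsAsFactors = FALSE)
  attr(out, "n_peaks") <- n
  out
}
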