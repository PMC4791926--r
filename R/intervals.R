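#' Overlapping pairs between two peak sets
#'
#' Finds every pair `(a, b)` with overlap length at least `min_overlap_bp`
#' ("at least partial overlap" is the default, 1 bp). Intervals sharing only a
#' boundary under the half-open BED convention do not overlap.
#'
#' @param a,b [GenomicRanges::GRanges] peak sets.
#' @param min_overlap_bp minimum overlap length in bp (default 1).
#' @return a data.frame with columns `a`, `b` (indices into the inputs),
#'   `chrom`, `start0`, `end0` (the 0-based half-open overlap span) and
#'   `overlap_bp`.
#' @export
intersect_sets <- function(a, b, min_overlap_bp = 1) {
  if (length(a) == 0 || length(b) == 0) {
    return(data.frame(a = integer(), b = integer(), chrom = character(),
                      start0 = numeric(), end0 = numeric(),
                      overlap_bp = numeric()))
  }
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap_bp,
                                ignore.strand = TRUE),
    warning = function(w) {
      # sets need not share chromosomes; that is not a data problem
      if (grepl("sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  o <- order(q, s)
  q <- q[o]; s <- s[o]
  ov_start <- pmax(BiocGenerics::start(a)[q], BiocGenerics::start(b)[s])
  ov_end <- pmin(BiocGenerics::end(a)[q], BiocGenerics::end(b)[s])
  data.frame(a = q, b = s,
             chrom = as.character(GenomicRanges::seqnames(a))[q],
             start0 = ov_start - 1, end0 = ov_end,
             overlap_bp = ov_end - ov_start + 1)
}

# overlapsAny without the harmless "no sequence levels in common" warning:
# query and subject legitimately need not share chromosomes.
quiet_overlaps_any <- function(x, y) {
  withCallingHandlers(
    IRanges::overlapsAny(x, y, ignore.strand = TRUE),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Merge overlapping or book-ended intervals
#'
#' Strand is ignored; metadata columns are dropped. Total covered bp is
#' preserved and the operation is idempotent.
#'
#' @param x a [GenomicRanges::GRanges].
#' @return a merged, sorted [GenomicRanges::GRanges].
#' @export
merge_intervals <- function(x) {
  sort_peaks(GenomicRanges::reduce(x, ignore.strand = TRUE))
}

#' Transcription start sites of gene models
#'
#' The TSS is the transcript start for `+` strand genes and the transcript
#' end for `-` strand genes, reported as a 0-based coordinate.
#'
#' @param genes a `gene_models` object (see [gene_models()]).
#' @return a data.frame with columns `chrom`, `pos0`, `gene`.
#' @export
gene_tss <- function(genes) {
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  pos0 <- ifelse(plus, BiocGenerics::start(genes) - 1,
                 BiocGenerics::end(genes))
  data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
             pos0 = pos0, gene = S4Vectors::mcols(genes)$gene_name,
             stringsAsFactors = FALSE)
}

#' Nearest TSS for each peak
#'
#' Distance is measured from the peak midpoint, `floor((start0 + end0) / 2)`
#' in 0-based coordinates, to the TSS. Ties are broken by the
#' lexicographically smallest gene name. Peaks on chromosomes without genes
#' get `NA`.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param genes a `gene_models` object.
#' @return a data.frame with columns `gene`, `distance` (signed, positive when
#'   the midpoint is downstream of the TSS in gene orientation) and
#'   `abs_distance`.
#' @export
nearest_tss <- function(peaks, genes) {
  n <- length(peaks)
  out <- data.frame(gene = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    abs_distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0 || length(genes) == 0) return(out)
  tss <- gene_tss(genes)
  gstrand <- as.character(BiocGenerics::strand(genes))
  mid0 <- floor((BiocGenerics::start(peaks) - 1 + BiocGenerics::end(peaks)) / 2)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  for (chr in unique(pchrom)) {
    gi <- which(tss$chrom == chr)
    if (length(gi) == 0) next
    # collapse genes sharing a TSS position to the lexicographically smallest
    # name (all tie in distance); keep gene index for strand lookup
    o <- gi[order(tss$pos0[gi], tss$gene[gi])]
    first <- !duplicated(tss$pos0[o])
    upos <- tss$pos0[o][first]
    uidx <- o[first]
    pi <- which(pchrom == chr)
    m <- mid0[pi]
    left <- findInterval(m, upos)
    right <- pmin(left + 1L, length(upos))
    leftc <- pmax(left, 1L)
    dl <- abs(m - upos[leftc])
    dr <- abs(m - upos[right])
    dl[left == 0] <- Inf
    use_left <- dl < dr |
      (dl == dr & tss$gene[uidx][leftc] <= tss$gene[uidx][right])
    pick <- ifelse(use_left, uidx[leftc], uidx[right])
    d <- pmin(dl, dr)
    sign_raw <- m - tss$pos0[pick]
    signed <- ifelse(gstrand[pick] == "-", -sign_raw, sign_raw)
    out$gene[pi] <- tss$gene[pick]
    out$distance[pi] <- signed
    out$abs_distance[pi] <- d
  }
  out
}
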