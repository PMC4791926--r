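#' Replicate consensus peak set
#'
#' Candidate regions are the merged union of all replicate peaks; a region is
#' retained when at least `k` distinct replicates contribute >= 1 overlapping
#' peak. With a single replicate and `k = 1` the consensus degenerates to the
#' replicate itself (merged).
#'
#' @param replicate_sets a list of [GenomicRanges::GRanges], one per
#'   replicate.
#' @param k minimum replicate support, `1 <= k <= length(replicate_sets)`.
#' @return a [GenomicRanges::GRanges] of disjoint regions with metadata
#'   columns `support` (replicate count) and, when every replicate carries a
#'   `score` column, `mean_score` (mean score of contributing peaks).
#' @export
consensus_peaks <- function(replicate_sets, k) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1)
  if (k < 1 || k > length(replicate_sets)) {
    stop("k must be between 1 and the number of replicates (",
         length(replicate_sets), "), got ", k)
  }
  all_peaks <- suppressWarnings(do.call(c, lapply(replicate_sets,
                                                  GenomicRanges::granges)))
  cand <- merge_intervals(all_peaks)
  if (length(cand) == 0) {
    S4Vectors::mcols(cand)$support <- integer()
    return(cand)
  }
  sup <- Reduce(`+`, lapply(replicate_sets, function(r) {
    as.integer(quiet_overlaps_any(cand, r))
  }))
  S4Vectors::mcols(cand)$support <- sup
  has_scores <- all(vapply(replicate_sets, function(r) {
    "score" %in% names(S4Vectors::mcols(r))
  }, TRUE))
  if (has_scores) {
    tot <- numeric(length(cand))
    cnt <- numeric(length(cand))
    for (r in replicate_sets) {
      h <- GenomicRanges::findOverlaps(cand, r, ignore.strand = TRUE)
      q <- S4Vectors::queryHits(h)
      sc <- S4Vectors::mcols(r)$score[S4Vectors::subjectHits(h)]
      tot <- tot + as.numeric(tapply(sc, factor(q, seq_along(cand)), sum,
                                     default = 0))
      cnt <- cnt + as.numeric(tapply(rep(1, length(q)),
                                     factor(q, seq_along(cand)), sum,
                                     default = 0))
    }
    S4Vectors::mcols(cand)$mean_score <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  cand[sup >= k]
}

#' Differential regions between two consensus sets
#'
#' The differential rule is presence/absence: a region is unique to A when it
#' overlaps no region of B (and vice versa). When both sets carry a
#' `mean_score` column and `score_ratio` is given, shared regions whose score
#' ratio against the best-overlapping partner exceeds `score_ratio` are also
#' included on the stronger side, flagged in the `by_score` metadata column.
#'
#' @param consensus_a,consensus_b [GenomicRanges::GRanges] consensus sets of
#'   the same mark.
#' @param score_ratio optional ratio threshold (e.g. `1` to approximate a
#'   fold-change > 1 rule); `NULL` (default) disables the score route.
#' @return a list of class `differential_regions` with elements `a_unique`,
#'   `b_unique` (GRanges with a `by_score` flag) and `counts`.
#' @export
differential_regions <- function(consensus_a, consensus_b,
                                 score_ratio = NULL) {
  pick_unique <- function(x, other) {
    u <- x[!quiet_overlaps_any(x, other)]
    S4Vectors::mcols(u)$by_score <- rep(FALSE, length(u))
    u
  }
  a_unique <- pick_unique(consensus_a, consensus_b)
  b_unique <- pick_unique(consensus_b, consensus_a)
  if (!is.null(score_ratio)) {
    sa <- S4Vectors::mcols(consensus_a)$mean_score
    sb <- S4Vectors::mcols(consensus_b)$mean_score
    if (!is.null(sa) && !is.null(sb)) {
      add_score_route <- function(x, other, sx, sother) {
        h <- GenomicRanges::findOverlaps(x, other, ignore.strand = TRUE)
        if (length(h) == 0) return(x[0])
        q <- S4Vectors::queryHits(h)
        best <- tapply(sother[S4Vectors::subjectHits(h)],
                       factor(q, seq_along(x)), max)
        idx <- which(!is.na(best) & sx / best > score_ratio)
        extra <- x[idx]
        S4Vectors::mcols(extra)$by_score <- rep(TRUE, length(extra))
        extra
      }
      a_unique <- sort_peaks(c(a_unique,
                               add_score_route(consensus_a, consensus_b,
                                               sa, sb)))
      b_unique <- sort_peaks(c(b_unique,
                               add_score_route(consensus_b, consensus_a,
                                               sb, sa)))
    }
  }
  structure(list(a_unique = a_unique, b_unique = b_unique,
                 counts = c(a_unique = length(a_unique),
                            b_unique = length(b_unique)),
                 score_ratio = score_ratio),
            class = "differential_regions")
}
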