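#' Region-based hypergeometric gene-set enrichment
#'
#' Regions are mapped to genes by nearest TSS; each gene set is then tested
#' by an upper-tail hypergeometric: drawing `k` set members among the `n`
#' foreground genes from a background of `N` genes containing `K` members.
#' The foreground must be a subset of the background after gene mapping; if
#' not, the background is united with the foreground with a warning. Sets
#' with zero background members are skipped (flagged `NA`). FDR is
#' Benjamini-Hochberg across tested sets.
#'
#' @param foreground,background [GenomicRanges::GRanges] region sets, or
#'   character vectors of gene names (then used as-is).
#' @param gene_sets a named list of character vectors (see [read_gmt()]).
#' @param genes a `gene_models` object (required when regions are GRanges).
#' @return a data.frame with one row per set: `set`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`, and a list-column `enriched_genes`.
#' @export
region_enrichment <- function(foreground, background, gene_sets,
                              genes = NULL) {
  to_genes <- function(x) {
    if (is.character(x)) return(unique(x))
    stopifnot(!is.null(genes))
    g <- nearest_tss(x, genes)$gene
    sort(unique(g[!is.na(g)]))
  }
  fg <- to_genes(foreground)
  if (length(fg) == 0) stop("empty foreground after gene mapping")
  bg <- to_genes(background)
  if (!all(fg %in% bg)) {
    warning("foreground not contained in background after gene mapping; ",
            "uniting them")
    bg <- sort(union(bg, fg))
  }
  N <- length(bg)
  n <- length(fg)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], bg)
    K <- length(members)
    if (K == 0) {
      return(data.frame(set = nm, k = NA_integer_, n = n, K = 0L, N = N,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    hit <- intersect(members, fg)
    k <- length(hit)
    # upper tail: P(X >= k)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
                      stringsAsFactors = FALSE)
    attr(out, "enriched") <- sort(hit)
    out
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  tested <- !is.na(res$p)
  res$fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$enriched_genes <- lapply(rows, function(r) {
    e <- attr(r, "enriched")
    if (is.null(e)) character() else e
  })
  rownames(res) <- NULL
  res
}

#' Enrichment-map similarity edges
#'
#' Nodes are the sets passing the `p` and `fdr` thresholds; an edge connects
#' two nodes whose enriched-gene sets have a Jaccard coefficient meeting the
#' similarity criterion. The conventional enrichment-map rule (edge when
#' `J >= jaccard_cutoff`) is the default; `direction = "below"` draws edges
#' when `J < jaccard_cutoff` instead.
#'
#' @param results a data.frame from [region_enrichment()].
#' @param p_max,fdr_max node thresholds (defaults 0.05 and 0.1).
#' @param jaccard_cutoff similarity cutoff (default 0.25).
#' @param direction `"above"` (conventional, default) or `"below"`.
#' @return a data.frame with columns `set1`, `set2`, `jaccard`, plus a
#'   `nodes` attribute listing the sets passing the thresholds.
#' @export
similarity_edges <- function(results, p_max = 0.05, fdr_max = 0.1,
                             jaccard_cutoff = 0.25,
                             direction = c("above", "below")) {
  direction <- match.arg(direction)
  ok <- !is.na(results$p) & results$p < p_max & results$fdr < fdr_max
  nodes <- results$set[ok]
  gene_lists <- results$enriched_genes[ok]
  edges <- data.frame(set1 = character(), set2 = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    cmb <- utils::combn(length(nodes), 2)
    jac <- apply(cmb, 2, function(ij) {
      a <- gene_lists[[ij[1]]]; b <- gene_lists[[ij[2]]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    })
    keep <- if (direction == "above") jac >= jaccard_cutoff else
      jac < jaccard_cutoff
    edges <- data.frame(set1 = nodes[cmb[1, keep]],
                        set2 = nodes[cmb[2, keep]],
                        jaccard = jac[keep], stringsAsFactors = FALSE)
  }
  attr(edges, "nodes") <- nodes
  edges
}
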