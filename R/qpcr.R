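#' A qPCR assay for one target
#'
#' Holds cycle-threshold (Ct) values for the bound (enriched) reaction, the
#' matching input-dilution reaction, and optionally a negative-control
#' capture reaction (e.g. glucosylation without UDP-azide-glucose),
#' replicate-matched.
#'
#' @param gene target name.
#' @param ct_bound,ct_input numeric Ct vectors, one value per replicate.
#' @param input_fraction fraction of input genomic DNA carried by the input
#'   dilution (default 0.00027, i.e. 0.027%).
#' @param ct_negctrl optional Ct vector of the negative-control reaction.
#' @return a `qpcr_assay` object.
#' @export
qpcr_assay <- function(gene, ct_bound, ct_input, input_fraction = 0.00027,
                       ct_negctrl = NULL) {
  stopifnot(length(ct_bound) >= 1, length(ct_bound) == length(ct_input),
            all(ct_bound > 0), all(ct_input > 0),
            input_fraction > 0, input_fraction <= 1)
  if (!is.null(ct_negctrl)) stopifnot(length(ct_negctrl) == length(ct_bound))
  structure(list(gene = gene, ct_bound = ct_bound, ct_input = ct_input,
                 input_fraction = input_fraction, ct_negctrl = ct_negctrl),
            class = "qpcr_assay")
}

# per-replicate input-normalised delta-Ct: Ct(bound) minus the input Ct
# adjusted to 100% of material, so assays run at different input dilutions
# stay comparable.
delta_ct <- function(assay, use_negctrl = FALSE) {
  ct <- if (use_negctrl) assay$ct_negctrl else assay$ct_bound
  if (is.null(ct)) stop("assay for ", assay$gene, " has no such reaction")
  ct - (assay$ct_input - log2(1 / assay$input_fraction))
}

#' Fold enrichment by the delta-delta-Ct method
#'
#' `fold = 2^(-mean(ddCt))` where `ddCt = dCt(target) - dCt(reference)` per
#' replicate and `dCt` is the bound-minus-input Ct difference corrected for
#' the input dilution fraction. The standard deviation is computed over the
#' per-replicate fold values. `fold(target, target)` is exactly 1 and adding
#' a constant to every Ct leaves the fold unchanged.
#'
#' @param target,reference `qpcr_assay` objects with matched replicate
#'   structure.
#' @param use_negctrl compute the fold of the negative-control reaction
#'   instead of the bound reaction (reference side always uses bound).
#' @return a list with `fold`, `sd`, `ddct` (mean), and `folds`
#'   (per replicate).
#' @export
ddct_fold <- function(target, reference, use_negctrl = FALSE) {
  stopifnot(inherits(target, "qpcr_assay"), inherits(reference, "qpcr_assay"),
            length(target$ct_bound) == length(reference$ct_bound))
  ddct <- delta_ct(target, use_negctrl) - delta_ct(reference)
  folds <- 2^(-ddct)
  list(fold = 2^(-mean(ddct)),
       sd = if (length(folds) > 1) stats::sd(folds) else 0,
       ddct = mean(ddct), folds = folds)
}

#' Read a qPCR Ct table
#'
#' TSV with header and columns `gene`, `role` (one of `bound`, `negctrl`,
#' `input`), `input_fraction`, `replicate`, `ct`.
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "role", "input_fraction", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop("qPCR TSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$role), c("bound", "negctrl", "input"))
  if (length(bad)) stop("unknown qPCR role(s): ", paste(bad, collapse = ", "))
  tab
}

#' Fold-enrichment table for all targets in a Ct table
#'
#' Builds one [qpcr_assay()] per gene from a [read_qpcr()] table and reports
#' the delta-delta-Ct fold of the bound reaction and (when present) of the
#' negative-control reaction, each against the reference gene.
#'
#' @param tab a data.frame from [read_qpcr()].
#' @param reference_gene name of the negative-control reference locus.
#' @return a data.frame: `gene`, `fold`, `sd`, `negctrl_fold`.
#' @export
qpcr_table <- function(tab, reference_gene) {
  assay_of <- function(g) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    sub <- sub[order(sub$role, sub$replicate), , drop = FALSE]
    bound <- sub[sub$role == "bound", , drop = FALSE]
    input <- sub[sub$role == "input", , drop = FALSE]
    neg <- sub[sub$role == "negctrl", , drop = FALSE]
    if (nrow(input) == 0) stop("gene ", g, ": missing input Ct")
    qpcr_assay(g, bound$ct[order(bound$replicate)],
               input$ct[order(input$replicate)],
               input_fraction = input$input_fraction[1],
               ct_negctrl = if (nrow(neg)) neg$ct[order(neg$replicate)]
               else NULL)
  }
  ref <- assay_of(reference_gene)
  targets <- setdiff(unique(tab$gene), reference_gene)
  out <- do.call(rbind, lapply(targets, function(g) {
    a <- assay_of(g)
    r <- ddct_fold(a, ref)
    ng <- if (!is.null(a$ct_negctrl)) ddct_fold(a, ref, use_negctrl = TRUE)
    data.frame(gene = g, fold = r$fold, sd = r$sd,
               negctrl_fold = if (is.null(ng)) NA_real_ else ng$fold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
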