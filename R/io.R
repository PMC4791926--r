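#' Read a BED3/BED6 file into a sorted GRanges peak set
#'
#' Coordinates are interpreted as BED standard 0-based half-open and converted
#' to the 1-based closed GRanges convention. Column 4 (name), 5 (score) and
#' 6 (strand) are kept when present. The returned ranges are sorted by
#' (chromosome, start).
#'
#' @param path path to a tab-separated BED file.
#' @param label optional free-form label (e.g. `"5hmC/normal/rep1"`) stored in
#'   `metadata(x)$label`.
#' @return a sorted [GenomicRanges::GRanges]; empty (with a warning) for an
#'   empty file.
#' @export
read_bed <- function(path, label = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty BED file: ", path)
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer coordinates")
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": require 0 <= start < end, got [", start0[bad[1]], ", ",
         end0[bad[1]], ")")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (all(nf >= 4)) {
    nm <- vapply(fields, `[[`, "", 4L)
    if (!all(nm == ".")) S4Vectors::mcols(gr)$name <- nm
  }
  if (all(nf >= 5)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (!anyNA(sc)) S4Vectors::mcols(gr)$score <- sc
  }
  if (all(nf >= 6)) {
    st <- vapply(fields, `[[`, "", 6L)
    if (all(st %in% c("+", "-", "."))) {
      BiocGenerics::strand(gr) <- sub("^\\.$", "*", st)
    }
  }
  gr <- sort_peaks(gr)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a GRanges to BED
#'
#' Emits BED3 when neither name nor score nor strand information is present,
#' BED6 otherwise. Coordinates are converted back to 0-based half-open, so
#' `read_bed(write_bed(x))` round-trips coordinates exactly.
#'
#' @param x a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  mc <- S4Vectors::mcols(x)
  has_name <- "name" %in% names(mc)
  has_score <- "score" %in% names(mc)
  strands <- as.character(BiocGenerics::strand(x))
  has_strand <- any(strands != "*")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = BiocGenerics::start(x) - 1L,
                   end = BiocGenerics::end(x))
  if (has_name || has_score || has_strand) {
    df$name <- if (has_name) mc$name else "."
    df$score <- if (has_score) format_num(mc$score) else "0"
    df$strand <- sub("^\\*$", ".", strands)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

# Deterministic (chromosome name, start, end) ordering.
sort_peaks <- function(gr) {
  if (length(gr) == 0) return(gr)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr))
  gr[o]
}

#' Read gene models from BED12 or a tabular exon-structure TSV
#'
#' Accepts either standard BED12 (blocks become exons) or a TSV with a header
#' line and columns `chrom, start, end, name, strand, exon_starts, exon_ends`
#' (0-based half-open, comma-separated exon lists). Exons must be sorted,
#' pairwise disjoint and contained in the transcript span; strand must be
#' `+` or `-`. Duplicate gene names are collapsed by keeping the longest
#' transcript (ties: leftmost).
#'
#' @param path input file path.
#' @return a `gene_models` object: a [GenomicRanges::GRanges] with metadata
#'   columns `gene_name` and `exons` (a [GenomicRanges::GRangesList]).
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (grepl("\\bchrom\\b", first)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "name", "strand",
              "exon_starts", "exon_ends")
    if (!all(need %in% names(tab))) {
      stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    }
    ex_start <- lapply(strsplit(as.character(tab$exon_starts), ","),
                       as.numeric)
    ex_end <- lapply(strsplit(as.character(tab$exon_ends), ","), as.numeric)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 12) stop("BED12 requires 12 columns, got ", ncol(tab))
    names(tab)[c(1:4, 6, 10:12)] <- c("chrom", "start", "end", "name",
                                      "strand", "block_count", "block_sizes",
                                      "block_starts")
    sizes <- lapply(strsplit(sub(",$", "", as.character(tab$block_sizes)), ","),
                    as.numeric)
    offs <- lapply(strsplit(sub(",$", "", as.character(tab$block_starts)), ","),
                   as.numeric)
    ex_start <- Map(function(s, o) s + o, tab$start, offs)
    ex_end <- Map(`+`, ex_start, sizes)
  }
  gene_models(chrom = tab$chrom, start0 = tab$start, end0 = tab$end,
              name = tab$name, strand = tab$strand,
              exon_start0 = ex_start, exon_end0 = ex_end)
}

#' Construct gene models from parsed 0-based coordinates
#'
#' Validates exon structure, applies longest-transcript deduplication by gene
#' name, and wraps everything in a `gene_models` GRanges.
#'
#' @param chrom,start0,end0,name,strand per-transcript vectors (0-based
#'   half-open transcript span).
#' @param exon_start0,exon_end0 lists of numeric vectors (0-based half-open
#'   exon blocks).
#' @return a `gene_models` object.
#' @export
gene_models <- function(chrom, start0, end0, name, strand,
                        exon_start0, exon_end0) {
  n <- length(chrom)
  stopifnot(length(start0) == n, length(end0) == n, length(name) == n,
            length(strand) == n, length(exon_start0) == n,
            length(exon_end0) == n)
  if (!all(strand %in% c("+", "-"))) {
    stop("gene model parse error: strand must be '+' or '-'")
  }
  if (any(start0 >= end0)) stop("gene model parse error: start >= end")
  for (i in seq_len(n)) {
    es <- exon_start0[[i]]; ee <- exon_end0[[i]]
    if (length(es) == 0 || length(es) != length(ee)) {
      stop("gene ", name[i], ": malformed exon block lists")
    }
    if (any(es >= ee)) stop("gene ", name[i], ": empty exon block")
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    if (any(es < start0[i]) || any(ee > end0[i])) {
      stop("gene ", name[i], ": exon outside transcript span")
    }
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)])) {
      stop("gene ", name[i], ": overlapping exon blocks")
    }
    exon_start0[[i]] <- es; exon_end0[[i]] <- ee
  }
  # longest transcript per gene name; ties resolved leftmost then first listed
  wid <- end0 - start0
  o <- order(name, -wid, chrom, start0)
  keep <- o[!duplicated(name[o])]
  keep <- sort(keep)
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start0[keep] + 1, end0[keep]),
                               strand = strand[keep])
  S4Vectors::mcols(gr)$gene_name <- name[keep]
  ex_n <- lengths(exon_start0[keep])
  ex_flat <- GenomicRanges::GRanges(
    rep(chrom[keep], ex_n),
    IRanges::IRanges(unlist(exon_start0[keep]) + 1,
                     unlist(exon_end0[keep])))
  S4Vectors::mcols(gr)$exons <- S4Vectors::split(
    ex_flat, factor(rep(seq_along(keep), ex_n), seq_along(keep)))
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           BiocGenerics::start(gr))]
}

#' Read a per-gene expression table
#'
#' TSV with a header, a `gene` column and one or more numeric replicate
#' columns. A single expression value per gene is computed as the arithmetic
#' mean across replicate columns (missing values ignored); genes with no
#' finite value are dropped with a warning. Duplicate gene rows are an error:
#' probe-to-gene aggregation must happen upstream.
#'
#' @param path input TSV path.
#' @return a data.frame with columns `gene` and `expr` (replicate means).
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("expression TSV needs a 'gene' column")
  reps <- setdiff(names(tab), "gene")
  if (length(reps) == 0) stop("expression TSV needs >=1 replicate column")
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene rows in expression table: ",
         tab$gene[duplicated(tab$gene)][1])
  }
  m <- as.matrix(tab[, reps, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[reps], is.numeric, TRUE))
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[reps[bad[1]]]]))))[1]
    stop("expression parse error: non-numeric value in column '",
         reps[bad[1]], "' row ", badrow)
  }
  expr <- rowMeans(m, na.rm = TRUE)
  drop <- !is.finite(expr)
  if (any(drop)) {
    warning(sum(drop), " gene(s) with all-missing expression dropped")
  }
  data.frame(gene = tab$gene[!drop], expr = expr[!drop],
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: per line a set name, a description and >=1 tab-separated gene
#' names. Duplicate genes within a line are collapsed; duplicate set names or
#' empty gene lists are errors.
#'
#' @param path GMT path.
#' @return a named list of character vectors with a `description` attribute
#'   (named character vector, one entry per set).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT parse error at line ", which(nf < 3)[1],
         ": fewer than 3 fields (name, description, >=1 gene)")
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("GMT parse error: duplicate set name '", nms[duplicated(nms)][1], "'")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), nms)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors, as from [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
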