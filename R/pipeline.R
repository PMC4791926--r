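#' Load a written synthetic dataset back from standard formats
#'
#' Reads the files emitted by [write_dataset()]: gene models, CGI/DHS/CpG
#' tracks, per-(mark, condition, replicate) peak BEDs, expression TSVs and
#' the GMT collection.
#'
#' @param dir directory written by [write_dataset()].
#' @return a list shaped like a `synthetic_dataset` (without `config`).
#' @export
load_dataset <- function(dir) {
  stopifnot(dir.exists(dir))
  genes <- read_gene_models(file.path(dir, "genes.tsv"))
  read_track <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_bed(p) else GenomicRanges::GRanges()
  }
  reps <- list()
  for (cond in c("normal", "cancer")) {
    reps[[cond]] <- list()
    for (mark in c("mc", "hmc")) {
      files <- sort(list.files(dir, sprintf("^%s_%s_rep[0-9]+\\.bed$",
                                            mark, cond)))
      if (length(files) == 0) {
        stop("no replicate BED files for (", mark, ", ", cond, ") in ", dir)
      }
      reps[[cond]][[mark]] <- lapply(files, function(f) {
        read_bed(file.path(dir, f), label = sub("\\.bed$", "", f))
      })
    }
  }
  expression <- lapply(c(normal = "normal", cancer = "cancer"), function(cn) {
    utils::read.delim(file.path(dir, sprintf("expression_%s.tsv", cn)),
               stringsAsFactors = FALSE)
  })
  hmedip_path <- file.path(dir, "hmedip_normal.bed")
  list(genome = list(genes = genes, cgi = read_track("cgi.bed"),
                     dhs = read_track("dhs.bed"),
                     cpg = read_track("cpg.bed")),
       marks = list(replicates = reps,
                    hmedip = if (file.exists(hmedip_path))
                      read_bed(hmedip_path) else NULL),
       expression = expression,
       gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")))
}

tsv_out <- function(df, path) {
  # list-columns flattened for a stable on-disk schema
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full locus-dynamics analysis
#'
#' Orchestrates every stage on a dataset (in-memory `synthetic_dataset` or a
#' directory written by [write_dataset()]): feature annotation, replicate
#' consensus and differential sets per mark, expression-tier association
#' statistics per condition, 5hmC fate classification with the dual-null
#' tests and the cross-class comparison, same-cell-line co-incidence,
#' technique concordance (when a second-technique set is present), the
#' CpG-random background comparison, and region-based gene-set enrichment
#' with enrichment-map edges. All result tables are written as TSV under
#' `out_dir` together with a machine-readable `run_log.json`; outputs are
#' deterministic for a given dataset.
#'
#' @param dataset a `synthetic_dataset` or a directory path.
#' @param out_dir output directory.
#' @param params a [feature_params()] list.
#' @param alpha significance level used throughout (default 0.05).
#' @param k_mc,k_hmc replicate support required for the 5mC and 5hmC
#'   consensus sets (defaults 3 and 1, the replicate designs of the two
#'   assays).
#' @param enrich_p_max,enrich_fdr_max,jaccard_cutoff enrichment-map
#'   thresholds.
#' @return invisibly, a list with every stage's results.
#' @export
run_pipeline <- function(dataset, out_dir, params = feature_params(),
                         alpha = 0.05, k_mc = 3, k_hmc = 1,
                         enrich_p_max = 0.05, enrich_fdr_max = 0.1,
                         jaccard_cutoff = 0.25) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genome <- dataset$genome
  index <- stage("annotation", build_feature_index(genome$genes, genome$cgi,
                                                   genome$dhs, params))

  ## consensus and differential sets -----------------------------------
  consensus <- stage("consensus", {
    lapply(dataset$marks$replicates, function(cond) {
      list(mc = consensus_peaks(cond$mc, min(k_mc, length(cond$mc))),
           hmc = consensus_peaks(cond$hmc, min(k_hmc, length(cond$hmc))))
    })
  })
  differential <- stage("differential", {
    list(mc = differential_regions(consensus$normal$mc, consensus$cancer$mc),
         hmc = differential_regions(consensus$normal$hmc,
                                    consensus$cancer$hmc))
  })

  ## feature distributions ---------------------------------------------
  fdist <- stage("feature_distribution", {
    sets <- list(mc_normal = consensus$normal$mc,
                 mc_cancer = consensus$cancer$mc,
                 hmc_normal = consensus$normal$hmc,
                 hmc_cancer = consensus$cancer$hmc,
                 mc_normal_unique = differential$mc$a_unique,
                 mc_cancer_unique = differential$mc$b_unique,
                 hmc_normal_unique = differential$hmc$a_unique,
                 hmc_cancer_unique = differential$hmc$b_unique)
    do.call(rbind, lapply(names(sets), function(nm) {
      d <- feature_distribution(sets[[nm]], index)
      cbind(peak_set = nm, d, n_peaks = attr(d, "n_peaks"),
            stringsAsFactors = FALSE)
    }))
  })
  tsv_out(fdist, file.path(out_dir, "feature_distribution.tsv"))

  ## expression-tier association ----------------------------------------
  association <- stage("association", {
    diff_sets <- list(normal = list(mc = differential$mc$a_unique,
                                    hmc = differential$hmc$a_unique),
                      cancer = list(mc = differential$mc$b_unique,
                                    hmc = differential$hmc$b_unique))
    tiers <- lapply(dataset$expression, function(tab) {
      expr <- data.frame(gene = tab$gene,
                         expr = rowMeans(tab[, -1, drop = FALSE],
                                         na.rm = TRUE))
      tier_split(expr)
    })
    rows <- list()
    tcs <- list()
    for (cond in names(diff_sets)) {
      for (mark in names(diff_sets[[cond]])) {
        tc <- assign_peaks_to_tiers(diff_sets[[cond]][[mark]], genome$genes,
                                    tiers[[cond]], index)
        tcs[[paste(mark, cond, sep = "_")]] <- tc
        st <- association_stats(tc, alpha)
        rows[[length(rows) + 1]] <- cbind(
          mark = ifelse(mark == "mc", "5mC", "5hmC"), condition = cond, st,
          n_excluded = tc$n_excluded, stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), tier_counts = tcs, tiers = tiers)
  })
  tsv_out(association$table, file.path(out_dir, "association.tsv"))

  ## 5hmC fate dynamics --------------------------------------------------
  dynamics <- stage("dynamics", {
    classes <- classify_dynamics(consensus$normal$hmc, consensus$normal$mc,
                                 consensus$cancer$hmc, consensus$cancer$mc)
    tab <- dynamics_table(classes, index, alpha)
    fc <- dynamics_feature_counts(classes, index)
    comparison <- if (all(fc$totals > 0)) {
      compare_dynamic_classes(fc$counts, fc$totals, alpha)
    } else NULL
    list(classes = classes, table = tab, comparison = comparison)
  })
  tsv_out(dynamics$table, file.path(out_dir, "dynamics.tsv"))
  if (!is.null(dynamics$comparison)) {
    tsv_out(dynamics$comparison, file.path(out_dir,
                                           "dynamics_class_comparison.tsv"))
  }

  ## co-incidence ---------------------------------------------------------
  coincidence <- stage("coincidence", {
    lapply(consensus, function(cond) {
      coincidence_regions(cond$mc, cond$hmc, index)
    })
  })
  co_tab <- do.call(rbind, lapply(names(coincidence), function(cond) {
    cbind(condition = cond, coincidence[[cond]]$distribution,
          n_coincident = coincidence[[cond]]$n, stringsAsFactors = FALSE)
  }))
  tsv_out(co_tab, file.path(out_dir, "coincidence.tsv"))
  for (cond in names(coincidence)) {
    write_bed(coincidence[[cond]]$spans,
              file.path(out_dir, sprintf("coincidence_%s.bed", cond)))
  }

  ## technique concordance ------------------------------------------------
  concordance <- NULL
  if (!is.null(dataset$marks$hmedip) && length(dataset$marks$hmedip) > 0) {
    concordance <- stage("concordance", {
      method_concordance(consensus$normal$hmc, dataset$marks$hmedip,
                         genome$genes, index)
    })
    tsv_out(data.frame(gene_fraction = concordance$gene_fraction,
                       strict_fraction = concordance$strict_fraction,
                       strict_fraction_within =
                         concordance$strict_fraction_within,
                       n_genes_tech1 = concordance$n_genes_tech1,
                       n_shared_genes = concordance$n_shared_genes),
            file.path(out_dir, "concordance.tsv"))
    tsv_out(concordance$feature_comparison,
            file.path(out_dir, "concordance_features.tsv"))
  }

  ## CpG-random background ------------------------------------------------
  background <- NULL
  if (length(genome$cpg) > 0) {
    background <- stage("random_background", {
      random_background_expectation(consensus$normal$hmc, genome$cpg, index,
                                    alpha)
    })
    tsv_out(background, file.path(out_dir, "cpg_background.tsv"))
  }

  ## region enrichment ----------------------------------------------------
  enrichment <- stage("enrichment", {
    bg <- merge_intervals(c(GenomicRanges::granges(consensus$normal$hmc),
                            GenomicRanges::granges(consensus$cancer$hmc)))
    # whole differential sets plus the intergenic-stratified region lists
    # (the stratum with the study design's planted pathway signal)
    in_intergenic <- function(x) x[annotate_peaks(x, index)[, "intergenic"]]
    lapply(list(hmc_normal_unique = differential$hmc$a_unique,
                hmc_cancer_unique = differential$hmc$b_unique,
                hmc_normal_unique_intergenic =
                  in_intergenic(differential$hmc$a_unique),
                hmc_cancer_unique_intergenic =
                  in_intergenic(differential$hmc$b_unique)),
           function(fg) {
             res <- region_enrichment(fg, bg, dataset$gene_sets,
                                      genome$genes)
             edges <- similarity_edges(res, enrich_p_max, enrich_fdr_max,
                                       jaccard_cutoff)
             list(results = res, edges = edges)
           })
  })
  for (nm in names(enrichment)) {
    tsv_out(enrichment[[nm]]$results,
            file.path(out_dir, sprintf("enrichment_%s.tsv", nm)))
    tsv_out(enrichment[[nm]]$edges,
            file.path(out_dir, sprintf("enrichment_edges_%s.tsv", nm)))
  }

  ## run log --------------------------------------------------------------
  log <- list(
    package = "hmcdyn",
    version = as.character(utils::packageVersion("hmcdyn")),
    seed = if (!is.null(dataset$config)) dataset$config$seed else NA,
    params = unclass(params),
    alpha = alpha,
    bonferroni_m = length(FEATURES_DYNAMICS),
    k_consensus = c(mc = k_mc, hmc = k_hmc),
    enrichment = list(p_max = enrich_p_max, fdr_max = enrich_fdr_max,
                      jaccard_cutoff = jaccard_cutoff),
    n_peaks = lapply(consensus, function(cond) lapply(cond, length)),
    n_differential = list(mc = as.list(differential$mc$counts),
                          hmc = as.list(differential$hmc$counts)))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(index = index, consensus = consensus,
                 differential = differential,
                 feature_distribution = fdist, association = association,
                 dynamics = dynamics, coincidence = coincidence,
                 concordance = concordance, background = background,
                 enrichment = enrichment, log = log))
}
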