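# Table readers/writers, the expression filter, pipeline configuration and
# the end-to-end orchestration.

#' Expression-count filter (CPM > 1 in >= 5 percent of samples)
#'
#' @param counts Genes-x-samples raw count matrix.
#' @param cpm_min CPM threshold (default 1, strict `>`).
#' @param min_frac Minimum fraction of samples above threshold (default 0.05).
#' @return The retained rows, with attribute `filter_report`
#'   (n_in, n_retained, n_removed).
#' @export
filter_expression <- function(counts, cpm_min = 1, min_frac = 0.05) {
  stopifnot(is.matrix(counts))
  cpm <- t(t(counts) / pmax(colSums(counts), 1)) * 1e6
  keep <- rowMeans(cpm > cpm_min) >= min_frac
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(n_in = nrow(counts), n_retained = sum(keep),
                                     n_removed = sum(!keep))
  out
}

#' Load a genes-x-samples expression TSV
#'
#' First column is the gene id, remaining columns are samples. When
#' `counts = TRUE` the table is treated as raw counts and the
#' CPM > 1 in >= 5 percent of samples retention filter is applied.
#'
#' @param path Expression TSV.
#' @param counts Apply the count filter (default `FALSE`: values are
#'   already normalised/log-scale).
#' @return Numeric matrix (with `filter_report` attribute when filtered).
#' @export
load_expression <- function(path, counts = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) {
    stop(sprintf("duplicate gene id(s) in '%s': %s", path,
                 paste(utils::head(unique(df[[1]][duplicated(df[[1]])]), 3),
                       collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("non-numeric expression cells in '%s'", path),
                           call. = FALSE)
  rownames(m) <- df[[1]]
  if (counts) m <- filter_expression(m) else attr(m, "filter_report") <- NULL
  m
}

validate_bundle <- function(bundle) {
  imm <- bundle$immune
  bad <- which(imm$proportion < 0 | imm$proportion > 1)
  if (length(bad)) {
    stop(sprintf("validation error: immune proportion outside [0, 1] at row %d (%s/%s)",
                 bad[1], imm$patient_id[bad[1]], imm$sector_id[bad[1]]), call. = FALSE)
  }
  check_classes(bundle$mutations)
  if (nrow(bundle$segments)) {
    bad <- which(bundle$segments$start > bundle$segments$end)
    if (length(bad)) stop(sprintf("validation error: segment start > end at row %d", bad[1]),
                          call. = FALSE)
    if (any(bundle$segments$integer_cn < 0)) {
      stop("validation error: negative integer copy number", call. = FALSE)
    }
  }
  if (nrow(bundle$hla) && any(bundle$hla$minor_cn < 0)) {
    stop("validation error: negative HLA minor copy number", call. = FALSE)
  }
  # orphan sector keys between immune and expression
  ikeys <- unique(sample_key(bundle$immune$patient_id, bundle$immune$sector_id))
  ekeys <- colnames(bundle$expression)
  orphans <- c(setdiff(ikeys, ekeys), setdiff(ekeys, ikeys))
  if (length(orphans)) {
    warning(sprintf("orphan sector key(s) between immune and expression tables: %s",
                    paste(orphans, collapse = ", ")), call. = FALSE)
  }
  invisible(bundle)
}

#' Load a cohort bundle from a directory written by [write_cohort()]
#'
#' Re-reads every table, validates domain invariants (proportions in
#' [0, 1], known mutation classes, segment coordinates, non-negative copy
#' numbers) and warns on sector keys present in one table but not another.
#'
#' @param dir Directory containing the tables and `manifest.json`.
#' @param counts Treat the expression table as raw counts (apply the CPM
#'   filter); default `FALSE`.
#' @return A `cohort_bundle`.
#' @export
load_tables <- function(dir, counts = FALSE) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing input file '%s'", p), call. = FALSE)
    p
  }
  rd <- function(f, sep) utils::read.table(need(f), header = TRUE, sep = sep,
                                           stringsAsFactors = FALSE, check.names = FALSE)
  bundle <- structure(list(
    immune = rd("immune_proportions.csv", ","),
    expression = load_expression(need("expression.tsv"), counts = counts),
    mutations = rd("mutations.tsv", "\t"),
    segments = rd("segments.tsv", "\t"),
    hla = rd("hla.tsv", "\t"),
    densities = rd("densities.csv", ","),
    clinical = rd("clinical.csv", ","),
    subsets = NULL, config = NULL
  ), class = "cohort_bundle")
  bundle$subsets <- unique(bundle$immune$subset_name)
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest)) {
    bundle$config <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  validate_bundle(bundle)
  bundle
}

#' Pipeline configuration
#'
#' Bundles generator settings (or an input directory), stage selection and
#' the analysis thresholds. Defaults are the thresholds of the source
#' analysis: DEG FDR 0.01, network gates |rho| >= 0.4 and p < 0.05,
#' neoantigen IC50 < 500 nM at epitope lengths 8-11, HLA-LOH minor CN
#' < 0.5. Unknown keys are rejected.
#'
#' @param generator A [cohort_config()] (synthetic run), or `NULL` with
#'   `input_dir` set (load run).
#' @param input_dir Directory of tables for a load run.
#' @param out_dir Results directory.
#' @param stages Stages to execute, a subset of
#'   `c("ith", "phylo", "editing", "cnv", "network", "survival")`.
#' @param seed Integer seed for stochastic stages (bootstrap).
#' @param fdr_deg,rho_min,edge_p,ic50_max,epitope_lengths,minor_cn_loh
#'   Analysis thresholds.
#' @param bootstrap_B Bootstrap replicates for the signature FDR.
#' @param ... Unknown keys: rejected with an error.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(), input_dir = NULL,
                            out_dir = tempfile("ithscape_results_"),
                            stages = c("ith", "phylo", "editing", "cnv",
                                       "network", "survival"),
                            seed = 1L, fdr_deg = 0.01, rho_min = 0.4,
                            edge_p = 0.05, ic50_max = 500,
                            epitope_lengths = 8:11, minor_cn_loh = 0.5,
                            bootstrap_B = 200L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_config(names(extra)[1], "unknown configuration key")
  }
  for (f in c("fdr_deg", "rho_min", "edge_p", "ic50_max", "minor_cn_loh")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) stop_config(f, "must be a positive number")
  }
  bad <- setdiff(stages, c("ith", "phylo", "editing", "cnv", "network", "survival"))
  if (length(bad)) stop_config("stages", paste("unknown stage:", bad[1]))
  structure(list(generator = generator, input_dir = input_dir, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed), fdr_deg = fdr_deg,
                 rho_min = rho_min, edge_p = edge_p, ic50_max = ic50_max,
                 epitope_lengths = epitope_lengths, minor_cn_loh = minor_cn_loh,
                 bootstrap_B = as.integer(bootstrap_B)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `generator:` block mirrors [cohort_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  gen <- if (!is.null(raw$generator)) do.call(cohort_config, raw$generator) else NULL
  raw$generator <- NULL
  do.call(pipeline_config, c(list(generator = gen), raw))
}

log_msg <- function(...) message(sprintf(...))

#' Run the full multi-sector ITH analysis pipeline
#'
#' Generates (or loads) the cohort, computes ITH scores and the median
#' split, builds per-patient phylogenies, calls neoantigen clonality,
#' immunoediting and HLA-LOH, compares copy-number events between groups,
#' infers the transcriptome-immune networks, and runs the survival and
#' signature analyses. All result tables are written to
#' `config$out_dir`, together with a machine-readable `summary.json` (no
#' timestamps: re-running at the same seed is bit-identical) and a run log
#' recording every threshold applied. Progress goes to stderr.
#'
#' @param config A [pipeline_config()].
#' @return List of class `ithscape_run` with all in-memory results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = config$out_dir, config = config)
  wr <- function(df, f, sep = ",") {
    utils::write.table(df, file.path(config$out_dir, f), sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  run_log <- c(sprintf("seed: %d", config$seed),
               sprintf("thresholds: fdr_deg=%g rho_min=%g edge_p=%g ic50_max=%g minor_cn_loh=%g",
                       config$fdr_deg, config$rho_min, config$edge_p,
                       config$ic50_max, config$minor_cn_loh))
  stage <- function(name, fn) {
    log_msg("[ithscape] stage %s", name)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  summary_json <- list(seed = config$seed, stages = config$stages)

  ## load or simulate
  truth <- NULL
  if (!is.null(config$input_dir)) {
    bundle <- stage("load", function() load_tables(config$input_dir))
  } else {
    gen <- stage("simulate", function() generate_cohort(config$generator))
    bundle <- gen$bundle
    truth <- gen$truth
    write_cohort(bundle, file.path(config$out_dir, "cohort"))
  }
  res$bundle <- bundle
  res$truth <- truth
  summary_json$n_patients <- length(unique(bundle$immune$patient_id))
  summary_json$n_sectors <- length(unique(sample_key(bundle$immune$patient_id,
                                                     bundle$immune$sector_id)))

  ## ITH scores + median split (always needed downstream)
  scores <- stage("ith", function() {
    do.call(rbind, lapply(c("immune_spearman", "immune_euclidean", "rna",
                            "dna", "density_sd"),
                          function(m) suppressWarnings(cohort_ith(bundle, m))))
  })
  groups <- assign_ith_groups(scores[scores$metric == "immune_spearman", ])
  res$scores <- scores
  res$groups <- groups
  if ("ith" %in% config$stages) {
    wr(scores, "ith_scores.csv")
    wr(groups, "ith_groups.csv")
  }
  summary_json$median_immune_ith <- unname(groups$cutoff[1])
  summary_json$n_high <- sum(groups$group == "high")

  if ("phylo" %in% config$stages) {
    trees <- stage("phylo", function() suppressWarnings(cohort_phylogenies(bundle)))
    res$trees <- trees
    tdir <- file.path(config$out_dir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (p in names(trees)) {
      if (!is.null(trees[[p]]$dna)) write_newick(trees[[p]]$dna,
                                                 file.path(tdir, paste0(p, "_dna.nwk")))
      if (!is.null(trees[[p]]$rna)) write_newick(trees[[p]]$rna,
                                                 file.path(tdir, paste0(p, "_rna.nwk")))
    }
    summary_json$n_trees <- sum(vapply(trees, function(t) !is.null(t$dna), logical(1)))
  }

  if ("editing" %in% config$stages) {
    ed <- stage("editing", function() {
      hla <- call_hla_loh(bundle$hla, threshold = config$minor_cn_loh)
      sc <- suppressWarnings(cohort_editing_scores(bundle$mutations))
      sc_pat <- suppressWarnings(cohort_editing_scores(bundle$mutations,
                                                       level = "patient"))
      strat <- suppressWarnings(stratified_editing_comparison(sc_pat, groups,
                                                              hla$patients))
      clon <- do.call(rbind, lapply(unique(bundle$mutations$patient_id), function(p) {
        cl <- tryCatch(classify_clonality(
          bundle$mutations[bundle$mutations$patient_id == p, ]),
          error = function(e) NULL)
        if (is.null(cl)) return(NULL)
        data.frame(patient_id = p, clonal = cl$clonal, subclonal = cl$subclonal,
                   total = cl$total, stringsAsFactors = FALSE)
      }))
      list(hla = hla, scores = sc, strata = strat, clonality = clon)
    })
    res$editing <- ed
    wr(ed$scores, "editing_scores.csv")
    wr(ed$hla$patients, "hla_loh_patients.csv")
    wr(ed$strata$strata, "editing_strata.csv")
    if (!is.null(ed$clonality)) wr(ed$clonality, "neoantigen_clonality.csv")
    summary_json$n_loh_patients <- sum(ed$hla$patients$loh)
    summary_json$median_editing_ratio <- stats::median(ed$scores$ratio)
  }

  if ("cnv" %in% config$stages) {
    cnv <- stage("cnv", function() {
      agf <- cohort_altered_fraction(bundle$segments)
      bands <- cytoband_cnv_comparison(bundle$segments, synthetic_cytobands(), groups)
      list(agf = agf, bands = bands)
    })
    res$cnv <- cnv
    wr(cnv$agf, "altered_genome_fraction.csv")
    wr(cnv$bands, "cytoband_comparison.csv")
    summary_json$n_significant_bands <- sum(cnv$bands$q < 0.05)
  }

  if ("network" %in% config$stages) {
    net <- stage("network", function() {
      degs <- select_degs(bundle$expression, groups, fdr = config$fdr_deg)
      immune_list <- if (!is.null(truth)) truth$immune_genes else character(0)
      kept <- filter_immune_genes(degs[degs$significant, , drop = FALSE], immune_list)
      edges <- lapply(c("low", "high"), function(gr) {
        tryCatch(build_network(bundle$expression[kept$gene, , drop = FALSE],
                               bundle$immune, groups, gr,
                               rho_min = config$rho_min, p_max = config$edge_p),
                 error = function(e) NULL)
      })
      names(edges) <- c("low", "high")
      list(degs = degs, kept = kept, edges = edges)
    })
    res$network <- net
    wr(net$degs, "deg_table.csv")
    for (gr in names(net$edges)) {
      if (!is.null(net$edges[[gr]])) {
        export_network(net$edges[[gr]],
                       file.path(config$out_dir, paste0("network_", gr, ".tsv")))
      }
    }
    summary_json$n_degs <- sum(net$degs$significant)
    summary_json$n_edges_low <- if (!is.null(net$edges$low)) nrow(net$edges$low) else 0L
    summary_json$n_edges_high <- if (!is.null(net$edges$high)) nrow(net$edges$high) else 0L
  }

  if ("survival" %in% config$stages) {
    surv <- stage("survival", function() {
      rec <- bundle$clinical
      rec$group <- groups$group[match(rec$patient_id, groups$patient_id)]
      rec <- rec[!is.na(rec$group), , drop = FALSE]
      km <- km_logrank(rec)
      cov <- intersect(c("group", "stage", "mvi", "size_cm"), names(rec))
      cox <- tryCatch(cox_model(rec, cov), error = function(e) {
        warning(sprintf("multivariate Cox skipped: %s", conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      sig_boot <- NULL
      if (!is.null(res$network) && sum(res$network$degs$significant) >= 10) {
        sig <- res$network$degs[res$network$degs$significant,
                                c("gene", "direction")]
        pat_expr <- patient_mean_expression(bundle$expression)
        set.seed(config$seed)
        sig_boot <- tryCatch(
          bootstrap_fdr(pat_expr, sig, rec, B = config$bootstrap_B),
          error = function(e) NULL)
      }
      list(km = km, cox = cox, bootstrap = sig_boot, records = rec)
    })
    res$survival <- surv
    wr(km_curve_points(surv$km), "km_curves.csv")
    if (!is.null(surv$cox)) wr(surv$cox, "cox_model.csv")
    summary_json$logrank_p <- surv$km$p_value
    summary_json$logrank_hr <- surv$km$hazard_ratio
    if (!is.null(surv$bootstrap)) summary_json$bootstrap_fdr <- surv$bootstrap$fdr
  }

  jsonlite::write_json(summary_json, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(run_log, file.path(config$out_dir, "run_log.txt"))
  class(res) <- "ithscape_run"
  res
}

#' Patient-level expression (mean over a patient's sectors)
#'
#' A bulk-biopsy proxy: averages each gene over the sectors of a patient,
#' giving a genes-x-patients matrix for signature segregation.
#'
#' @param expr Genes-x-sectors matrix with `"<patient>_<sector>"` columns.
#' @return Genes-x-patients matrix.
#' @export
patient_mean_expression <- function(expr) {
  pats <- sub("_[^_]+$", "", colnames(expr))
  out <- vapply(unique(pats), function(p) {
    rowMeans(expr[, pats == p, drop = FALSE])
  }, numeric(nrow(expr)))
  matrix(out, nrow = nrow(expr),
         dimnames = list(rownames(expr), unique(pats)))
}

#' @export
print.ithscape_run <- function(x, ...) {
  cat("ithscape pipeline run\n")
  cat(sprintf("  output: %s\n", x$out_dir))
  cat(sprintf("  %d patients; median immune-ITH %.4f\n",
              length(unique(x$groups$patient_id)), x$groups$cutoff[1]))
  if (!is.null(x$network)) {
    cat(sprintf("  DEGs (q < %g): %d\n", x$config$fdr_deg,
                sum(x$network$degs$significant)))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  log-rank p = %.4g, HR = %.2f\n",
                x$survival$km$p_value, x$survival$km$hazard_ratio))
  }
  invisible(x)
}
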