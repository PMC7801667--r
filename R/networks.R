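# ITH-associated differential expression and bipartite transcriptome-immune
# correlation networks.

#' Differentially expressed genes between low and high ITH groups
#'
#' Per gene, a two-group test on sector-level expression values between the
#' two ITH groups (default: two-sided Wilcoxon rank-sum; pluggable, e.g. a
#' moderated test), with Benjamini-Hochberg adjustment across genes.
#' Significance is called at `q < fdr`; direction is the sign of the
#' high-group minus low-group median.
#'
#' @param expr Genes-x-sectors expression matrix; column names are sample
#'   keys `"<patient>_<sector>"`.
#' @param groups Patient group assignment from [assign_ith_groups()].
#' @param fdr FDR threshold (default 0.01).
#' @param test Function `(x_low, x_high) -> p-value`; default rank-sum.
#' @return Data frame `gene`, `direction` (`"up_in_high"`/`"up_in_low"`),
#'   `p`, `q`, `significant`.
#' @export
select_degs <- function(expr, groups, fdr = 0.01, test = NULL) {
  grp <- sector_groups(colnames(expr), groups)
  if (sum(grp == "low", na.rm = TRUE) < 2L || sum(grp == "high", na.rm = TRUE) < 2L) {
    stop("need >= 2 sectors per ITH group", call. = FALSE)
  }
  test <- test %||% function(x, y) {
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  lo <- expr[, which(grp == "low"), drop = FALSE]
  hi <- expr[, which(grp == "high"), drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(i) test(lo[i, ], hi[i, ]), numeric(1))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  dmed <- apply(hi, 1, stats::median) - apply(lo, 1, stats::median)
  data.frame(gene = rownames(expr),
             direction = ifelse(dmed >= 0, "up_in_high", "up_in_low"),
             p = p, q = q, significant = q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Map sample keys "P01_S2" to their patient's ITH group.
sector_groups <- function(keys, groups) {
  pat <- sub("_[^_]+$", "", keys)
  groups$group[match(pat, groups$patient_id)]
}

#' Remove immune-lineage genes from a DEG table
#'
#' Drops genes present in a deconvolution-style immune gene list (one gene
#' per line when given as a file) so the network links tumour-intrinsic
#' transcripts, not immune infiltrate content, to immune proportions.
#'
#' @param degs DEG table from [select_degs()].
#' @param immune_genes Character vector of gene ids, or path to a
#'   one-gene-per-line text file.
#' @return The filtered DEG table with attribute `n_removed`.
#' @export
filter_immune_genes <- function(degs, immune_genes) {
  if (length(immune_genes) == 1L && file.exists(immune_genes)) {
    immune_genes <- readLines(immune_genes)
    immune_genes <- immune_genes[nzchar(trimws(immune_genes))]
  }
  keep <- !(degs$gene %in% immune_genes)
  if (!any(keep)) {
    warning("all genes removed by the immune gene filter", call. = FALSE)
  }
  out <- degs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Bipartite gene-to-immune-subset correlation network
#'
#' Within the sectors of one ITH group, correlates each gene's expression
#' with each immune subset's proportion (Spearman) and retains edges with
#' `|rho| >= rho_min` and `p < p_max` (raw p, per the gating convention of
#' the source analysis — no multiplicity adjustment at the edge level).
#'
#' @param expr Genes-x-sectors expression matrix restricted to the genes of
#'   interest (e.g. immune-filtered DEGs).
#' @param immune Long immune table (`patient_id`, `sector_id`,
#'   `subset_name`, `proportion`).
#' @param groups Patient group assignment from [assign_ith_groups()].
#' @param which_group `"low"` or `"high"`: the network's sector stratum;
#'   `"all"` uses every matched sector.
#' @param rho_min Absolute correlation gate (default 0.4).
#' @param p_max Raw p-value gate (default 0.05, strict `<`).
#' @return Data frame `gene`, `subset`, `rho`, `p`, `sign`.
#' @export
build_network <- function(expr, immune, groups, which_group = c("low", "high", "all"),
                          rho_min = 0.4, p_max = 0.05) {
  which_group <- match.arg(which_group)
  assert_columns(immune, c("patient_id", "sector_id", "subset_name", "proportion"),
                 "immune table")
  ikey <- sample_key(immune$patient_id, immune$sector_id)
  orphans_e <- setdiff(colnames(expr), ikey)
  orphans_i <- setdiff(ikey, colnames(expr))
  if (length(orphans_e)) {
    stop(sprintf("join error: expression sectors absent from immune table: %s",
                 paste(utils::head(orphans_e, 5), collapse = ", ")), call. = FALSE)
  }
  keys <- colnames(expr)
  if (which_group != "all") {
    keys <- keys[!is.na(sector_groups(keys, groups)) &
                   sector_groups(keys, groups) == which_group]
  }
  if (length(keys) < 3L) stop("need >= 3 sectors in the chosen group", call. = FALSE)
  subsets <- unique(immune$subset_name)
  prop <- vapply(subsets, function(su) {
    rows <- immune[immune$subset_name == su, ]
    rows$proportion[match(keys, sample_key(rows$patient_id, rows$sector_id))]
  }, numeric(length(keys)))

  edges <- list()
  for (g in rownames(expr)) {
    x <- expr[g, keys]
    for (k in seq_along(subsets)) {
      ct <- suppressWarnings(stats::cor.test(x, prop[, k], method = "spearman"))
      if (!is.na(ct$estimate) && abs(ct$estimate) >= rho_min && ct$p.value < p_max) {
        edges[[length(edges) + 1L]] <- data.frame(
          gene = g, subset = subsets[k],
          rho = unname(ct$estimate), p = ct$p.value,
          sign = if (ct$estimate > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, edges) %||%
    data.frame(gene = character(0), subset = character(0), rho = numeric(0),
               p = numeric(0), sign = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a network edge list to TSV
#'
#' @param edges Edge table from [build_network()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path) {
  assert_columns(edges, c("gene", "subset", "rho", "p", "sign"), "edge list")
  ok <- try(utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                               quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop(sprintf("failed writing '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a network edge list written by [export_network()]
#'
#' @param path Edge-list TSV.
#' @return Edge data frame.
#' @export
read_network <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
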