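# Patient-level intratumoural heterogeneity (ITH) scores.
#
# All pairwise scores follow the same scheme: a dissimilarity is computed
# for every unordered pair of a patient's tumour sectors and the patient
# score is the median of the pairwise values. Immune- and RNA-ITH use
# 1 - Spearman rho (range [0, 2]); DNA-ITH uses the fraction of mutations
# unique to one sector of the pair (range [0, 1]); density heterogeneity
# uses the SD of in-tissue cell density across regions.

new_ith_score <- function(patient_id, metric, pairwise, value, n_sectors) {
  structure(list(patient_id = patient_id, metric = metric,
                 pairwise_values = pairwise, value = value,
                 n_sectors = n_sectors),
            class = "ith_score")
}

#' @export
print.ith_score <- function(x, ...) {
  cat(sprintf("ITH score [%s] patient %s: %.4f (%d sectors, %d pairs)\n",
              x$metric, x$patient_id, x$value, x$n_sectors,
              length(x$pairwise_values)))
  invisible(x)
}

# Accepts a subsets-x-sectors matrix or the long immune table for one
# patient; returns the matrix, erroring on schema violations.
as_profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  assert_columns(profiles, c("sector_id", "subset_name", "proportion"),
                 "immune profiles")
  if (length(unique(profiles$patient_id %||% "?")) > 1L) {
    stop("immune profiles: expected a single patient", call. = FALSE)
  }
  secs <- unique(profiles$sector_id)
  subs <- unique(profiles$subset_name)
  m <- matrix(NA_real_, length(subs), length(secs), dimnames = list(subs, secs))
  for (s in secs) {
    rows <- profiles[profiles$sector_id == s, ]
    if (!setequal(rows$subset_name, subs) || nrow(rows) != length(subs)) {
      stop(sprintf("schema error: sector %s has mismatched subset names", s),
           call. = FALSE)
    }
    m[rows$subset_name, s] <- rows$proportion
  }
  m
}

check_sectors <- function(n, patient_id = "?") {
  if (n < 2L) {
    stop(sprintf("insufficient sectors for patient %s: need >= 2, got %d",
                 patient_id, n), call. = FALSE)
  }
}

pairwise_median <- function(labels, fun) {
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  vals <- vapply(pairs, function(p) fun(p[1], p[2]), numeric(1))
  names(vals) <- vapply(pairs, paste, character(1), collapse = "|")
  list(pairwise = vals, value = stats::median(vals))
}

#' Immune ITH score (1 - Spearman rho over subset proportions)
#'
#' For every unordered pair of sectors, computes the Spearman rank
#' correlation between the two sectors' immune subset proportion vectors
#' (average ranks on ties) and takes 1 - rho as the pairwise
#' dissimilarity; the patient score is the median over pairs.
#'
#' @param profiles A subsets-x-sectors proportion matrix for one patient,
#'   or the long immune table (`sector_id`, `subset_name`, `proportion`)
#'   restricted to one patient.
#' @param patient_id Identifier used in messages and the result.
#' @return An `ith_score` with metric `"immune_spearman"`.
#' @export
immune_ith_spearman <- function(profiles, patient_id = "?") {
  m <- as_profile_matrix(profiles)
  check_sectors(ncol(m), patient_id)
  if (any(m < 0 | m > 1)) {
    stop(sprintf("patient %s: proportions outside [0, 1]", patient_id),
         call. = FALSE)
  }
  pm <- pairwise_median(colnames(m), function(a, b) {
    1 - spearman_rho(m[, a], m[, b],
                     sprintf("proportions (patient %s, sectors %s/%s)",
                             patient_id, a, b))
  })
  new_ith_score(patient_id, "immune_spearman", pm$pairwise, pm$value, ncol(m))
}

#' Immune ITH score (Euclidean distance between proportion vectors)
#'
#' @inheritParams immune_ith_spearman
#' @return An `ith_score` with metric `"immune_euclidean"`.
#' @export
immune_ith_euclidean <- function(profiles, patient_id = "?") {
  m <- as_profile_matrix(profiles)
  check_sectors(ncol(m), patient_id)
  if (any(m < 0 | m > 1)) {
    stop(sprintf("patient %s: proportions outside [0, 1]", patient_id),
         call. = FALSE)
  }
  pm <- pairwise_median(colnames(m), function(a, b) {
    sqrt(sum((m[, a] - m[, b])^2))
  })
  new_ith_score(patient_id, "immune_euclidean", pm$pairwise, pm$value, ncol(m))
}

#' RNA ITH score (1 - Spearman rho over gene expression)
#'
#' @param expr Genes-x-sectors expression matrix restricted to one
#'   patient's sectors (at least 2 columns).
#' @param patient_id Identifier used in messages and the result.
#' @return An `ith_score` with metric `"rna"`.
#' @export
rna_ith <- function(expr, patient_id = "?") {
  stopifnot(is.matrix(expr))
  check_sectors(ncol(expr), patient_id)
  if (nrow(expr) < 2L) {
    stop(sprintf("patient %s: need >= 2 genes", patient_id), call. = FALSE)
  }
  pm <- pairwise_median(colnames(expr), function(a, b) {
    1 - spearman_rho(expr[, a], expr[, b],
                     sprintf("expression (patient %s, sectors %s/%s)",
                             patient_id, a, b))
  })
  new_ith_score(patient_id, "rna", pm$pairwise, pm$value, ncol(expr))
}

#' DNA ITH score (unique over total mutations, pairwise)
#'
#' Mutation identity is the site key (chrom, pos, ref, alt). For each
#' sector pair the dissimilarity is the number of mutations present in
#' exactly one of the two sectors divided by the size of their union; a
#' pair with an empty union scores 0.
#'
#' @param catalog Mutation table for one patient with columns `sector_id`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param patient_id Identifier used in messages and the result.
#' @return An `ith_score` with metric `"dna"`.
#' @export
dna_ith <- function(catalog, patient_id = "?") {
  assert_columns(catalog, c("sector_id", "chrom", "pos", "ref", "alt"),
                 "mutation catalog")
  secs <- unique(catalog$sector_id)
  check_sectors(length(secs), patient_id)
  key <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt, sep = ":")
  sets <- split(key, factor(catalog$sector_id, levels = secs))
  sets <- lapply(sets, unique)
  pm <- pairwise_median(secs, function(a, b) {
    u <- union(sets[[a]], sets[[b]])
    if (!length(u)) return(0)
    length(setdiff(u, intersect(sets[[a]], sets[[b]]))) / length(u)
  })
  new_ith_score(patient_id, "dna", pm$pairwise, pm$value, length(secs))
}

#' Density heterogeneity (SD of cell density across tumour regions)
#'
#' Per cell type, the sample SD (n - 1 denominator) of density across
#' regions; the patient value is the unweighted mean of the per-type SDs.
#'
#' @param densities Density table for one patient with columns `region_id`,
#'   `cell_type`, `density_per_mm2`.
#' @param cell_types Cell types to use (default: all present).
#' @param patient_id Identifier used in messages and the result.
#' @return An `ith_score` with metric `"density_sd"`; `pairwise_values`
#'   holds the per-type SDs.
#' @export
density_ith_sd <- function(densities, cell_types = NULL, patient_id = "?") {
  assert_columns(densities, c("region_id", "cell_type", "density_per_mm2"),
                 "density table")
  cell_types <- cell_types %||% unique(densities$cell_type)
  n_reg <- length(unique(densities$region_id))
  if (n_reg < 2L) {
    stop(sprintf("insufficient regions for patient %s: need >= 2, got %d",
                 patient_id, n_reg), call. = FALSE)
  }
  sds <- vapply(cell_types, function(ct) {
    stats::sd(densities$density_per_mm2[densities$cell_type == ct])
  }, numeric(1))
  new_ith_score(patient_id, "density_sd", sds, mean(sds), n_reg)
}

#' Compute one ITH metric for every patient in a cohort bundle
#'
#' Patients failing the metric's preconditions (e.g. a single sector) are
#' dropped with a warning naming them.
#'
#' @param bundle A `cohort_bundle`.
#' @param metric One of `"immune_spearman"`, `"immune_euclidean"`, `"rna"`,
#'   `"dna"`, `"density_sd"`.
#' @return Data frame `patient_id`, `metric`, `value`, `n_sectors`.
#' @export
cohort_ith <- function(bundle,
                       metric = c("immune_spearman", "immune_euclidean",
                                  "rna", "dna", "density_sd")) {
  metric <- match.arg(metric)
  pids <- unique(bundle$immune$patient_id)
  rows <- lapply(pids, function(p) {
    sc <- tryCatch(switch(
      metric,
      immune_spearman = immune_ith_spearman(
        bundle$immune[bundle$immune$patient_id == p, ], p),
      immune_euclidean = immune_ith_euclidean(
        bundle$immune[bundle$immune$patient_id == p, ], p),
      rna = {
        cols <- grep(paste0("^", p, "_"), colnames(bundle$expression), value = TRUE)
        rna_ith(bundle$expression[, cols, drop = FALSE], p)
      },
      dna = dna_ith(bundle$mutations[bundle$mutations$patient_id == p, ], p),
      density_sd = density_ith_sd(
        bundle$densities[bundle$densities$patient_id == p, ], patient_id = p)
    ), error = function(e) {
      warning(sprintf("patient %s skipped: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(sc)) return(NULL)
    data.frame(patient_id = p, metric = metric, value = sc$value,
               n_sectors = sc$n_sectors, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(patient_id = character(0), metric = character(0),
               value = numeric(0), n_sectors = integer(0))
  rownames(out) <- NULL
  out
}

#' Median-split assignment of patients into low/high ITH groups
#'
#' The cutoff is the cohort median of the score; patients at or below the
#' median are `"low"`, strictly above are `"high"` (so an all-tied cohort
#' is all low — the split is deterministic).
#'
#' @param scores Data frame with `patient_id` and `value` (e.g. from
#'   [cohort_ith()]), or a list of `ith_score` objects.
#' @return Data frame `patient_id`, `group`, `cutoff`.
#' @export
assign_ith_groups <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores) &&
      all(vapply(scores, inherits, logical(1), "ith_score"))) {
    scores <- data.frame(
      patient_id = vapply(scores, `[[`, character(1), "patient_id"),
      value = vapply(scores, `[[`, numeric(1), "value"),
      stringsAsFactors = FALSE)
  }
  assert_columns(scores, c("patient_id", "value"), "scores")
  if (nrow(scores) < 2L) stop("need >= 2 patients for a median split", call. = FALSE)
  cutoff <- stats::median(scores$value)
  data.frame(patient_id = scores$patient_id,
             group = ifelse(scores$value <= cutoff, "low", "high"),
             cutoff = cutoff, stringsAsFactors = FALSE)
}

#' Two-group rank-sum comparison of a per-sector (or per-patient) quantity
#'
#' Maps each observation to its patient's ITH group and runs a two-sided
#' Wilcoxon rank-sum (Mann-Whitney U) test, returning box-plot summary
#' statistics per group.
#'
#' @param values Numeric vector of observations.
#' @param patients Patient id per observation.
#' @param groups Group assignment from [assign_ith_groups()].
#' @return List with `p_value`, `statistic`, and a `summary` data frame
#'   (group, n, median, q1, q3).
#' @export
compare_groups <- function(values, patients, groups) {
  stopifnot(length(values) == length(patients))
  g <- groups$group[match(patients, groups$patient_id)]
  keep <- !is.na(g) & !is.na(values)
  values <- values[keep]; g <- g[keep]
  if (!all(c("low", "high") %in% g)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  # exact rank-sum distribution where wilcox.test supports it (small n,
  # no ties), normal approximation with continuity correction otherwise
  wt <- suppressWarnings(stats::wilcox.test(values[g == "low"], values[g == "high"]))
  qs <- function(gr) {
    v <- values[g == gr]
    data.frame(group = gr, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       summary = rbind(qs("low"), qs("high")))
}
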