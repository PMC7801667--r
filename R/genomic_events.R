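# Mutation-class accounting, neoantigen clonality, immunoediting scores,
# HLA loss of heterozygosity and copy-number event calling.

MUTATION_CLASSES <- c("silent", "missense", "nonsense")

mutation_site_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

check_classes <- function(records) {
  bad <- setdiff(unique(records$class), MUTATION_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown mutation class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
}

# One row per distinct site within the queried scope (a site present in
# several sectors is counted once).
dedup_sites <- function(records) {
  records[!duplicated(mutation_site_key(records)), , drop = FALSE]
}

#' Count non-silent (nonsynonymous) mutations
#'
#' Non-silent mutations are those of class missense or nonsense,
#' deduplicated by site key (chrom, pos, ref, alt) within the records
#' passed in — so querying all of a patient's sectors counts each shared
#' site once.
#'
#' @param records Mutation table with columns `chrom`, `pos`, `ref`, `alt`,
#'   `class`.
#' @return Integer count.
#' @export
count_nonsilent <- function(records) {
  if (!nrow(records)) return(0L)
  check_classes(records)
  rec <- dedup_sites(records)
  sum(rec$class %in% c("missense", "nonsense"))
}

#' Filter predicted epitopes to binders
#'
#' Keeps 8- to 11-mer epitopes with predicted MHC-I binding affinity
#' strictly below 500 nM.
#'
#' @param calls Data frame with columns `length` and `ic50_nm`.
#' @param max_ic50 Affinity threshold in nM (strict `<`; default 500).
#' @param lengths Admissible epitope lengths (default 8..11).
#' @return The retained rows.
#' @export
filter_neoantigens <- function(calls, max_ic50 = 500, lengths = 8:11) {
  assert_columns(calls, c("length", "ic50_nm"), "neoantigen calls")
  if (any(calls$ic50_nm <= 0, na.rm = TRUE)) {
    stop("non-positive ic50_nm", call. = FALSE)
  }
  calls[calls$length %in% lengths & calls$ic50_nm < max_ic50, , drop = FALSE]
}

#' Classify neoantigen-bearing mutation sites as clonal or subclonal
#'
#' Clonal sites are present in every sector of the patient; subclonal
#' sites in at least one but not all. `clonal + subclonal = total` always.
#'
#' @param catalog Mutation table for one patient (>= 2 sectors).
#' @param neoantigen_keys Optional character vector of site keys
#'   (`"chrom:pos:ref:alt"`) to restrict to; default: sites with
#'   `n_neoantigens > 0`.
#' @return List with `clonal`, `subclonal`, `total` counts and the per-site
#'   data frame `sites` (site, n_sectors_present, clonal flag).
#' @export
classify_clonality <- function(catalog, neoantigen_keys = NULL) {
  secs <- unique(catalog$sector_id)
  if (length(secs) < 2L) {
    stop("clonality undefined: need >= 2 sectors", call. = FALSE)
  }
  key <- mutation_site_key(catalog)
  if (is.null(neoantigen_keys)) {
    neoantigen_keys <- unique(key[catalog$n_neoantigens > 0])
  }
  keep <- key %in% neoantigen_keys
  tab <- table(site = key[keep], sector = catalog$sector_id[keep])
  if (!nrow(tab)) {
    return(list(clonal = 0L, subclonal = 0L, total = 0L,
                sites = data.frame(site = character(0), n_sectors_present = integer(0),
                                   clonal = logical(0))))
  }
  present <- rowSums(tab > 0)
  clonal <- present == length(secs)
  list(clonal = sum(clonal), subclonal = sum(!clonal), total = length(present),
       sites = data.frame(site = rownames(tab),
                          n_sectors_present = as.integer(present),
                          clonal = as.logical(clonal), row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Empirical trinucleotide mutational spectrum
#'
#' @param records Mutation table with a `context` column over the
#'   96-category alphabet of [trinucleotide_contexts()].
#' @return Named numeric vector of length 96 summing to 1.
#' @export
estimate_spectrum <- function(records) {
  if (!nrow(records)) stop("cannot estimate a spectrum from zero mutations", call. = FALSE)
  ctx96 <- trinucleotide_contexts()
  bad <- setdiff(unique(records$context), ctx96)
  if (length(bad)) {
    stop(sprintf("unknown trinucleotide context(s): %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  counts <- table(factor(records$context, levels = ctx96))
  stats::setNames(as.numeric(counts) / sum(counts), ctx96)
}

#' Immunoediting score (observed over expected neoantigenic mutations)
#'
#' The expected count is built from the empirical mutational spectrum: for
#' each trinucleotide context c, `p(c)` is the cohort-wide fraction of
#' non-silent mutations in context c that carry at least one predicted
#' neoantigen, estimated leave-one-out (all mutations of the sample's
#' patient are excluded from the background). With `f(c)` the sample's own
#' spectrum over its non-silent mutations,
#' `expected = N_nonsilent * sum_c f(c) p(c)`; the score is
#' `observed / expected` where observed is the sample's count of
#' neoantigen-bearing non-silent sites. A score below 1 indicates depletion
#' of neoantigens relative to the mutational process (immunoediting).
#' Contexts absent from the background get add-one smoothing
#' `p(c) = (k + 1) / (n + 2)`.
#'
#' @param sample_records Mutation rows of the scored unit (a sector or a
#'   patient); sites are deduplicated within this scope.
#' @param cohort_records Mutation rows of the whole cohort (may include the
#'   sample's patient; it is excluded by `patient_id`).
#' @return List of class `editing_score`: `observed`, `expected`, `ratio`,
#'   `neo_per_nonsilent`, `n_nonsilent`.
#' @export
immunoediting_score <- function(sample_records, cohort_records) {
  if (!nrow(sample_records)) stop("empty sample", call. = FALSE)
  check_classes(sample_records)
  check_classes(cohort_records)
  sample_pat <- unique(sample_records$patient_id)
  bg <- cohort_records[!(cohort_records$patient_id %in% sample_pat), , drop = FALSE]
  bg <- bg[!duplicated(paste(bg$patient_id, mutation_site_key(bg))), , drop = FALSE]
  bg <- bg[bg$class != "silent", , drop = FALSE]

  smp <- dedup_sites(sample_records)
  smp <- smp[smp$class != "silent", , drop = FALSE]
  n_ns <- nrow(smp)
  if (!n_ns) stop("sample has no non-silent mutations", call. = FALSE)

  ctx96 <- trinucleotide_contexts()
  bg_tot <- table(factor(bg$context, levels = ctx96))
  bg_neo <- table(factor(bg$context[bg$n_neoantigens > 0], levels = ctx96))
  n_c <- as.numeric(bg_tot)
  k_c <- as.numeric(bg_neo)
  p_c <- ifelse(n_c > 0, k_c / n_c, (k_c + 1) / (n_c + 2))
  names(p_c) <- ctx96

  f_c <- as.numeric(table(factor(smp$context, levels = ctx96))) / n_ns
  expected <- n_ns * sum(f_c * p_c)
  if (expected <= 0) stop("undefined immunoediting score: expected count is 0", call. = FALSE)
  observed <- sum(smp$n_neoantigens > 0)
  structure(list(observed = observed, expected = expected,
                 ratio = observed / expected,
                 neo_per_nonsilent = sum(smp$n_neoantigens) / n_ns,
                 n_nonsilent = n_ns),
            class = "editing_score")
}

#' @export
print.editing_score <- function(x, ...) {
  cat(sprintf("Immunoediting score: %d observed / %.2f expected = %.3f (neo/non-silent %.3f)\n",
              x$observed, x$expected, x$ratio, x$neo_per_nonsilent))
  invisible(x)
}

#' Per-sector immunoediting scores for a whole cohort
#'
#' @param mutations Cohort mutation table.
#' @param level `"sector"` (one score per tumour sector, the unit plotted
#'   in the source analyses) or `"patient"`.
#' @return Data frame with ids, `observed`, `expected`, `ratio`,
#'   `neo_per_nonsilent`; units failing preconditions are skipped with a
#'   warning.
#' @export
cohort_editing_scores <- function(mutations, level = c("sector", "patient")) {
  level <- match.arg(level)
  units <- if (level == "sector") {
    unique(mutations[c("patient_id", "sector_id")])
  } else {
    data.frame(patient_id = unique(mutations$patient_id), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, , drop = FALSE]
    sel <- mutations$patient_id == u$patient_id
    if (level == "sector") sel <- sel & mutations$sector_id == u$sector_id
    es <- tryCatch(immunoediting_score(mutations[sel, , drop = FALSE], mutations),
                   error = function(e) {
                     warning(sprintf("%s skipped: %s", paste(unlist(u), collapse = "/"),
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (is.null(es)) return(NULL)
    cbind(u, data.frame(observed = es$observed, expected = es$expected,
                        ratio = es$ratio, neo_per_nonsilent = es$neo_per_nonsilent,
                        n_nonsilent = es$n_nonsilent))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(units[0, , drop = FALSE],
                 data.frame(observed = integer(0), expected = numeric(0),
                            ratio = numeric(0), neo_per_nonsilent = numeric(0),
                            n_nonsilent = integer(0)))
  }
  rownames(out) <- NULL
  out
}

#' Call HLA loss of heterozygosity from allele minor copy numbers
#'
#' A sector has HLA-LOH when any class-I allele's minor copy number is
#' strictly below 0.5; a patient has an HLA-LOH event when any sector does.
#'
#' @param hla Table with columns `patient_id`, `sector_id`, `allele`,
#'   `minor_cn` (>= 0).
#' @param threshold LOH threshold on the minor allele copy number
#'   (strict `<`; default 0.5).
#' @return List with data frames `sectors` (patient_id, sector_id, min_minor_cn,
#'   loh) and `patients` (patient_id, loh).
#' @export
call_hla_loh <- function(hla, threshold = 0.5) {
  assert_columns(hla, c("patient_id", "sector_id", "allele", "minor_cn"), "HLA table")
  if (any(hla$minor_cn < 0)) stop("negative minor allele copy number", call. = FALSE)
  key <- sample_key(hla$patient_id, hla$sector_id)
  mins <- tapply(hla$minor_cn, key, min)
  ids <- do.call(rbind, strsplit(names(mins), "_(?=[^_]+$)", perl = TRUE))
  sectors <- data.frame(patient_id = ids[, 1], sector_id = ids[, 2],
                        min_minor_cn = as.numeric(mins),
                        loh = as.numeric(mins) < threshold,
                        row.names = NULL, stringsAsFactors = FALSE)
  pat_loh <- tapply(sectors$loh, sectors$patient_id, any)
  patients <- data.frame(patient_id = names(pat_loh), loh = as.logical(pat_loh),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(sectors = sectors, patients = patients)
}

#' Altered genome fraction of a segmented copy-number profile
#'
#' The reference ploidy is the length-weighted median of the integer copy
#' number (ties resolve to the lower CN); the fraction is the total length
#' of segments whose CN differs from it, over the total segment length.
#' Invariant under splitting a segment into adjacent pieces of equal CN.
#'
#' @param segments Segment table for one sector with columns `start`,
#'   `end` (1-based inclusive), `integer_cn`.
#' @return Fraction in [0, 1].
#' @export
altered_genome_fraction <- function(segments) {
  if (!nrow(segments)) stop("empty segment profile", call. = FALSE)
  len <- segments$end - segments$start + 1
  if (any(len <= 0)) stop("segment with start > end", call. = FALSE)
  med <- weighted_median_cn(segments$integer_cn, len)
  sum(len[segments$integer_cn != med]) / sum(len)
}

#' Per-sector altered genome fractions for a cohort
#'
#' @param segments Cohort segment table (`patient_id`, `sector_id`, ...).
#' @return Data frame `patient_id`, `sector_id`, `altered_fraction`.
#' @export
cohort_altered_fraction <- function(segments) {
  units <- unique(segments[c("patient_id", "sector_id")])
  units$altered_fraction <- vapply(seq_len(nrow(units)), function(i) {
    sel <- segments$patient_id == units$patient_id[i] &
      segments$sector_id == units$sector_id[i]
    altered_genome_fraction(segments[sel, , drop = FALSE])
  }, numeric(1))
  rownames(units) <- NULL
  units
}

# Length-weighted mean integer CN of the segments overlapping one band;
# NA when nothing overlaps.
band_mean_cn <- function(segments, band) {
  sel <- segments$chrom == band$chrom &
    segments$end >= band$start & segments$start <= band$end
  if (!any(sel)) return(NA_real_)
  s <- segments[sel, , drop = FALSE]
  ov <- pmin(s$end, band$end) - pmax(s$start, band$start) + 1
  sum(s$integer_cn * ov) / sum(ov)
}

#' Cytoband-level CNV comparison between ITH groups
#'
#' Per sector and band, the band is called deleted / neutral / amplified by
#' comparing its length-weighted mean integer CN with the sector's own
#' length-weighted median CN (ploidy proxy). Per band and direction, a
#' two-sided Fisher's exact test compares event counts between low and
#' high ITH sectors, with Benjamini-Hochberg adjustment across bands
#' within each direction.
#'
#' @param segments Cohort segment table.
#' @param cytobands Band table (`chrom`, `start`, `end`, `band_name`),
#'   1-based inclusive, e.g. [synthetic_cytobands()].
#' @param groups Patient group assignment from [assign_ith_groups()].
#' @return Data frame per band and direction (`band_name`, `direction`,
#'   event counts per group, `p`, `q`).
#' @export
cytoband_cnv_comparison <- function(segments, cytobands, groups) {
  assert_columns(cytobands, c("chrom", "start", "end", "band_name"), "cytoband table")
  units <- unique(segments[c("patient_id", "sector_id")])
  units$group <- groups$group[match(units$patient_id, groups$patient_id)]
  units <- units[!is.na(units$group), , drop = FALSE]
  if (!all(c("low", "high") %in% units$group)) {
    stop("both ITH groups must contribute sectors", call. = FALSE)
  }

  status <- matrix(NA_character_, nrow(units), nrow(cytobands),
                   dimnames = list(NULL, cytobands$band_name))
  for (i in seq_len(nrow(units))) {
    sel <- segments$patient_id == units$patient_id[i] &
      segments$sector_id == units$sector_id[i]
    seg <- segments[sel, , drop = FALSE]
    med <- weighted_median_cn(seg$integer_cn, seg$end - seg$start + 1)
    for (b in seq_len(nrow(cytobands))) {
      cn <- band_mean_cn(seg, cytobands[b, ])
      status[i, b] <- if (is.na(cn)) NA_character_
        else if (cn < med) "deleted" else if (cn > med) "amplified" else "neutral"
    }
  }

  res <- list()
  for (direction in c("deleted", "amplified")) {
    p <- rep(NA_real_, nrow(cytobands))
    tallies <- matrix(NA_integer_, nrow(cytobands), 4)
    for (b in seq_len(nrow(cytobands))) {
      st <- status[, b]
      ok <- !is.na(st)
      if (!any(ok)) next  # band with no overlapping segment anywhere: excluded
      ev <- st[ok] == direction
      gr <- units$group[ok]
      tab <- table(factor(ev, levels = c(TRUE, FALSE)),
                   factor(gr, levels = c("high", "low")))
      p[b] <- stats::fisher.test(tab)$p.value
      tallies[b, ] <- c(tab)
    }
    keep <- !is.na(p)
    res[[direction]] <- data.frame(
      band_name = cytobands$band_name[keep], direction = direction,
      n_event_high = tallies[keep, 1], n_other_high = tallies[keep, 2],
      n_event_low = tallies[keep, 3], n_other_low = tallies[keep, 4],
      p = p[keep], q = stats::p.adjust(p[keep], method = "BH"),
      stringsAsFactors = FALSE)
  }
  out <- rbind(res$deleted, res$amplified)
  rownames(out) <- NULL
  out
}

#' Stratified immunoediting comparison across ITH group x HLA status
#'
#' Crosses the low/high ITH grouping with patient HLA-LOH status and, per
#' stratum, tests for neoantigen depletion by comparing the stratum's total
#' observed neoantigenic-mutation count with its total expected count
#' (one-sided Poisson test, alternative "less"). The aggregate count test
#' is used because per-sector ratios are pseudo-replicated (a patient's
#' trunk mutations recur in every sector) and right-skewed at small
#' mutation counts, so a rank test on them is anti-conservative; use
#' patient-level scores (see [cohort_editing_scores()]) for a calibrated
#' test. The spec'd between-stratum two-sided rank-sum comparisons of the
#' ratio and of neoantigens-per-non-silent are also emitted. Empty strata
#' are skipped with a warning.
#'
#' @param scores Score table from [cohort_editing_scores()]; patient level
#'   recommended for the depletion test.
#' @param groups Patient group assignment from [assign_ith_groups()].
#' @param hla_patients Patient-level HLA table from [call_hla_loh()]
#'   (`$patients`).
#' @return List with `strata` (per-stratum n, observed/expected totals,
#'   median ratio, depletion p) and `pairwise` (between-stratum rank-sum
#'   p-values).
#' @export
stratified_editing_comparison <- function(scores, groups, hla_patients) {
  scores$group <- groups$group[match(scores$patient_id, groups$patient_id)]
  scores$hla <- ifelse(hla_patients$loh[match(scores$patient_id,
                                              hla_patients$patient_id)],
                       "loh", "intact")
  scores <- scores[!is.na(scores$group) & !is.na(scores$hla), , drop = FALSE]
  scores$stratum <- paste(scores$group, scores$hla, sep = "/")
  all_strata <- as.vector(outer(c("low", "high"), c("intact", "loh"), paste, sep = "/"))

  strata <- do.call(rbind, lapply(all_strata, function(st) {
    d <- scores[scores$stratum == st, , drop = FALSE]
    if (!nrow(d)) {
      warning(sprintf("stratum %s is empty; skipped", st), call. = FALSE)
      return(data.frame(stratum = st, n = 0L, observed = NA_real_,
                        expected = NA_real_, median_ratio = NA_real_,
                        depletion_p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- if (nrow(d) >= 2 && sum(d$expected) > 0) {
      stats::poisson.test(sum(d$observed), sum(d$expected),
                          alternative = "less")$p.value
    } else NA_real_
    data.frame(stratum = st, n = nrow(d), observed = sum(d$observed),
               expected = sum(d$expected),
               median_ratio = stats::median(d$ratio),
               depletion_p = p, stringsAsFactors = FALSE)
  }))

  present <- unique(scores$stratum)
  prs <- if (length(present) >= 2) utils::combn(sort(present), 2, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(prs, function(pr) {
    a <- scores[scores$stratum == pr[1], ]
    b <- scores[scores$stratum == pr[2], ]
    data.frame(
      stratum_a = pr[1], stratum_b = pr[2],
      p_ratio = suppressWarnings(stats::wilcox.test(a$ratio, b$ratio))$p.value,
      p_neo_per_nonsilent = suppressWarnings(
        stats::wilcox.test(a$neo_per_nonsilent, b$neo_per_nonsilent))$p.value,
      stringsAsFactors = FALSE)
  })) %||% data.frame(stratum_a = character(0), stratum_b = character(0),
                      p_ratio = numeric(0), p_neo_per_nonsilent = numeric(0))
  list(strata = strata, pairwise = pairwise)
}
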