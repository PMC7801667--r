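# Shared tiny fixtures built in code.

make_profiles <- function(..., subsets = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- subsets %||% paste0("sub", seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_mutations <- function(sets, patient_id = "P01") {
  # sets: named list sector -> character vector of site ids; each id becomes
  # a synthetic (chrom, pos) pair
  all_sites <- unique(unlist(sets))
  pos <- stats::setNames(seq_along(all_sites) * 101, all_sites)
  do.call(rbind, lapply(names(sets), function(s) {
    if (!length(sets[[s]])) return(NULL)
    data.frame(patient_id = patient_id, sector_id = s, chrom = "chr1",
               pos = unname(pos[sets[[s]]]), ref = "C", alt = "T",
               class = "missense", context = "A[C>T]G",
               n_neoantigens = 1L, min_ic50_nm = 100,
               stringsAsFactors = FALSE)
  }))
}

# a config with planted gene sets shrunk to fit small n_genes
light_config <- function(n_patients, seed, n_genes = 40, ...) {
  cohort_config(n_patients = n_patients, seed = seed, n_genes = n_genes,
                n_deg = 5, n_coupled = 2, n_immune_genes = 3, ...)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(n_patients = 8, seed = 42,
                                              n_genes = 120, n_deg = 10,
                                              n_coupled = 4, n_immune_genes = 6))
    }
    cache
  }
})
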