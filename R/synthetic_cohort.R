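# Synthetic multi-sector cohort generator with ground truth.
#
# Emulates a hepatocellular-carcinoma-style multi-region profiling study:
# each patient contributes 2-5 spatially distinct tumour sectors, each with
# an immune composition (15 CyTOF-style subsets), a gene-expression profile,
# a somatic mutation catalogue with trinucleotide context and neoantigen
# annotation, arm-level copy-number segments, HLA allele copy numbers,
# in-tissue cell densities and clinical outcome. A single per-patient
# heterogeneity dial h controls how divergent the sectors are in every
# data layer, giving known ground truth for parameter-recovery tests.

#' Configuration for the synthetic cohort generator
#'
#' All arguments have defaults chosen to emulate a ~28-patient multi-sector
#' liver-cancer cohort. The per-patient heterogeneity dial `h` scales
#' sector-to-sector dispersion in the immune, expression, mutation and
#' copy-number layers simultaneously.
#'
#' @param n_patients Number of patients.
#' @param sectors_range Integer interval (length 2) of sectors per patient,
#'   sampled uniformly; default 2..5.
#' @param n_subsets Number of immune subsets in the composition (default 15).
#' @param n_genes Number of genes in the expression matrix.
#' @param n_trunk_mutations Clonal (trunk) mutations per patient, present in
#'   every sector.
#' @param subclonal_rate Expected private mutations per sector per unit h
#'   (Poisson rate multiplier).
#' @param h Optional fixed heterogeneity dial; if `NULL` each patient draws
#'   h log-uniformly from `h_range`.
#' @param h_range Range of the log-uniform dial draw.
#' @param editing_factor Multiplier in (0, 1] applied to the per-context
#'   neoantigen probability of "edited" patients (low-ITH, HLA-intact);
#'   1 disables immunoediting.
#' @param loh_probability Baseline per-patient probability of an HLA-LOH
#'   event; low-dial patients get 1.5x this, high-dial patients 0.5x.
#' @param hazard_ratio True recurrence hazard ratio of the high-ITH half of
#'   the cohort relative to the low half.
#' @param censoring_rate Approximate fraction of patients censored.
#' @param seed Integer seed; drives per-patient substreams so adding a
#'   patient never perturbs earlier patients.
#' @param n_deg Planted differentially expressed genes per direction
#'   (up-in-high and up-in-low).
#' @param n_coupled Planted immune-coupled genes (alternating sign).
#' @param n_immune_genes Genes designated as immune-lineage (the
#'   deconvolution-style exclusion list consumed by [filter_immune_genes()]).
#' @param deg_shift Additive log-scale expression shift of planted DEGs
#'   between ITH groups.
#' @param sigma_expr Sector-level expression noise SD per unit sqrt(h).
#' @param gene_sd SD of gene baseline means across genes.
#' @param dirichlet_k Immune composition precision; sector proportions are
#'   Dirichlet with concentration `dirichlet_k / h * baseline`.
#' @param class_probs Probabilities of mutation classes
#'   (silent, missense, nonsense).
#' @param neo_context_probs Length-96 vector of per-context neoantigen
#'   probabilities for non-silent mutations; default a linear ramp
#'   0.05..0.25 over [trinucleotide_contexts()].
#' @param coupling_b,coupling_sd Effect size and noise SD of the planted
#'   gene-to-subset couplings (defaults give Spearman rho near 0.7).
#' @param baseline_hazard Recurrence hazard per month of the low-ITH group.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 28L,
                          sectors_range = c(2L, 5L),
                          n_subsets = 15L,
                          n_genes = 500L,
                          n_trunk_mutations = 50L,
                          subclonal_rate = 30,
                          h = NULL,
                          h_range = c(0.01, 6),
                          editing_factor = 0.5,
                          loh_probability = 0.3,
                          hazard_ratio = 2,
                          censoring_rate = 0.2,
                          seed = 1L,
                          n_deg = 50L,
                          n_coupled = 12L,
                          n_immune_genes = 30L,
                          deg_shift = 1.2,
                          sigma_expr = 1,
                          gene_sd = 1.5,
                          dirichlet_k = 60,
                          class_probs = c(silent = 0.3, missense = 0.6, nonsense = 0.1),
                          neo_context_probs = NULL,
                          coupling_b = 1.15,
                          coupling_sd = 1,
                          baseline_hazard = log(2) / 20) {
  cfg <- list(
    n_patients = as.integer(n_patients), sectors_range = as.integer(sectors_range),
    n_subsets = as.integer(n_subsets), n_genes = as.integer(n_genes),
    n_trunk_mutations = as.integer(n_trunk_mutations),
    subclonal_rate = subclonal_rate, h = h, h_range = h_range,
    editing_factor = editing_factor, loh_probability = loh_probability,
    hazard_ratio = hazard_ratio, censoring_rate = censoring_rate,
    seed = as.integer(seed), n_deg = as.integer(n_deg),
    n_coupled = as.integer(n_coupled), n_immune_genes = as.integer(n_immune_genes),
    deg_shift = deg_shift, sigma_expr = sigma_expr, gene_sd = gene_sd,
    dirichlet_k = dirichlet_k, class_probs = class_probs,
    neo_context_probs = neo_context_probs %||%
      seq(0.05, 0.25, length.out = 96),
    coupling_b = coupling_b, coupling_sd = coupling_sd,
    baseline_hazard = baseline_hazard
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop_config("n_patients", "must be >= 0")
  if (length(cfg$sectors_range) != 2L || any(cfg$sectors_range < 1L) ||
      cfg$sectors_range[1] > cfg$sectors_range[2]) {
    stop_config("sectors_range", "must be an increasing integer interval with min >= 1")
  }
  for (f in c("n_subsets", "n_genes", "n_trunk_mutations")) {
    if (cfg[[f]] < 1L) stop_config(f, "must be >= 1")
  }
  if (cfg$subclonal_rate < 0) stop_config("subclonal_rate", "must be >= 0")
  if (!is.null(cfg$h)) {
    if (any(cfg$h <= 0)) stop_config("h", "must be > 0")
    if (!length(cfg$h) %in% c(1L, cfg$n_patients)) {
      stop_config("h", "must have length 1 or n_patients")
    }
  }
  if (any(cfg$h_range <= 0) || cfg$h_range[1] > cfg$h_range[2]) {
    stop_config("h_range", "must be a positive increasing interval")
  }
  if (cfg$editing_factor <= 0 || cfg$editing_factor > 1) {
    stop_config("editing_factor", "must be in (0, 1]")
  }
  if (cfg$loh_probability < 0 || cfg$loh_probability > 1) {
    stop_config("loh_probability", "must be in [0, 1]")
  }
  if (cfg$hazard_ratio <= 0) stop_config("hazard_ratio", "must be > 0")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stop_config("censoring_rate", "must be in [0, 1)")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-8 || any(cfg$class_probs < 0)) {
    stop_config("class_probs", "must be non-negative and sum to 1")
  }
  if (length(cfg$neo_context_probs) != 96L ||
      any(cfg$neo_context_probs < 0) || any(cfg$neo_context_probs > 1)) {
    stop_config("neo_context_probs", "must be 96 probabilities in [0, 1]")
  }
  invisible(cfg)
}

# CyTOF-style immune subset labels (fractions of CD45+ cells).
immune_subset_names <- function(n) {
  base <- c("CD8_T", "CD4_T", "Treg", "B_cells", "Plasma_cells", "NK", "NKT",
            "MAIT", "Gamma_delta_T", "Monocytes", "Macrophages", "DC",
            "Neutrophils", "Mast_cells", "ILC")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("Subset_", seq_len(n - length(base))))
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# Arm-level synthetic chromosome scaffold (Mb-scale lengths, hg-like order).
chrom_scaffold <- function() {
  len <- c(248, 243, 198, 190, 182, 171, 159, 146, 141, 136, 135, 133,
           114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6
  data.frame(
    chrom = paste0("chr", seq_along(len)),
    length = len,
    centromere = round(len * 0.4),
    stringsAsFactors = FALSE
  )
}

#' Arm-level cytoband table matching the synthetic genome scaffold
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `band_name`
#'   (1-based inclusive coordinates), two bands (p and q arm) per chromosome.
#' @export
synthetic_cytobands <- function() {
  sc <- chrom_scaffold()
  num <- sub("chr", "", sc$chrom)
  rbind(
    data.frame(chrom = sc$chrom, start = 1, end = sc$centromere,
               band_name = paste0(num, "p"), stringsAsFactors = FALSE),
    data.frame(chrom = sc$chrom, start = sc$centromere + 1, end = sc$length,
               band_name = paste0(num, "q"), stringsAsFactors = FALSE)
  )
}

#' Generate a synthetic multi-sector cohort with ground truth
#'
#' Draws, per patient, a heterogeneity dial h and 2-5 tumour sectors whose
#' immune composition, expression, mutation, copy-number, HLA, density and
#' outcome layers all disperse with h (see the methods vignette for the
#' full generative model). Determinism: the same config (same seed) always
#' yields an identical cohort, and per-patient substreams mean earlier
#' patients are unchanged when `n_patients` grows.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `bundle` (class `cohort_bundle`: data frames
#'   `immune`, `mutations`, `segments`, `hla`, `densities`, `clinical`, an
#'   `expression` matrix, and the `config`) and `truth` (per-patient dial,
#'   ITH group, edited/LOH flags, per-mutation clonality, planted gene sets
#'   and network edges, true hazard ratio).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  ctx96 <- trinucleotide_contexts()
  subsets <- immune_subset_names(cfg$n_subsets)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  scaffold <- chrom_scaffold()

  # planted gene architecture (deterministic, not seed-dependent)
  n_deg_tot <- 2L * cfg$n_deg + cfg$n_coupled + cfg$n_immune_genes
  if (n_deg_tot > cfg$n_genes) stop_config("n_genes", "too small for planted gene sets")
  deg_up_low <- genes[seq_len(cfg$n_deg)]
  deg_up_high <- genes[cfg$n_deg + seq_len(cfg$n_deg)]
  coupled <- genes[2L * cfg$n_deg + seq_len(cfg$n_coupled)]
  immune_genes <- genes[2L * cfg$n_deg + cfg$n_coupled + seq_len(cfg$n_immune_genes)]
  coupled_subset <- subsets[((seq_len(cfg$n_coupled) - 1L) %% min(6L, cfg$n_subsets)) + 1L]
  coupled_sign <- ifelse(seq_len(cfg$n_coupled) %% 2L == 1L, 1, -1)

  # gene baseline means are a deterministic function of the seed only
  set.seed(patient_seed(cfg$seed, 0L, 9L))
  gene_mu <- stats::rnorm(cfg$n_genes, mean = 6, sd = cfg$gene_sd)
  names(gene_mu) <- genes

  pids <- sprintf("P%02d", seq_len(cfg$n_patients))

  per <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i, 0L))
    n_sec <- sample(seq(cfg$sectors_range[1], cfg$sectors_range[2]), 1L)
    h <- if (is.null(cfg$h)) {
      exp(stats::runif(1, log(cfg$h_range[1]), log(cfg$h_range[2])))
    } else if (length(cfg$h) == 1L) cfg$h else cfg$h[i]
    secs <- sprintf("S%d", seq_len(n_sec))

    ## immune composition
    baseline <- rdirichlet1(rep(2, cfg$n_subsets))
    props <- vapply(seq_len(n_sec), function(s) {
      rdirichlet1(pmax(cfg$dirichlet_k / h * baseline, 1e-3))
    }, numeric(cfg$n_subsets))
    dimnames(props) <- list(subsets, secs)

    ## expression: baseline + sector noise; planted DEG genes also carry a
    ## patient-level effect (tumour-intrinsic programme), all other genes are
    ## independent sector noise so they are exact nulls for edge calibration
    pat_eff <- stats::rnorm(cfg$n_genes, 0, 0.5)
    planted <- c(deg_up_low, deg_up_high)
    pat_eff[!(genes %in% planted)] <- 0
    noise <- matrix(stats::rnorm(cfg$n_genes * n_sec, 0, cfg$sigma_expr * sqrt(h)),
                    cfg$n_genes, n_sec)
    expr <- gene_mu + pat_eff + noise
    dimnames(expr) <- list(genes, paste(pids[i], secs, sep = "_"))
    # planted couplings replace the patient effect with a subset-driven term
    for (k in seq_along(coupled)) {
      z <- (props[coupled_subset[k], ] - 1 / cfg$n_subsets) / 0.05
      expr[coupled[k], ] <- gene_mu[coupled[k]] +
        coupled_sign[k] * cfg$coupling_b * z +
        stats::rnorm(n_sec, 0, cfg$coupling_sd)
    }

    ## mutations: trunk (all sectors) + private (one sector each)
    n_priv <- stats::rpois(n_sec, cfg$subclonal_rate * h)
    n_mut <- cfg$n_trunk_mutations + sum(n_priv)
    ctx_i <- sample(ctx96, n_mut, replace = TRUE)
    cls_i <- sample(names(cfg$class_probs), n_mut, replace = TRUE, prob = cfg$class_probs)
    chrom_i <- sample(scaffold$chrom, n_mut, replace = TRUE)
    pos_i <- floor(stats::runif(n_mut, 1, scaffold$length[match(chrom_i, scaffold$chrom)]))
    ref_i <- substr(ctx_i, 3, 3)
    alt_i <- substr(ctx_i, 5, 5)
    site_i <- paste(chrom_i, pos_i, ref_i, alt_i, sep = ":")
    clonal_i <- rep(c(TRUE, FALSE), c(cfg$n_trunk_mutations, sum(n_priv)))
    sector_of_private <- rep(secs, n_priv)

    ## copy number: two arm segments per chromosome, aberrant prob grows with h
    p_ab <- min(0.6, 0.05 + 0.25 * h)
    n_arms <- 2L * nrow(scaffold)
    seg <- data.frame(
      patient_id = pids[i],
      sector_id = rep(secs, each = n_arms),
      chrom = rep(rep(scaffold$chrom, 2L), n_sec),
      start = rep(c(rep(1, nrow(scaffold)), scaffold$centromere + 1), n_sec),
      end = rep(c(scaffold$centromere, scaffold$length), n_sec),
      stringsAsFactors = FALSE
    )
    ab <- stats::runif(nrow(seg)) < p_ab
    cn <- ifelse(ab, sample(c(1L, 3L, 4L), nrow(seg), replace = TRUE,
                            prob = c(0.5, 0.35, 0.15)), 2L)
    seg$integer_cn <- cn
    seg$minor_cn <- ifelse(cn <= 1L, 0, 1)

    per[[i]] <- list(pid = pids[i], h = h, secs = secs, props = props,
                     expr = expr, ctx = ctx_i, cls = cls_i, site = site_i,
                     chrom = chrom_i, pos = pos_i, ref = ref_i, alt = alt_i,
                     clonal = clonal_i, sector_of_private = sector_of_private,
                     seg = seg)
  }

  h_all <- vapply(per, `[[`, numeric(1), "h")
  names(h_all) <- pids
  grp <- if (length(h_all)) {
    ifelse(h_all <= stats::median(h_all), "low", "high")  # ties to low (median split)
  } else {
    character(0)
  }

  ## second pass: HLA-LOH flags (elevated in low-dial patients)
  loh <- logical(cfg$n_patients)
  hla_rows <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i, 1L))
    p_loh <- min(1, cfg$loh_probability * if (grp[i] == "low") 1.5 else 0.5)
    loh[i] <- stats::runif(1) < p_loh
    lost <- sample(c("HLA-A", "HLA-B", "HLA-C"), 1L)
    for (s in per[[i]]$secs) {
      minor <- stats::runif(3, 0.8, 1.2)
      names(minor) <- c("HLA-A", "HLA-B", "HLA-C")
      if (loh[i]) minor[lost] <- stats::runif(1, 0, 0.45)
      hla_rows[[length(hla_rows) + 1L]] <- data.frame(
        patient_id = pids[i], sector_id = s,
        allele = names(minor), minor_cn = unname(minor),
        stringsAsFactors = FALSE)
    }
  }
  names(loh) <- pids
  edited <- grp == "low" & !loh
  names(edited) <- pids

  ## third pass: neoantigen assignment (depends on edited flag), densities,
  ## group-dependent expression shifts, clinical outcome
  mut_rows <- list()
  dens_rows <- list()
  clin_rows <- list()
  p_ctx <- cfg$neo_context_probs
  names(p_ctx) <- ctx96
  dens_types <- intersect(c("CD4_T", "CD8_T", "Treg"), subsets)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i, 2L))
    pp <- per[[i]]
    f_edit <- if (edited[i]) cfg$editing_factor else 1
    nonsilent <- pp$cls != "silent"
    p_neo <- ifelse(nonsilent, p_ctx[pp$ctx] * f_edit, 0)
    has_neo <- stats::runif(length(p_neo)) < p_neo
    n_neo <- ifelse(has_neo, 1L + stats::rpois(length(p_neo), 0.7), 0L)
    ic50 <- ifelse(has_neo, stats::runif(length(p_neo), 10, 499), NA_real_)

    site_sector <- ifelse(pp$clonal, NA_character_, pp$sector_of_private)
    for (s in pp$secs) {
      keep <- pp$clonal | (!is.na(site_sector) & site_sector == s)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        patient_id = pp$pid, sector_id = s,
        chrom = pp$chrom[keep], pos = pp$pos[keep],
        ref = pp$ref[keep], alt = pp$alt[keep],
        class = pp$cls[keep], context = pp$ctx[keep],
        n_neoantigens = n_neo[keep], min_ic50_nm = ic50[keep],
        stringsAsFactors = FALSE)
    }

    for (s in pp$secs) {
      d <- 2000 * pp$props[dens_types, s] + stats::rnorm(length(dens_types), 0, 15)
      dens_rows[[length(dens_rows) + 1L]] <- data.frame(
        patient_id = pp$pid, region_id = s,
        cell_type = dens_types, density_per_mm2 = pmax(0, unname(d)),
        stringsAsFactors = FALSE)
    }

    # planted DEG shift with the ITH group (applied to all sectors)
    shift <- if (grp[i] == "high") cfg$deg_shift else -cfg$deg_shift
    per[[i]]$expr[deg_up_high, ] <- per[[i]]$expr[deg_up_high, ] + shift / 2
    per[[i]]$expr[deg_up_low, ] <- per[[i]]$expr[deg_up_low, ] - shift / 2
    per[[i]]$expr[coupled, ] <- per[[i]]$expr[coupled, ] + shift / 2

    haz <- cfg$baseline_hazard * if (grp[i] == "high") cfg$hazard_ratio else 1
    t_event <- stats::rexp(1, haz)
    cens_haz <- cfg$baseline_hazard * cfg$censoring_rate / max(1e-9, 1 - cfg$censoring_rate)
    t_cens <- if (cfg$censoring_rate > 0) stats::rexp(1, cens_haz) else Inf
    stage_p <- if (grp[i] == "high") c(0.25, 0.40, 0.35) else c(0.50, 0.35, 0.15)
    clin_rows[[length(clin_rows) + 1L]] <- data.frame(
      patient_id = pp$pid,
      time_months = max(round(min(t_event, t_cens), 3), 0.001),
      event = as.integer(t_event <= t_cens),
      stage = sample(c("I", "II", "III"), 1L, prob = stage_p),
      mvi = stats::rbinom(1, 1, if (grp[i] == "high") 0.55 else 0.30),
      size_cm = round(stats::rlnorm(1, log(if (grp[i] == "high") 4.5 else 3), 0.3), 1),
      stringsAsFactors = FALSE)
  }

  immune <- do.call(rbind, lapply(per, function(pp) {
    data.frame(
      patient_id = pp$pid,
      sector_id = rep(pp$secs, each = cfg$n_subsets),
      subset_name = rep(subsets, length(pp$secs)),
      proportion = as.vector(pp$props),
      stringsAsFactors = FALSE)
  })) %||% data.frame(patient_id = character(0), sector_id = character(0),
                      subset_name = character(0), proportion = numeric(0),
                      stringsAsFactors = FALSE)
  expression <- do.call(cbind, lapply(per, `[[`, "expr"))
  if (is.null(expression)) {
    expression <- matrix(numeric(0), nrow = cfg$n_genes, ncol = 0,
                         dimnames = list(genes, character(0)))
  }
  empty_mut <- data.frame(patient_id = character(0), sector_id = character(0),
                          chrom = character(0), pos = numeric(0), ref = character(0),
                          alt = character(0), class = character(0), context = character(0),
                          n_neoantigens = integer(0), min_ic50_nm = numeric(0),
                          stringsAsFactors = FALSE)
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else empty_mut
  segments <- do.call(rbind, lapply(per, `[[`, "seg")) %||%
    data.frame(patient_id = character(0), sector_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), integer_cn = integer(0),
               minor_cn = numeric(0), stringsAsFactors = FALSE)
  hla <- if (length(hla_rows)) do.call(rbind, hla_rows) else
    data.frame(patient_id = character(0), sector_id = character(0),
               allele = character(0), minor_cn = numeric(0), stringsAsFactors = FALSE)
  densities <- if (length(dens_rows)) do.call(rbind, dens_rows) else
    data.frame(patient_id = character(0), region_id = character(0),
               cell_type = character(0), density_per_mm2 = numeric(0),
               stringsAsFactors = FALSE)
  clinical <- if (length(clin_rows)) do.call(rbind, clin_rows) else
    data.frame(patient_id = character(0), time_months = numeric(0), event = integer(0),
               stage = character(0), mvi = integer(0), size_cm = numeric(0),
               stringsAsFactors = FALSE)
  rownames(immune) <- rownames(mutations) <- rownames(segments) <- NULL
  rownames(hla) <- rownames(densities) <- rownames(clinical) <- NULL

  clonality <- do.call(rbind, lapply(per, function(pp) {
    if (!length(pp$site)) return(NULL)
    data.frame(patient_id = pp$pid, site = pp$site, clonal = pp$clonal,
               stringsAsFactors = FALSE)
  }))

  bundle <- structure(list(
    immune = immune, expression = expression, mutations = mutations,
    segments = segments, hla = hla, densities = densities, clinical = clinical,
    subsets = subsets, config = cfg
  ), class = "cohort_bundle")

  truth <- list(
    h = h_all, ith_group = grp, edited = edited, loh = loh,
    clonality = clonality,
    deg_up_high = deg_up_high, deg_up_low = deg_up_low,
    coupled_genes = coupled, immune_genes = immune_genes,
    network_edges = data.frame(gene = coupled, subset = coupled_subset,
                               sign = ifelse(coupled_sign > 0, "positive", "negative"),
                               stringsAsFactors = FALSE),
    true_hazard_ratio = cfg$hazard_ratio,
    neo_context_probs = stats::setNames(p_ctx, ctx96)
  )

  list(bundle = bundle, truth = truth)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_pat <- length(unique(x$immune$patient_id))
  n_sec <- length(unique(sample_key(x$immune$patient_id, x$immune$sector_id)))
  cat("Multi-sector cohort bundle\n")
  cat(sprintf("  %d patients, %d tumour sectors\n", n_pat, n_sec))
  cat(sprintf("  %d immune subsets, %d genes, %d mutation rows\n",
              length(x$subsets), nrow(x$expression), nrow(x$mutations)))
  invisible(x)
}

#' Write a cohort bundle to a directory of plain-text tables
#'
#' Emits the immune proportions and density CSVs, expression/mutation/
#' segment/HLA TSVs, clinical CSV and a JSON manifest recording file names
#' and the generator seed. Output is re-loadable with [load_tables()].
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list(
    immune = "immune_proportions.csv", expression = "expression.tsv",
    mutations = "mutations.tsv", segments = "segments.tsv", hla = "hla.tsv",
    densities = "densities.csv", clinical = "clinical.csv"
  )
  wr <- function(df, path, sep) {
    tryCatch(utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE),
             error = function(e) stop(sprintf("failed writing '%s': %s", path,
                                              conditionMessage(e)), call. = FALSE))
  }
  wr(bundle$immune, file.path(dir, files$immune), ",")
  expr_df <- data.frame(gene = rownames(bundle$expression),
                        bundle$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wr(expr_df, file.path(dir, files$expression), "\t")
  wr(bundle$mutations, file.path(dir, files$mutations), "\t")
  wr(bundle$segments, file.path(dir, files$segments), "\t")
  wr(bundle$hla, file.path(dir, files$hla), "\t")
  wr(bundle$densities, file.path(dir, files$densities), ",")
  wr(bundle$clinical, file.path(dir, files$clinical), ",")
  manifest <- list(files = files, seed = bundle$config$seed,
                   n_patients = bundle$config$n_patients,
                   subsets = bundle$subsets)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
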