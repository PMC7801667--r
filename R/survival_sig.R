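# Kaplan-Meier / log-rank / Cox contracts and the ITH transcriptomic
# signature segregation with bootstrap FDR and leave-one-out stability.

as_surv_df <- function(records) {
  assert_columns(records, c("patient_id", "time_months", "event"), "survival records")
  if (any(records$time_months <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  records
}

#' Kaplan-Meier curves and log-rank test between two groups
#'
#' @param records Data frame with `patient_id`, `time_months` (> 0),
#'   `event` (1 event / 0 censored) and the grouping column.
#' @param group_field Name of the grouping column (two levels).
#' @return List of class `km_logrank`: `fit` (survfit), `chisq`, `df`,
#'   `p_value` (two-sided log-rank), `hazard_ratio` + `hr_ci` (from a
#'   single-covariate Cox fit), `groups`.
#' @export
km_logrank <- function(records, group_field = "group") {
  records <- as_surv_df(records)
  g <- factor(records[[group_field]])
  if (nlevels(g) < 2L) stop("need two groups for a log-rank test", call. = FALSE)
  if (nlevels(g) > 2L) stop("log-rank contract is two groups", call. = FALSE)
  if (sum(records$event) < 1) {
    stop("log-rank p undefined: all observations censored", call. = FALSE)
  }
  s <- survival::Surv(records$time_months, records$event)
  fit <- survival::survfit(s ~ g)
  sd_ <- survival::survdiff(s ~ g)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- tryCatch({
    cx <- suppressWarnings(survival::coxph(s ~ g, ties = "efron"))
    ci <- exp(stats::confint(cx))
    list(hr = unname(exp(stats::coef(cx))), ci = unname(ci[1, ]))
  }, error = function(e) list(hr = NA_real_, ci = c(NA_real_, NA_real_)))
  structure(list(fit = fit, chisq = unname(chisq), df = 1, p_value = p,
                 hazard_ratio = hr$hr, hr_ci = hr$ci, groups = levels(g)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.3f (df = %d), p = %.4g; HR[%s vs %s] = %.3f [%.3f, %.3f]\n",
              x$chisq, x$df, x$p_value, x$groups[2], x$groups[1],
              x$hazard_ratio, x$hr_ci[1], x$hr_ci[2]))
  invisible(x)
}

#' Kaplan-Meier step-function points per group
#'
#' @param km A `km_logrank` result.
#' @return Data frame `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curve_points <- function(km) {
  fit <- km$fit
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  data.frame(group = sub("^g=", "", strata), time = fit$time, surv = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event,
             stringsAsFactors = FALSE)
}

#' Cox proportional hazards model over clinical covariates
#'
#' Partial-likelihood fit with the Efron tie convention. Non-convergence or
#' inestimable (e.g. collinear) covariates raise an explicit error rather
#' than returning silent NAs.
#'
#' @param records Survival records (see [km_logrank()]) including the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return Data frame `term`, `coef`, `hr`, `ci_lo`, `ci_hi`, `p`.
#' @export
cox_model <- function(records, covariates) {
  records <- as_surv_df(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop(sprintf("unknown covariate(s): %s", paste(miss, collapse = ", ")),
                         call. = FALSE)
  if (sum(records$event) < length(covariates) + 1) {
    stop("too few events for the number of covariates", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        stop(sprintf("Cox model did not converge: %s", conditionMessage(w)),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop(sprintf("Cox model inestimable (collinear covariate?): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  ci <- exp(stats::confint(fit))
  sm <- summary(fit)$coefficients
  data.frame(term = names(cf), coef = unname(cf), hr = unname(exp(cf)),
             ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]),
             p = unname(sm[, "Pr(>|z|)"]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Segregate patients of an external cohort by the ITH signature
#'
#' Gene-wise z-scores across patients; each patient's `score_high` is the
#' mean z over up-in-high genes and `score_low` the mean over up-in-low
#' genes. Patients with `score_high - score_low > 0` are `"high-like"`,
#' else `"low-like"` (ties to low-like) — so sign-flipping the signature
#' exactly swaps the groups, and gene-wise affine rescaling of expression
#' leaves the assignment unchanged.
#'
#' @param expr Genes-x-patients expression matrix of the external cohort.
#' @param signature Data frame `gene`, `direction`
#'   (`"up_in_high"`/`"up_in_low"`), e.g. significant rows of
#'   [select_degs()].
#' @param min_genes Minimum matched signature genes (default 10); fewer is
#'   an error reporting the coverage.
#' @return Data frame `patient_id`, `score_high`, `score_low`, `group`,
#'   with attribute `coverage` (matched fraction of the signature).
#' @export
signature_segregate <- function(expr, signature, min_genes = 10L) {
  assert_columns(signature, c("gene", "direction"), "signature")
  matched <- intersect(signature$gene, rownames(expr))
  coverage <- length(matched) / nrow(signature)
  if (length(matched) < min_genes) {
    stop(sprintf("only %d/%d signature genes present (coverage %.1f%%); need >= %d",
                 length(matched), nrow(signature), 100 * coverage, min_genes),
         call. = FALSE)
  }
  sig <- signature[signature$gene %in% matched, ]
  z <- t(scale(t(expr[sig$gene, , drop = FALSE])))
  z[is.na(z)] <- 0  # constant genes carry no signal
  up_hi <- sig$gene[sig$direction == "up_in_high"]
  up_lo <- sig$gene[sig$direction == "up_in_low"]
  score_high <- if (length(up_hi)) colMeans(z[up_hi, , drop = FALSE]) else rep(0, ncol(expr))
  score_low <- if (length(up_lo)) colMeans(z[up_lo, , drop = FALSE]) else rep(0, ncol(expr))
  out <- data.frame(patient_id = colnames(expr),
                    score_high = unname(score_high), score_low = unname(score_low),
                    group = ifelse(score_high - score_low > 0, "high-like", "low-like"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "coverage") <- coverage
  out
}

#' Bootstrap false-discovery estimate of a signature's survival split
#'
#' Resamples patients with replacement B times; each replicate re-runs
#' [signature_segregate()] and the log-rank test on the distinct patients
#' drawn (duplicates are collapsed: a duplicated patient has identical
#' expression, hence an identical group call, and counting it several
#' times would pseudo-replicate the survival comparison and inflate the
#' null rejection rate). The FDR estimate is the fraction of replicates
#' that fail to separate survival (log-rank p at or above `alpha`);
#' degenerate replicates (a single group) count as failures.
#'
#' @param expr Genes-x-patients expression matrix.
#' @param signature Signature table (see [signature_segregate()]).
#' @param records Survival records keyed by `patient_id`.
#' @param B Number of bootstrap replicates (>= 100; the headline analysis
#'   convention is 1000).
#' @param alpha Log-rank significance threshold per replicate (default 0.05).
#' @return List: `fdr`, `B`, `n_failures`.
#' @export
bootstrap_fdr <- function(expr, signature, records, B = 1000L, alpha = 0.05) {
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  records <- as_surv_df(records)
  pats <- intersect(colnames(expr), records$patient_id)
  if (length(pats) < 10L) stop("need >= 10 patients with expression and outcome", call. = FALSE)
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- unique(sample(length(pats), replace = TRUE))
    ex <- expr[, pats[idx], drop = FALSE]
    seg <- tryCatch(signature_segregate(ex, signature), error = function(e) NULL)
    ok <- FALSE
    if (!is.null(seg) && length(unique(seg$group)) == 2L) {
      rec <- records[match(pats[idx], records$patient_id), ]
      rec$group <- seg$group
      p <- tryCatch(km_logrank(rec)$p_value, error = function(e) NA_real_)
      ok <- !is.na(p) && p < alpha
    }
    if (!ok) fails <- fails + 1L
  }
  list(fdr = fails / B, B = B, n_failures = fails)
}

#' Leave-one-patient-out stability of the DEG signature
#'
#' Re-runs the DEG selection with each patient's sectors held out and
#' reports the mean fraction of the full-cohort DEG set recovered per fold.
#'
#' @param expr Genes-x-sectors expression matrix.
#' @param groups Patient group assignment from [assign_ith_groups()].
#' @param deg_pipeline Function `(expr, groups) -> DEG table`; default
#'   [select_degs()] at FDR 0.01.
#' @return List: `consistency` (mean over folds), `per_fold` data frame,
#'   `n_full` (full-cohort DEG count).
#' @export
leave_one_out_stability <- function(expr, groups, deg_pipeline = NULL) {
  deg_pipeline <- deg_pipeline %||% function(e, g) select_degs(e, g)
  pats <- unique(groups$patient_id)
  by_grp <- table(groups$group)
  if (length(pats) < 3L || any(by_grp < 3L)) {
    stop("need >= 3 patients per group for leave-one-out", call. = FALSE)
  }
  full <- deg_pipeline(expr, groups)
  full_set <- full$gene[full$significant]
  if (!length(full_set)) {
    warning("no significant DEGs on the full cohort; consistency is NA", call. = FALSE)
  }
  rows <- lapply(pats, function(p) {
    keep_cols <- !startsWith(colnames(expr), paste0(p, "_"))
    g2 <- groups[groups$patient_id != p, , drop = FALSE]
    if (length(unique(g2$group)) < 2L) {
      warning(sprintf("fold %s leaves an empty group; skipped", p), call. = FALSE)
      return(NULL)
    }
    fold <- tryCatch(deg_pipeline(expr[, keep_cols, drop = FALSE], g2),
                     error = function(e) NULL)
    if (is.null(fold)) {
      warning(sprintf("fold %s failed; skipped", p), call. = FALSE)
      return(NULL)
    }
    fold_set <- fold$gene[fold$significant]
    data.frame(held_out = p,
               consistency = if (length(full_set))
                 length(intersect(fold_set, full_set)) / length(full_set)
               else NA_real_,
               n_degs = length(fold_set), stringsAsFactors = FALSE)
  })
  per_fold <- do.call(rbind, rows)
  list(consistency = mean(per_fold$consistency), per_fold = per_fold,
       n_full = length(full_set))
}
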