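# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 96 trinucleotide substitution categories
#'
#' Pyrimidine-collapsed single-base substitution contexts, written as
#' `"A[C>T]G"`: the central pyrimidine (`C` or `T`) mutates, flanked by one
#' base on each side. 6 substitution types x 16 flank combinations = 96.
#'
#' @return Character vector of length 96, in a fixed canonical order.
#' @export
trinucleotide_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

# Spearman rho between two numeric vectors, erroring on zero rank variance
# instead of propagating NA.
spearman_rho <- function(x, y, what = "vector") {
  if (length(x) != length(y)) {
    stop("spearman: length mismatch", call. = FALSE)
  }
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("undefined correlation: constant ", what, call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

# Length-weighted median of integer copy numbers; ties resolve to the lower
# CN so a half/half genome counts as altered.
weighted_median_cn <- function(cn, len) {
  stopifnot(length(cn) == length(len), all(len > 0))
  o <- order(cn)
  cn <- cn[o]
  len <- len[o]
  cum <- cumsum(len) / sum(len)
  cn[which(cum >= 0.5)[1]]
}

# Sample key "P01_S2" used to match sectors across tables.
sample_key <- function(patient_id, sector_id) paste(patient_id, sector_id, sep = "_")

# Per-patient deterministic substream seed derived from the global seed so
# that adding patients never perturbs earlier patients. `stream` separates
# independent passes over the same patient.
patient_seed <- function(seed, i, stream = 0L) {
  (abs(seed) %% 1000003L) * 1009L + i * 97L + stream * 31L
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}
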