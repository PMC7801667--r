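# Per-patient evolutionary trees of tumour sectors (plus the adjacent
# non-tumour sample) built by neighbour joining from DNA Hamming or
# RNA 1 - Spearman distance matrices.

#' DNA distance matrix (Hamming distance between mutational profiles)
#'
#' Builds the binary presence matrix of each sector over the union of
#' mutation sites and counts differing sites per sample pair. The adjacent
#' non-tumour sample, when included, is the all-reference (all-zero)
#' profile — somatic calls are tumour-vs-normal — making it the natural
#' outgroup.
#'
#' @param catalog Mutation table for one patient (`sector_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param include_nontumour Add the all-zero non-tumour profile (label `"N"`).
#' @return A symmetric labelled distance matrix (class `matrix`) with
#'   attribute `kind = "dna_hamming"`.
#' @export
dna_distance_matrix <- function(catalog, include_nontumour = TRUE) {
  assert_columns(catalog, c("sector_id", "chrom", "pos", "ref", "alt"),
                 "mutation catalog")
  secs <- unique(catalog$sector_id)
  if (length(secs) + include_nontumour < 2L) {
    stop("need >= 2 samples for a distance matrix", call. = FALSE)
  }
  key <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt, sep = ":")
  sites <- unique(key)
  prof <- vapply(secs, function(s) {
    as.numeric(sites %in% key[catalog$sector_id == s])
  }, numeric(length(sites)))
  prof <- matrix(prof, nrow = length(sites), dimnames = list(sites, secs))
  if (include_nontumour) prof <- cbind(prof, N = 0)
  labs <- colnames(prof)
  d <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      d[i, j] <- sum(prof[, i] != prof[, j])
    }
  }
  attr(d, "kind") <- "dna_hamming"
  d
}

#' RNA distance matrix (1 - Spearman correlation between samples)
#'
#' @param expr Genes-x-samples expression matrix (include the non-tumour
#'   column if a rooted tree is wanted).
#' @return A symmetric labelled distance matrix with attribute
#'   `kind = "rna_one_minus_spearman"`.
#' @export
rna_distance_matrix <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop("need >= 2 samples for a distance matrix", call. = FALSE)
  labs <- colnames(expr)
  d <- matrix(0, ncol(expr), ncol(expr), dimnames = list(labs, labs))
  for (i in seq_len(ncol(expr))) {
    for (j in seq_len(ncol(expr))) {
      if (i != j) {
        d[i, j] <- 1 - spearman_rho(expr[, i], expr[, j],
                                    sprintf("expression (%s/%s)", labs[i], labs[j]))
      }
    }
  }
  attr(d, "kind") <- "rna_one_minus_spearman"
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative estimated
#' branch lengths are clamped to zero, with the total clamped deficit
#' recorded in the `clamped_deficit` attribute and reported via a message.
#'
#' @param dm Symmetric non-negative labelled distance matrix with zero
#'   diagonal and >= 3 labels.
#' @return An unrooted `phylo` tree (leaf set = matrix labels).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3L) stop("need >= 3 labels for neighbour joining", call. = FALSE)
  if (any(dm < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (anyDuplicated(rownames(dm))) stop("labels must be unique", call. = FALSE)
  # stable label order so agglomeration ties break deterministically
  ord <- order(rownames(dm))
  tree <- ape::nj(dm[ord, ord, drop = FALSE])
  neg <- tree$edge.length < 0
  deficit <- -sum(tree$edge.length[neg])
  if (deficit > 0) {
    message(sprintf("neighbor_joining: clamped %d negative branch length(s), total deficit %.4g",
                    sum(neg), deficit))
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Pairwise leaf-to-leaf path distances on a tree
#'
#' @param tree A `phylo` tree.
#' @return Symmetric labelled matrix of summed branch lengths.
#' @export
tree_leaf_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

#' Serialize a tree to a newick string
#'
#' Labels containing whitespace or newick metacharacters are single-quoted
#' per the newick convention (unlike `ape::write.tree`, spaces survive).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A newick string terminated by `";"`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_lab <- function(x) {
    if (grepl("[][[:space:]():;,']", x)) sprintf("'%s'", gsub("'", "''", x)) else x
  }
  rec <- function(node) {
    if (node <= n_tip) return(quote_lab(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(rec(tree$edge[e, 2]), ":",
             format(tree$edge.length[e], digits = 12, scientific = FALSE))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Write a tree to a newick file
#'
#' @param tree A `phylo` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ok <- try(writeLines(as_newick(tree), path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("failed writing '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Read a newick file
#'
#' @param path Newick file written by [write_newick()] (or any standard
#'   newick file).
#' @return A `phylo` tree with any quoting stripped from labels.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <- gsub("''", "'",
                                 sub("^'(.*)'$", "\\1", tree$tip.label[quoted]))
  tree
}

#' Build DNA and RNA sector trees for every patient in a bundle
#'
#' Patients with fewer than 3 samples (sectors + non-tumour) for a given
#' layer are skipped with a warning.
#'
#' @param bundle A `cohort_bundle`.
#' @return Named list per patient with elements `dna` and `rna`
#'   (`phylo` or `NULL`).
#' @export
cohort_phylogenies <- function(bundle) {
  pids <- unique(bundle$immune$patient_id)
  out <- lapply(pids, function(p) {
    dna <- tryCatch({
      dm <- dna_distance_matrix(bundle$mutations[bundle$mutations$patient_id == p, ])
      neighbor_joining(dm)
    }, error = function(e) {
      warning(sprintf("patient %s DNA tree skipped: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    rna <- tryCatch({
      cols <- grep(paste0("^", p, "_"), colnames(bundle$expression), value = TRUE)
      expr <- bundle$expression[, cols, drop = FALSE]
      colnames(expr) <- sub(paste0("^", p, "_"), "", colnames(expr))
      if (ncol(expr) < 3L) stop("need >= 3 sectors for an RNA tree")
      neighbor_joining(rna_distance_matrix(expr))
    }, error = function(e) {
      warning(sprintf("patient %s RNA tree skipped: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    list(dna = dna, rna = rna)
  })
  names(out) <- pids
  out
}
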