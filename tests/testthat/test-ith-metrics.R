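test_that("immune ITH is 0 for identical sectors and 2 for rank reversal", {
  m <- make_profiles(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(immune_ith_spearman(m)$value, 0)
  m2 <- make_profiles(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.3, 0.2, 0.1))
  sc <- immune_ith_spearman(m2)
  expect_equal(sc$value, 2)
  expect_equal(unname(sc$pairwise_values), 2)
})

test_that("immune ITH equals the brute-force rank-correlation oracle", {
  set.seed(7)
  m <- matrix(stats::rgamma(45, 2), 15, 3)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- paste0("sub", 1:15)
  colnames(m) <- c("S1", "S2", "S3")
  sc <- immune_ith_spearman(m, "P01")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  want <- stats::median(vapply(pairs, function(p) {
    1 - spearman_oracle(m[, p[1]], m[, p[2]])
  }, numeric(1)))
  expect_equal(sc$value, want, tolerance = 1e-12)
  expect_equal(sc$n_sectors, 3L)
})

test_that("immune ITH errors are informative", {
  one <- make_profiles(c(0.5, 0.5))
  expect_error(immune_ith_spearman(one, "P09"), "insufficient sectors.*P09")
  const <- make_profiles(c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.2, 0.3, 0.4))
  expect_error(immune_ith_spearman(const, "P09"), "undefined correlation")
  long <- data.frame(sector_id = c("S1", "S1", "S2"),
                     subset_name = c("a", "b", "a"),
                     proportion = c(0.5, 0.5, 1))
  expect_error(immune_ith_spearman(long), "schema error")
  bad <- make_profiles(c(0.5, 1.2), c(0.3, 0.4))
  expect_error(immune_ith_spearman(bad), "outside \\[0, 1\\]")
})

test_that("euclidean immune ITH matches the closed form", {
  expect_equal(immune_ith_euclidean(make_profiles(c(0.3, 0.7), c(0.3, 0.7)))$value, 0)
  sc <- immune_ith_euclidean(make_profiles(c(0.3, 0.7), c(0.0, 1.0)))
  expect_equal(sc$value, sqrt(0.09 + 0.09), tolerance = 1e-12)
})

test_that("rna ITH handles duplicates, reversals and matches the oracle", {
  set.seed(13)
  e <- matrix(stats::rnorm(600), 200, 3,
              dimnames = list(sprintf("g%03d", 1:200), c("S1", "S2", "S3")))
  dup <- e[, c(1, 1)]
  colnames(dup) <- c("S1", "S2")
  expect_equal(rna_ith(dup)$value, 0)
  rev2 <- cbind(S1 = e[, 1], S2 = -e[, 1])
  expect_equal(rna_ith(rev2)$value, 2)
  sc <- rna_ith(e, "P01")
  want <- stats::median(c(1 - spearman_oracle(e[, 1], e[, 2]),
                          1 - spearman_oracle(e[, 1], e[, 3]),
                          1 - spearman_oracle(e[, 2], e[, 3])))
  expect_equal(sc$value, want, tolerance = 1e-12)
})

test_that("dna ITH is the unique-over-union fraction", {
  cat2 <- make_mutations(list(S1 = c("m1", "m2", "m3"), S2 = c("m2", "m3", "m4")))
  expect_equal(dna_ith(cat2)$value, 0.5)
  same <- make_mutations(list(S1 = c("m1", "m2"), S2 = c("m1", "m2")))
  expect_equal(dna_ith(same)$value, 0)
  expect_error(dna_ith(make_mutations(list(S1 = "m1"))), "insufficient sectors")
})

test_that("dna ITH matches set enumeration on generated structure and is 0 without private mutations", {
  g <- generate_cohort(light_config(3, 11, n_genes = 20))
  mut <- g$bundle$mutations
  p <- unique(mut$patient_id)[1]
  mp <- mut[mut$patient_id == p, ]
  sc <- dna_ith(mp, p)
  secs <- unique(mp$sector_id)
  sets <- lapply(secs, function(s) {
    unique(paste(mp$chrom, mp$pos, mp$ref, mp$alt)[mp$sector_id == s])
  })
  pairs <- utils::combn(length(secs), 2)
  want <- stats::median(apply(pairs, 2, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    u <- union(a, b)
    (length(setdiff(a, b)) + length(setdiff(b, a))) / length(u)
  }))
  expect_equal(sc$value, want, tolerance = 1e-12)

  g0 <- generate_cohort(light_config(3, 11, n_genes = 20,
                                      subclonal_rate = 0))
  sc0 <- cohort_ith(g0$bundle, "dna")
  expect_equal(sc0$value, rep(0, nrow(sc0)))
})

test_that("density heterogeneity is the sample SD, averaged over cell types", {
  d <- data.frame(region_id = paste0("R", 1:4), cell_type = "CD8_T",
                  density_per_mm2 = c(100, 120, 80, 100))
  sc <- density_ith_sd(d)
  expect_equal(sc$value, sd_oracle(c(100, 120, 80, 100)), tolerance = 1e-9)
  expect_equal(sc$value, 16.32993, tolerance = 1e-5)
  flat <- data.frame(region_id = paste0("R", 1:3), cell_type = "Treg",
                     density_per_mm2 = c(50, 50, 50))
  expect_equal(density_ith_sd(flat)$value, 0)
  expect_error(density_ith_sd(d[1, ]), "insufficient regions")
})

test_that("density heterogeneity tracks immune ITH on generated cohorts", {
  g <- generate_cohort(light_config(30, 17, n_genes = 20))
  de <- cohort_ith(g$bundle, "density_sd")
  im <- cohort_ith(g$bundle, "immune_spearman")
  rho <- stats::cor(de$value, im$value[match(de$patient_id, im$patient_id)],
                    method = "spearman")
  expect_gt(rho, 0.3)
})

test_that("median split puts ties in the low group and matches hand example", {
  sc <- data.frame(patient_id = paste0("P", 1:4), value = c(0.1, 0.2, 0.3, 0.4))
  grp <- assign_ith_groups(sc)
  expect_equal(grp$cutoff, rep(0.25, 4))
  expect_equal(grp$group, c("low", "low", "high", "high"))
  tied <- data.frame(patient_id = paste0("P", 1:3), value = c(0.2, 0.2, 0.2))
  expect_equal(assign_ith_groups(tied)$group, rep("low", 3))
  expect_error(assign_ith_groups(sc[1, ]), ">= 2 patients")
})

test_that("group comparison reproduces the exact rank-sum tail for full separation", {
  grp <- data.frame(patient_id = paste0("P", 1:20),
                    group = rep(c("low", "high"), each = 10), cutoff = 0)
  vals <- c(1:10, 101:110)
  res <- compare_groups(vals, paste0("P", 1:20), grp)
  expect_equal(res$p_value, ranksum_exact_oracle(vals[1:10], vals[11:20]),
               tolerance = 1e-12)
  expect_equal(res$summary$median, c(5.5, 105.5))
})

test_that("group comparison is null for identical distributions and errors on one group", {
  grp <- data.frame(patient_id = paste0("P", 1:20),
                    group = rep(c("low", "high"), each = 10), cutoff = 0)
  vals <- rep(c(5, 7, 9, 11, 13), 4)
  res <- compare_groups(vals, paste0("P", 1:20), grp)
  expect_gt(res$p_value, 0.5)
  expect_error(compare_groups(vals[1:10], paste0("P", 1:10), grp), "non-empty")
})

test_that("pairwise scores are symmetric under sector relabelling", {
  set.seed(5)
  m <- matrix(stats::rgamma(60, 2), 15, 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- paste0("sub", 1:15)
  colnames(m) <- paste0("S", 1:4)
  sc1 <- immune_ith_spearman(m)
  perm <- m[, c(3, 1, 4, 2)]
  sc2 <- immune_ith_spearman(perm)
  expect_equal(sort(unname(sc1$pairwise_values)), sort(unname(sc2$pairwise_values)),
               tolerance = 1e-12)
  expect_equal(sc1$value, sc2$value, tolerance = 1e-12)
})

test_that("duplicating a sector never increases the median score", {
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(stats::rgamma(45, 2), 15, 3)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- paste0("sub", 1:15)
    colnames(m) <- paste0("S", 1:3)
    dup <- cbind(m, S4 = m[, 1])
    expect_lte(immune_ith_spearman(dup)$value, immune_ith_spearman(m)$value + 1e-12)
  }
})

test_that("score bounds hold across generated cohorts", {
  g <- small_cohort()
  for (metric in c("immune_spearman", "rna")) {
    v <- cohort_ith(g$bundle, metric)$value
    expect_true(all(v >= 0 & v <= 2))
  }
  v <- cohort_ith(g$bundle, "dna")$value
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(cohort_ith(g$bundle, "immune_euclidean")$value >= 0))
})
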