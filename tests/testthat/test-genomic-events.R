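mut_row <- function(pos, class, sector = "S1", context = "A[C>T]G",
                    n_neo = 0L, patient = "P01") {
  data.frame(patient_id = patient, sector_id = sector, chrom = "chr1",
             pos = pos, ref = "C", alt = "T", class = class, context = context,
             n_neoantigens = n_neo, min_ic50_nm = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("non-silent counting includes missense and nonsense, deduplicated", {
  rec <- rbind(mut_row(1, "missense"), mut_row(2, "missense"),
               mut_row(3, "nonsense"), mut_row(4, "silent"),
               mut_row(5, "silent"), mut_row(6, "silent"))
  expect_equal(count_nonsilent(rec), 3L)
  expect_equal(count_nonsilent(rec[0, ]), 0L)
  tri <- rbind(mut_row(1, "missense", "S1"), mut_row(1, "missense", "S2"),
               mut_row(1, "missense", "S3"))
  expect_equal(count_nonsilent(tri), 1L)
  bad <- mut_row(1, "frameshift")
  expect_error(count_nonsilent(bad), "unknown mutation class")
})

test_that("neoantigen filter applies the strict 500 nM and 8-11-mer gates", {
  calls <- data.frame(length = c(9, 9, 12, 8, 11, 7),
                      ic50_nm = c(450, 500, 10, 499.99, 1, 100))
  kept <- filter_neoantigens(calls)
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$ic50_nm < 500 & kept$length %in% 8:11))
  expect_false(any(kept$ic50_nm == 500))
  expect_error(filter_neoantigens(data.frame(length = 9, ic50_nm = -1)),
               "non-positive")
})

test_that("clonality splits sites by presence in all vs some sectors", {
  cat2 <- make_mutations(list(S1 = c("m1", "m2"), S2 = c("m1", "m3")))
  cl <- classify_clonality(cat2)
  expect_equal(cl$clonal, 1L)
  expect_equal(cl$subclonal, 2L)
  expect_equal(cl$total, 3L)
  allshared <- make_mutations(list(S1 = c("m1", "m2"), S2 = c("m1", "m2")))
  expect_equal(classify_clonality(allshared)$subclonal, 0L)
  expect_error(classify_clonality(make_mutations(list(S1 = "m1"))), "2 sectors")
})

test_that("clonal + subclonal = total on every generated patient", {
  g <- small_cohort()
  for (p in unique(g$bundle$mutations$patient_id)) {
    cl <- classify_clonality(g$bundle$mutations[g$bundle$mutations$patient_id == p, ])
    expect_identical(cl$clonal + cl$subclonal, cl$total)
  }
})

test_that("mutational spectrum is a normalized 96-vector", {
  rec <- mut_row(1:5, "missense", context = "A[C>T]G")
  f <- estimate_spectrum(rec)
  expect_length(f, 96)
  expect_equal(sum(f), 1)
  expect_equal(unname(f["A[C>T]G"]), 1)
  expect_error(estimate_spectrum(rec[0, ]), "zero mutations")
  expect_error(estimate_spectrum(mut_row(1, "missense", context = "bogus")),
               "unknown trinucleotide")
})

test_that("uniformly drawn contexts give a near-uniform spectrum", {
  set.seed(3)
  ctx <- sample(trinucleotide_contexts(), 9600, replace = TRUE)
  rec <- mut_row(seq_along(ctx), "missense")
  rec$context <- ctx
  f <- estimate_spectrum(rec)
  # binomial tolerance: sd of a single cell frequency is sqrt(p(1-p)/n)
  expect_lt(max(abs(f - 1 / 96)), 6 * sqrt((1 / 96) * (95 / 96) / 9600))
})

test_that("immunoediting score matches hand-computed neutral and edited cases", {
  # cohort background: one context, half the non-silent mutations neoantigenic
  bg <- mut_row(1:100, "missense", patient = "P99",
                n_neo = rep(c(1L, 0L), 50))
  smp10 <- mut_row(1:10, "missense", patient = "P01", n_neo = rep(c(1L, 0L), 5))
  es <- immunoediting_score(smp10, rbind(smp10, bg))
  expect_equal(es$expected, 5)
  expect_equal(es$ratio, 1.0)
  smp2 <- smp10
  smp2$n_neoantigens <- c(1L, 1L, rep(0L, 8))
  es2 <- immunoediting_score(smp2, rbind(smp2, bg))
  expect_equal(es2$ratio, 0.4)
})

test_that("two-context toy matches the per-mutation enumeration oracle", {
  ctxA <- "A[C>A]A"; ctxB <- "A[C>G]A"
  bg <- rbind(
    within(mut_row(1:10, "missense", patient = "P90"), {
      context <- ctxA; n_neoantigens <- rep(c(1L, 0L, 0L, 0L, 0L), 2)  # p = 0.2
    }),
    within(mut_row(11:20, "missense", patient = "P90"), {
      context <- ctxB; n_neoantigens <- rep(c(1L, 1L, 1L, 1L, 0L), 2)  # p = 0.8
    }))
  smp <- mut_row(1:10, "missense", patient = "P01",
                 n_neo = c(rep(1L, 5), rep(0L, 5)))
  smp$context <- rep(c(ctxA, ctxB), 5)
  es <- immunoediting_score(smp, rbind(smp, bg))
  expect_equal(es$expected, 10 * (0.5 * 0.2 + 0.5 * 0.8))
  expect_equal(es$ratio, 1.0)
  orc <- editing_oracle(smp, stats::setNames(list(0.2, 0.8), c(ctxA, ctxB)))
  expect_equal(es$expected, orc$expected, tolerance = 1e-12)
  expect_equal(es$observed, orc$observed)
})

test_that("immunoediting background is leave-one-patient-out with smoothing", {
  # the sample's own neo-rich mutations must not inflate its expectation
  bg <- mut_row(1:20, "missense", patient = "P99", n_neo = 0L)
  smp <- mut_row(1:5, "missense", patient = "P01", n_neo = 1L)
  # p(c) comes from P99 only (0/20): the sample's own neoantigen-rich
  # mutations never contaminate its expectation, which is 0 here -> error
  expect_error(immunoediting_score(smp, rbind(smp, bg)), "undefined")
  smp_other_ctx <- smp
  smp_other_ctx$context <- "T[T>A]T"  # context absent from background
  es2 <- immunoediting_score(smp_other_ctx, rbind(smp_other_ctx, bg))
  expect_equal(es2$expected, 5 * 0.5)  # (0+1)/(0+2)
  expect_error(immunoediting_score(mut_row(1, "silent"), bg), "non-silent")
})

test_that("neutral generator calibrates the mean editing ratio near 1", {
  g <- generate_cohort(light_config(28, 5, n_genes = 20,
                                     editing_factor = 1))
  mut <- g$bundle$mutations
  dedup <- mut[!duplicated(paste(mut$patient_id, mut$chrom, mut$pos)), ]
  expect_gt(sum(dedup$class != "silent"), 2000)
  es <- suppressWarnings(cohort_editing_scores(mut, level = "patient"))
  expect_gt(mean(es$ratio), 0.95)
  expect_lt(mean(es$ratio), 1.05)
})

test_that("HLA-LOH is called strictly below 0.5 on any allele", {
  hla <- data.frame(patient_id = rep("P01", 9),
                    sector_id = rep(c("S1", "S2", "S3"), each = 3),
                    allele = rep(c("HLA-A", "HLA-B", "HLA-C"), 3),
                    minor_cn = c(0.4, 1.0, 0.9,  0.5, 0.6, 0.7,  1, 1, 1))
  calls <- call_hla_loh(hla)
  expect_equal(calls$sectors$loh[calls$sectors$sector_id == "S1"], TRUE)
  expect_equal(calls$sectors$loh[calls$sectors$sector_id == "S2"], FALSE)  # 0.5 intact
  expect_equal(calls$sectors$loh[calls$sectors$sector_id == "S3"], FALSE)
  expect_true(calls$patients$loh)  # any sector
  hla$minor_cn[1] <- -0.1
  expect_error(call_hla_loh(hla), "negative")
})

test_that("altered genome fraction uses the length-weighted median with low-CN ties", {
  seg <- data.frame(start = c(1, 51, 81), end = c(50, 80, 100),
                    integer_cn = c(2L, 3L, 2L))
  expect_equal(altered_genome_fraction(seg), 0.3)
  flat <- data.frame(start = 1, end = 100, integer_cn = 2L)
  expect_equal(altered_genome_fraction(flat), 0)
  half <- data.frame(start = c(1, 101), end = c(100, 200), integer_cn = c(2L, 4L))
  expect_equal(altered_genome_fraction(half), 0.5)  # tie -> lower CN is median
  expect_error(altered_genome_fraction(seg[0, ]), "empty")
})

test_that("altered genome fraction is invariant under segment splitting", {
  seg <- data.frame(start = c(1, 51, 81), end = c(50, 80, 100),
                    integer_cn = c(2L, 3L, 2L))
  split <- data.frame(start = c(1, 26, 51, 81), end = c(25, 50, 80, 100),
                      integer_cn = c(2L, 2L, 3L, 2L))
  expect_equal(altered_genome_fraction(split), altered_genome_fraction(seg))
})

test_that("cytoband comparison matches the hypergeometric and BH oracles", {
  # one band deleted in all 10 high sectors, none of 10 low
  bands <- data.frame(chrom = "chr1", start = 1, end = 1000, band_name = "1p")
  seg <- do.call(rbind, lapply(1:20, function(i) {
    grp_hi <- i <= 10
    data.frame(patient_id = sprintf("P%02d", i), sector_id = "S1",
               chrom = "chr1", start = c(1, 1001), end = c(1000, 10000),
               integer_cn = c(if (grp_hi) 1L else 2L, 2L),
               minor_cn = 1, stringsAsFactors = FALSE)
  }))
  groups <- data.frame(patient_id = sprintf("P%02d", 1:20),
                       group = rep(c("high", "low"), each = 10), cutoff = 0)
  res <- cytoband_cnv_comparison(seg, bands, groups)
  del <- res[res$direction == "deleted", ]
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(del$p, fisher_oracle(tab), tolerance = 1e-12)
  expect_equal(del$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("identical copy numbers yield p = 1 everywhere", {
  bands <- synthetic_cytobands()[1:6, ]
  seg <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(patient_id = sprintf("P%02d", i), sector_id = "S1",
               chrom = bands$chrom, start = bands$start, end = bands$end,
               integer_cn = 2L, minor_cn = 1, stringsAsFactors = FALSE)
  }))
  groups <- data.frame(patient_id = sprintf("P%02d", 1:8),
                       group = rep(c("high", "low"), each = 4), cutoff = 0)
  res <- cytoband_cnv_comparison(seg, bands, groups)
  expect_true(all(res$p == 1))
})

test_that("BH adjustment matches the step-up hand rule", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  expect_equal(stats::p.adjust(p, "BH"), c(0.004, 0.02, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-9)
  set.seed(2)
  for (i in 1:5) {
    pr <- stats::runif(20)
    expect_equal(stats::p.adjust(pr, "BH"), bh_oracle(pr), tolerance = 1e-12)
  }
})

test_that("editing depletion is planted only in low-ITH HLA-intact patients", {
  g <- generate_cohort(light_config(40, 1, n_genes = 20, editing_factor = 0.5))
  grp <- assign_ith_groups(cohort_ith(g$bundle, "immune_spearman"))
  hla <- call_hla_loh(g$bundle$hla)
  es <- suppressWarnings(cohort_editing_scores(g$bundle$mutations,
                                               level = "patient"))
  st <- suppressWarnings(stratified_editing_comparison(es, grp, hla$patients))
  dep <- st$strata
  # Bonferroni over the four strata tested per cohort
  alpha <- 0.05 / 4
  low_intact <- dep[dep$stratum == "low/intact", ]
  others <- dep[dep$stratum != "low/intact" & dep$n > 2, ]
  expect_lt(low_intact$depletion_p, alpha)
  expect_lt(low_intact$median_ratio, 1)
  expect_true(all(others$depletion_p > alpha, na.rm = TRUE))
})

test_that("stratified comparison survives single-stratum input", {
  es <- data.frame(patient_id = "P01", sector_id = "S1", observed = 1,
                   expected = 1, ratio = 1, neo_per_nonsilent = 1,
                   n_nonsilent = 10)
  grp <- data.frame(patient_id = "P01", group = "low", cutoff = 0)
  hla <- data.frame(patient_id = "P01", loh = FALSE)
  w <- testthat::capture_warnings(st <- stratified_editing_comparison(es, grp, hla))
  expect_match(w, "empty", all = TRUE)
  expect_equal(sum(st$strata$n), 1L)
  expect_equal(nrow(st$pairwise), 0L)
})

test_that("counting operations are invariant to record order", {
  g <- small_cohort()
  mut <- g$bundle$mutations
  mp <- mut[mut$patient_id == "P01", ]
  set.seed(1)
  shuf <- mp[sample(nrow(mp)), ]
  expect_equal(count_nonsilent(shuf), count_nonsilent(mp))
  expect_equal(classify_clonality(shuf)$total, classify_clonality(mp)$total)
  expect_equal(estimate_spectrum(shuf), estimate_spectrum(mp))
})
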