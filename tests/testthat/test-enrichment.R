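# Catalog loading, stratification, biomarker likelihood, odds ratios,
# Fisher exact tests, decile profiles and efficacy comparisons.

test_that("catalog rows sharing a CpG merge with designs unioned", {
  path <- write_catalog_fixture(data.frame(
    chrom = "chr1", pos = c(100L, 100L, 300L),
    design = c("population", "case_control", "case_control")))
  cat <- load_catalog(path)
  expect_s3_class(cat, "BiomarkerCatalog")
  expect_equal(nrow(cat), 2L)
  row1 <- cat[cat$pos == 100L, ]
  expect_true(row1$design_population && row1$design_case_control)
  expect_false(cat$design_population[cat$pos == 300L])
})

test_that("empty catalogs are valid and unknown designs are rejected", {
  path <- write_catalog_fixture(data.frame(
    chrom = character(), pos = integer(), design = character()))
  expect_equal(nrow(load_catalog(path)), 0L)
  bad <- write_catalog_fixture(data.frame(chrom = "chr1", pos = 1L,
                                          design = "cohort"))
  expect_error(load_catalog(bad), "cohort")
})

test_that("design stratification reproduces inclusion-exclusion and
           one-decimal percentages", {
  # 44 population-only, 222 case-control-only, 3 both -> 47/225/269
  rows <- data.frame(
    chrom = "chr1",
    pos = c(1:44 * 10L, 45:266 * 10L, 267:269 * 10L, 267:269 * 10L),
    design = c(rep("population", 44), rep("case_control", 222),
               rep("population", 3), rep("case_control", 3)))
  st <- stratify_catalog(load_catalog(write_catalog_fixture(rows)))
  expect_equal(st$n_total, 269L)
  expect_equal(st$n_population, 47L)
  expect_equal(st$n_case_control, 225L)
  expect_equal(st$n_both, 3L)
  expect_equal(st$n_population + st$n_case_control - st$n_both, st$n_total)
  expect_equal(st$pct_population, 17.5)
  expect_equal(st$pct_case_control, 83.6)
  # single dual-design entry
  one <- stratify_catalog(load_catalog(write_catalog_fixture(data.frame(
    chrom = "chr1", pos = c(5L, 5L),
    design = c("population", "case_control")))))
  expect_equal(unlist(one[c("n_total", "n_population", "n_case_control",
                            "n_both")]),
               c(n_total = 1L, n_population = 1L, n_case_control = 1L,
                 n_both = 1L))
})

test_that("biomarker likelihood is the catalog fraction of the set", {
  cat <- load_catalog(write_catalog_fixture(data.frame(
    chrom = "chr1", pos = c(100L, 200L), design = "population")))
  set <- paste0("chr1:", (1:10) * 100L)
  expect_equal(biomarker_likelihood(set, cat), 0.2)
  expect_equal(biomarker_likelihood(paste0("chr2:", 1:5), cat), 0)
  expect_equal(biomarker_likelihood(c("chr1:100", "chr1:200"), cat), 1)
  expect_error(biomarker_likelihood(character(), cat), "empty")
})

test_that("odds ratios carry Woolf CIs and Haldane correction", {
  r <- odds_ratio_ci(10, 90, 5, 95)
  expect_equal(r$odds_ratio, (10 * 95) / (90 * 5), tolerance = 1e-12)
  # closed-form Woolf oracle
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(r$ci_low, exp(log(r$odds_ratio) - qnorm(0.975) * se))
  expect_equal(r$ci_high, exp(log(r$odds_ratio) + qnorm(0.975) * se))
  expect_equal(round(r$ci_low, 3), 0.695)
  expect_equal(round(r$ci_high, 2), 6.42)
  expect_false(r$corrected)
  # equal proportions give OR 1
  expect_equal(odds_ratio_ci(20, 80, 10, 40)$odds_ratio, 1)
  # zero cell: +0.5 everywhere, flagged
  rz <- odds_ratio_ci(0, 10, 5, 5)
  expect_true(rz$corrected)
  expect_equal(rz$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio_ci(0, 0, 5, 5), "undefined")
  # an outcome absent from both groups is correctable, not degenerate
  r00 <- odds_ratio_ci(0, 5, 0, 5)
  expect_true(r00$corrected)
  expect_equal(r00$odds_ratio, 1)
  expect_error(odds_ratio_ci(10, 90, -1, 5), "non-negative")
})

test_that("OR is invariant under row+column swap and inverts under row swap", {
  set.seed(3)
  for (i in 1:25) {
    t4 <- rpois(4, 20) + 1
    r <- odds_ratio_ci(t4[1], t4[2], t4[3], t4[4])
    swapped <- odds_ratio_ci(t4[4], t4[3], t4[2], t4[1])
    expect_equal(swapped$odds_ratio, r$odds_ratio)
    inv <- odds_ratio_ci(t4[2], t4[1], t4[4], t4[3])
    expect_equal(inv$odds_ratio, 1 / r$odds_ratio)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  }
})

test_that("two-sided Fisher p matches enumeration and stats::fisher.test", {
  cases <- list(c(1, 9, 9, 1), c(5, 5, 5, 5), c(10, 0, 0, 10),
                c(3, 7, 2, 11), c(0, 5, 8, 2))
  for (t4 in cases) {
    p <- fisher_exact_two_sided(t4[1], t4[2], t4[3], t4[4])
    expect_equal(p, oracle_fisher_enum(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10),
               2 / choose(20, 10), tolerance = 1e-12)
  # directional alternative agrees with fisher.test too
  expect_equal(fisher_exact_two_sided(8, 2, 3, 7, alternative = "greater"),
               fisher.test(matrix(c(8, 2, 3, 7), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("random small tables agree with full enumeration", {
  set.seed(9)
  for (i in 1:200) {
    t4 <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    if ((t4[1] + t4[2]) == 0 || (t4[3] + t4[4]) == 0) next
    expect_equal(fisher_exact_two_sided(t4[1], t4[2], t4[3], t4[4]),
                 oracle_fisher_enum(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-9)
  }
})

decile_fixture <- function(hits_by_decile) {
  # 100 CpGs, 10 per decile, with the given catalog hits per decile
  vt <- vtable_fixture(ri = seq(0.5, 99.5, length.out = 100))
  vt <- assign_deciles(vt)
  hit_pos <- unlist(lapply(seq_along(hits_by_decile), function(g) {
    vt$pos[which(vt$decile == g)][seq_len(hits_by_decile[g])]
  }))
  cat <- load_catalog(write_catalog_fixture(data.frame(
    chrom = "chr1", pos = hit_pos, design = "population")))
  list(vt = vt, cat = cat)
}

test_that("decile profiles conserve hits and report both OR and ratio", {
  fx <- decile_fixture(c(0, 0, 0, 0, 0, 1, 1, 1, 2, 5))
  prof <- decile_or_profile(fx$vt, fx$cat)
  expect_equal(nrow(prof), 10L)
  expect_equal(sum(prof$a), 10L) # conservation of catalog hits
  # decile 10: 2x2 is (5, 5, 5, 85)
  d10 <- prof[prof$decile == 10, ]
  expect_equal(unlist(d10[c("a", "b", "c", "d")]),
               c(a = 5, b = 5, c = 5, d = 85))
  ref <- odds_ratio_ci(5, 5, 5, 85)
  expect_equal(d10$odds_ratio, ref$odds_ratio)
  expect_equal(d10$p_value, ref$p_value)
  expect_equal(d10$likelihood_ratio, (5 / 10) / (10 / 100))
})

test_that("uniform hits give flat decile profiles; concentration gives the
           10-fold ratio", {
  flat <- decile_or_profile(decile_fixture(rep(1, 10))$vt,
                            decile_fixture(rep(1, 10))$cat)
  expect_true(all(abs(flat$likelihood_ratio - 1) < 1e-12))
  expect_true(all(abs(flat$odds_ratio - 1) < 1e-12))
  conc <- decile_fixture(c(rep(0, 9), 10))
  prof <- decile_or_profile(conc$vt, conc$cat)
  expect_equal(prof$likelihood_ratio[10], 10)
})

test_that("status ORs use the hypomethylated class as reference", {
  # intermediate 90/10 variable, hypo 7/93 -> OR 119.57
  vt <- vtable_fixture(
    ri = c(rep(80, 90), rep(5, 10), rep(80, 7), rep(5, 93)),
    median_beta = c(rep(50, 100), rep(10, 100)))
  ors <- status_or(rbind(vt, vtable_fixture(ri = c(50, 10),
                                            median_beta = c(90, 90),
                                            pos = c(90001L, 90002L))))
  expect_equal(ors$intermediate$odds_ratio, (90 * 93) / (10 * 7),
               tolerance = 1e-12)
  expect_equal(ors$hyper$a + ors$hyper$b, 2)
  vt_no_hypo <- vtable_fixture(ri = c(50, 10), median_beta = c(50, 90))
  expect_error(status_or(vt_no_hypo), "empty status class")
})

test_that("efficacy comparisons treat candidate and reference as
           independent groups", {
  cat <- load_catalog(write_catalog_fixture(data.frame(
    chrom = "chr1", pos = 1:70 * 7L, design = "population")))
  cand <- paste0("chr1:", 1:1000)
  r_self <- efficacy_vs_reference(cand, cand, cat)
  expect_equal(r_self$odds_ratio, 1)
  expect_equal(r_self$p_value, 1)
  # toy counts (20, 980, 50, 9950) -> OR 4.06
  cand2 <- c(paste0("chr1:", 1:20 * 7L), paste0("chr2:", 1:980))
  ref2 <- c(paste0("chr1:", 21:70 * 7L), paste0("chr3:", 1:9950))
  r <- efficacy_vs_reference(cand2, ref2, cat)
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 20, b = 980, c = 50, d = 9950))
  expect_equal(r$odds_ratio, (20 * 9950) / (980 * 50), tolerance = 1e-12)
  expect_error(efficacy_vs_reference(character(), ref2, cat), "non-empty")
})

test_that("design filters restrict the catalog and error when empty", {
  cat <- load_catalog(write_catalog_fixture(data.frame(
    chrom = "chr1", pos = c(100L, 200L),
    design = c("case_control", "case_control"))))
  cand <- paste0("chr1:", 1:10 * 100L)
  ref <- paste0("chr1:", 11:100 * 100L)
  r <- efficacy_vs_reference(cand, ref, cat, design_filter = "case_control")
  expect_equal(r$a, 2)
  expect_error(
    efficacy_vs_reference(cand, ref, cat, design_filter = "population"),
    "population")
  expect_error(biomarker_likelihood(cand, cat, design_filter = "cohort"),
               "design_filter")
})
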