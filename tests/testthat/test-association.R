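# Per-CpG smoking regression, regional profiles and trait association.

# A balanced design where smoking is orthogonal to age and sex.
balanced_matrix <- function(delta = -10, n_per_group = 10) {
  md <- data.frame(
    sample_id = sprintf("S%03d", 1:(2 * n_per_group)),
    age = rep(rep(c(40, 50, 60, 70), length.out = n_per_group), 2),
    sex = rep(c("male", "female"), n_per_group),
    smoking = rep(c("current", "never"), each = n_per_group),
    cell_type = "monocyte", stringsAsFactors = FALSE)
  base <- 50 + 0.2 * md$age + 3 * (md$sex == "male")
  beta <- rbind(base + delta * (md$smoking == "current"),
                rep(60, 2 * n_per_group))
  rownames(beta) <- c("chr1:100", "chr1:200")
  matrix_fixture(beta, md)
}

test_that("a noiseless planted difference is recovered exactly", {
  res <- smoking_association(balanced_matrix(delta = -10))
  row <- res[res$cpg == "chr1:100", ]
  expect_equal(row$beta_S, -10, tolerance = 1e-10)
  expect_equal(row$n_used, 20L)
  expect_lt(row$p_value, 1e-12)
  # a constant response has a zero smoking coefficient
  expect_equal(res$beta_S[res$cpg == "chr1:200"], 0, tolerance = 1e-10)
})

test_that("the adjusted coefficient equals the group-mean difference in a
           balanced design", {
  set.seed(31)
  mat <- balanced_matrix(delta = -6)
  mat$beta[1, ] <- mat$beta[1, ] + rnorm(20, sd = 2)
  res <- smoking_association(mat, cpg_subset = "chr1:100")
  cur <- mat$samples$smoking == "current"
  # age and sex are orthogonal to smoking here, so OLS adjustment changes
  # nothing relative to the raw contrast of group means of the residuals
  raw <- mean(mat$beta[1, cur]) - mean(mat$beta[1, !cur])
  expect_equal(res$beta_S, raw, tolerance = 1e-8)
})

test_that("former and unknown smokers are excluded before fitting", {
  md <- data.frame(sample_id = sprintf("S%02d", 1:12),
                   age = (1:12) * 2 + 40, sex = rep(c("male", "female"), 6),
                   smoking = c(rep("current", 4), rep("never", 4),
                               rep("former", 3), "unknown"),
                   cell_type = "monocyte", stringsAsFactors = FALSE)
  beta <- matrix(c(rep(30, 4), rep(40, 4), rep(90, 4)), nrow = 1)
  rownames(beta) <- "chr1:100"
  res <- smoking_association(matrix_fixture(beta, md))
  expect_equal(res$n_used, 8L) # formers/unknown dropped
  expect_equal(res$beta_S, -10, tolerance = 1e-10)
  # a cohort of only former smokers is unusable
  md$smoking <- "former"
  expect_error(smoking_association(matrix_fixture(beta, md)),
               "current and one never")
})

test_that("CpGs without enough usable samples are skipped with a reason", {
  mat <- balanced_matrix()
  mat$beta[2, 3:20] <- NA
  res <- smoking_association(mat)
  expect_equal(res$skipped_reason[res$cpg == "chr1:200"],
               "insufficient degrees of freedom")
  expect_true(is.na(res$p_value[res$cpg == "chr1:200"]))
})

test_that("p-values are uniform under the null", {
  set.seed(33)
  n <- 60; n_cpg <- 1000
  md <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   age = runif(n, 34, 74),
                   sex = sample(c("male", "female"), n, TRUE),
                   smoking = sample(c("current", "never"), n, TRUE),
                   cell_type = "monocyte", stringsAsFactors = FALSE)
  beta <- matrix(runif(n_cpg * n, 20, 80), nrow = n_cpg)
  rownames(beta) <- paste0("chr1:", seq_len(n_cpg) * 100L)
  res <- smoking_association(matrix_fixture(beta, md))
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("regional profiles report R2, group summaries and RI around an
           anchor", {
  set.seed(35)
  n <- 40
  md <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   age = runif(n, 34, 74),
                   sex = rep(c("male", "female"), n / 2),
                   smoking = rep(c("current", "never"), each = n / 2),
                   cell_type = "monocyte", stringsAsFactors = FALSE)
  anchor <- runif(n, 20, 80)
  beta <- rbind(anchor,
                100 - anchor,           # perfectly anticorrelated
                runif(n, 20, 80),       # independent noise
                runif(n, 20, 80))       # outside the window
  rownames(beta) <- c("chr1:1000", "chr1:1500", "chr1:2000", "chr1:90000")
  mat <- matrix_fixture(beta, md)
  prof <- regional_profile(mat, "chr1:1000", window_bp = 5000)
  expect_equal(nrow(prof), 3L) # the distant CpG is excluded
  expect_equal(prof$r2_with_anchor[prof$cpg == "chr1:1000"], 1)
  expect_equal(prof$r2_with_anchor[prof$cpg == "chr1:1500"], 1)
  expect_lt(prof$r2_with_anchor[prof$cpg == "chr1:2000"], 0.2)
  expect_equal(prof$mean_current[prof$cpg == "chr1:1000"],
               mean(anchor[md$smoking == "current"]))
  expect_equal(prof$sd_never[prof$cpg == "chr1:1000"],
               sd(anchor[md$smoking == "never"]))
  expect_equal(prof$reference_interval[1],
               reference_interval(anchor))
  # anchor row reproduces the genome-wide smoking scan
  scan <- smoking_association(mat, cpg_subset = "chr1:1000")
  expect_equal(prof$p_value[prof$cpg == "chr1:1000"], scan$p_value)
  expect_error(regional_profile(mat, "chr9:1", 100), "anchor")
})

test_that("an independent CpG shows near-zero R2 at n = 200", {
  set.seed(36)
  n <- 200
  md <- data.frame(sample_id = sprintf("S%03d", 1:n), age = rep(50, n),
                   sex = rep(c("male", "female"), n / 2),
                   smoking = rep(c("current", "never"), n / 2),
                   cell_type = "monocyte", stringsAsFactors = FALSE)
  beta <- rbind(runif(n, 0, 100), runif(n, 0, 100))
  rownames(beta) <- c("chr1:100", "chr1:200")
  prof <- regional_profile(matrix_fixture(beta, md), "chr1:100", 1000)
  expect_lt(prof$r2_with_anchor[prof$cpg == "chr1:200"], 0.05)
})

test_that("trait association recovers exact and planted slopes", {
  mat <- balanced_matrix()
  dn <- mat$beta[1, ]
  exact <- trait_association(mat, setNames(2 * dn, colnames(mat$beta)),
                             cpg_subset = "chr1:100")
  expect_equal(exact$beta_dnam, 2, tolerance = 1e-10)
  expect_lt(exact$p_value, 1e-12)
  # planted slope 0.5 with unit noise at n = 300
  set.seed(37)
  n <- 300
  md <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   age = runif(n, 34, 74),
                   sex = sample(c("male", "female"), n, TRUE),
                   smoking = sample(c("current", "never"), n, TRUE),
                   cell_type = "monocyte", stringsAsFactors = FALSE)
  beta <- matrix(runif(n, 20, 80), nrow = 1,
                 dimnames = list("chr1:100", md$sample_id))
  trait <- 0.5 * beta[1, ] + rnorm(n)
  res <- trait_association(matrix_fixture(beta, md), trait)
  expect_gt(res$beta_dnam, 0.4)
  expect_lt(res$beta_dnam, 0.6)
  # a trait independent of methylation has a near-zero coefficient
  res0 <- trait_association(matrix_fixture(beta, md),
                            setNames(rnorm(n) + 5, md$sample_id),
                            covariates = character(0))
  expect_lt(abs(res0$beta_dnam), 0.1)
  expect_gt(res0$p_value, 0.001)
})
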