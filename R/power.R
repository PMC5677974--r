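# Monte-Carlo power of the Fisher-exact efficacy comparison: probability
# of detecting a planted enrichment of associated CpGs in a targeted
# subset of a probe set.

#' Solve 2x2 membership probabilities for a planted odds ratio
#'
#' Finds `p1` (probability that an associated CpG is targeted) and `p0`
#' (for non-associated CpGs) such that `odds(p1)/odds(p0) = odds_ratio`
#' and the marginal targeted fraction matches `target_fraction`. With
#' `marginal = "overall"` (default) the constraint is on the overall
#' expected fraction of targeted CpGs,
#' `(n_assoc p1 + (n_total - n_assoc) p0) / n_total = target_fraction`;
#' with `"nonassoc"`, `p0 = target_fraction` directly.
#'
#' @param target_fraction Fraction of CpGs targeted, in (0, 1).
#' @param odds_ratio Planted odds ratio (> 0).
#' @param n_total,n_assoc Total and associated CpG counts.
#' @param marginal `"overall"` or `"nonassoc"`, see above.
#' @return List with `p1`, `p0` (solved to residual below 1e-12).
#' @export
solve_cell_probabilities <- function(target_fraction, odds_ratio,
                                     n_total, n_assoc,
                                     marginal = c("overall", "nonassoc")) {
  marginal <- match.arg(marginal)
  stopifnot(target_fraction > 0, target_fraction < 1, odds_ratio > 0,
            n_assoc > 0, n_total > n_assoc)
  p1_from_p0 <- function(p0) {
    o1 <- odds_ratio * p0 / (1 - p0)
    o1 / (1 + o1)
  }
  if (marginal == "nonassoc") {
    p0 <- target_fraction
  } else {
    f <- function(p0)
      (n_assoc * p1_from_p0(p0) + (n_total - n_assoc) * p0) / n_total -
        target_fraction
    # the marginal fraction is increasing in p0; bracket within (0, 1)
    upper <- min(1 - 1e-12, max(target_fraction, target_fraction / odds_ratio) * 1.01)
    if (f(upper) < 0) upper <- 1 - 1e-12
    p0 <- uniroot(f, c(1e-14, upper), tol = 1e-15)$root
    if (abs(f(p0)) > 1e-12)
      stop("no membership probabilities in (0,1) satisfy the constraints",
           call. = FALSE)
  }
  list(p1 = p1_from_p0(p0), p0 = p0)
}

#' Monte-Carlo power of the Fisher-exact efficacy comparison
#'
#' Simulates 2x2 tables under the planted-enrichment model — `a ~
#' Binomial(n_assoc, p1)` associated CpGs targeted and `c ~
#' Binomial(n_total - n_assoc, p0)` non-associated CpGs targeted — and
#' reports the fraction of replicates whose Fisher exact test rejects at
#' `alpha`. The default tests the directional (enrichment) alternative;
#' `alternative = "two.sided"` is available. `method = "approx"` replaces
#' the exact test by the two-proportion normal (score) test, which is
#' flagged in the output and useful as a large-count cross-check.
#'
#' @param n_total Total CpG count (e.g. 473814 array probes).
#' @param n_assoc Number of associated CpGs (e.g. 269).
#' @param target_fraction Fraction of CpGs targeted (e.g. 0.10).
#' @param odds_ratio Planted enrichment odds ratio (e.g. 2.0).
#' @param alpha Significance level (default 0.05).
#' @param n_reps Monte-Carlo replicates (default 10000).
#' @param seed Seed for reproducibility (required; the caller's RNG state
#'   is preserved).
#' @param alternative `"greater"` (directional, default) or `"two.sided"`.
#' @param method `"exact"` or `"approx"`.
#' @param marginal Passed to [solve_cell_probabilities()].
#' @return A `PowerResult` list: `power`, `mc_se`, `p1`, `p0`, `n_reps`,
#'   `alpha`, `alternative`, `method`, `seed`.
#' @export
estimate_power <- function(n_total, n_assoc, target_fraction, odds_ratio,
                           alpha = 0.05, n_reps = 10000, seed,
                           alternative = c("greater", "two.sided"),
                           method = c("exact", "approx"),
                           marginal = "overall") {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1)
  pr <- solve_cell_probabilities(target_fraction, odds_ratio, n_total,
                                 n_assoc, marginal)
  pv <- with_seed(seed, {
    a <- rbinom(n_reps, n_assoc, pr$p1)
    cc <- rbinom(n_reps, n_total - n_assoc, pr$p0)
    if (method == "exact") {
      vapply(seq_len(n_reps), function(r)
        fisher_exact_two_sided(a[r], n_assoc - a[r], cc[r],
                               n_total - n_assoc - cc[r],
                               alternative = alternative), 0)
    } else {
      n1 <- n_assoc; n0 <- n_total - n_assoc
      phat <- (a + cc) / n_total
      z <- (a / n1 - cc / n0) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n0))
      if (alternative == "greater") pnorm(z, lower.tail = FALSE)
      else 2 * pnorm(abs(z), lower.tail = FALSE)
    }
  })
  power <- mean(pv < alpha)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_reps),
                 p1 = pr$p1, p0 = pr$p0, n_reps = n_reps, alpha = alpha,
                 alternative = alternative, method = method, seed = seed),
            class = "PowerResult")
}

#' @export
print.PowerResult <- function(x, ...) {
  cat(sprintf("Fisher-exact efficacy power: %.1f%% (MC SE %.2f%%, %d reps, alpha %g, %s %s test)\n",
              100 * x$power, 100 * x$mc_se, x$n_reps, x$alpha,
              x$alternative,
              if (x$method == "exact") "exact" else "normal-approximation"))
  cat(sprintf("  membership probabilities: p1 = %.5f (associated), p0 = %.5f\n",
              x$p1, x$p0))
  invisible(x)
}
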