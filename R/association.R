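# Per-CpG association of DNA methylation with smoking status (linear model
# with age and sex adjustment) and regional biomarker profiles; the same
# OLS engine serves quantitative-trait (e.g. expression) association.

# Least squares with t-tests on the coefficient of interest.
# y: response; X: design matrix with intercept; coef_idx: tested column.
ols_test <- function(y, X, coef_idx) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL) # collinear design
  df_res <- length(y) - ncol(X)
  if (df_res < 1L) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * diag(XtXinv))
  tval <- beta / se
  list(beta = beta[coef_idx], se = se[coef_idx], t = tval[coef_idx],
       p = 2 * pt(abs(tval[coef_idx]), df_res, lower.tail = FALSE),
       n = length(y))
}

# Design for the smoking model: indicator S (never = 0, current = 1),
# age in years, sex indicator (female = 0, male = 1). Former and unknown
# smokers are excluded before fitting.
smoking_design <- function(samples) {
  keep <- samples$smoking %in% c("current", "never")
  if (!any(samples$smoking[keep] == "current") ||
      !any(samples$smoking[keep] == "never"))
    stop("need at least one current and one never smoker after exclusions",
         call. = FALSE)
  X <- cbind(intercept = 1,
             smoking = as.numeric(samples$smoking[keep] == "current"),
             age = samples$age[keep],
             sex = as.numeric(samples$sex[keep] == "male"))
  list(keep = keep, X = X)
}

#' Per-CpG association of methylation with smoking status
#'
#' Fits, for each CpG, the linear model
#' `M = b0 + bS * S + bAge * Age + bSex * Sex` where `M` is the methylation
#' level in percent, `S` is 1 for current and 0 for never smokers (former
#' and unknown smokers are excluded), and tests `bS` with a two-sided
#' t-test. Missing responses are dropped listwise per CpG; CpGs with too few
#' residual degrees of freedom or a collinear design are skipped with the
#' reason recorded.
#'
#' @param mat A `MethylationMatrix`.
#' @param cpg_subset Optional character vector of `"chrom:pos"` keys to
#'   restrict the scan.
#' @return Data frame with one row per CpG: `cpg`, `n_used`, `beta_S`
#'   (adjusted current - never difference in percentage points), `se`, `t`,
#'   `p_value`, `skipped_reason` (`NA` when fitted).
#' @export
smoking_association <- function(mat, cpg_subset = NULL) {
  des <- smoking_design(mat$samples)
  keys <- rownames(mat$beta)
  rows <- if (is.null(cpg_subset)) seq_along(keys) else
    which(keys %in% cpg_subset)
  B <- mat$beta[rows, des$keep, drop = FALSE]
  out <- data.frame(cpg = keys[rows], n_used = NA_integer_,
                    beta_S = NA_real_, se = NA_real_, t = NA_real_,
                    p_value = NA_real_, skipped_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(B))) {
    ok <- !is.na(B[i, ])
    if (sum(ok) < ncol(des$X) + 1L) {
      out$skipped_reason[i] <- "insufficient degrees of freedom"
      next
    }
    fit <- ols_test(B[i, ok], des$X[ok, , drop = FALSE], 2L)
    if (is.null(fit)) {
      out$skipped_reason[i] <- "collinear design"
      next
    }
    out$n_used[i] <- fit$n; out$beta_S[i] <- fit$beta
    out$se[i] <- fit$se; out$t[i] <- fit$t; out$p_value[i] <- fit$p
  }
  out
}

#' Regional variability and association profile around an anchor CpG
#'
#' For every CpG within `window_bp` of the anchor: the smoking-association
#' p-value, the squared Pearson correlation of its methylation levels with
#' the anchor's (pairwise-complete, requiring at least `min_overlap`
#' shared samples), group means and SDs for current and never smokers, and
#' the reference interval.
#'
#' @param mat A `MethylationMatrix`.
#' @param anchor_cpg Anchor as `"chrom:pos"`.
#' @param window_bp Half-window in bases (> 0).
#' @param config A [variability_config()] for the reference intervals.
#' @param min_overlap Minimum paired samples for the correlation
#'   (default 10).
#' @return Data frame with one row per CpG in the window.
#' @export
regional_profile <- function(mat, anchor_cpg, window_bp,
                             config = variability_config(),
                             min_overlap = 10) {
  stopifnot(window_bp > 0)
  keys <- rownames(mat$beta)
  ai <- match(anchor_cpg, keys)
  if (is.na(ai)) stop("anchor CpG not in matrix: ", anchor_cpg, call. = FALSE)
  achrom <- mat$cpgs$chrom[ai]; apos <- mat$cpgs$pos[ai]
  in_win <- mat$cpgs$chrom == achrom &
    abs(mat$cpgs$pos - apos) <= window_bp
  assoc <- smoking_association(mat, cpg_subset = keys[in_win])
  anchor_beta <- mat$beta[ai, ]
  grp_cur <- mat$samples$smoking == "current"
  grp_nev <- mat$samples$smoking == "never"
  idx <- which(in_win)
  r2 <- vapply(idx, function(i) {
    ok <- !is.na(mat$beta[i, ]) & !is.na(anchor_beta)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (sd(mat$beta[i, ok]) == 0 || sd(anchor_beta[ok]) == 0) return(NA_real_)
    cor(mat$beta[i, ok], anchor_beta[ok])^2
  }, 0)
  gstat <- function(i, grp, f) {
    v <- mat$beta[i, grp]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else f(v)
  }
  data.frame(cpg = keys[idx],
             distance = mat$cpgs$pos[idx] - apos,
             p_value = assoc$p_value[match(keys[idx], assoc$cpg)],
             r2_with_anchor = r2,
             mean_current = vapply(idx, gstat, 0, grp = grp_cur, f = mean),
             sd_current = vapply(idx, gstat, 0, grp = grp_cur, f = sd),
             mean_never = vapply(idx, gstat, 0, grp = grp_nev, f = mean),
             sd_never = vapply(idx, gstat, 0, grp = grp_nev, f = sd),
             reference_interval = vapply(idx, function(i) {
               v <- mat$beta[i, !is.na(mat$beta[i, ])]
               if (length(v) == 0L) NA_real_ else reference_interval(v, config)
             }, 0),
             stringsAsFactors = FALSE)
}

#' Per-CpG association of a quantitative trait with methylation
#'
#' Regresses a continuous per-sample trait (e.g. log expression) on each
#' CpG's methylation level with age and sex covariates (configurable) and
#' tests the methylation coefficient two-sided.
#'
#' @param mat A `MethylationMatrix`.
#' @param trait_values Named numeric vector (names = sample ids) or data
#'   frame with `sample_id`, `value`.
#' @param covariates Character subset of `c("age", "sex")` (default both).
#' @param cpg_subset Optional `"chrom:pos"` keys to restrict the scan.
#' @return Data frame: `cpg`, `n_used`, `beta_dnam` (trait change per
#'   percentage point), `se`, `t`, `p_value`, `skipped_reason`.
#' @export
trait_association <- function(mat, trait_values,
                              covariates = c("age", "sex"),
                              cpg_subset = NULL) {
  if (is.data.frame(trait_values))
    trait_values <- setNames(trait_values$value, trait_values$sample_id)
  y_all <- as.numeric(trait_values[colnames(mat$beta)])
  covs <- cbind(
    if ("age" %in% covariates) age = mat$samples$age,
    if ("sex" %in% covariates) sex = as.numeric(mat$samples$sex == "male"))
  keys <- rownames(mat$beta)
  rows <- if (is.null(cpg_subset)) seq_along(keys) else
    which(keys %in% cpg_subset)
  out <- data.frame(cpg = keys[rows], n_used = NA_integer_,
                    beta_dnam = NA_real_, se = NA_real_, t = NA_real_,
                    p_value = NA_real_, skipped_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(rows)) {
    i <- rows[k]
    ok <- !is.na(mat$beta[i, ]) & !is.na(y_all)
    X <- cbind(intercept = 1, dnam = mat$beta[i, ok],
               if (!is.null(covs)) covs[ok, , drop = FALSE])
    if (sum(ok) < ncol(X) + 1L) {
      out$skipped_reason[k] <- "insufficient degrees of freedom"
      next
    }
    fit <- ols_test(y_all[ok], X, 2L)
    if (is.null(fit)) {
      out$skipped_reason[k] <- "collinear design"
      next
    }
    out$n_used[k] <- fit$n; out$beta_dnam[k] <- fit$beta
    out$se[k] <- fit$se; out$t[k] <- fit$t; out$p_value[k] <- fit$p
  }
  out
}
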