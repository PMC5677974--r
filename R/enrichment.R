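# Biomarker-catalog enrichment: likelihoods, 2x2 odds ratios with Woolf
# CIs, Fisher exact tests, decile profiles and efficacy comparisons.

DESIGN_LABELS <- c("population", "case_control")

#' Load a catalog of previously reported EWAS CpGs
#'
#' @param path TSV with columns `cpg_id`, `chrom`, `pos`, `trait`, `design`
#'   (`population` or `case_control`), `tissue`, `ethnicity`. Rows sharing a
#'   CpG coordinate are merged: a unique CpG entry carries the union of its
#'   design labels and traits.
#' @return A `BiomarkerCatalog` data frame with one row per unique CpG and
#'   logical columns `design_population`, `design_case_control`.
#' @export
load_catalog <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = "chrom")))
  need <- c("cpg_id", "chrom", "pos", "trait", "design", "tissue", "ethnicity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(new_catalog(df[0, , drop = FALSE]))
  bad <- which(!(df$design %in% DESIGN_LABELS))
  if (length(bad))
    stop_bad_lines(sprintf("unknown design label '%s'", df$design[bad[1]]),
                   bad + 1L) # +1 for the header line
  new_catalog(df)
}

new_catalog <- function(df) {
  key <- cpg_key(df$chrom, df$pos)
  agg <- function(x) vapply(split(as.character(x), key)[unique(key)],
                            function(v) paste(sort(unique(v)), collapse = ";"),
                            "")
  first <- !duplicated(key)
  out <- data.frame(cpg_id = df$cpg_id[first],
                    chrom = df$chrom[first], pos = as.integer(df$pos[first]),
                    trait = if (nrow(df)) unname(agg(df$trait)) else character(),
                    tissue = if (nrow(df)) unname(agg(df$tissue)) else character(),
                    ethnicity = if (nrow(df)) unname(agg(df$ethnicity)) else character(),
                    stringsAsFactors = FALSE)
  designs <- split(as.character(df$design), key)[unique(key)]
  out$design_population <- vapply(designs, function(d) "population" %in% d, TRUE)
  out$design_case_control <- vapply(designs, function(d) "case_control" %in% d, TRUE)
  if (nrow(df) == 0L) {
    out$design_population <- logical()
    out$design_case_control <- logical()
  }
  ord <- genomic_order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("BiomarkerCatalog", "data.frame"))
}

catalog_keys <- function(catalog, design_filter = "all") {
  keep <- switch(design_filter,
                 all = rep(TRUE, nrow(catalog)),
                 population = catalog$design_population,
                 case_control = catalog$design_case_control,
                 stop("design_filter must be all/population/case_control",
                      call. = FALSE))
  cpg_key(catalog$chrom[keep], catalog$pos[keep])
}

#' Stratify a biomarker catalog by study design
#'
#' Counts unique CpGs derived from population-based and case-control
#' designs, their overlap, and percentages of the total (one-decimal
#' rounding). When every entry is labelled, inclusion-exclusion holds:
#' `n_population + n_case_control - n_both = n_total`.
#'
#' @param catalog A `BiomarkerCatalog`.
#' @return List with `n_total`, `n_population`, `n_case_control`, `n_both`,
#'   `pct_population`, `pct_case_control`.
#' @export
stratify_catalog <- function(catalog) {
  n_total <- nrow(catalog)
  n_pop <- sum(catalog$design_population)
  n_cc <- sum(catalog$design_case_control)
  n_both <- sum(catalog$design_population & catalog$design_case_control)
  list(n_total = n_total, n_population = n_pop, n_case_control = n_cc,
       n_both = n_both,
       pct_population = round(100 * n_pop / n_total, 1),
       pct_case_control = round(100 * n_cc / n_total, 1))
}

#' Biomarker likelihood of a CpG set
#'
#' The fraction of a CpG set previously reported as associated in published
#' EWASs: catalog members in the set divided by the set size.
#'
#' @param cpg_set Character vector of `"chrom:pos"` keys (or a data frame
#'   with `chrom`/`pos` columns).
#' @param catalog A `BiomarkerCatalog`.
#' @param design_filter `"all"`, `"population"` or `"case_control"`.
#' @return The likelihood as a fraction.
#' @export
biomarker_likelihood <- function(cpg_set, catalog, design_filter = "all") {
  keys <- as_cpg_keys(cpg_set)
  if (length(keys) == 0L) stop("empty CpG set", call. = FALSE)
  mean(keys %in% catalog_keys(catalog, design_filter))
}

as_cpg_keys <- function(x) {
  if (is.data.frame(x)) return(unique(cpg_key(x$chrom, x$pos)))
  unique(as.character(x))
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` with the Woolf log-scale 95% CI
#' `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero, 0.5
#' is added to all four cells first (Haldane-Anscombe) and the result is
#' flagged. The two-sided Fisher p-value of the uncorrected table is
#' attached.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are the compared
#'   groups, columns the outcome (e.g. catalog member / not).
#' @param conf_level Confidence level (default 0.95).
#' @return A `ContingencyResult` list: `a,b,c,d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`.
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  for (nm in c("a", "b", "c", "d")) check_count(get(nm), nm)
  if ((a == 0 && b == 0) || (c == 0 && d == 0))
    stop("odds ratio undefined: a compared group is empty", call. = FALSE)
  corrected <- any(c(a, b, c, d) == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (corrected) { aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5 }
  or <- (aa * dd) / (bb * cc)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  structure(list(a = a, b = b, c = c, d = d,
                 odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p_value = fisher_exact_two_sided(a, b, c, d),
                 corrected = corrected),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("2x2 [%d %d; %d %d]: OR = %.3g (95%% CI %.3g-%.3g), Fisher p = %.3g%s\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$ci_low, x$ci_high,
              x$p_value,
              if (isTRUE(x$corrected)) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric point probabilities
#' of all tables no more probable than the observed one (the
#' point-probability rule, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment of
#'   the first row in the first column).
#' @return The p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  m <- a + b; n <- c + d; k <- a + c
  if (alternative == "greater")
    return(phyper(a - 1, m, n, k, lower.tail = FALSE))
  supp <- max(0, k - n):min(k, m)
  pp <- dhyper(supp, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(pp[pp <= pobs * (1 + 1e-7)]))
}

#' Decile odds-ratio profile of biomarker likelihood
#'
#' For each reference-interval decile of an analysis subset, computes (i)
#' the odds ratio of catalog membership for the decile against the rest of
#' the subset (a proper 2x2 with CI and Fisher p) and (ii) the ratio of the
#' decile's biomarker likelihood to the subset-average likelihood (the
#' "x-fold the average" quantity). Both are reported.
#'
#' @param vtable A `VariabilityTable` with deciles assigned
#'   ([assign_deciles()]).
#' @param catalog A `BiomarkerCatalog`.
#' @return Data frame with one row per decile: cells, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `corrected`, `likelihood`,
#'   `likelihood_ratio`.
#' @export
decile_or_profile <- function(vtable, catalog) {
  in_sub <- !is.na(vtable$decile)
  if (!any(in_sub)) stop("no deciles assigned; run assign_deciles()",
                         call. = FALSE)
  keys <- cpg_key(vtable$chrom, vtable$pos)
  hit <- keys %in% catalog_keys(catalog)
  n_sub <- sum(in_sub)
  hits_sub <- sum(hit & in_sub)
  avg_lik <- hits_sub / n_sub
  deciles <- sort(unique(vtable$decile[in_sub]))
  rows <- lapply(deciles, function(g) {
    ing <- in_sub & vtable$decile == g
    a <- sum(hit & ing); b <- sum(!hit & ing)
    c <- hits_sub - a; d <- (n_sub - sum(ing)) - c
    res <- odds_ratio_ci(a, b, c, d)
    lik <- a / sum(ing)
    data.frame(decile = g, a = a, b = b, c = c, d = d,
               odds_ratio = res$odds_ratio, ci_low = res$ci_low,
               ci_high = res$ci_high, p_value = res$p_value,
               corrected = res$corrected, likelihood = lik,
               likelihood_ratio = lik / avg_lik)
  })
  out <- do.call(rbind, rows)
  attr(out, "average_likelihood") <- avg_lik
  out
}

#' Odds ratios of common variability by methylation status
#'
#' For the hypermethylated and intermediately methylated classes, the odds
#' of being commonly variable relative to the hypomethylated reference
#' class.
#'
#' @param vtable A `VariabilityTable`.
#' @return Named list of `ContingencyResult`s (`hyper`, `intermediate`).
#' @export
status_or <- function(vtable) {
  counts <- function(st) {
    in_st <- vtable$status == st
    if (!any(in_st)) stop("empty status class: ", st, call. = FALSE)
    c(sum(in_st & vtable$commonly_variable),
      sum(in_st & !vtable$commonly_variable))
  }
  ref <- counts("hypo")
  setNames(lapply(c("hyper", "intermediate"), function(st) {
    x <- counts(st)
    odds_ratio_ci(x[1], x[2], ref[1], ref[2])
  }), c("hyper", "intermediate"))
}

#' Efficacy of a candidate target set against a reference set
#'
#' Compares the biomarker likelihood of a candidate CpG set with a reference
#' set (e.g. an array probe set) as a 2x2 of catalog membership. The two
#' sets are treated as independent groups; overlap is permitted and each set
#' is counted in full.
#'
#' @param candidate_set,reference_set CpG sets (`"chrom:pos"` keys or
#'   data frames with `chrom`/`pos`).
#' @param catalog A `BiomarkerCatalog`.
#' @param design_filter Restrict the catalog to `"population"` or
#'   `"case_control"` designs (default `"all"`).
#' @return A `ContingencyResult`.
#' @export
efficacy_vs_reference <- function(candidate_set, reference_set, catalog,
                                  design_filter = "all") {
  cand <- as_cpg_keys(candidate_set)
  ref <- as_cpg_keys(reference_set)
  if (length(cand) == 0L || length(ref) == 0L)
    stop("candidate and reference sets must be non-empty", call. = FALSE)
  ck <- catalog_keys(catalog, design_filter)
  if (length(ck) == 0L)
    stop("no catalog entries for design_filter = '", design_filter, "'",
         call. = FALSE)
  a <- sum(cand %in% ck); b <- length(cand) - a
  c <- sum(ref %in% ck); d <- length(ref) - c
  odds_ratio_ci(a, b, c, d)
}
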