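# Inter-individual variability statistics: reference intervals, methylation
# status classes, commonly-variable flags and decile assignment.

#' Configuration for variability statistics
#'
#' Defaults follow the standard reference-interval definition (p95 - p5),
#' hypo/hyper median thresholds of 20% / 80% (inclusive), and a 30%
#' (inclusive) reference-interval threshold for the commonly-variable flag.
#'
#' @param lower_percentile,upper_percentile Percentiles defining the
#'   reference interval (defaults 5 and 95).
#' @param hypo_max Median beta (percent) at or below which a CpG is
#'   hypomethylated (default 20).
#' @param hyper_min Median beta at or above which a CpG is hypermethylated
#'   (default 80).
#' @param commonly_variable_min_ri Reference interval (percent, inclusive)
#'   defining commonly variable CpGs (default 30).
#' @param n_deciles Number of variability bins for [assign_deciles()]
#'   (default 10).
#' @param quantile_method `"type7"` (linear interpolation between order
#'   statistics, the default) or `"nearest_rank"` (inverse ECDF).
#' @return A `VariabilityConfig` list.
#' @export
variability_config <- function(lower_percentile = 5, upper_percentile = 95,
                               hypo_max = 20, hyper_min = 80,
                               commonly_variable_min_ri = 30,
                               n_deciles = 10,
                               quantile_method = c("type7", "nearest_rank")) {
  quantile_method <- match.arg(quantile_method)
  stopifnot(lower_percentile >= 0, lower_percentile < upper_percentile,
            upper_percentile <= 100, hypo_max < hyper_min)
  structure(list(lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 hypo_max = hypo_max, hyper_min = hyper_min,
                 commonly_variable_min_ri = commonly_variable_min_ri,
                 n_deciles = n_deciles,
                 quantile_method = quantile_method),
            class = "VariabilityConfig")
}

#' Percentile of methylation levels across individuals
#'
#' Linear-interpolation ("type 7") quantile by default; nearest-rank
#' available. Missing values are dropped.
#'
#' @param values Numeric beta values (percent).
#' @param p Percentile in \[0, 100\].
#' @param method `"type7"` or `"nearest_rank"`.
#' @return The percentile as a percent.
#' @export
percentile <- function(values, p, method = c("type7", "nearest_rank")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 100)) stop("p must lie in [0, 100]", call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("percentile undefined: all values missing", call. = FALSE)
  type <- if (method == "type7") 7L else 1L
  unname(quantile(values, p / 100, type = type, names = FALSE))
}

#' Reference interval of a CpG's methylation levels
#'
#' The difference between the 95th and 5th percentiles (configurable) of
#' beta values across individuals — the package's inter-individual
#' variability statistic.
#'
#' @param values Numeric beta values (percent).
#' @param config A [variability_config()].
#' @return Reference interval in percent, in \[0, 100\].
#' @export
reference_interval <- function(values, config = variability_config()) {
  percentile(values, config$upper_percentile, config$quantile_method) -
    percentile(values, config$lower_percentile, config$quantile_method)
}

#' Classify methylation status from the median beta value
#'
#' Hypomethylated if the median is at or below `hypo_max`, hypermethylated
#' if at or above `hyper_min`, intermediate otherwise. Boundary medians go
#' to the hypo/hyper classes.
#'
#' @param median_beta Median beta values in percent (vectorized).
#' @param config A [variability_config()].
#' @return Character vector: `"hypo"`, `"hyper"` or `"intermediate"`.
#' @export
classify_status <- function(median_beta, config = variability_config()) {
  if (any(!is.na(median_beta) & (median_beta < 0 | median_beta > 100)))
    stop("median beta out of [0, 100]", call. = FALSE)
  ifelse(median_beta <= config$hypo_max, "hypo",
         ifelse(median_beta >= config$hyper_min, "hyper", "intermediate"))
}

#' Per-CpG variability table
#'
#' Computes, for every CpG of a methylation matrix: the number of
#' non-missing samples, the median beta, the reference interval, the
#' methylation-status class and the commonly-variable flag.
#'
#' @param mat A `MethylationMatrix`.
#' @param config A [variability_config()].
#' @return A `VariabilityTable` data frame with columns `chrom`, `pos`,
#'   `n_obs`, `median_beta`, `reference_interval`, `status`,
#'   `commonly_variable`, `decile` (`NA` until [assign_deciles()]).
#' @export
build_variability_table <- function(mat, config = variability_config()) {
  type <- if (config$quantile_method == "type7") 7L else 1L
  probs <- c(config$lower_percentile, 50, config$upper_percentile) / 100
  qs <- t(apply(mat$beta, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, probs, type = type, names = FALSE)
  }))
  ri <- qs[, 3L] - qs[, 1L]
  med <- qs[, 2L]
  out <- data.frame(chrom = mat$cpgs$chrom, pos = mat$cpgs$pos,
                    n_obs = rowSums(!is.na(mat$beta)),
                    median_beta = med,
                    reference_interval = ri,
                    status = classify_status(med, config),
                    commonly_variable = ri >= config$commonly_variable_min_ri,
                    decile = NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("VariabilityTable", "data.frame"))
}

#' Assign reference-interval deciles on an analysis subset
#'
#' Ranks the CpGs of `subset` by reference interval (ascending; ties broken
#' by genomic order) and splits them into `n_deciles` near-equal bins whose
#' sizes differ by at most one, extras going to the narrowest bins. Decile 1
#' is the narrowest. CpGs outside the subset keep `decile = NA`.
#'
#' @param vtable A `VariabilityTable`.
#' @param subset Character vector of `"chrom:pos"` keys defining the
#'   analysis subset (e.g. array-probed CpGs), or `NULL` for all CpGs.
#' @param n_deciles Number of bins (default from the table's config).
#' @return The `VariabilityTable` with `decile` filled in on the subset.
#' @export
assign_deciles <- function(vtable, subset = NULL, n_deciles = NULL) {
  config <- attr(vtable, "config") %||% variability_config()
  n_deciles <- n_deciles %||% config$n_deciles
  keys <- cpg_key(vtable$chrom, vtable$pos)
  idx <- if (is.null(subset)) seq_len(nrow(vtable)) else which(keys %in% subset)
  n <- length(idx)
  if (n < n_deciles)
    stop("subset has fewer CpGs (", n, ") than deciles (", n_deciles, ")",
         call. = FALSE)
  grank <- integer(n)
  grank[genomic_order(vtable$chrom[idx], vtable$pos[idx])] <- seq_len(n)
  ord <- idx[order(vtable$reference_interval[idx], grank)]
  sizes <- rep(n %/% n_deciles, n_deciles)
  extra <- n %% n_deciles
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  vtable$decile <- replace(rep(NA_integer_, nrow(vtable)), ord,
                           rep(seq_len(n_deciles), times = sizes))
  vtable
}

#' @export
print.VariabilityTable <- function(x, ...) {
  cat(sprintf("VariabilityTable: %d CpGs; %.1f%% commonly variable (RI >= %g%%)\n",
              nrow(x), 100 * mean(x$commonly_variable, na.rm = TRUE),
              (attr(x, "config") %||% variability_config())$commonly_variable_min_ri))
  tab <- table(x$status)
  cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a variability table as TSV
#'
#' @param vtable A `VariabilityTable`.
#' @param path Output path.
#' @export
write_variability_tsv <- function(vtable, path) {
  fwrite(as.data.frame(vtable), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
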