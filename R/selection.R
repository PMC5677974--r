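# Construction of commonly-variable (CDMV) target CpG sets.

#' Specification of a CDMV target set
#'
#' @param min_ri Minimum reference interval in percent, inclusive
#'   (default 30).
#' @param max_ri Optional cap: CpGs with reference interval strictly above
#'   `max_ri` are removed (`NULL` = no cap). The customary cap is 70.
#' @param exclude_repeats Exclude CpGs inside repeat intervals
#'   (default `TRUE`).
#' @return A `TargetSetSpec` list.
#' @export
target_set_spec <- function(min_ri = 30, max_ri = NULL,
                            exclude_repeats = TRUE) {
  if (!is.null(max_ri) && min_ri >= max_ri)
    stop("min_ri must be below max_ri", call. = FALSE)
  structure(list(min_ri = min_ri, max_ri = max_ri,
                 exclude_repeats = exclude_repeats),
            class = "TargetSetSpec")
}

#' Build a CDMV target set from a variability table
#'
#' Selects CpGs with a reference interval of at least `min_ri` percent,
#' outside repetitive regions (repeat membership tested at the C position),
#' optionally dropping CpGs above an upper reference-interval cap. Removal
#' counts for each criterion are attached as an `accounting` attribute and
#' reported via [message()].
#'
#' @param vtable A `VariabilityTable`.
#' @param repeats `IntervalSet` of repeat regions, or `NULL` / empty for no
#'   repeat exclusion.
#' @param spec A [target_set_spec()].
#' @return A `CpGSet` data frame (`chrom`, `pos`, `reference_interval`).
#' @export
build_cdmv_set <- function(vtable, repeats = NULL,
                           spec = target_set_spec()) {
  n0 <- nrow(vtable)
  pass_ri <- vtable$reference_interval >= spec$min_ri
  in_repeat <- if (spec$exclude_repeats && !is.null(repeats) &&
                   nrow(repeats) > 0L)
    annotate_cpgs(vtable[, c("chrom", "pos")], repeats)
  else rep(FALSE, n0)
  over_cap <- if (!is.null(spec$max_ri))
    vtable$reference_interval > spec$max_ri
  else rep(FALSE, n0)
  keep <- pass_ri & !in_repeat & !over_cap
  accounting <- list(n_input = n0,
                     n_below_min_ri = sum(!pass_ri),
                     n_in_repeats = sum(pass_ri & in_repeat),
                     n_above_max_ri = sum(pass_ri & !in_repeat & over_cap),
                     n_selected = sum(keep),
                     spec = unclass(spec))
  message(sprintf("build_cdmv_set: %d/%d CpGs selected (%d below RI %g, %d in repeats, %d above cap)",
                  accounting$n_selected, n0, accounting$n_below_min_ri,
                  spec$min_ri, accounting$n_in_repeats,
                  accounting$n_above_max_ri))
  if (!any(keep)) warning("CDMV set is empty", call. = FALSE)
  out <- vtable[keep, c("chrom", "pos", "reference_interval")]
  rownames(out) <- NULL
  structure(out, accounting = accounting,
            class = c("CpGSet", "data.frame"))
}

#' Cap the reference interval of a CpG set
#'
#' Removes CpGs whose reference interval is strictly above `max_ri`
#' (a CpG exactly at the cap is retained), reporting the removed fraction.
#'
#' @param cpg_set A `CpGSet` (or data frame with `chrom`/`pos`).
#' @param vtable The `VariabilityTable` supplying reference intervals.
#' @param max_ri Cap in percent (default 70); `NULL` returns the set
#'   unchanged.
#' @return The filtered `CpGSet` with a `removed_fraction` attribute.
#' @export
apply_ri_cap <- function(cpg_set, vtable, max_ri = 70) {
  if (is.null(max_ri)) return(cpg_set)
  ri <- vtable$reference_interval[match(cpg_key(cpg_set$chrom, cpg_set$pos),
                                        cpg_key(vtable$chrom, vtable$pos))]
  keep <- !is.na(ri) & ri <= max_ri
  removed <- mean(!keep)
  message(sprintf("apply_ri_cap: removed %.1f%% of CpGs with RI > %g%%",
                  100 * removed, max_ri))
  out <- cpg_set[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, removed_fraction = removed,
            class = c("CpGSet", "data.frame"))
}

#' Write a CDMV accounting report as JSON
#'
#' @param cpg_set A `CpGSet` from [build_cdmv_set()].
#' @param path Output JSON path.
#' @export
write_accounting_json <- function(cpg_set, path) {
  jsonlite::write_json(attr(cpg_set, "accounting"), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
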