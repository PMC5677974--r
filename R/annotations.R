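# Genomic annotation intervals (BED convention), promoter / CGI-shore
# derivation, CpG membership and regulatory-element enrichment.
#
# Intervals are 0-based half-open [start, end) throughout; CpG positions
# are 1-based C positions. The single conversion point is cpg_to_granges().

new_interval_set <- function(chrom, start, end, strand = NULL, name = "intervals") {
  strand <- strand %||% rep(".", length(chrom))
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), strand = strand,
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative interval start", call. = FALSE)
  if (any(df$start >= df$end)) stop("interval start >= end", call. = FALSE)
  rownames(df) <- NULL
  structure(df, name = name, class = c("IntervalSet", "data.frame"))
}

#' Read a BED3/BED6 file into an IntervalSet
#'
#' @param path BED file path (tab-separated, no track lines); 3 or more
#'   columns. Column 6, when present, is the strand.
#' @param name Label for the set (default: file base name).
#' @return An `IntervalSet` data frame (`chrom`, `start`, `end`, `strand`)
#'   using 0-based half-open coordinates.
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  name <- name %||% sub("\\.bed(\\.gz)?$", "", basename(path))
  if (file.size(path) == 0L)
    return(new_interval_set(character(), numeric(), numeric(), name = name))
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(new_interval_set(character(), numeric(), numeric(), name = name))
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path, call. = FALSE)
  start <- as.numeric(dt[[2]]); end <- as.numeric(dt[[3]])
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad)) stop_bad_lines("invalid BED interval (start >= end)", bad)
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else NULL
  new_interval_set(dt[[1]], start, end, strand, name = name)
}

#' Write an IntervalSet (or CpG set) as BED
#'
#' @param x An `IntervalSet`, or a data frame with `chrom`/`pos` (1-based
#'   CpG positions, written as single-base intervals).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  df <- if (!is.null(x$start)) {
    data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
               end = format(x$end, scientific = FALSE, trim = TRUE))
  } else {
    data.frame(chrom = x$chrom, start = x$pos - 1L, end = x$pos)
  }
  fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' @param path TSV with columns `chrom`, `pos` (1-based TSS coordinate) and
#'   `strand` (`+` or `-`).
#' @return Validated data frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = "chrom")))
  if (!all(c("chrom", "pos", "strand") %in% names(df)))
    stop("TSS table needs columns chrom, pos, strand", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  df$pos <- as.integer(df$pos)
  df
}

#' Derive promoter intervals from TSS records
#'
#' A promoter spans 2 kb upstream to 500 bp downstream of the TSS
#' (strand-aware, clipped at the chromosome start). With the default
#' `tss_in_downstream = FALSE`, the window is 2,000 upstream bases, the TSS
#' base itself, and 500 downstream bases (width 2,501); with
#' `tss_in_downstream = TRUE` the TSS counts as the first of the 500
#' downstream bases (width 2,500).
#'
#' @param tss_records Data frame with `chrom`, `pos` (1-based), `strand`.
#' @param upstream,downstream Window sizes in bases (defaults 2000 and 500).
#' @param tss_in_downstream See above.
#' @return An `IntervalSet` of promoters (0-based half-open).
#' @export
derive_promoters <- function(tss_records, upstream = 2000, downstream = 500,
                             tss_in_downstream = FALSE) {
  t0 <- tss_records$pos - 1L # 0-based TSS base
  plus <- tss_records$strand == "+"
  down <- if (tss_in_downstream) downstream - 1L else downstream
  start <- ifelse(plus, t0 - upstream, t0 - down)
  end <- ifelse(plus, t0 + down + 1L, t0 + upstream + 1L)
  new_interval_set(tss_records$chrom, pmax(start, 0), end,
                   tss_records$strand, name = "promoters")
}

#' Derive CGI shores from CpG-island intervals
#'
#' Each island \[s, e) contributes the 2-kb flanks \[s - 2000, s) and
#' \[e, e + 2000), clipped at the chromosome start. By default shore bases
#' overlapping another island are kept; `subtract_cgi = TRUE` removes bases
#' covered by any island.
#'
#' @param cgi_intervals `IntervalSet` of CpG islands.
#' @param flank Flank width in bases (default 2000).
#' @param subtract_cgi Remove island-covered bases from the shores.
#' @return An `IntervalSet` of shores.
#' @export
derive_shores <- function(cgi_intervals, flank = 2000, subtract_cgi = FALSE) {
  if (nrow(cgi_intervals) == 0L)
    return(new_interval_set(character(), numeric(), numeric(), name = "shores"))
  left <- data.frame(chrom = cgi_intervals$chrom,
                     start = pmax(cgi_intervals$start - flank, 0),
                     end = cgi_intervals$start)
  right <- data.frame(chrom = cgi_intervals$chrom,
                      start = cgi_intervals$end,
                      end = cgi_intervals$end + flank)
  sh <- rbind(left, right)
  sh <- sh[sh$start < sh$end, , drop = FALSE]
  out <- new_interval_set(sh$chrom, sh$start, sh$end, name = "shores")
  if (subtract_cgi) {
    gr <- GenomicRanges::setdiff(interval_granges(out),
                                 interval_granges(cgi_intervals))
    out <- new_interval_set(as.character(GenomicRanges::seqnames(gr)),
                            GenomicRanges::start(gr) - 1L,
                            GenomicRanges::end(gr), name = "shores")
  }
  out
}

# IntervalSet (0-based half-open) -> GRanges (1-based closed).
interval_granges <- function(iset) {
  GenomicRanges::GRanges(iset$chrom,
                         IRanges::IRanges(start = iset$start + 1,
                                          end = iset$end))
}

# 1-based CpG C positions -> single-base GRanges.
cpg_to_granges <- function(chrom, pos, both_bases = FALSE) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = pos,
                                          end = pos + as.integer(both_bases)))
}

#' Flag CpGs contained in an interval set
#'
#' A CpG belongs to an interval iff its C position falls inside the 0-based
#' half-open interval; `both_bases = TRUE` additionally requires the G at
#' `pos + 1` (any overlap of the dinucleotide with the interval).
#'
#' @param cpg_keys Data frame with `chrom`, `pos` (1-based), or a character
#'   vector of `"chrom:pos"` keys.
#' @param interval_set An `IntervalSet`.
#' @param both_bases Overlap rule, see above (default C position only).
#' @return Logical vector of membership flags.
#' @export
annotate_cpgs <- function(cpg_keys, interval_set, both_bases = FALSE) {
  if (is.character(cpg_keys)) {
    parts <- strsplit(cpg_keys, ":", fixed = TRUE)
    cpg_keys <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                           pos = as.integer(vapply(parts, `[`, "", 2L)))
  }
  if (nrow(interval_set) == 0L) return(rep(FALSE, nrow(cpg_keys)))
  # disjoint chromosome sets are a legitimate all-FALSE case, not a warning
  hits <- suppressWarnings(GenomicRanges::countOverlaps(
    cpg_to_granges(cpg_keys$chrom, cpg_keys$pos, both_bases),
    interval_granges(interval_set)))
  hits > 0L
}

#' Regulatory-element enrichment of a CpG set
#'
#' Compares the fraction of CpGs overlapping an annotation between a CpG
#' set and a background set (independent groups, overlap permitted), as an
#' odds ratio with Woolf CI and Fisher p.
#'
#' @param cpg_set,background_cpgs CpG sets (data frames with `chrom`/`pos`
#'   or `"chrom:pos"` keys).
#' @param interval_set The annotation `IntervalSet`.
#' @return A `ContingencyResult`.
#' @export
regulatory_enrichment <- function(cpg_set, interval_set, background_cpgs) {
  keys_df <- function(x) {
    if (is.character(x)) {
      parts <- strsplit(unique(x), ":", fixed = TRUE)
      data.frame(chrom = vapply(parts, `[`, "", 1L),
                 pos = as.integer(vapply(parts, `[`, "", 2L)))
    } else unique(x[, c("chrom", "pos")])
  }
  s <- keys_df(cpg_set); bg <- keys_df(background_cpgs)
  in_s <- annotate_cpgs(s, interval_set)
  in_bg <- annotate_cpgs(bg, interval_set)
  odds_ratio_ci(sum(in_s), sum(!in_s), sum(in_bg), sum(!in_bg))
}

#' Reference-interval distribution summaries by annotation
#'
#' For each annotation, summarizes the reference intervals of the CpGs it
#' contains (n, median, quartiles), with a background row over all CpGs of
#' the table.
#'
#' @param vtable A `VariabilityTable`.
#' @param interval_sets Named list of `IntervalSet`s.
#' @return Data frame with one row per element plus `background`.
#' @export
ri_by_annotation <- function(vtable, interval_sets) {
  summarize <- function(ri, label) {
    if (length(ri) == 0L)
      return(data.frame(element = label, n = 0L, q1 = NA_real_,
                        median_ri = NA_real_, q3 = NA_real_))
    q <- quantile(ri, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(element = label, n = length(ri), q1 = q[1],
               median_ri = q[2], q3 = q[3])
  }
  rows <- lapply(names(interval_sets), function(nm) {
    inside <- annotate_cpgs(vtable[, c("chrom", "pos")], interval_sets[[nm]])
    summarize(vtable$reference_interval[inside], nm)
  })
  out <- rbind(do.call(rbind, rows),
               summarize(vtable$reference_interval, "background"))
  rownames(out) <- NULL
  out
}
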