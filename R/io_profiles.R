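# Per-sample methylation-call I/O and cohort matrix assembly.
#
# The QC pipeline order is fixed: per-sample depth filtering and per-sample
# variant masking happen before matrix assembly and the call-rate filter.

new_call_table <- function(df, sample_id) {
  df <- df[, c("chrom", "pos", "meth", "unmeth")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$depth <- df$meth + df$unmeth
  df$beta <- ifelse(df$depth > 0, 100 * df$meth / df$depth, NA_real_)
  df <- df[genomic_order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id,
            class = c("MethylationCallTable", "data.frame"))
}

#' Read a Bismark-style per-CpG coverage file
#'
#' Expects the 6-column Bismark `.cov` dialect: chrom, start, end,
#' methylation percent, methylated count, unmethylated count, one cytosine
#' per line with 1-based `start == end`. The file's methylation-percent
#' column is ignored; beta values are always recomputed from the counts.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @param zero_based Set `TRUE` for 0-based bedGraph-style starts; positions
#'   are converted so that internal coordinates are always 1-based C
#'   positions.
#' @param drop_nonautosomal Drop records outside chr1-chr22 (default `TRUE`).
#' @return A `MethylationCallTable`: data frame with columns `chrom`, `pos`,
#'   `meth`, `unmeth`, `depth`, `beta` (percent) and a `sample_id` attribute.
#' @export
read_coverage_file <- function(path, sample_id = NULL, zero_based = FALSE,
                               drop_nonautosomal = TRUE) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.(cov|tsv|txt)(\\.gz)?$", "", basename(path))
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1),
              fill = TRUE, data.table = TRUE)
  if (ncol(dt) < 6L)
    stop("coverage file must have 6 tab-separated columns: ", path, call. = FALSE)
  setnames(dt, 1:6, c("chrom", "start", "end", "beta_file", "meth", "unmeth"))
  for (col in c("start", "meth", "unmeth")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad)) stop_bad_lines(sprintf("non-integer '%s' field", col), bad)
    dt[[col]] <- as.integer(v)
  }
  neg <- which(dt$meth < 0L | dt$unmeth < 0L)
  if (length(neg)) stop_bad_lines("negative read count", neg)
  pos <- if (zero_based) dt$start + 1L else dt$start
  bad <- which(pos < 1L)
  if (length(bad)) stop_bad_lines("non-positive position", bad)
  df <- data.frame(chrom = dt$chrom, pos = pos, meth = dt$meth,
                   unmeth = dt$unmeth, stringsAsFactors = FALSE)
  if (drop_nonautosomal) df <- df[is_autosome(df$chrom), , drop = FALSE]
  new_call_table(df, sample_id)
}

#' Merge forward- and reverse-strand cytosine calls into CpG units
#'
#' Reverse-strand calls report the G of the dinucleotide at forward position
#' `pos + 1`; their counts are added to the forward C record under the
#' forward C position. Reverse records without a matching forward C are kept
#' as their own CpG unit, with a warning.
#'
#' @param forward_calls,reverse_calls `MethylationCallTable`s for the two
#'   strands of the same sample.
#' @return A merged `MethylationCallTable` keyed by forward C positions.
#' @export
merge_strand_calls <- function(forward_calls, reverse_calls) {
  sample_id <- attr(forward_calls, "sample_id")
  if (nrow(reverse_calls) == 0L) return(new_call_table(forward_calls, sample_id))
  rev <- as.data.frame(reverse_calls)
  rev$pos <- rev$pos - 1L # G position -> C position of the same dinucleotide
  fkey <- cpg_key(forward_calls$chrom, forward_calls$pos)
  rkey <- cpg_key(rev$chrom, rev$pos)
  hit <- match(rkey, fkey)
  fwd <- as.data.frame(forward_calls)
  matched <- !is.na(hit)
  if (any(matched)) {
    fwd$meth[hit[matched]] <- fwd$meth[hit[matched]] + rev$meth[matched]
    fwd$unmeth[hit[matched]] <- fwd$unmeth[hit[matched]] + rev$unmeth[matched]
  }
  if (any(!matched)) {
    warning(sum(!matched), " reverse-strand call(s) without a forward C at pos-1;",
            " kept as standalone CpGs", call. = FALSE)
    orphan <- rev[!matched, , drop = FALSE]
    orphan$pos <- orphan$pos + 1L # no C at pos: keep at its own coordinate
    fwd <- rbind(fwd[, c("chrom", "pos", "meth", "unmeth")],
                 orphan[, c("chrom", "pos", "meth", "unmeth")])
  }
  new_call_table(fwd, sample_id)
}

#' Filter CpG calls by read depth
#'
#' Removes CpGs with low (`< min_depth`) or extremely high (`> max_depth`)
#' read depth; the boundary depths themselves are retained.
#'
#' @param calls A `MethylationCallTable`.
#' @param min_depth,max_depth Inclusive depth bounds (defaults 6 and 300).
#' @return The filtered `MethylationCallTable`.
#' @export
filter_depth <- function(calls, min_depth = 6, max_depth = 300) {
  if (min_depth > max_depth)
    stop("min_depth must not exceed max_depth", call. = FALSE)
  keep <- calls$depth >= min_depth & calls$depth <= max_depth
  new_call_table(as.data.frame(calls)[keep, , drop = FALSE],
                 attr(calls, "sample_id"))
}

#' Mask CpG calls overlapping this sample's genetic variants
#'
#' A variant carried by the sample at either base of the CpG dinucleotide
#' (the C at `pos` or the G at `pos + 1`) alters the CpG sequence, so the
#' methylation call is set to missing (the record is removed).
#'
#' @param calls A `MethylationCallTable`.
#' @param sample_variants Data frame with columns `chrom`, `pos` (1-based) of
#'   positions where THIS sample carries a non-reference allele, e.g. from
#'   [read_sample_variants()].
#' @return The masked `MethylationCallTable`.
#' @export
mask_variant_cpgs <- function(calls, sample_variants) {
  if (is.null(sample_variants) || nrow(sample_variants) == 0L) return(calls)
  vkey <- cpg_key(sample_variants$chrom, sample_variants$pos)
  hit_c <- cpg_key(calls$chrom, calls$pos) %in% vkey
  hit_g <- cpg_key(calls$chrom, calls$pos + 1L) %in% vkey
  new_call_table(as.data.frame(calls)[!(hit_c | hit_g), , drop = FALSE],
                 attr(calls, "sample_id"))
}

#' Extract one sample's non-reference positions from a VCF
#'
#' Any genotype containing an ALT allele (het or hom) marks the position as
#' variant for that sample; zygosity is not distinguished.
#'
#' @param vcf_path Path to a VCF (v4.x) with GT fields.
#' @param sample_id Sample column to extract.
#' @return Data frame with columns `chrom`, `pos`.
#' @export
read_sample_variants <- function(vcf_path, sample_id) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L || !(sample_id %in% colnames(vcf@gt)))
    stop("VCF has no genotype column for sample '", sample_id, "'",
         call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample_id]
  has_alt <- !is.na(gt) & grepl("[1-9]", gt)
  data.frame(chrom = as.character(vcf@fix[has_alt, "CHROM"]),
             pos = as.integer(vcf@fix[has_alt, "POS"]),
             stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `age`, `sex`
#'   (`male`/`female`), `smoking` (`current`/`former`/`never`/`unknown`) and
#'   `cell_type`.
#' @return Validated data frame.
#' @export
read_metadata <- function(path) {
  md <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "age", "sex", "smoking", "cell_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_ids in metadata", call. = FALSE)
  if (any(!is.finite(md$age) | md$age <= 0))
    stop("ages must be positive", call. = FALSE)
  if (!all(md$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(md$smoking %in% c("current", "former", "never", "unknown")))
    stop("smoking must be current/former/never/unknown", call. = FALSE)
  md
}

#' Assemble per-sample calls into a cohort methylation matrix
#'
#' Takes the union of CpGs over all (already depth-filtered and
#' variant-masked) call tables, marks missing cells where a sample lacks a
#' call, and drops CpGs observed in fewer than `min_call_rate` of the
#' samples (inclusive threshold).
#'
#' @param calls_per_sample Named list of `MethylationCallTable`s (names =
#'   sample ids), or unnamed with sample ids taken from the tables.
#' @param metadata Sample metadata data frame covering every sample id.
#' @param min_call_rate Minimum fraction of non-missing samples per CpG
#'   (default 0.5, compared with `>=`).
#' @return A `MethylationMatrix`: list with `beta` (CpG-by-sample percent
#'   matrix, `NA` = missing), `cpgs` (chrom/pos data frame), `samples`
#'   (metadata rows in column order), `call_rate`, and a `qc` report of
#'   per-stage counts.
#' @export
assemble_matrix <- function(calls_per_sample, metadata, min_call_rate = 0.5) {
  if (length(calls_per_sample) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  ids <- names(calls_per_sample)
  if (is.null(ids))
    ids <- vapply(calls_per_sample, attr, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  metadata <- validate_metadata(metadata)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "),
         call. = FALSE)
  keys <- unique(unlist(lapply(calls_per_sample,
                               function(ct) cpg_key(ct$chrom, ct$pos)),
                        use.names = FALSE))
  parts <- strsplit(keys, ":", fixed = TRUE)
  cpgs <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     pos = as.integer(vapply(parts, `[`, "", 2L)),
                     stringsAsFactors = FALSE)
  ord <- genomic_order(cpgs$chrom, cpgs$pos)
  cpgs <- cpgs[ord, , drop = FALSE]
  keys <- keys[ord]
  beta <- matrix(NA_real_, nrow = length(keys), ncol = length(ids),
                 dimnames = list(keys, ids))
  for (j in seq_along(ids)) {
    ct <- calls_per_sample[[j]]
    beta[match(cpg_key(ct$chrom, ct$pos), keys), j] <- ct$beta
  }
  call_rate <- rowMeans(!is.na(beta))
  keep <- call_rate >= min_call_rate
  qc <- list(n_samples = length(ids),
             n_cpgs_union = length(keys),
             n_cpgs_retained = sum(keep),
             n_cpgs_dropped_call_rate = sum(!keep),
             min_call_rate = min_call_rate,
             calls_per_sample = setNames(
               vapply(calls_per_sample, nrow, 0L), ids))
  message(sprintf("assemble_matrix: %d samples; %d CpGs in union; %d retained at call rate >= %g",
                  qc$n_samples, qc$n_cpgs_union, qc$n_cpgs_retained,
                  min_call_rate))
  rownames(cpgs) <- NULL
  structure(list(beta = beta[keep, , drop = FALSE],
                 cpgs = cpgs[keep, , drop = FALSE],
                 samples = metadata[match(ids, metadata$sample_id), ,
                                    drop = FALSE],
                 call_rate = call_rate[keep],
                 qc = qc),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d CpGs x %d samples (%.1f%% missing)\n",
              nrow(x$beta), ncol(x$beta),
              100 * mean(is.na(x$beta))))
  invisible(x)
}

#' Write / read a methylation matrix as TSV
#'
#' Rows are CpGs keyed `"chrom:pos"`, columns are sample ids, missing cells
#' are `NA`.
#'
#' @param mat A `MethylationMatrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(cpg = rownames(mat$beta), mat$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param metadata Sample metadata for the matrix being read.
#' @export
read_matrix_tsv <- function(path, metadata) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  beta <- as.matrix(df[, -1, drop = FALSE])
  rownames(beta) <- df$cpg
  parts <- strsplit(df$cpg, ":", fixed = TRUE)
  cpgs <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     pos = as.integer(vapply(parts, `[`, "", 2L)),
                     stringsAsFactors = FALSE)
  metadata <- validate_metadata(metadata)
  structure(list(beta = beta, cpgs = cpgs,
                 samples = metadata[match(colnames(beta),
                                          metadata$sample_id), , drop = FALSE],
                 call_rate = rowMeans(!is.na(beta)),
                 qc = list()),
            class = "MethylationMatrix")
}

#' Write the QC report of a methylation matrix as JSON
#'
#' @param mat A `MethylationMatrix` from [assemble_matrix()].
#' @param path Output JSON path.
#' @export
write_qc_json <- function(mat, path) {
  jsonlite::write_json(mat$qc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
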