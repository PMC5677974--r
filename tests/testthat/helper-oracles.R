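# Independent oracles and fixture builders shared across tests.

# Brute-force linear-interpolation quantile: sort the values, take
# h = (n - 1) p + 1 and interpolate between the flanking order statistics.
oracle_quantile_type7 <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Two-sided Fisher p by full enumeration of all 2x2 tables with the same
# margins, summing point probabilities no larger than the observed one.
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  probs <- vapply(max(0, k - n):min(k, m), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, 0)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Write a Bismark-style coverage file from a record data frame with
# columns chrom, pos, meth, unmeth.
write_cov_fixture <- function(df, path = tempfile(fileext = ".cov")) {
  depth <- df$meth + df$unmeth
  beta <- ifelse(depth > 0, round(100 * df$meth / depth, 4), 0)
  writeLines(paste(df$chrom, df$pos, df$pos, beta, df$meth, df$unmeth,
                   sep = "\t"), path)
  path
}

# A MethylationMatrix built directly from a beta matrix (percent scale).
matrix_fixture <- function(beta, metadata = NULL) {
  n <- nrow(beta); m <- ncol(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- paste0("chr1:", seq_len(n) * 100L)
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%03d", seq_len(m))
  parts <- strsplit(rownames(beta), ":", fixed = TRUE)
  if (is.null(metadata))
    metadata <- data.frame(sample_id = colnames(beta),
                           age = seq(40, 70, length.out = m),
                           sex = rep(c("male", "female"), length.out = m),
                           smoking = rep(c("current", "never"),
                                         length.out = m),
                           cell_type = "monocyte",
                           stringsAsFactors = FALSE)
  structure(list(beta = beta,
                 cpgs = data.frame(chrom = vapply(parts, `[`, "", 1L),
                                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                                   stringsAsFactors = FALSE),
                 samples = metadata,
                 call_rate = rowMeans(!is.na(beta)),
                 qc = list()),
            class = "MethylationMatrix")
}

# A VariabilityTable built directly from per-CpG reference intervals.
vtable_fixture <- function(ri, median_beta = rep(50, length(ri)),
                           chrom = "chr1", pos = seq_along(ri) * 100L) {
  cfg <- variability_config()
  structure(data.frame(chrom = chrom, pos = pos,
                       n_obs = 10L, median_beta = median_beta,
                       reference_interval = ri,
                       status = classify_status(median_beta, cfg),
                       commonly_variable = ri >= 30,
                       decile = NA_integer_, stringsAsFactors = FALSE),
            config = cfg, class = c("VariabilityTable", "data.frame"))
}

# Write a biomarker-catalog TSV from per-row fields.
write_catalog_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  for (col in c("cpg_id", "trait", "tissue", "ethnicity"))
    if (is.null(df[[col]]))
      df[[col]] <- if (nrow(df)) paste0(col, "_", seq_len(nrow(df)))
                   else character(0)
  write.table(df[, c("cpg_id", "chrom", "pos", "trait", "design",
                     "tissue", "ethnicity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
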