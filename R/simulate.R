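# Synthetic WGBS cohort generator with known ground truth.
#
# The generative model: each CpG belongs to a methylation class (hypo /
# hyper / intermediate) with a per-CpG true mean methylation mu drawn from
# the class's centre distribution; each individual's true beta is drawn
# around mu with a class-specific inter-individual spread (clipped normal);
# sequencing gives Poisson read depths (minimum 1) and binomially sampled
# methylated read counts, so observed betas carry beta-binomial-style
# noise on top of the true inter-individual variation.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a WGBS cohort of ~100 adults at 15x mean post-QC depth:
#' most CpGs near-saturated hypermethylated, a hypomethylated minority, and
#' a small intermediately methylated class carrying most of the
#' inter-individual variability. Class spreads are standard deviations of
#' the true (pre-sequencing) per-individual beta in percentage points; at
#' 15x depth the binomial read noise adds to them, so observed reference
#' intervals for the hypo/hyper classes land near 10-20% and those of the
#' intermediate class near 50-60%.
#'
#' @param n_samples Number of individuals (default 102).
#' @param n_cpgs Number of CpGs (default 10000).
#' @param seed Mandatory RNG seed.
#' @param class_mix Named fractions of `hypo`, `hyper`, `intermediate` CpGs
#'   (default 0.11 / 0.80 / 0.09); must sum to 1.
#' @param class_centres Named list of `c(lo, hi)` uniform ranges (percent)
#'   for the per-CpG true mean by class.
#' @param class_spread Named per-class inter-individual SD of the true beta
#'   (percentage points).
#' @param depth_mean Mean sequencing depth (default 15); per-sample mean
#'   depths vary with SD `depth_sd`, per-CpG depths are Poisson with
#'   minimum 1.
#' @param depth_sd SD of per-sample mean depth (default 1).
#' @param n_assoc Number of planted catalog-associated CpGs (default 1% of
#'   `n_cpgs`).
#' @param assoc_odds_ratio Planted odds ratio of catalog association
#'   between broad- and narrow-reference-interval strata (default 3).
#' @param n_smoking_cpgs CpGs with a planted smoking effect (default 10).
#' @param smoking_effect Shift of the true beta in current smokers, in
#'   percentage points (default -10, demethylation in smokers).
#' @param smoking_mix Named fractions of `current`, `never`, `former`
#'   smokers (default 0.3 / 0.6 / 0.1).
#' @param chrom Chromosome name for all simulated CpGs (default "chr1").
#' @param spacing_mean Mean spacing between CpGs in bases (default 50).
#' @param annotation_spec List controlling [simulate_annotations()]:
#'   `n_cgi`, `cgi_length`, `n_repeats`, `repeat_length`, `n_dhs`,
#'   `dhs_length`, `n_tss`, `manifest_fraction`, `manifest_bias` (sampling
#'   weight of low-spread classes in the probe manifest).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_samples = 102, n_cpgs = 10000, seed,
                       class_mix = c(hypo = 0.11, hyper = 0.80,
                                     intermediate = 0.09),
                       class_centres = list(hypo = c(0, 5),
                                            hyper = c(88, 100),
                                            intermediate = c(20, 80)),
                       class_spread = c(hypo = 1.5, hyper = 3,
                                        intermediate = 15),
                       depth_mean = 15, depth_sd = 1,
                       n_assoc = NULL, assoc_odds_ratio = 3,
                       n_smoking_cpgs = 10, smoking_effect = -10,
                       smoking_mix = c(current = 0.3, never = 0.6,
                                       former = 0.1),
                       chrom = "chr1", spacing_mean = 50,
                       annotation_spec = list()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, n_samples > 1, n_cpgs > 0,
            depth_mean >= 1)
  ann <- utils::modifyList(
    list(n_cgi = 20, cgi_length = 1000, n_repeats = 30, repeat_length = 500,
         n_dhs = 20, dhs_length = 800, n_tss = 20,
         manifest_fraction = 0.2, manifest_bias = 4), annotation_spec)
  structure(list(n_samples = n_samples, n_cpgs = n_cpgs, seed = seed,
                 class_mix = class_mix, class_centres = class_centres,
                 class_spread = class_spread, depth_mean = depth_mean,
                 depth_sd = depth_sd,
                 n_assoc = n_assoc %||% max(10L, round(0.01 * n_cpgs)),
                 assoc_odds_ratio = assoc_odds_ratio,
                 n_smoking_cpgs = n_smoking_cpgs,
                 smoking_effect = smoking_effect, smoking_mix = smoking_mix,
                 chrom = chrom, spacing_mean = spacing_mean,
                 annotation_spec = ann),
            class = "SimulationConfig")
}

clip01 <- function(x) pmin(pmax(x, 0), 100)

#' Simulate a cohort methylation matrix in memory
#'
#' Draws the full generative model (classes, true betas, smoking effects,
#' depths, read counts) and returns the observed `MethylationMatrix`
#' together with the ground truth. All randomness flows from
#' `config$seed`; the same seed reproduces the same cohort exactly.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (a `MethylationMatrix` of observed betas),
#'   `truth` (per-CpG data frame: `chrom`, `pos`, `class`, `mu`, `spread`,
#'   `true_ri` — the reference interval of the true, pre-sequencing betas —
#'   `smoking_effect`), `true_beta` (CpG x sample matrix), `metadata`.
#' @export
simulate_beta_matrix <- function(config) {
  with_seed(config$seed, {
    n <- config$n_cpgs; m <- config$n_samples
    cls <- sample(names(config$class_mix), n, replace = TRUE,
                  prob = config$class_mix)
    mu <- numeric(n)
    for (k in names(config$class_centres)) {
      idx <- cls == k
      rg <- config$class_centres[[k]]
      mu[idx] <- runif(sum(idx), rg[1], rg[2])
    }
    spread <- unname(config$class_spread[cls])
    pos <- cumsum(2L + rpois(n, config$spacing_mean - 2L))
    metadata <- data.frame(
      sample_id = sprintf("S%03d", seq_len(m)),
      age = round(runif(m, 34, 74), 1),
      sex = sample(c("male", "female"), m, replace = TRUE),
      smoking = sample(names(config$smoking_mix), m, replace = TRUE,
                       prob = config$smoking_mix),
      cell_type = "monocyte", stringsAsFactors = FALSE)
    true_beta <- clip01(matrix(rnorm(n * m, mean = mu, sd = spread),
                               nrow = n, ncol = m))
    smoking_effect <- rep(0, n)
    if (config$n_smoking_cpgs > 0) {
      # plant effects at intermediately methylated CpGs, where a shift of a
      # few percentage points is observable without clipping
      inter <- which(cls == "intermediate")
      affected <- sample(inter, min(config$n_smoking_cpgs, length(inter)))
      smoking_effect[affected] <- config$smoking_effect
      cur <- metadata$smoking == "current"
      true_beta[affected, cur] <-
        clip01(true_beta[affected, cur] + config$smoking_effect)
    }
    sample_depth <- pmax(1, rnorm(m, config$depth_mean, config$depth_sd))
    depth <- matrix(pmax(1L, rpois(n * m, rep(sample_depth, each = n))),
                    nrow = n, ncol = m)
    meth <- matrix(rbinom(n * m, as.vector(depth),
                          as.vector(true_beta) / 100),
                   nrow = n, ncol = m)
    beta <- 100 * meth / depth
    keys <- cpg_key(config$chrom, pos)
    dimnames(beta) <- list(keys, metadata$sample_id)
    truth <- data.frame(chrom = config$chrom, pos = pos, class = cls,
                        mu = mu, spread = spread,
                        true_ri = apply(true_beta, 1L, function(x)
                          diff(quantile(x, c(0.05, 0.95), type = 7,
                                        names = FALSE))),
                        smoking_effect = smoking_effect,
                        stringsAsFactors = FALSE)
    mat <- structure(list(beta = beta,
                          cpgs = truth[, c("chrom", "pos")],
                          samples = metadata,
                          call_rate = rep(1, n),
                          qc = list(simulated = TRUE)),
                     class = "MethylationMatrix")
    list(matrix = mat, truth = truth, true_beta = true_beta,
         meth = meth, depth = depth, metadata = metadata)
  })
}

#' Simulate a cohort and write its input files
#'
#' Writes per-sample Bismark-style coverage files (`<sample>.cov`: chrom,
#' pos, pos, beta percent, methylated count, unmethylated count), a
#' metadata TSV, a ground-truth TSV and a `truth.json` manifest carrying
#' the configuration. Re-running with the same config produces
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [simulate_beta_matrix()] result plus `files`.
#' @export
simulate_cohort <- function(config, out_dir) {
  sim <- simulate_beta_matrix(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cov_files <- character(0)
  for (j in seq_len(config$n_samples)) {
    f <- file.path(out_dir, paste0(sim$metadata$sample_id[j], ".cov"))
    fwrite(data.table(chrom = sim$truth$chrom, start = sim$truth$pos,
                      end = sim$truth$pos,
                      beta = round(100 * sim$meth[, j] / sim$depth[, j], 4),
                      meth = sim$meth[, j],
                      unmeth = sim$depth[, j] - sim$meth[, j]),
           f, sep = "\t", col.names = FALSE, quote = FALSE)
    cov_files <- c(cov_files, f)
  }
  meta_file <- file.path(out_dir, "metadata.tsv")
  fwrite(sim$metadata, meta_file, sep = "\t", quote = FALSE)
  truth_file <- file.path(out_dir, "truth.tsv")
  fwrite(sim$truth, truth_file, sep = "\t", quote = FALSE)
  manifest_file <- file.path(out_dir, "truth.json")
  cfg <- unclass(config)
  cfg$class_centres <- lapply(cfg$class_centres, as.numeric)
  jsonlite::write_json(list(config = cfg,
                            n_files = length(cov_files)),
                       manifest_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  sim$files <- list(coverage = cov_files, metadata = meta_file,
                    truth = truth_file, manifest = manifest_file)
  invisible(sim)
}

#' Plant a biomarker catalog with a known odds ratio
#'
#' Samples "associated" CpGs so that the odds of catalog membership for
#' broad-reference-interval CpGs relative to narrow ones equal
#' `config$assoc_odds_ratio`, then assigns study-design labels
#' (population / case-control / both) at proportions mirroring published
#' EWAS catalogs (47 : 225 with 3 in both, rescaled).
#'
#' @param config A [sim_config()] (supplies `n_assoc`, `assoc_odds_ratio`
#'   and the seed offset).
#' @param vtable_truth Data frame with `chrom`, `pos` and either `true_ri`
#'   (from [simulate_beta_matrix()]'s truth) or `reference_interval`; the
#'   broad stratum is RI >= 30.
#' @param broad Optional logical vector overriding the stratum definition.
#' @return A `BiomarkerCatalog`, with attribute `planted` (logical vector
#'   over the vtable rows).
#' @export
simulate_catalog <- function(config, vtable_truth, broad = NULL) {
  ri <- vtable_truth$true_ri %||% vtable_truth$reference_interval
  broad <- broad %||% (ri >= 30)
  n_total <- length(broad); n_broad <- sum(broad)
  if (n_broad == 0L || n_broad == n_total)
    stop("both broad and narrow strata must be non-empty", call. = FALSE)
  pr <- solve_cell_probabilities(config$n_assoc / n_total,
                                 config$assoc_odds_ratio,
                                 n_total, n_broad)
  with_seed(config$seed + 1L, {
    p <- ifelse(broad, pr$p1, pr$p0)
    planted <- runif(n_total) < p
    idx <- which(planted)
    if (length(idx) == 0L) stop("no catalog CpGs planted; increase n_assoc",
                                call. = FALSE)
    # design labels at published proportions: 44 population-only,
    # 222 case-control-only, 3 both (of 269)
    lab <- sample(c("population", "case_control", "both"), length(idx),
                  replace = TRUE, prob = c(44, 222, 3) / 269)
    rows <- data.frame(
      cpg_id = sprintf("sim%06d", idx),
      chrom = vtable_truth$chrom[idx], pos = vtable_truth$pos[idx],
      trait = "simulated_trait", design = ifelse(lab == "both",
                                                 "population", lab),
      tissue = "whole_blood", ethnicity = "simulated",
      stringsAsFactors = FALSE)
    extra <- rows[lab == "both", , drop = FALSE]
    if (nrow(extra)) extra$design <- "case_control"
    cat <- new_catalog(rbind(rows, extra))
    attr(cat, "planted") <- planted
    cat
  })
}

#' Simulate annotation tracks and a probe manifest
#'
#' Generates CpG-island, repeat and DHS-like interval sets plus TSS records
#' on the simulated chromosome, and an array-style probe manifest sampling
#' a fraction of CpGs with sampling weight `manifest_bias` for the
#' low-spread (hypo/hyper) classes — emulating the tendency of existing
#' probe sets toward low-variability CpGs.
#'
#' @param config A [sim_config()].
#' @param truth Truth data frame from [simulate_beta_matrix()].
#' @param out_dir Optional directory; when given, writes `cgi.bed`,
#'   `repeats.bed`, `dhs.bed`, `tss.tsv` and `manifest.tsv`.
#' @return List with `cgi`, `repeats`, `dhs` (`IntervalSet`s), `tss`
#'   (data frame), `manifest` (data frame `probe_id`, `chrom`, `pos`).
#' @export
simulate_annotations <- function(config, truth, out_dir = NULL) {
  ann <- config$annotation_spec
  span <- max(truth$pos) + 1000L
  with_seed(config$seed + 2L, {
    mk <- function(n_iv, len, name) {
      if (n_iv == 0L)
        return(new_interval_set(character(), numeric(), numeric(),
                                name = name))
      start <- sort(sample.int(max(span - len, 1L), n_iv))
      new_interval_set(rep(config$chrom, n_iv), start, start + len,
                       name = name)
    }
    cgi <- mk(ann$n_cgi, ann$cgi_length, "cgi")
    repeats <- mk(ann$n_repeats, ann$repeat_length, "repeats")
    dhs <- mk(ann$n_dhs, ann$dhs_length, "dhs")
    tss <- data.frame(chrom = rep(config$chrom, ann$n_tss),
                      pos = sort(sample.int(span, ann$n_tss)),
                      strand = sample(c("+", "-"), ann$n_tss,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
    w <- ifelse(truth$class == "intermediate", 1, ann$manifest_bias)
    n_probe <- round(ann$manifest_fraction * nrow(truth))
    pick <- sort(sample.int(nrow(truth), n_probe, prob = w))
    manifest <- data.frame(probe_id = sprintf("probe%06d", pick),
                           chrom = truth$chrom[pick],
                           pos = truth$pos[pick], stringsAsFactors = FALSE)
    out <- list(cgi = cgi, repeats = repeats, dhs = dhs, tss = tss,
                manifest = manifest)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bed(cgi, file.path(out_dir, "cgi.bed"))
      write_bed(repeats, file.path(out_dir, "repeats.bed"))
      write_bed(dhs, file.path(out_dir, "dhs.bed"))
      fwrite(tss, file.path(out_dir, "tss.tsv"), sep = "\t", quote = FALSE)
      fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
             quote = FALSE)
    }
    out
  })
}
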