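# Shared internal helpers: CpG keys, coordinate conventions, input checks.

AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build canonical CpG identifiers
#'
#' A CpG is identified by the 1-based forward-strand position of its C, as
#' `"chrom:pos"`. Used as the join key everywhere sets of CpGs are compared.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based C positions.
#' @return Character vector of `"chrom:pos"` keys.
#' @export
cpg_key <- function(chrom, pos) {
  if (length(chrom) == 0L) return(character(0))
  paste0(as.character(chrom), ":", as.integer(pos))
}

is_autosome <- function(chrom) as.character(chrom) %in% AUTOSOMES

stop_bad_lines <- function(what, lines) {
  stop(sprintf("%s at line(s): %s", what,
               paste(head(lines, 10L), collapse = ", ")), call. = FALSE)
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.numeric(x)
}

# Order rows genomically: chromosome (natural order), then position.
genomic_order <- function(chrom, pos) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  order(is.na(num), num, chrom, pos)
}

# Save/restore the RNG state so seeded routines do not disturb callers.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
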