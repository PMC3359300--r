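#' Read a binned gene-expression table
#'
#' Ingests tab-delimited expression tables of the kind distributed with
#' microarray chromosome profiles (columns `chromosome`, `start`, `end`,
#' `value`; 0-based half-open base-pair coordinates). Rows are filtered to
#' one chromosome, sorted, and validated: bins must not overlap and
#' expression levels must be finite and non-negative.
#'
#' @param path Path to the tab-delimited table (with header).
#' @param chromosome Chromosome label to extract. May be omitted when the
#'   table contains a single chromosome.
#' @return An `expression_profile` object: a list with elements `chromosome`
#'   and `bins` (data frame with columns `start`, `end`, `level`).
#' @seealso [bin_to_monomers()], [affinity_profile()]
#' @export
read_expression_table <- function(path, chromosome = NULL) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("chromosome", "start", "end", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("expression table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(chromosome)) {
    chroms <- unique(tab$chromosome)
    if (length(chroms) != 1)
      stop("table contains several chromosomes (", paste(chroms, collapse = ", "),
           "); supply `chromosome`")
    chromosome <- chroms
  }
  keep <- tab$chromosome == chromosome
  if (!any(keep)) stop("no rows for chromosome '", chromosome, "'")
  tab <- tab[keep, , drop = FALSE]
  line_no <- which(keep) + 1L   # header is line 1
  for (col in c("start", "end", "value")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("malformed value in column '", col, "' at line ", line_no[bad[1]])
    tab[[col]] <- v
  }
  if (any(tab$start >= tab$end)) {
    bad <- which(tab$start >= tab$end)[1]
    stop("bin with start >= end at line ", line_no[bad])
  }
  if (any(tab$value < 0)) {
    bad <- which(tab$value < 0)[1]
    stop("negative expression level at line ", line_no[bad])
  }
  ord <- order(tab$start)
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) > 1 && any(tab$start[-1] < tab$end[-nrow(tab)]))
    stop("overlapping bins in expression table for chromosome '", chromosome, "'")
  new_expression_profile(chromosome,
                         data.frame(start = tab$start, end = tab$end,
                                    level = tab$value))
}

new_expression_profile <- function(chromosome, bins) {
  stopifnot(is.data.frame(bins), all(c("start", "end", "level") %in% names(bins)))
  structure(list(chromosome = chromosome, bins = bins),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("expression profile:", x$chromosome, "-", nrow(x$bins), "bins spanning",
      format(max(x$bins$end)), "bp\n")
  invisible(x)
}

#' Bin an expression profile to monomer resolution
#'
#' Projects a base-pair expression profile onto the monomers of the
#' coarse-grained polymer, each monomer covering `bin_size_bp` (150 kb by
#' default) of sequence. A monomer's level is the length-weighted mean of the
#' source bins overlapping it; monomers with no overlapping data are treated
#' as not expressed (level 0). The chain length is
#' `N = ceiling(chrom_length_bp / bin_size_bp)`.
#'
#' @param profile An `expression_profile`, from [read_expression_table()].
#' @param chrom_length_bp Total chromosome length in base pairs.
#' @param bin_size_bp Genomic content of one monomer, in bp.
#' @return A `binned_expression` object: list with `levels` (length-N numeric)
#'   and `bin_size_bp`.
#' @export
bin_to_monomers <- function(profile, chrom_length_bp, bin_size_bp = 150000L) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!is.numeric(chrom_length_bp) || chrom_length_bp <= 0)
    stop("chrom_length_bp must be positive")
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive")
  n <- as.integer(ceiling(chrom_length_bp / bin_size_bp))
  if (n < 2) stop("chromosome shorter than two monomers; nothing to simulate")
  weight <- numeric(n)
  total <- numeric(n)
  bins <- profile$bins
  for (r in seq_len(nrow(bins))) {
    s <- bins$start[r]; e <- min(bins$end[r], chrom_length_bp)
    if (e <= s) next
    m_first <- floor(s / bin_size_bp) + 1
    m_last <- min(ceiling(e / bin_size_bp), n)
    for (m in m_first:m_last) {
      ov <- min(e, m * bin_size_bp) - max(s, (m - 1) * bin_size_bp)
      if (ov > 0) {
        weight[m] <- weight[m] + ov
        total[m] <- total[m] + ov * bins$level[r]
      }
    }
  }
  levels <- ifelse(weight > 0, total / pmax(weight, 1e-300), 0)
  new_binned_expression(levels, bin_size_bp)
}

new_binned_expression <- function(levels, bin_size_bp = 150000L) {
  levels <- as.numeric(levels)
  if (length(levels) < 2) stop("need at least two monomers")
  if (any(!is.finite(levels)) || any(levels < 0))
    stop("expression levels must be finite and non-negative")
  structure(list(levels = levels, bin_size_bp = as.integer(bin_size_bp)),
            class = "binned_expression")
}

#' @export
print.binned_expression <- function(x, ...) {
  cat("binned expression:", length(x$levels), "monomers of",
      x$bin_size_bp, "bp; level range [",
      format(min(x$levels)), ",", format(max(x$levels)), "]\n")
  invisible(x)
}

#' Synthesise a block-structured expression profile
#'
#' Generates the kind of per-monomer expression profile seen along real
#' chromosomes -- contiguous highly and lowly expressed blocks plus noise --
#' together with a matching region annotation. Blocks are given as monomer
#' ranges (1-based, inclusive); monomers outside every block have level 0.
#' Noise is Gaussian, truncated at zero so levels stay non-negative. A block
#' is labelled `high` when its mean level exceeds the median of the generated
#' profile, `low` otherwise.
#'
#' @param n_monomers Chain length N.
#' @param blocks Data frame with columns `start`, `end` (monomer indices,
#'   1-based inclusive) and `level` (block mean expression).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer seed; the output is deterministic given it.
#' @param bin_size_bp Genomic content of one monomer.
#' @return List with `expression` (a `binned_expression`) and `regions` (a
#'   region data frame with columns `label`, `start`, `end`).
#' @export
synth_expression_profile <- function(n_monomers, blocks, noise_sd = 0,
                                     seed = NULL, bin_size_bp = 150000L) {
  stopifnot(is.data.frame(blocks), all(c("start", "end", "level") %in% names(blocks)))
  if (n_monomers < 2) stop("need at least two monomers")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(blocks$start < 1) || any(blocks$end > n_monomers) ||
      any(blocks$start > blocks$end))
    stop("blocks must satisfy 1 <= start <= end <= n_monomers")
  if (any(blocks$level < 0)) stop("block levels must be non-negative")
  ord <- order(blocks$start)
  blocks <- blocks[ord, , drop = FALSE]
  if (nrow(blocks) > 1 && any(blocks$start[-1] <= blocks$end[-nrow(blocks)]))
    stop("overlapping blocks")
  if (!is.null(seed)) set.seed(seed)
  levels <- numeric(n_monomers)
  for (r in seq_len(nrow(blocks))) {
    idx <- blocks$start[r]:blocks$end[r]
    levels[idx] <- pmax(0, blocks$level[r] + rnorm(length(idx), 0, noise_sd))
  }
  med <- median(levels)
  regions <- data.frame(
    label = ifelse(blocks$level > med, "high", "low"),
    start = as.integer(blocks$start),
    end = as.integer(blocks$end),
    stringsAsFactors = FALSE)
  list(expression = new_binned_expression(levels, bin_size_bp),
       regions = regions)
}

#' Map expression levels to loop-formation affinities
#'
#' Converts a per-monomer expression profile into per-monomer interaction
#' affinities by linear interpolation between the two anchors of the model:
#' the monomer with the highest expression level receives the minimum
#' affinity `a_min` (transcriptional machinery shields the fibre from direct
#' DNA-DNA contacts) and unexpressed monomers receive the maximum affinity
#' `a_max`:
#' \deqn{a_i = a_{max} - (a_{max} - a_{min}) \frac{e_i - e_{min}}{e_{max} - e_{min}}}
#' The mapping is an extension point: pass `mapping` to substitute another
#' monotonically non-increasing function of expression.
#'
#' @param binned A `binned_expression` (or bare numeric level vector).
#' @param a_min,a_max Affinity bounds, each in `[0, 1]` with
#'   `a_min <= a_max`. Defaults follow the calibrated fibroblast/K562 setup
#'   (0.01 and 0.065).
#' @param mapping Optional function `(levels, a_min, a_max) -> affinities`
#'   replacing the linear map.
#' @return An `affinity_profile` object: list with `affinities`, `a_min`,
#'   `a_max`.
#' @export
affinity_profile <- function(binned, a_min = 0.01, a_max = 0.065,
                             mapping = NULL) {
  e <- if (inherits(binned, "binned_expression")) binned$levels else as.numeric(binned)
  if (any(!is.finite(e)) || any(e < 0))
    stop("expression levels must be finite and non-negative")
  if (!(a_min >= 0 && a_min <= a_max && a_max <= 1))
    stop("need 0 <= a_min <= a_max <= 1")
  if (!is.null(mapping)) {
    a <- mapping(e, a_min, a_max)
  } else if (a_min == a_max) {
    a <- rep(a_min, length(e))
  } else {
    e_min <- min(e); e_max <- max(e)
    if (e_max == e_min)
      stop("all expression levels identical: affinity mapping undefined ",
           "(use a_min == a_max for a homogeneous fibre)")
    a <- a_max - (a_max - a_min) * (e - e_min) / (e_max - e_min)
  }
  if (any(a < a_min - 1e-12) || any(a > a_max + 1e-12))
    stop("mapping produced affinities outside [a_min, a_max]")
  structure(list(affinities = pmin(pmax(a, a_min), a_max),
                 a_min = a_min, a_max = a_max),
            class = "affinity_profile")
}

#' @export
print.affinity_profile <- function(x, ...) {
  cat("affinity profile:", length(x$affinities), "monomers in [",
      x$a_min, ",", x$a_max, "]\n")
  invisible(x)
}

# resolve an affinity argument to a bare numeric vector
as_affinities <- function(x, n = NULL) {
  a <- if (inherits(x, "affinity_profile")) x$affinities else as.numeric(x)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("affinities must lie in [0, 1]")
  if (!is.null(n)) {
    if (length(a) == 1) a <- rep(a, n)
    if (length(a) != n) stop("affinity vector has wrong length")
  }
  a
}

#' Read high/low expression regions from a BED file
#'
#' BED intervals (0-based, half-open, base-pair coordinates; the 4th column
#' carries the label `high` or `low`) are converted to monomer index ranges
#' by any-overlap.
#'
#' @param path BED file path.
#' @param n_monomers Chain length, for clipping.
#' @param bin_size_bp Genomic content of one monomer.
#' @return Region data frame with columns `label`, `start`, `end` (monomer
#'   indices, 1-based inclusive).
#' @export
read_regions_bed <- function(path, n_monomers, bin_size_bp = 150000L) {
  if (!file.exists(path)) stop("region file not found: ", path)
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED region file needs 4 columns (chrom,start,end,label)")
  start_m <- pmax(1L, floor(as.numeric(bed[[2]]) / bin_size_bp) + 1L)
  end_m <- pmin(as.integer(n_monomers), as.integer(ceiling(as.numeric(bed[[3]]) / bin_size_bp)))
  keep <- start_m <= end_m
  regions <- data.frame(label = as.character(bed[[4]])[keep],
                        start = as.integer(start_m[keep]),
                        end = as.integer(end_m[keep]),
                        stringsAsFactors = FALSE)
  validate_regions(regions, n_monomers)
  regions
}

validate_regions <- function(regions, n_monomers) {
  stopifnot(is.data.frame(regions),
            all(c("label", "start", "end") %in% names(regions)))
  if (!all(regions$label %in% c("high", "low")))
    stop("region labels must be 'high' or 'low'")
  if (any(regions$start < 1) || any(regions$end > n_monomers) ||
      any(regions$start > regions$end))
    stop("region bounds outside the chain")
  for (lab in unique(regions$label)) {
    r <- regions[regions$label == lab, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
      stop("overlapping '", lab, "' regions")
  }
  invisible(regions)
}

region_members <- function(regions, label, n_monomers) {
  r <- regions[regions$label == label, , drop = FALSE]
  if (nrow(r) == 0) return(integer(0))
  sort(unique(unlist(mapply(seq, r$start, r$end, SIMPLIFY = FALSE))))
}

#' Write a binned expression profile as a tab-delimited table
#'
#' Inverse of [read_expression_table()] + [bin_to_monomers()] for exactly
#' tiling monomer bins.
#'
#' @param binned A `binned_expression`.
#' @param path Output path.
#' @param chromosome Chromosome label for the first column.
#' @export
write_expression_table <- function(binned, path, chromosome = "chrS") {
  stopifnot(inherits(binned, "binned_expression"))
  n <- length(binned$levels)
  tab <- data.frame(chromosome = chromosome,
                    start = (seq_len(n) - 1) * binned$bin_size_bp,
                    end = seq_len(n) * binned$bin_size_bp,
                    value = binned$levels)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write monomer regions as a BED file
#'
#' @param regions Region data frame (`label`, `start`, `end`, monomer
#'   indices 1-based inclusive).
#' @param path Output path.
#' @param chromosome Chromosome label.
#' @param bin_size_bp Genomic content of one monomer.
#' @export
write_regions_bed <- function(regions, path, chromosome = "chrS",
                              bin_size_bp = 150000L) {
  bed <- data.frame(chrom = chromosome,
                    start = (regions$start - 1) * bin_size_bp,
                    end = regions$end * bin_size_bp,
                    name = regions$label)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
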