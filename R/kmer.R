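#' Count canonical k-mers in a read set
#'
#' Builds the depth spectrum of distinct canonical k-mers (the
#' lexicographic minimum of each k-mer and its reverse complement, so both
#' strands collapse to one key). Windows containing non-ACGT symbols are
#' skipped. Counting is done in C++ with 2-bit packed 64-bit codes, which
#' caps `k` at 31.
#'
#' @param reads one of: a character vector of read sequences, a
#'   [simulate_reads()] result, a `Biostrings::DNAStringSet`, or a path to a
#'   FASTA/FASTQ file (gzipped allowed; format inferred from the
#'   extension).
#' @param k odd k-mer length, `3 <= k <= 31`.
#' @return a [kmer_spectrum()]; empty read sets give an empty spectrum.
#' @examples
#' count_kmers("ACGTA", k = 3)  # {depth 1: 1 k-mer, depth 2: 1 k-mer}
#' @export
count_kmers <- function(reads, k = 21) {
  .assert(.is_count(k) && k >= 3 && k <= 31,
          "'k' must be an integer in [3, 31]", "cytokmer_validation_error")
  .assert(k %% 2 == 1,
          "'k' must be odd: even k-mers can be their own reverse complement",
          "cytokmer_validation_error")
  if (inherits(reads, "read_sim")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  .assert(is.character(reads), "unsupported 'reads' input",
          "cytokmer_validation_error")
  if (length(reads) == 0) {
    return(kmer_spectrum(integer(0), numeric(0), k = k,
                         provenance = "empty read set"))
  }
  df <- cpp_kmer_spectrum(reads, as.integer(k))
  kmer_spectrum(df$depth, df$count, k = k,
                provenance = sprintf("counted from %d reads", length(reads)))
}

#' Filter reads before counting
#'
#' Two pre-filters commonly applied ahead of spectrum analysis: dropping
#' reads whose mean Phred quality is below a floor, and removing exact
#' duplicate reads (PCR duplicates). Quality is interpreted per read (mean
#' of Phred+33 scores), not per base.
#'
#' @param reads character vector of sequences.
#' @param quality optional character vector of Phred+33 quality strings,
#'   same length as `reads`.
#' @param min_mean_quality mean-quality floor (default 20); ignored when
#'   `quality` is `NULL`.
#' @param drop_duplicates remove exact duplicate sequences.
#' @return filtered character vector of reads.
#' @export
filter_reads <- function(reads, quality = NULL, min_mean_quality = 20,
                         drop_duplicates = FALSE) {
  .assert(is.character(reads), "'reads' must be a character vector",
          "cytokmer_validation_error")
  keep <- rep(TRUE, length(reads))
  if (!is.null(quality)) {
    .assert(length(quality) == length(reads),
            "'quality' must match 'reads' in length",
            "cytokmer_validation_error")
    meanq <- vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE)
    keep <- keep & meanq >= min_mean_quality
  }
  reads <- reads[keep]
  if (drop_duplicates) reads <- reads[!duplicated(reads)]
  reads
}

.dense_counts <- function(spec) {
  n <- numeric(max(spec$depth))
  n[spec$depth] <- spec$count
  n
}

#' Error-depth cutoff from the spectrum valley
#'
#' Sequencing errors pile distinct k-mers at depth 1-2; genuine genomic
#' k-mers form peaks at the coverage depth. The cutoff is the first valley:
#' the smallest depth `c >= 2` with `N_{c-1} > N_c` and `N_c <= N_{c+1}`.
#' When no valley exists (unimodal spectrum with no initial descent), or the
#' valley has no mass above it (pure-error spectrum, warned about), the
#' cutoff falls back to 1.
#'
#' @param spec a [kmer_spectrum()].
#' @return integer depth cutoff `c >= 1`.
#' @export
error_cutoff <- function(spec) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  .assert(length(spec$depth) > 0, "empty spectrum",
          "cytokmer_empty_input_error")
  n <- .dense_counts(spec)
  dmax <- length(n)
  if (dmax < 3) return(1L)
  # the valley rule separates an error spike at depth 1-2 from the genomic
  # peaks; without an initial descent there is no error spike and the
  # first dip would be a genuine inter-peak valley (het vs hom), so keep
  # everything
  if (n[1] <= n[2]) return(1L)
  nn <- c(n, 0) # sentinel so the valley after a final descent is visible
  for (d in 2:dmax) {
    if (nn[d - 1] > nn[d] && nn[d] <= nn[d + 1]) {
      if (sum(n[d:dmax]) > 0) return(as.integer(d))
      warning("no genomic peak above the error region; cutoff = 1",
              call. = FALSE)
      return(1L)
    }
  }
  if (all(diff(n) <= 0)) {
    warning("no genomic peak: spectrum decreases monotonically; cutoff = 1",
            call. = FALSE)
  }
  1L
}

#' Genome size from the spectrum quotient
#'
#' The classic spectrum estimator: genome size is the total number of
#' k-mer occurrences above the error cutoff divided by the peak depth,
#' `G = T(c) / d_hom` with `T(c) = sum_{d >= c} d * N_d`. The peak is the
#' depth with the most distinct k-mers at or above `c` (ties broken toward
#' the smaller depth), refined by 3-point parabolic interpolation on log
#' counts plus a half-unit continuity correction (the interpolated maximum
#' of a Poisson depth law sits 0.5 below its mean; see the package
#' vignette). Isolated single-bin peaks are used as-is.
#'
#' @param spec a [kmer_spectrum()].
#' @param c depth cutoff, typically from [error_cutoff()].
#' @return list with `d_hom` (possibly fractional) and `genome_size_bp`.
#' @export
genome_size <- function(spec, c = error_cutoff(spec)) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  keep <- spec$depth >= c
  .assert(any(keep & spec$count > 0), "no spectrum mass above the cutoff",
          "cytokmer_estimation_error")
  n <- .dense_counts(spec)
  above <- seq_along(n) >= c
  m <- which(above & n == max(n[above]))[1]
  d_hom <- as.numeric(m)
  if (m > 1 && m < length(n) && m - 1 >= c && n[m - 1] > 0 && n[m + 1] > 0) {
    l <- log(n[(m - 1):(m + 1)])
    den <- l[1] - 2 * l[2] + l[3]
    if (den < 0) {
      delta <- 0.5 * (l[1] - l[3]) / den
      delta <- max(-0.5, min(0.5, delta))
      d_hom <- m + delta + 0.5 # Poisson continuity correction
    }
  }
  list(d_hom = d_hom, genome_size_bp = occurrence_mass(spec, c) / d_hom)
}

#' Repeat fraction from high-depth spectrum mass
#'
#' Multi-copy sequence shows up as occurrence mass at multiples of the
#' single-copy depth. The repeat fraction is the share of retained mass
#' above `mult * d_hom`; the default threshold 1.5 is the midpoint between
#' the single-copy and two-copy peaks.
#'
#' @param spec a [kmer_spectrum()].
#' @param c depth cutoff.
#' @param d_hom single-copy (homozygous) peak depth.
#' @param mult repeat threshold in units of `d_hom`.
#' @return proportion in `[0, 1]`.
#' @export
repeat_fraction <- function(spec, c, d_hom, mult = 1.5) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  .assert(is.numeric(d_hom) && d_hom > 0, "'d_hom' must be > 0",
          "cytokmer_validation_error")
  total <- occurrence_mass(spec, c)
  .assert(total > 0, "no spectrum mass above the cutoff",
          "cytokmer_estimation_error")
  keep <- spec$depth >= c & spec$depth > mult * d_hom
  sum(as.numeric(spec$depth[keep]) * spec$count[keep]) / total
}

#' Per-site heterozygosity from the half-depth peak
#'
#' Heterozygous sites split k-mer windows between haplotypes, producing a
#' peak at half the homozygous depth. The occurrence mass in the het window
#' `[0.35, 0.65) * d_hom` relative to the single-copy mass (het window plus
#' hom window `[0.65, 1.5] * d_hom`) estimates the fraction `f` of
#' single-copy k-mers covering a heterozygous site; inverting
#' `f = 1 - (1 - h)^k` gives the per-site rate
#' `h = 1 - (1 - f)^(1/k)`.
#'
#' @param spec a [kmer_spectrum()].
#' @param c depth cutoff.
#' @param d_hom homozygous peak depth; must be >= 4 for the half-depth peak
#'   to be resolvable.
#' @param k k-mer length (defaults to the spectrum's).
#' @return per-site heterozygosity in `[0, 1]`.
#' @export
heterozygosity <- function(spec, c, d_hom, k = spec$k) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  .assert(is.numeric(d_hom) && d_hom >= 4,
          "'d_hom' must be >= 4 for the heterozygous peak to resolve",
          "cytokmer_validation_error")
  d <- spec$depth
  mass <- as.numeric(d) * spec$count
  in_het <- d >= c & d >= 0.35 * d_hom & d < 0.65 * d_hom
  in_hom <- d >= c & d >= 0.65 * d_hom & d <= 1.5 * d_hom
  m_het <- sum(mass[in_het])
  m_hom <- sum(mass[in_hom])
  .assert(m_het + m_hom > 0, "no mass in the het/hom windows",
          "cytokmer_estimation_error")
  f <- m_het / (m_het + m_hom)
  1 - (1 - f)^(1 / k)
}

#' Full spectrum report: cutoff, peak, genome size, repeats, heterozygosity
#'
#' Chains [error_cutoff()], [genome_size()], [repeat_fraction()] and
#' [heterozygosity()] and converts base pairs to picograms
#' (`pg = bp / 1e6 / 978`). Heterozygosity is `NA` (with a warning) when
#' the peak depth is below 4.
#'
#' @param spec a [kmer_spectrum()].
#' @param repeat_mult repeat threshold passed to [repeat_fraction()].
#' @return list of class `kmer_estimate`: `k`, `error_cutoff`, `d_hom`,
#'   `genome_size_bp`, `genome_size_pg`, `repeat_fraction`,
#'   `heterozygosity`.
#' @export
kmer_report <- function(spec, repeat_mult = 1.5) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  cc <- error_cutoff(spec)
  gs <- genome_size(spec, cc)
  rep_frac <- repeat_fraction(spec, cc, gs$d_hom, mult = repeat_mult)
  het <- if (gs$d_hom >= 4) {
    heterozygosity(spec, cc, gs$d_hom)
  } else {
    warning("peak depth < 4: heterozygosity unresolvable", call. = FALSE)
    NA_real_
  }
  structure(
    list(k = spec$k, error_cutoff = cc, d_hom = gs$d_hom,
         genome_size_bp = gs$genome_size_bp,
         genome_size_pg = mb_to_pg(gs$genome_size_bp / 1e6),
         repeat_fraction = rep_frac, heterozygosity = het),
    class = "kmer_estimate"
  )
}

#' @export
print.kmer_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("<kmer_estimate> k = %d | cutoff = %d, peak depth = %.2f\n",
           "  genome %.4g bp (%.4g pg), repeats %.1f%%, heterozygosity %s\n"),
    x$k, x$error_cutoff, x$d_hom, x$genome_size_bp, x$genome_size_pg,
    100 * x$repeat_fraction,
    if (is.na(x$heterozygosity)) "NA" else
      sprintf("%.2f%%", 100 * x$heterozygosity)))
  invisible(x)
}
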