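#' Configuration for the diploid k-mer simulators
#'
#' Shared parameterisation of [simulate_kmer_spectrum()] (analytic or
#' Poisson-sampled spectra) and [simulate_reads()] (actual diploid read
#' sets). A diploid genome of haploid length `genome_length` carries
#' heterozygous sites at per-site rate `heterozygosity`, a fraction
#' `repeat_fraction` of its length in repeats of copy number
#' `repeat_multiplicity`, and is sequenced to `coverage`-fold depth in
#' `read_length`-bp reads with per-base error rate `error_rate`.
#'
#' @param genome_length haploid genome length, bp.
#' @param coverage sequencing depth, fold.
#' @param k odd k-mer length >= 3 (odd k-mers cannot be their own reverse
#'   complement, avoiding palindrome double-counting).
#' @param heterozygosity per-site probability the two haplotypes differ.
#' @param repeat_fraction proportion of the genome inside repeats.
#' @param repeat_multiplicity integer copy number of the repeat family
#'   (>= 2).
#' @param error_rate per-base sequencing error probability.
#' @param read_length read length, bp (> k).
#' @param noise if `TRUE`, [simulate_kmer_spectrum()] Poisson-samples each
#'   depth bin instead of returning the expected spectrum.
#' @param seed integer seed.
#' @return object of class `kmer_sim_config`.
#' @export
kmer_sim_config <- function(genome_length, coverage, k = 21,
                            heterozygosity = 0, repeat_fraction = 0,
                            repeat_multiplicity = 2, error_rate = 0,
                            read_length = 150, noise = FALSE, seed = 1) {
  .assert(.is_count(genome_length) && genome_length >= 1,
          "'genome_length' must be a positive count",
          "cytokmer_validation_error")
  .assert(is.numeric(coverage) && coverage > 0, "'coverage' must be > 0",
          "cytokmer_validation_error")
  .assert(.is_count(k) && k >= 3 && k %% 2 == 1,
          "'k' must be an odd integer >= 3 (palindrome avoidance)",
          "cytokmer_validation_error")
  .assert(.is_prob(heterozygosity), "'heterozygosity' must be in [0,1)",
          "cytokmer_validation_error")
  .assert(.is_prob(repeat_fraction), "'repeat_fraction' must be in [0,1)",
          "cytokmer_validation_error")
  .assert(.is_count(repeat_multiplicity) && repeat_multiplicity >= 2,
          "'repeat_multiplicity' must be an integer >= 2",
          "cytokmer_validation_error")
  .assert(.is_prob(error_rate), "'error_rate' must be in [0,1)",
          "cytokmer_validation_error")
  .assert(.is_count(read_length) && read_length > k,
          "'read_length' must exceed 'k'", "cytokmer_validation_error")
  structure(
    list(genome_length = as.integer(genome_length), coverage = coverage,
         k = as.integer(k), heterozygosity = heterozygosity,
         repeat_fraction = repeat_fraction,
         repeat_multiplicity = as.integer(repeat_multiplicity),
         error_rate = error_rate, read_length = as.integer(read_length),
         noise = isTRUE(noise), seed = .check_seed(seed)),
    class = "kmer_sim_config"
  )
}

#' Expected per-k-mer depth
#'
#' A read of length `R` contributes `R - k + 1` k-mer windows, so `C`-fold
#' base coverage translates to k-mer coverage
#' `lambda_k = C * (R - k + 1) / R`.
#'
#' @param cfg a [kmer_sim_config()].
#' @return numeric scalar.
#' @export
kmer_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "kmer_sim_config"))
  cfg$coverage * (cfg$read_length - cfg$k + 1) / cfg$read_length
}

#' Simulate a diploid k-mer spectrum
#'
#' Builds the mixture spectrum implied by the configuration: a homozygous
#' single-copy component at depth `lambda_k`, a heterozygous component at
#' `lambda_k / 2` carrying an occurrence-mass share
#' `1 - (1 - heterozygosity)^k` of the single-copy mass (a k-mer window is
#' haplotype-specific as soon as it covers one heterozygous site), a repeat
#' component at `repeat_multiplicity * lambda_k` carrying `repeat_fraction`
#' of the genomic mass, and error k-mers concentrated at depth 1-2
#' (geometric depth law). Each component spreads over depths as a Poisson
#' pmf; total genomic occurrence mass equals
#' `genome_length * lambda_k` by construction. With `noise = TRUE` every
#' depth bin is Poisson-sampled around its expectation.
#'
#' @param cfg a [kmer_sim_config()].
#' @return a [kmer_spectrum()]; the generating truth is attached as
#'   attribute `"truth"`.
#' @export
simulate_kmer_spectrum <- function(cfg) {
  stopifnot(inherits(cfg, "kmer_sim_config"))
  lam <- kmer_coverage(cfg)
  if (lam < 4) {
    warning("k-mer coverage lambda_k = ", signif(lam, 3),
            " < 4: spectrum peaks will be unresolvable",
            call. = FALSE)
  }
  G <- cfg$genome_length
  r <- cfg$repeat_fraction
  m <- cfg$repeat_multiplicity
  f_het <- 1 - (1 - cfg$heterozygosity)^cfg$k

  # distinct-k-mer budgets per component (occurrence mass / component depth)
  d_hom <- (1 - r) * (1 - f_het) * G
  d_het <- 2 * (1 - r) * f_het * G          # het k-mers: double count, half depth
  d_rep <- r * G / m
  d_err <- G * cfg$coverage * cfg$error_rate * cfg$k

  dmax <- max(qpois(1 - 1e-12, m * lam) + 10, ceiling(3 * lam), 20)
  d <- seq_len(dmax)
  nd <- d_hom * dpois(d, lam) +
    d_het * dpois(d, lam / 2) +
    d_rep * dpois(d, m * lam)
  # geometric error depths starting at 1: heavily concentrated at 1-2
  p_err <- 0.8
  nd <- nd + d_err * dgeom(d - 1, p_err)
  if (cfg$noise) {
    nd <- withr::with_seed(cfg$seed, rpois(length(nd), nd))
  }
  spec <- kmer_spectrum(d[nd > 0], nd[nd > 0], k = cfg$k,
                        provenance = sprintf(
                          "simulated diploid spectrum (noise=%s)",
                          cfg$noise))
  attr(spec, "truth") <- list(lambda_k = lam, config = cfg)
  spec
}

#' Simulate a diploid genome and its sequencing reads
#'
#' Desk-scale end-to-end harness for the counting and estimation stages:
#' builds a random haploid sequence with a repeat family
#' (`repeat_fraction` of the genome as `repeat_multiplicity` copies of one
#' unit), derives a second haplotype by independent per-site heterozygous
#' substitutions, then samples `ceiling(genome_length * coverage /
#' read_length)` reads uniformly and strand-symmetrically, balanced across
#' haplotypes, with independent per-base errors.
#'
#' @param cfg a [kmer_sim_config()] with `genome_length <= 1e7`.
#' @return list of class `read_sim`: `reads` (character vector), `ids`,
#'   `quality` (uniform placeholder qualities), `haplotypes` (character
#'   2-vector), `truth`.
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "kmer_sim_config"))
  .assert(cfg$genome_length <= 1e7,
          "'genome_length' above the 1e7 bp desk-scale cap",
          "cytokmer_size_error")
  G <- cfg$genome_length
  rl <- cfg$read_length
  .assert(G >= rl, "'genome_length' must be >= 'read_length'",
          "cytokmer_validation_error")
  bases <- c("A", "C", "G", "T")

  withr::with_seed(cfg$seed, {
    rep_unit_len <- round(cfg$repeat_fraction * G / cfg$repeat_multiplicity)
    rep_total <- rep_unit_len * cfg$repeat_multiplicity
    uniq_len <- G - rep_total
    hap1 <- c(sample(bases, uniq_len, replace = TRUE),
              rep(sample(bases, rep_unit_len, replace = TRUE),
                  times = cfg$repeat_multiplicity))
    hap2 <- hap1
    if (cfg$heterozygosity > 0) {
      het_idx <- which(runif(G) < cfg$heterozygosity)
      if (length(het_idx)) {
        # substitute with a uniformly chosen different base
        shift <- sample.int(3, length(het_idx), replace = TRUE)
        cur <- match(hap1[het_idx], bases) - 1L
        hap2[het_idx] <- bases[((cur + shift) %% 4L) + 1L]
      }
    }
    hap1 <- paste(hap1, collapse = "")
    hap2 <- paste(hap2, collapse = "")

    n_reads <- ceiling(G * cfg$coverage / rl)
    hap_of <- rep_len(c(1L, 2L), n_reads)          # haplotype-balanced
    starts <- sample.int(G - rl + 1L, n_reads, replace = TRUE)
    reads <- character(n_reads)
    reads[hap_of == 1L] <- substring(hap1, starts[hap_of == 1L],
                                     starts[hap_of == 1L] + rl - 1L)
    reads[hap_of == 2L] <- substring(hap2, starts[hap_of == 2L],
                                     starts[hap_of == 2L] + rl - 1L)
    flip <- runif(n_reads) < 0.5
    if (any(flip)) {
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
    }
    if (cfg$error_rate > 0) {
      n_err <- rbinom(n_reads, rl, cfg$error_rate)
      for (i in which(n_err > 0)) {
        at <- sample.int(rl, n_err[i])
        shift <- sample.int(3, n_err[i], replace = TRUE)
        cur <- match(unlist(strsplit(substring(reads[i], at, at), "")),
                     bases) - 1L
        for (j in seq_along(at)) {
          substr(reads[i], at[j], at[j]) <-
            bases[((cur[j] + shift[j]) %% 4L) + 1L]
        }
      }
    }
  })

  structure(
    list(reads = reads,
         ids = sprintf("read_%d_hap%d", seq_len(n_reads), hap_of),
         quality = strrep("I", rl),
         haplotypes = c(hap1, hap2),
         truth = list(config = cfg, lambda_k = kmer_coverage(cfg))),
    class = "read_sim"
  )
}

#' @export
print.read_sim <- function(x, ...) {
  cat("<read_sim>", length(x$reads), "reads of", nchar(x$reads[1]), "bp,",
      "haploid genome", nchar(x$haplotypes[1]), "bp\n")
  invisible(x)
}

#' Write simulated reads and haplotypes to FASTQ/FASTA
#'
#' @param sim a [simulate_reads()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "read_sim"))
  dss <- Biostrings::DNAStringSet(sim$reads)
  names(dss) <- sim$ids
  quals <- Biostrings::BStringSet(rep(sim$quality, length(sim$reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
write_genome_fasta <- function(sim, path) {
  stopifnot(inherits(sim, "read_sim"))
  dss <- Biostrings::DNAStringSet(sim$haplotypes)
  names(dss) <- c("haplotype1", "haplotype2")
  Biostrings::writeXStringSet(dss, path, format = "fasta")
  invisible(path)
}
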