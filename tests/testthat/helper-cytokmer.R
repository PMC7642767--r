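# shared test utilities: brute-force oracles and small constructors

# reverse complement of a character vector of sequences
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# brute-force canonical k-mer spectrum: plain substring extraction plus
# table(), deliberately independent of the packed-integer counting path
oracle_kmer_spectrum <- function(reads, k) {
  wins <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins)) return(list(depth = integer(0), count = numeric(0)))
  canon <- pmin(wins, revcomp_chr(wins))
  depths <- table(canon)
  h <- table(as.integer(depths))
  list(depth = as.integer(names(h)), count = as.numeric(h))
}

# hand-built peak table for classification tests
make_peaks <- function(position, sd = rep(1, length(position)),
                       area = rep(1000, length(position))) {
  structure(data.frame(position = position, sd = sd,
                       cv = 100 * sd / position, area = area),
            class = c("peak_table", "data.frame"))
}

# one simulated FCM replicate taken through the whole estimation chain
estimate_from_sim <- function(cfg, expected_range) {
  et <- simulate_fcm_events(cfg)
  pk <- detect_and_fit_peaks(build_histogram(et), events = et)
  cl <- classify_peaks(pk, cfg$standard_1c, expected_range)
  estimate_gs(cl[cl$source == "sample" & cl$ploidy_label == "2C", ],
              cl[cl$source == "standard" & cl$ploidy_label == "2C", ],
              cfg$standard_1c)
}
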