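#' K-mer depth spectra
#'
#' A `kmer_spectrum` is the histogram a k-mer counter emits: for each depth
#' `d >= 1`, the number `N_d` of distinct canonical k-mers observed exactly
#' `d` times. All spectrum estimators in the package consume this type.
#'
#' @param depth integer vector of depths (>= 1, strictly increasing after
#'   sorting; duplicates are summed).
#' @param count non-negative counts of distinct k-mers per depth.
#' @param k the (odd) k-mer length the spectrum was built with.
#' @param provenance free-text origin note.
#' @return object of class `kmer_spectrum` with fields `depth`, `count`,
#'   `k`, `provenance`.
#' @export
kmer_spectrum <- function(depth, count, k, provenance = "unknown") {
  .assert(.is_count(k) && k %% 2 == 1 && k >= 3,
          "'k' must be an odd integer >= 3 (even k admits palindromic k-mers)",
          "cytokmer_validation_error")
  .assert(length(depth) == length(count), "depth/count length mismatch",
          "cytokmer_validation_error")
  if (length(depth)) {
    .assert(all(depth >= 1) && all(depth == round(depth)),
            "depths must be integers >= 1", "cytokmer_validation_error")
    .assert(all(count >= 0) && all(is.finite(count)),
            "counts must be finite and >= 0", "cytokmer_validation_error")
    agg <- tapply(as.numeric(count), as.integer(depth), sum)
    depth <- as.integer(names(agg))
    count <- as.numeric(agg)
    ord <- order(depth)
    depth <- depth[ord]; count <- count[ord]
    keep <- count > 0
    depth <- depth[keep]; count <- count[keep]
  }
  structure(list(depth = as.integer(depth), count = as.numeric(count),
                 k = as.integer(k), provenance = provenance),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("<kmer_spectrum> k =", x$k, "|", length(x$depth), "depth bins,",
      format(sum(x$count), big.mark = ","), "distinct k-mers, total mass",
      format(occurrence_mass(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total k-mer occurrence mass above a depth cutoff
#'
#' `T(c) = sum_{d >= c} d * N_d`, the "total number of k-mers" entering the
#' genome-size quotient once error k-mers below `c` are discarded.
#'
#' @param spec a [kmer_spectrum()].
#' @param c lowest depth retained (default 1 = everything).
#' @return numeric scalar.
#' @export
occurrence_mass <- function(spec, c = 1) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  keep <- spec$depth >= c
  sum(as.numeric(spec$depth[keep]) * spec$count[keep])
}

#' Read and write spectra in two-column histogram format
#'
#' Whitespace-separated `depth count` rows, ascending depth — the de-facto
#' interchange dialect of k-mer counters, so spectra computed elsewhere
#' (e.g. `jellyfish histo`) drop straight in.
#'
#' @param spec a [kmer_spectrum()].
#' @param path file path.
#' @param k k-mer length to attach when reading (the format does not carry
#'   it).
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns a `kmer_spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  writeLines(paste(spec$depth, format(spec$count, scientific = FALSE,
                                      trim = TRUE)), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, k) {
  df <- read.table(path, header = FALSE, col.names = c("depth", "count"))
  kmer_spectrum(df$depth, df$count, k = k, provenance = path)
}
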