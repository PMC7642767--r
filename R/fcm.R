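#' Bin fluorescence events into a channel histogram
#'
#' Equal-width channels spanning `[0, max(fluorescence)]`, mirroring the
#' relative-intensity histograms a cytometer displays.
#'
#' @param events an [event_table()].
#' @param n_channels number of channels (>= 64; default 1024 mimics common
#'   instrument resolution).
#' @return an object of class `fcm_histogram` with `bin_edges` (length
#'   `n_channels + 1`), `mids` and `counts`; `sum(counts)` equals the number
#'   of events.
#' @export
build_histogram <- function(events, n_channels = 1024) {
  stopifnot(inherits(events, "event_table"))
  .assert(length(events$fluorescence) >= 1, "no events to bin",
          "cytokmer_empty_input_error")
  .assert(.is_count(n_channels) && n_channels >= 64,
          "'n_channels' must be a count >= 64", "cytokmer_validation_error")
  hi <- max(events$fluorescence)
  if (hi <= 0) hi <- 1 # all-zero degenerate stream still bins
  edges <- seq(0, hi, length.out = n_channels + 1)
  idx <- findInterval(events$fluorescence, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_channels)
  structure(
    list(n_channels = as.integer(n_channels), bin_edges = edges,
         mids = (edges[-1] + edges[-length(edges)]) / 2, counts = counts,
         n_events = length(events$fluorescence)),
    class = "fcm_histogram"
  )
}

#' @export
print.fcm_histogram <- function(x, ...) {
  cat("<fcm_histogram>", x$n_channels, "channels,", x$n_events, "events,",
      "range [0,", format(max(x$bin_edges), digits = 5), "]\n")
  invisible(x)
}

#' Detect and fit fluorescence peaks
#'
#' Smooths the channel counts with a centred moving average, finds interior
#' local maxima whose smoothed height exceeds `min_peak_events`, and refines
#' each by a Gaussian moment fit (weighted mean and sd of channel midpoints)
#' over the contiguous window descending from the mode to the valley floor
#' on each side. Edge channels are not peak candidates, so a monotone debris
#' tail never registers as a peak.
#'
#' @param hist an `fcm_histogram` from [build_histogram()].
#' @param min_peak_events minimum smoothed height for a candidate mode;
#'   default 0.5% of the total event count.
#' @param smooth_window moving-average width in channels (odd; default 5).
#' @param events optional [event_table()] the histogram was built from;
#'   when supplied, each peak's mean and sd are computed from the raw event
#'   values inside the peak window instead of from binned midpoints,
#'   removing channel-quantization error.
#' @return a `data.frame` of class `peak_table`, sorted by position, with
#'   columns `position`, `sd`, `cv` (percent), `area` (event count).
#' @export
detect_and_fit_peaks <- function(hist, min_peak_events = NULL,
                                 smooth_window = 5, events = NULL) {
  stopifnot(inherits(hist, "fcm_histogram"))
  .assert(sum(hist$counts) > 0, "histogram is empty",
          "cytokmer_empty_input_error")
  if (is.null(min_peak_events)) min_peak_events <- 0.005 * hist$n_events
  .assert(.is_count(smooth_window %/% 1) && smooth_window >= 1,
          "'smooth_window' must be >= 1", "cytokmer_validation_error")
  w <- as.integer(smooth_window)
  if (w %% 2 == 0) w <- w + 1L
  # mode detection needs smoothing on the scale of a whole peak, or Poisson
  # ripple on a flat top splinters one population into several maxima; a
  # wider window is used for detection, raw counts/events for the moments
  wd <- 4L * w + 1L
  # moving average with honest partial windows at the edges (zero-padding
  # would bend a monotone debris slope into a spurious interior maximum)
  n <- length(hist$counts)
  h <- wd %/% 2L
  cs <- cumsum(c(0, hist$counts))
  lo_i <- pmax(seq_len(n) - h, 1L)
  hi_i <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi_i + 1L] - cs[lo_i]) / (hi_i - lo_i + 1L)

  # interior local maxima: strictly above the left neighbour, >= the right
  # (left-biased plateau tie-break), above the height floor
  cand <- which(sm[2:(n - 1)] > sm[1:(n - 2)] &
                  sm[2:(n - 1)] >= sm[3:n]) + 1L
  cand <- cand[sm[cand] * wd >= min_peak_events]
  # collapse runs of adjacent candidates (flat tops) to their first channel
  if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) > 1)]
  .assert(length(cand) > 0, "no peak exceeds 'min_peak_events'",
          "cytokmer_no_peak_error")
  # topographic prominence filter: a mode must rise at least half its own
  # height above the saddles connecting it to higher ground on either side.
  # This collapses Poisson ripple on a flat top to its highest mode and
  # rejects spurious maxima riding a monotone debris slope.
  saddle <- function(m, step) {
    j <- m + step
    minv <- sm[m]
    while (j >= 1 && j <= n) {
      if (sm[j] > sm[m]) return(minv)
      minv <- min(minv, sm[j])
      j <- j + step
    }
    -Inf # no higher ground on this side
  }
  prominent <- vapply(cand, function(m) {
    s <- max(saddle(m, -1L), saddle(m, 1L))
    !is.finite(s) || s <= 0.5 * sm[m]
  }, logical(1))
  cand <- cand[prominent]
  .assert(length(cand) > 0, "no sufficiently prominent peak",
          "cytokmer_no_peak_error")

  ev <- NULL
  if (!is.null(events)) {
    stopifnot(inherits(events, "event_table"))
    ev <- events$fluorescence
  }
  # walk one flank outward to the valley floor: shallow ripple dips (above
  # half the mode height) are crossed, a rise after a true valley stops the
  # walk, as does a zero channel
  flank <- function(m, step) {
    i <- m
    vmin <- sm[m]
    repeat {
      nxt <- i + step
      if (nxt < 1 || nxt > n || sm[nxt] == 0) return(i)
      if (sm[nxt] <= sm[i]) {
        vmin <- min(vmin, sm[nxt])
      } else if (vmin <= 0.5 * sm[m]) {
        return(i)
      }
      i <- nxt
    }
  }
  fit_one <- function(m) {
    lo <- flank(m, -1L)
    hi <- flank(m, +1L)
    # a genuine population stands well above the level just outside its
    # window; the broad maximum of a noisy monotone debris slope does not
    base_l <- if (lo > 1) sm[lo - 1] else sm[lo]
    base_r <- if (hi < n) sm[hi + 1] else sm[hi]
    if (sm[m] < 2 * max(base_l, base_r)) return(NULL)
    win <- lo:hi
    wts <- hist$counts[win]
    if (sum(wts) == 0) return(NULL)
    if (!is.null(ev)) {
      inside <- ev >= hist$bin_edges[lo] & ev <= hist$bin_edges[hi + 1]
      mu <- mean(ev[inside])
      s2 <- if (sum(inside) > 1) stats::var(ev[inside]) else 0
    } else {
      mu <- sum(hist$mids[win] * wts) / sum(wts)
      s2 <- sum(wts * (hist$mids[win] - mu)^2) / sum(wts)
    }
    data.frame(position = mu, sd = sqrt(s2),
               cv = 100 * sqrt(s2) / mu, area = sum(wts))
  }
  fits <- do.call(rbind, lapply(cand, fit_one))
  fits <- fits[fits$area >= min_peak_events, , drop = FALSE]
  .assert(nrow(fits) > 0, "no peak exceeds 'min_peak_events'",
          "cytokmer_no_peak_error")
  fits <- fits[order(fits$position), , drop = FALSE]
  rownames(fits) <- NULL
  class(fits) <- c("peak_table", "data.frame")
  fits
}

#' Label fitted peaks as sample 2C, standard 2C or 4C
#'
#' Resolves which peak belongs to the co-prepared internal standard and
#' which to the sample. Every ordered pair of peaks is tried as
#' (standard 2C, sample 2C); a pairing is consistent when the implied sample
#' 1C — `standard_1c * position_sample / position_standard` — falls inside
#' `expected_sample_range`. Among consistent pairings the one leaving the
#' fewest peaks unexplained wins, where a leftover peak is explained if it
#' sits at twice an assigned 2C position within `4c_tol_sd` combined
#' standard deviations (such peaks are labelled 4C and excluded from
#' estimation). Two equally good pairings raise an ambiguity error — the
#' situation where a different internal standard should be used.
#'
#' @param peaks a `peak_table` from [detect_and_fit_peaks()] (>= 2 rows).
#' @param standard_1c known 1C of the internal standard, pg.
#' @param expected_sample_range numeric length-2, the plausible sample 1C
#'   range in pg; deliberately user-declared, never guessed.
#' @param tol_sd_4c combined-sd multiple for the doubling rule (default 3).
#' @return the `peak_table` with added columns `ploidy_label`
#'   (`2C`/`4C`/`unassigned`) and `source` (`sample`/`standard`/`NA`).
#' @export
classify_peaks <- function(peaks, standard_1c, expected_sample_range,
                           tol_sd_4c = 3) {
  stopifnot(inherits(peaks, "peak_table"))
  .assert(nrow(peaks) >= 2, "need at least two peaks to classify",
          "cytokmer_classification_error")
  .assert(length(expected_sample_range) == 2 &&
            expected_sample_range[1] < expected_sample_range[2],
          "'expected_sample_range' must be an increasing (lo, hi) in pg",
          "cytokmer_validation_error")
  np <- nrow(peaks)
  pos <- peaks$position
  sds <- peaks$sd

  is_double_of <- function(p, q) {
    tol <- tol_sd_4c * sqrt(sds[p]^2 + (2 * sds[q])^2)
    abs(pos[p] - 2 * pos[q]) <= tol
  }

  cands <- list()
  for (std in seq_len(np)) for (smp in seq_len(np)) {
    if (std == smp) next
    implied <- standard_1c * pos[smp] / pos[std]
    if (implied < expected_sample_range[1] ||
        implied > expected_sample_range[2]) next
    rest <- setdiff(seq_len(np), c(std, smp))
    explained <- vapply(rest, function(p) {
      is_double_of(p, std) || is_double_of(p, smp)
    }, logical(1))
    cands[[length(cands) + 1]] <- list(std = std, smp = smp,
                                       implied = implied,
                                       unexplained = sum(!explained),
                                       fourc = rest[explained])
  }
  .assert(length(cands) > 0,
          "no peak pairing yields a sample 1C inside 'expected_sample_range'",
          "cytokmer_classification_error")
  unexp <- vapply(cands, `[[`, numeric(1), "unexplained")
  best <- which(unexp == min(unexp))
  if (length(best) > 1) {
    stop(structure(
      class = c("cytokmer_ambiguity_error", "error", "condition"),
      list(message = paste(
        "ambiguous peak assignment: more than one pairing is consistent",
        "with 'expected_sample_range'; re-run with a different internal",
        "standard whose peak separates from the sample"), call = NULL)
    ))
  }
  ch <- cands[[best]]
  peaks$ploidy_label <- "unassigned"
  peaks$source <- NA_character_
  peaks$ploidy_label[c(ch$std, ch$smp)] <- "2C"
  peaks$source[ch$std] <- "standard"
  peaks$source[ch$smp] <- "sample"
  if (length(ch$fourc)) {
    for (p in ch$fourc) {
      peaks$ploidy_label[p] <- "4C"
      peaks$source[p] <- if (is_double_of(p, ch$smp)) "sample" else "standard"
    }
  }
  peaks
}

#' Peak-level CV quality control
#'
#' A fitted peak passes QC when its coefficient of variation is strictly
#' below `cv_max` percent (default 5, the conventional acceptance bar for
#' cytometry C-value work).
#'
#' @param peak one row of a `peak_table` (or any list with a `cv` field).
#' @param cv_max threshold in percent.
#' @return logical flag.
#' @export
qc_cv <- function(peak, cv_max = 5.0) {
  cv <- if (is.data.frame(peak)) peak$cv[1] else peak$cv
  .assert(is.numeric(cv) && is.finite(cv) && cv >= 0,
          "peak has no valid 'cv'", "cytokmer_validation_error")
  cv < cv_max
}

#' Genome size from the 2C peak-position ratio
#'
#' The calibration at the heart of internal-standard flow cytometry: the
#' sample's DNA content is the standard's known content scaled by the ratio
#' of mean 2C peak positions,
#' `1C_sample = 1C_standard * position_sample / position_standard`.
#'
#' @param sample_peak,standard_peak single rows of a classified
#'   `peak_table` (sample 2C and standard 2C).
#' @param standard_1c the standard's 1C value, pg.
#' @param cv_max QC threshold applied to both peaks, percent.
#' @param replicate_id carried through to the result.
#' @return a list of class `ratio_estimate`: `one_c` (pg), `genome_mb`
#'   (`one_c * 978`, unrounded), both peaks, `qc_pass`, `replicate_id`.
#' @export
estimate_gs <- function(sample_peak, standard_peak, standard_1c,
                        cv_max = 5.0, replicate_id = NA_character_) {
  pos_s <- if (is.data.frame(sample_peak)) sample_peak$position[1] else
    sample_peak$position
  pos_r <- if (is.data.frame(standard_peak)) standard_peak$position[1] else
    standard_peak$position
  .assert(is.finite(pos_s) && pos_s > 0 && is.finite(pos_r) && pos_r > 0,
          "peak positions must be > 0", "cytokmer_domain_error")
  .assert(is.numeric(standard_1c) && standard_1c > 0,
          "'standard_1c' must be > 0 pg", "cytokmer_domain_error")
  one_c <- standard_1c * pos_s / pos_r
  structure(
    list(one_c = one_c, genome_mb = pg_to_mb(one_c),
         sample_peak = sample_peak, standard_peak = standard_peak,
         qc_pass = qc_cv(sample_peak, cv_max) && qc_cv(standard_peak, cv_max),
         replicate_id = replicate_id),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> 1C = %.3f pg (%.0f Mb), qc_pass = %s\n",
              x$one_c, x$genome_mb, x$qc_pass))
  invisible(x)
}

#' Aggregate replicate estimates into a species/sex summary row
#'
#' Produces one reporting row per species and sex: mean 1C over QC-passed
#' replicates (2 decimals), the Mb equivalent rounded from the unrounded
#' mean, the standard error of the mean in Mb (omitted when n = 1), and the
#' replicate count. All arithmetic is done on unrounded values; rounding is
#' purely presentational.
#'
#' @param estimates list of [estimate_gs()] results, all from the same
#'   species and sex.
#' @param species,sex labels for the summary row.
#' @param require_qc drop estimates whose `qc_pass` is `FALSE` (default).
#' @return a one-row `data.frame` of class `species_summary`: `species`,
#'   `sex`, `mean_1c` (pg, 2 dp), `genome_mb` (integer Mb), `se_mb`
#'   (integer Mb or `NA`), `n`.
#' @export
aggregate_replicates <- function(estimates, species = NA_character_,
                                 sex = NA_character_, require_qc = TRUE) {
  .assert(is.list(estimates) && length(estimates) >= 1,
          "need at least one estimate", "cytokmer_validation_error")
  ok <- vapply(estimates, function(e) inherits(e, "ratio_estimate"),
               logical(1))
  .assert(all(ok), "all elements must be ratio_estimate objects",
          "cytokmer_validation_error")
  if (require_qc) {
    estimates <- Filter(function(e) isTRUE(e$qc_pass), estimates)
    .assert(length(estimates) >= 1, "no estimate passed QC",
            "cytokmer_validation_error")
  }
  pg <- vapply(estimates, `[[`, numeric(1), "one_c")
  n <- length(pg)
  mean_pg <- mean(pg)
  se_mb <- if (n >= 2) round(pg_to_mb(sd(pg) / sqrt(n))) else NA_real_
  out <- data.frame(species = species, sex = sex,
                    mean_1c = round(mean_pg, 2),
                    genome_mb = round(pg_to_mb(mean_pg)),
                    se_mb = se_mb, n = n)
  class(out) <- c("species_summary", "data.frame")
  out
}
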