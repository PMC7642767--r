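#' Configuration for the flow-cytometry event simulator
#'
#' Describes one co-preparation of a sample of unknown genome size with an
#' internal standard of known 1C value, as acquired on a cytometer in ungated
#' mode. Diploid G1 nuclei form a Gaussian 2C peak; a configurable fraction
#' of nuclei sit at 4C (replicated or endoreduplicated, at exactly twice the
#' 2C position); debris forms a decaying background below the lowest 2C peak.
#'
#' @param true_1c ground-truth haploid DNA content of the sample, pg (> 0).
#' @param standard_name,standard_1c internal standard identity and its 1C
#'   value in pg (> 0).
#' @param gain linear fluorescence gain, instrument units per pg of DNA.
#' @param cv_sample,cv_standard coefficients of variation of the two 2C
#'   peaks, percent (>= 0).
#' @param n_events total particles to emit (>= 1); instrument practice is to
#'   stop acquisition above ~20,000.
#' @param debris_fraction expected proportion of events that are debris.
#' @param tetraploid_fraction expected proportion of each population's nuclei
#'   at 4C. `debris_fraction + tetraploid_fraction` must be < 1.
#' @param seed integer seed; the simulator is a pure function of its config.
#' @return an object of class `fcm_sim_config`.
#' @export
fcm_sim_config <- function(true_1c, standard_name = "Locusta migratoria",
                           standard_1c = 6.20, gain = 10,
                           cv_sample = 2, cv_standard = 2,
                           n_events = 20000, debris_fraction = 0.05,
                           tetraploid_fraction = 0.10, seed = 1) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  .assert(num1(true_1c) && true_1c > 0, "'true_1c' must be > 0 pg",
          "cytokmer_validation_error")
  .assert(num1(standard_1c) && standard_1c > 0, "'standard_1c' must be > 0 pg",
          "cytokmer_validation_error")
  .assert(num1(gain) && gain > 0, "'gain' must be > 0",
          "cytokmer_validation_error")
  .assert(num1(cv_sample) && cv_sample >= 0, "'cv_sample' must be >= 0",
          "cytokmer_validation_error")
  .assert(num1(cv_standard) && cv_standard >= 0, "'cv_standard' must be >= 0",
          "cytokmer_validation_error")
  .assert(.is_count(n_events) && n_events >= 1, "'n_events' must be >= 1",
          "cytokmer_validation_error")
  .assert(.is_prob(debris_fraction), "'debris_fraction' must be in [0,1)",
          "cytokmer_validation_error")
  .assert(.is_prob(tetraploid_fraction),
          "'tetraploid_fraction' must be in [0,1)",
          "cytokmer_validation_error")
  .assert(debris_fraction + tetraploid_fraction < 1,
          "'debris_fraction' + 'tetraploid_fraction' must be < 1",
          "cytokmer_validation_error")
  structure(
    list(true_1c = true_1c, standard_name = standard_name,
         standard_1c = standard_1c, gain = gain, cv_sample = cv_sample,
         cv_standard = cv_standard, n_events = as.integer(n_events),
         debris_fraction = debris_fraction,
         tetraploid_fraction = tetraploid_fraction, seed = .check_seed(seed)),
    class = "fcm_sim_config"
  )
}

#' Simulate a co-prepared flow-cytometry event stream
#'
#' Emits `n_events` fluorescence intensities: sample and standard 2C nuclei
#' as Gaussian populations centred at `2 * 1C * gain` with the configured
#' CVs, 4C nuclei at exactly twice each 2C centre (same CV), and debris as a
#' truncated exponential on `(0, lowest 2C centre)`. Non-debris events split
#' evenly between sample and standard; population membership is multinomial.
#'
#' @param cfg an [fcm_sim_config()].
#' @param replicate_id replicate label for the returned table.
#' @param species,sex metadata copied into the returned table.
#' @return an [event_table()] whose `population_truth` labels each event
#'   `sample`, `standard` or `debris`, and whose `truth` field records the
#'   generating parameters.
#' @export
simulate_fcm_events <- function(cfg, replicate_id = "sim1",
                                species = "simulated", sex = NA_character_) {
  stopifnot(inherits(cfg, "fcm_sim_config"))
  c_sample <- 2 * cfg$true_1c * cfg$gain
  c_standard <- 2 * cfg$standard_1c * cfg$gain
  low <- min(c_sample, c_standard)

  withr::with_seed(cfg$seed, {
    n <- cfg$n_events
    half <- (1 - cfg$debris_fraction) / 2
    grp <- sample(c("debris", "sample", "standard"), n, replace = TRUE,
                  prob = c(cfg$debris_fraction, half, half))
    fl <- numeric(n)
    for (g in c("sample", "standard")) {
      idx <- which(grp == g)
      if (!length(idx)) next
      centre <- if (g == "sample") c_sample else c_standard
      cv <- if (g == "sample") cfg$cv_sample else cfg$cv_standard
      is4c <- runif(length(idx)) < cfg$tetraploid_fraction
      mu <- ifelse(is4c, 2 * centre, centre)
      fl[idx] <- rnorm(length(idx), mean = mu, sd = cv / 100 * mu)
    }
    idx <- which(grp == "debris")
    if (length(idx)) {
      # inverse-CDF draw from Exp(rate) truncated to (0, low); rate chosen so
      # the untruncated mean is low/4, giving the monotone low-channel tail
      rate <- 4 / low
      u <- runif(length(idx))
      fl[idx] <- -log(1 - u * (1 - exp(-rate * low))) / rate
    }
    fl <- pmax(fl, 0)
  })

  event_table(fl, replicate_id = replicate_id, species = species, sex = sex,
              standard_name = cfg$standard_name, standard_1c = cfg$standard_1c,
              population_truth = grp,
              truth = list(true_1c = cfg$true_1c, gain = cfg$gain,
                           sample_2c = c_sample, standard_2c = c_standard,
                           config = cfg))
}
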