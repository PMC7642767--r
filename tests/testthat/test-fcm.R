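test_that("histograms conserve events and isolate point masses", {
  et <- event_table(rep(7.5, 100))
  h <- build_histogram(et, n_channels = 1024)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(max(h$counts), 100)

  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, n_events = 20000,
                        seed = 1)
  et2 <- simulate_fcm_events(cfg)
  h2 <- build_histogram(et2)
  expect_equal(sum(h2$counts), 20000)
  # channels containing the true 2C centres are local maxima of the counts
  for (centre in c(124, 192.8)) {
    ch <- findInterval(centre, h2$bin_edges, all.inside = TRUE)
    expect_gt(h2$counts[ch], 0.5 * max(h2$counts))
  }
  expect_error(build_histogram(et, n_channels = 32),
               class = "cytokmer_validation_error")
})

test_that("two noiseless spikes are fitted at their positions with zero CV", {
  et <- event_table(c(rep(100, 500), rep(200, 500), 410))
  pk <- detect_and_fit_peaks(build_histogram(et), events = et)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$position, c(100, 200))
  expect_equal(pk$cv, c(0, 0))
  expect_equal(pk$area, c(500, 500))
})

test_that("fitted peaks recover simulated centres and CVs accurately", {
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, cv_sample = 2,
                        cv_standard = 2, n_events = 20000,
                        debris_fraction = 0, tetraploid_fraction = 0,
                        seed = 1)
  et <- simulate_fcm_events(cfg)
  pk <- detect_and_fit_peaks(build_histogram(et), events = et)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$position[1] - 124) / 124, 0.005)
  expect_lt(abs(pk$position[2] - 192.8) / 192.8, 0.005)
  expect_lt(max(abs(pk$cv - 2)), 0.5)
})

test_that("a pure debris slope raises a no-peak error", {
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, seed = 2,
                        debris_fraction = 0.98, tetraploid_fraction = 0,
                        n_events = 5000)
  ev <- simulate_fcm_events(cfg)
  debris_only <- event_table(ev$fluorescence[ev$population_truth == "debris"])
  expect_error(detect_and_fit_peaks(build_histogram(debris_only)),
               class = "cytokmer_no_peak_error")
})

test_that("peak classification resolves standard, sample and 4C peaks", {
  pk <- make_peaks(c(100, 200))
  cl <- classify_peaks(pk, standard_1c = 3.41, expected_sample_range = c(5, 9))
  expect_equal(cl$source, c("standard", "sample"))
  expect_equal(cl$ploidy_label, c("2C", "2C"))

  pk3 <- make_peaks(c(100, 200, 400))
  cl3 <- classify_peaks(pk3, 3.41, c(5, 9))
  expect_equal(cl3$source, c("standard", "sample", "sample"))
  expect_equal(cl3$ploidy_label, c("2C", "2C", "4C"))
})

test_that("overlapping peaks raise an ambiguity error, no consistent pairing a classification error", {
  pk <- make_peaks(c(100, 105))
  expect_error(classify_peaks(pk, 3.41, c(3, 4)),
               class = "cytokmer_ambiguity_error")
  expect_error(classify_peaks(make_peaks(c(100, 200)), 3.41, c(50, 60)),
               class = "cytokmer_classification_error")
})

test_that("the peak-ratio formula reproduces known ratios", {
  smp <- make_peaks(200)
  std <- make_peaks(100)
  expect_equal(estimate_gs(smp, std, 3.41)$one_c, 6.82)
  expect_equal(estimate_gs(make_peaks(150), make_peaks(150), 6.20)$one_c, 6.20)
  est <- estimate_gs(make_peaks(1554.8), make_peaks(1000.0), 6.20)
  expect_equal(round(est$one_c, 2), 9.64)
  expect_equal(est$genome_mb, est$one_c * 978)
  expect_error(estimate_gs(make_peaks(1), std, -2),
               class = "cytokmer_domain_error")
})

test_that("CV quality control is strict at the threshold", {
  expect_true(qc_cv(list(cv = 2.0)))
  expect_false(qc_cv(list(cv = 5.0)))
  expect_false(qc_cv(list(cv = 5.0001)))
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, cv_sample = 8,
                        debris_fraction = 0, tetraploid_fraction = 0,
                        seed = 3)
  et <- simulate_fcm_events(cfg)
  pk <- detect_and_fit_peaks(build_histogram(et), events = et)
  sample_pk <- pk[which.max(pk$position), ]
  expect_false(qc_cv(sample_pk))
})

test_that("replicate aggregation reports rounded means and standard errors", {
  ests <- lapply(c(10.0, 10.2, 10.4), function(pg) {
    estimate_gs(make_peaks(pg, sd = 0.01), make_peaks(6.20, sd = 0.01), 6.20)
  })
  s <- aggregate_replicates(ests, species = "sp", sex = "F")
  expect_equal(s$mean_1c, 10.20)
  expect_equal(s$genome_mb, 9976)
  expect_equal(s$se_mb, 113)
  expect_equal(s$n, 3)

  one <- aggregate_replicates(ests[2], species = "sp", sex = "M")
  expect_equal(one$n, 1)
  expect_true(is.na(one$se_mb))

  same <- aggregate_replicates(rep(ests[2], 4))
  expect_equal(same$se_mb, 0)
  expect_equal(same$mean_1c, 10.2)
})

test_that("pg/Mb conversions invert each other and reject negatives", {
  expect_equal(pg_to_mb(1), 978)
  expect_equal(pg_to_mb(0), 0)
  x <- c(0.5, 6.2, 18.64)
  expect_equal(mb_to_pg(pg_to_mb(x)), x, tolerance = 1e-12)
  expect_error(pg_to_mb(-1), class = "cytokmer_domain_error")
})

test_that("estimates are invariant to fluorescence gain and monotone in the sample peak", {
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, seed = 4)
  et <- simulate_fcm_events(cfg)
  scaled <- event_table(et$fluorescence * 3.7, standard_1c = 6.20,
                        population_truth = et$population_truth)
  fit <- function(e) {
    pk <- detect_and_fit_peaks(build_histogram(e), events = e)
    cl <- classify_peaks(pk, 6.20, c(8, 11))
    estimate_gs(cl[cl$source == "sample" & cl$ploidy_label == "2C", ],
                cl[cl$source == "standard" & cl$ploidy_label == "2C", ],
                6.20)$one_c
  }
  expect_equal(fit(et), fit(scaled), tolerance = 1e-9)

  std <- make_peaks(100)
  ones <- vapply(c(150, 200, 250), function(p) {
    estimate_gs(make_peaks(p), std, 6.20)$one_c
  }, numeric(1))
  expect_true(all(diff(ones) > 0))
})

test_that("simulated replicates recover the true 1C within one percent", {
  for (s in 1:3) {
    cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, cv_sample = 2,
                          cv_standard = 2, n_events = 20000,
                          debris_fraction = 0.05, seed = s)
    est <- estimate_from_sim(cfg, c(8, 11))
    expect_lt(abs(est$one_c - 9.64) / 9.64, 0.01)
    expect_true(est$qc_pass)
  }
})
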