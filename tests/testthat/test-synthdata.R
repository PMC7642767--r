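test_that("zero-noise FCM simulation puts every event exactly on its 2C centre", {
  cfg <- fcm_sim_config(true_1c = 6.20, standard_1c = 3.41, gain = 10,
                        cv_sample = 0, cv_standard = 0,
                        debris_fraction = 0, tetraploid_fraction = 0,
                        n_events = 500, seed = 1)
  et <- simulate_fcm_events(cfg)
  smp <- et$fluorescence[et$population_truth == "sample"]
  std <- et$fluorescence[et$population_truth == "standard"]
  expect_true(all(smp == 124.0))
  expect_true(all(std == 2 * 3.41 * 10))
  expect_length(et$fluorescence, 500)
})

test_that("simulated 2C populations have the configured centre and spread", {
  cfg <- fcm_sim_config(true_1c = 6.20, standard_1c = 3.41, cv_sample = 2,
                        n_events = 20000, debris_fraction = 0,
                        tetraploid_fraction = 0, seed = 7)
  et <- simulate_fcm_events(cfg)
  smp <- et$fluorescence[et$population_truth == "sample"]
  centre <- 2 * 6.20 * 10
  se <- (0.02 * centre) / sqrt(length(smp))
  expect_lt(abs(mean(smp) - centre), 3 * se)
})

test_that("debris events arrive at the configured rate and below the 2C peaks", {
  cfg <- fcm_sim_config(true_1c = 6.20, standard_1c = 3.41,
                        debris_fraction = 0.1, tetraploid_fraction = 0,
                        n_events = 20000, seed = 3)
  et <- simulate_fcm_events(cfg)
  ndeb <- sum(et$population_truth == "debris")
  bounds <- qbinom(c(0.005, 0.995), 20000, 0.1)
  expect_gte(ndeb, bounds[1])
  expect_lte(ndeb, bounds[2])
  expect_true(all(et$fluorescence[et$population_truth == "debris"] <
                    2 * 3.41 * 10))
})

test_that("FCM simulator is a pure function of its seed and validates fields", {
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, seed = 11)
  expect_identical(simulate_fcm_events(cfg)$fluorescence,
                   simulate_fcm_events(cfg)$fluorescence)
  expect_error(fcm_sim_config(true_1c = -1, standard_1c = 6.2),
               "true_1c", class = "cytokmer_validation_error")
  expect_error(fcm_sim_config(true_1c = 1, standard_1c = 6.2, n_events = 0),
               "n_events", class = "cytokmer_validation_error")
  expect_error(fcm_sim_config(true_1c = 1, standard_1c = 6.2,
                              debris_fraction = 0.6,
                              tetraploid_fraction = 0.5),
               class = "cytokmer_validation_error")
})

test_that("expected k-mer spectrum has the closed-form peak and conserves mass", {
  cfg <- kmer_sim_config(genome_length = 1e5, coverage = 30, k = 21,
                         read_length = 150)
  expect_equal(kmer_coverage(cfg), 30 * 130 / 150) # = 26
  sp <- simulate_kmer_spectrum(cfg)
  expect_equal(sp$depth[which.max(sp$count)], 26)
  expect_lt(abs(occurrence_mass(sp) - 1e5 * 26) / (1e5 * 26), 0.01)
})

test_that("repeat component carries its share of mass above 1.5x the peak", {
  cfg <- kmer_sim_config(1e5, 30, repeat_fraction = 0.5,
                         repeat_multiplicity = 2)
  sp <- simulate_kmer_spectrum(cfg)
  lam <- kmer_coverage(cfg)
  keep <- sp$depth > 1.5 * lam
  frac <- sum(sp$depth[keep] * sp$count[keep]) / occurrence_mass(sp)
  expect_lt(abs(frac - 0.5), 0.01)
})

test_that("unresolvable k-mer coverage warns and noise sampling is seeded", {
  expect_warning(simulate_kmer_spectrum(kmer_sim_config(1e4, 3)),
                 "unresolvable")
  cfg <- kmer_sim_config(1e5, 30, noise = TRUE, seed = 5)
  expect_identical(simulate_kmer_spectrum(cfg)$count,
                   simulate_kmer_spectrum(cfg)$count)
})

test_that("noiseless reads are exact substrings of the genome or its reverse complement", {
  cfg <- kmer_sim_config(20000, 5, read_length = 100, seed = 2)
  sim <- simulate_reads(cfg)
  rc <- revcomp_chr(sim$haplotypes[1])
  ok <- vapply(sim$reads, function(r) {
    grepl(r, sim$haplotypes[1], fixed = TRUE) || grepl(r, rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("read simulator hits the target coverage and is byte-deterministic", {
  cfg <- kmer_sim_config(50000, 20, read_length = 100, seed = 5)
  sim <- simulate_reads(cfg)
  expect_lt(abs(sum(nchar(sim$reads)) - 1e6), 100)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(simulate_reads(cfg), f1)
  write_reads_fastq(simulate_reads(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(simulate_reads(kmer_sim_config(2e7, 1)),
               class = "cytokmer_size_error")
})

test_that("Yule trees are ultrametric, deterministic and round-trip through Newick", {
  tr2 <- simulate_yule_tree(tree_sim_config(2, seed = 1))
  expect_length(tr2$tip.label, 2)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths[1], depths[2])

  tr <- simulate_yule_tree(tree_sim_config(64, seed = 9))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(all(tr$edge.length > 0))
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_true(ape::all.equal.phylo(tr, back, tolerance = 1e-9))

  expect_true(ape::all.equal.phylo(
    simulate_yule_tree(tree_sim_config(16, seed = 4)),
    simulate_yule_tree(tree_sim_config(16, seed = 4))))
  expect_error(tree_sim_config(1), class = "cytokmer_validation_error")
})

test_that("Brownian traits collapse to the root state when sigma2 = 0", {
  tr <- simulate_yule_tree(tree_sim_config(8, seed = 2))
  x <- simulate_bm_trait(tr, bm_params(sigma2 = 0, root_state = 10.8))
  expect_true(all(x == 10.8))
  expect_named(x, tr$tip.label)
})

test_that("simulated trait covariance matches sigma2 * C(lambda)", {
  tr <- simulate_yule_tree(tree_sim_config(8, seed = 99))
  C <- phylo_vcv(tr)
  n_rep <- 2000
  reps <- vapply(seq_len(n_rep), function(i) {
    simulate_bm_trait(tr, bm_params(sigma2 = 2, root_state = 0, seed = i))
  }, numeric(8))
  for (i in 1:8) for (j in 1:8) {
    prods <- reps[i, ] * reps[j, ]
    mc_se <- sd(prods) / sqrt(n_rep)
    expect_lt(abs(mean(prods) - 2 * C[i, j]), 5 * mc_se)
  }
  reps0 <- vapply(seq_len(n_rep), function(i) {
    simulate_bm_trait(tr, bm_params(sigma2 = 2, root_state = 0,
                                    lambda_true = 0, seed = 10000 + i))
  }, numeric(8))
  for (i in 1:7) for (j in (i + 1):8) {
    prods <- reps0[i, ] * reps0[j, ]
    expect_lt(abs(mean(prods)), 5 * sd(prods) / sqrt(n_rep))
  }
})

test_that("event tables round-trip through CSV with ground-truth labels", {
  cfg <- fcm_sim_config(true_1c = 9.64, standard_1c = 6.20, n_events = 2000,
                        seed = 6)
  et <- simulate_fcm_events(cfg)
  f <- tempfile(fileext = ".csv")
  write_event_csv(et, f)
  back <- read_event_csv(f, standard_1c = 6.20)
  expect_equal(back$fluorescence, et$fluorescence)
  expect_equal(back$population_truth, et$population_truth)
})
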