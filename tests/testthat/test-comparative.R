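test_that("shared-path covariance reads straight off small trees", {
  ch <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(ch)), diag(2))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["B", "B"], 2)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["C", "C"], 2)
  expect_equal(C["A", "C"], 0)

  yt <- simulate_yule_tree(tree_sim_config(32, seed = 5))
  Cy <- phylo_vcv(yt)
  expect_equal(Cy, t(Cy))
  expect_gte(min(eigen(Cy, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)

  dup <- ch
  dup$tip.label <- c("A", "A")
  expect_error(phylo_vcv(dup), class = "cytokmer_validation_error")
})

test_that("covariance scales linearly with the tree and signal statistics do not", {
  tr <- simulate_yule_tree(tree_sim_config(16, seed = 6))
  x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 3, seed = 7))
  tr_s <- tr
  tr_s$edge.length <- tr$edge.length * 4.2
  expect_equal(phylo_vcv(tr_s), 4.2 * phylo_vcv(tr))
  expect_equal(fit_lambda(tr_s, x)$lambda_hat, fit_lambda(tr, x)$lambda_hat,
               tolerance = 1e-5)
  expect_equal(blomberg_k(tr_s, x), blomberg_k(tr, x), tolerance = 1e-9)
})

test_that("Brownian log-likelihood matches the dense multivariate-normal formula", {
  C1 <- matrix(1, dimnames = list("A", "A"))
  expect_equal(bm_loglik(c(A = 0), C1, sigma2 = 1, root = 0),
               -0.5 * log(2 * pi))

  tr <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  C <- phylo_vcv(tr)
  x <- c(A = 0.3, B = -0.2, C = 1.1)
  sigma2 <- 0.7
  root <- 0.25
  S <- sigma2 * C
  resid <- x[rownames(C)] - root
  dense <- -0.5 * (3 * log(2 * pi) + log(det(S)) +
                     drop(t(resid) %*% solve(S) %*% resid))
  expect_equal(bm_loglik(x, C, sigma2, root), dense, tolerance = 1e-9)

  # sigma2 and C trade off exactly
  expect_equal(bm_loglik(x, 3 * C, sigma2 / 3, root),
               bm_loglik(x, C, sigma2, root), tolerance = 1e-9)
})

test_that("lambda optimum agrees with a fine grid search", {
  tr <- simulate_yule_tree(tree_sim_config(8, seed = 77))
  for (lt in c(0.3, 0.6, 1)) {
    x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 5,
                                         lambda_true = lt, seed = 70 + lt * 10))
    lf <- fit_lambda(tr, x)
    C <- phylo_vcv(tr)
    grid <- seq(0, 1, length.out = 2001)
    gl <- vapply(grid, function(l) {
      cytokmer:::.gls_profile(x[rownames(C)], C, l)$logL
    }, numeric(1))
    expect_lt(abs(lf$lambda_hat - grid[which.max(gl)]), 1e-3)
    expect_gte(lf$logL_max, lf$logL_lambda0 - 1e-8)
    expect_gte(lf$logL_max, lf$logL_lambda1 - 1e-8)
  }
})

test_that("lambda estimates recover the generating signal strength", {
  lam1 <- vapply(1:25, function(i) {
    tr <- simulate_yule_tree(tree_sim_config(64, seed = 1000 + i))
    x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 10,
                                         seed = 2000 + i))
    fit_lambda(tr, x)$lambda_hat
  }, numeric(1))
  expect_gte(mean(lam1), 0.90)

  lam0 <- vapply(1:25, function(i) {
    tr <- simulate_yule_tree(tree_sim_config(64, seed = 5000 + i))
    x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 10,
                                         lambda_true = 0, seed = 6000 + i))
    fit_lambda(tr, x)$lambda_hat
  }, numeric(1))
  expect_lte(mean(lam0), 0.10)

  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- stats::setNames(rnorm(8), star$tip.label)
  expect_error(fit_lambda(star, x), class = "cytokmer_unidentifiable_error")
})

test_that("lambda and K agree with an independent reference implementation", {
  tr <- simulate_yule_tree(tree_sim_config(32, seed = 321))
  x <- simulate_bm_trait(tr, bm_params(sigma2 = 1.5, root_state = 10,
                                       lambda_true = 0.7, seed = 322))
  lf <- fit_lambda(tr, x)
  ref_l <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(lf$lambda_hat, ref_l$lambda, tolerance = 1e-3)
  expect_equal(lf$logL_max, ref_l$logL, tolerance = 1e-4)
  expect_equal(blomberg_k(tr, x),
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-6)
})

test_that("K is exactly 1 on a star tree and near 1 under Brownian motion", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(41)
  for (i in 1:5) {
    x <- stats::setNames(rnorm(8, 10, 2), star$tip.label)
    expect_equal(blomberg_k(star, x), 1, tolerance = 1e-12)
  }

  kk <- vapply(1:100, function(i) {
    tr <- simulate_yule_tree(tree_sim_config(64, seed = 3000 + i))
    x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 10,
                                         seed = 4000 + i))
    blomberg_k(tr, x)
  }, numeric(1))
  expect_lt(abs(mean(kk) - 1), 3 * sd(kk) / sqrt(length(kk)))

  # phylogeny-free noise on a deep tree: K collapses below 1
  kn <- vapply(1:50, function(i) {
    tr <- simulate_yule_tree(tree_sim_config(64, seed = 100 + i))
    withr::with_seed(200 + i,
                     blomberg_k(tr, stats::setNames(rnorm(64), tr$tip.label)))
  }, numeric(1))
  expect_lt(median(kn), 1)
})

test_that("K permutation test is calibrated and detects structure", {
  tr <- simulate_yule_tree(tree_sim_config(64, seed = 7))
  x <- simulate_bm_trait(tr, bm_params(sigma2 = 1, root_state = 10, seed = 8))
  kp <- k_permutation_p(tr, x, n_perm = 999, seed = 9)
  expect_lte(kp$p_perm, 0.05)
  expect_gte(kp$p_perm, 1 / 1000) # add-one estimator can never reach zero

  # exchangeable (iid) traits: permutation p-values are uniform
  tr8 <- simulate_yule_tree(tree_sim_config(8, seed = 42))
  set.seed(13)
  pv <- replicate(200, {
    x0 <- stats::setNames(rnorm(8), tr8$tip.label)
    k_permutation_p(tr8, x0, n_perm = 99, seed = sample.int(1e6, 1))$p_perm
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)

  expect_error(
    k_permutation_p(tr8, stats::setNames(rep(1, 8), tr8$tip.label),
                    n_perm = 99, seed = 1),
    class = "cytokmer_degenerate_trait_error")
})

test_that("trait vectors align to tips with underscore/space normalization", {
  tr <- ape::read.tree(text = "((Acrida_cinerea:1,Oedaleus_asiaticus:1):1,(Bryodemella_holdereri:1.5,Haplotropis_brunneriana:1.5):0.5);")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("Oedaleus asiaticus", "Acrida cinerea",
                                   "Haplotropis brunneriana",
                                   "Bryodemella holdereri"),
                       value = c(9.83, 11.24, 14.45, 18.64)),
            f, row.names = FALSE)
  x <- read_trait_csv(f)
  k <- blomberg_k(tr, x)
  expect_true(is.finite(k) && k > 0)
  expect_error(blomberg_k(tr, x[1:3]), class = "cytokmer_validation_error")
})
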