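#' Shared-path-length (Brownian) covariance matrix of a tree
#'
#' Under Brownian motion, the covariance of two tips' trait values is
#' proportional to the depth of their most recent common ancestor; the
#' diagonal holds root-to-tip distances. Computed via `ape::vcv`.
#' Zero-length terminal branches are perturbed by `1e-8 *` tree depth (with
#' a warning) so the matrix stays invertible.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return symmetric positive semi-definite matrix with tip-label
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  .assert(inherits(tree, "phylo"), "'tree' must be an ape::phylo object",
          "cytokmer_validation_error")
  .assert(length(tree$tip.label) >= 2, "tree needs >= 2 tips",
          "cytokmer_validation_error")
  .assert(!anyDuplicated(tree$tip.label), "duplicate tip labels",
          "cytokmer_validation_error")
  .assert(!is.null(tree$edge.length) && all(tree$edge.length >= 0),
          "tree needs non-negative branch lengths",
          "cytokmer_validation_error")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- eps
    warning("zero-length terminal branches perturbed by ", signif(eps, 3),
            call. = FALSE)
  }
  ape::vcv(tree)
}

.align_trait <- function(x, C, normalize = TRUE) {
  .assert(is.numeric(x) && !is.null(names(x)) && all(is.finite(x)),
          "trait must be a named finite numeric vector",
          "cytokmer_validation_error")
  tips <- rownames(C)
  nm <- names(x)
  if (normalize && !all(tips %in% nm)) {
    nm <- gsub(" ", "_", nm)
    tips_n <- gsub(" ", "_", tips)
    .assert(all(tips_n %in% nm),
            "trait vector does not cover all tree tips",
            "cytokmer_validation_error")
    x <- setNames(x[match(tips_n, nm)], tips)
    return(x)
  }
  .assert(all(tips %in% nm), "trait vector does not cover all tree tips",
          "cytokmer_validation_error")
  x[tips]
}

.chol_safe <- function(M) {
  tryCatch(chol(M), error = function(e) {
    jit <- 1e-10 * mean(diag(M))
    message("near-singular covariance: adding diagonal jitter ",
            signif(jit, 3))
    chol(M + diag(jit, nrow(M)))
  })
}

#' Brownian-motion log-likelihood of a trait vector
#'
#' Multivariate-normal log density of the tip values with mean
#' `root * 1` and covariance `sigma2 * C`, evaluated through a Cholesky
#' factorization (no explicit inverse).
#'
#' @param x named trait vector over the tips of `C`.
#' @param C covariance matrix from [phylo_vcv()].
#' @param sigma2 Brownian rate (> 0).
#' @param root root state.
#' @return log-likelihood scalar.
#' @export
bm_loglik <- function(x, C, sigma2, root) {
  .assert(is.numeric(sigma2) && sigma2 > 0, "'sigma2' must be > 0",
          "cytokmer_validation_error")
  x <- .align_trait(x, C)
  n <- length(x)
  L <- .chol_safe(C)
  resid <- x - root
  z <- backsolve(L, resid, transpose = TRUE)
  logdet <- 2 * sum(log(diag(L)))
  -n / 2 * log(2 * pi) - 0.5 * (n * log(sigma2) + logdet) -
    sum(z^2) / (2 * sigma2)
}

.lambda_transform <- function(C, lambda) {
  d <- diag(C)
  Cl <- lambda * C
  diag(Cl) <- d
  Cl
}

# profile ML of (root, sigma2) for a fixed lambda; returns the pieces the
# optimizer and the reporters need
.gls_profile <- function(x, C, lambda) {
  Cl <- .lambda_transform(C, lambda)
  L <- .chol_safe(Cl)
  n <- length(x)
  one <- rep(1, n)
  zx <- backsolve(L, x, transpose = TRUE)
  z1 <- backsolve(L, one, transpose = TRUE)
  root <- sum(z1 * zx) / sum(z1^2)
  q <- sum((zx - root * z1)^2)
  sigma2 <- q / n
  logdet <- 2 * sum(log(diag(L)))
  logL <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) - 0.5 * logdet
  list(root = root, sigma2 = sigma2, logL = logL)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Profiles the Brownian likelihood over the lambda transform: for each
#' lambda in `[0, 1]` the off-diagonals of the shared-path matrix are scaled
#' by lambda, the root state and rate are solved in closed form by
#' generalized least squares, and lambda is optimized by bounded scalar
#' search (absolute tolerance `1e-6`), with both endpoints evaluated
#' explicitly. Likelihood-ratio tests against lambda = 0 (no signal) and
#' lambda = 1 (pure Brownian motion) use a chi-squared with 1 df.
#'
#' @param tree an `ape::phylo` tree (>= 4 tips, not a star tree).
#' @param x named trait vector over the tips.
#' @return list of class `lambda_fit`: `lambda_hat`, `sigma2_hat`,
#'   `root_hat`, `logL_max`, `logL_lambda0`, `logL_lambda1`, `p_vs_0`,
#'   `p_vs_1`.
#' @export
fit_lambda <- function(tree, x) {
  C <- phylo_vcv(tree)
  .assert(nrow(C) >= 4, "lambda needs >= 4 tips", "cytokmer_validation_error")
  off <- C[upper.tri(C)]
  .assert(any(off > 0),
          "star tree: all off-diagonal covariances are zero, lambda is unidentifiable",
          "cytokmer_unidentifiable_error")
  x <- .align_trait(x, C)
  f <- function(lambda) .gls_profile(x, C, lambda)$logL
  opt <- optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  ends <- c(`0` = f(0), `1` = f(1))
  cand <- c(opt$maximum, 0, 1)
  cand_l <- c(opt$objective, ends)
  lambda_hat <- cand[which.max(cand_l)]
  prof <- .gls_profile(x, C, lambda_hat)
  lrt_p <- function(l0) pchisq(max(0, 2 * (prof$logL - l0)), df = 1,
                               lower.tail = FALSE)
  structure(
    list(lambda_hat = lambda_hat, sigma2_hat = prof$sigma2,
         root_hat = prof$root, logL_max = prof$logL,
         logL_lambda0 = ends[["0"]], logL_lambda1 = ends[["1"]],
         p_vs_0 = lrt_p(ends[["0"]]), p_vs_1 = lrt_p(ends[["1"]])),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf(
    "<lambda_fit> lambda = %.4f (logL %.3f; vs 0: p = %.3g, vs 1: p = %.3g)\n",
    x$lambda_hat, x$logL_max, x$p_vs_0, x$p_vs_1))
  invisible(x)
}

#' Blomberg's K statistic
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically corrected mean to the error expected under Brownian
#' motion on the candidate tree:
#' `K = (MSE0 / MSE) / ((tr(C) - n / sum(C^-1)) / (n - 1))` with
#' `MSE0 = (x - a)'(x - a) / (n - 1)`,
#' `MSE = (x - a)' C^-1 (x - a) / (n - 1)` and GLS mean
#' `a = (1'C^-1 1)^-1 1'C^-1 x`. K = 1 matches the Brownian expectation;
#' K > 1 means relatives resemble each other more than Brownian motion
#' predicts.
#'
#' @inheritParams fit_lambda
#' @return numeric K >= 0.
#' @export
blomberg_k <- function(tree, x) {
  C <- phylo_vcv(tree)
  .assert(nrow(C) >= 4, "Blomberg's K needs >= 4 tips",
          "cytokmer_validation_error")
  x <- .align_trait(x, C)
  n <- length(x)
  L <- .chol_safe(C)
  one <- rep(1, n)
  zx <- backsolve(L, x, transpose = TRUE)
  z1 <- backsolve(L, one, transpose = TRUE)
  a <- sum(z1 * zx) / sum(z1^2)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- sum((zx - a * z1)^2) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(z1^2)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for Blomberg's K
#'
#' Permutes the assignment of trait values to tips with a seeded generator
#' and reports the add-one p-value
#' `p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams fit_lambda
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list of class `k_result`: `K`, `p_perm`, `n_perm`, `seed`.
#' @export
k_permutation_p <- function(tree, x, n_perm = 999, seed = 1) {
  .assert(.is_count(n_perm) && n_perm >= 99, "'n_perm' must be >= 99",
          "cytokmer_validation_error")
  C <- phylo_vcv(tree)
  x <- .align_trait(x, C)
  .assert(sd(x) > 0, "constant trait: K permutation test undefined",
          "cytokmer_degenerate_trait_error")
  k_obs <- blomberg_k(tree, x)
  tips <- names(x)
  perm_k <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      blomberg_k(tree, setNames(sample(x), tips))
    }, numeric(1))
  })
  structure(
    list(K = k_obs, p_perm = (1 + sum(perm_k >= k_obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm), seed = .check_seed(seed)),
    class = "k_result"
  )
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("<k_result> K = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$K, x$p_perm, x$n_perm, x$seed))
  invisible(x)
}

#' Read a species trait table
#'
#' CSV with columns `species`, `value`; returns the named vector the
#' comparative functions consume. Species matching against tree tips is
#' exact-string, with an underscore/space normalization applied at
#' alignment time.
#'
#' @param path CSV path.
#' @return named numeric vector.
#' @export
read_trait_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("species", "value") %in% names(df)),
          "trait CSV needs columns species, value",
          "cytokmer_validation_error")
  setNames(as.numeric(df$value), df$species)
}
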