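#' Configuration objects for the comparative-module test harness
#'
#' `tree_sim_config()` parameterises a pure-birth (Yule) tree simulation;
#' `bm_params()` parameterises Brownian-motion trait evolution on a tree,
#' with an optional Pagel-lambda transform of the covariance used to
#' generate traits of known, reduced phylogenetic signal.
#'
#' @param n_tips number of leaves (>= 2).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param sigma2 trait variance accrued per unit branch length (>= 0).
#' @param root_state trait value at the root (pg for C-value work).
#' @param lambda_true lambda in `[0, 1]` scaling off-diagonal shared-path
#'   covariances; 1 = pure Brownian motion, 0 = phylogenetic independence.
#' @param seed integer seed.
#' @return `tree_sim_config` / `bm_params` objects.
#' @export
tree_sim_config <- function(n_tips, birth_rate = 1, seed = 1) {
  .assert(.is_count(n_tips) && n_tips >= 2, "'n_tips' must be a count >= 2",
          "cytokmer_validation_error")
  .assert(is.numeric(birth_rate) && birth_rate > 0,
          "'birth_rate' must be > 0", "cytokmer_validation_error")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 seed = .check_seed(seed)),
            class = "tree_sim_config")
}

#' @rdname tree_sim_config
#' @export
bm_params <- function(sigma2 = 1, root_state = 0, lambda_true = 1, seed = 1) {
  .assert(is.numeric(sigma2) && sigma2 >= 0, "'sigma2' must be >= 0",
          "cytokmer_validation_error")
  .assert(is.numeric(lambda_true) && lambda_true >= 0 && lambda_true <= 1,
          "'lambda_true' must be in [0, 1]", "cytokmer_validation_error")
  structure(list(sigma2 = sigma2, root_state = root_state,
                 lambda_true = lambda_true, seed = .check_seed(seed)),
            class = "bm_params")
}

#' Simulate an ultrametric pure-birth tree
#'
#' Thin seeded wrapper around `ape::rphylo` with extinction rate zero:
#' an ultrametric Yule tree with positive branch lengths, suitable as a
#' harness for the phylogenetic-signal statistics.
#'
#' @param cfg a [tree_sim_config()].
#' @return an `ape::phylo` tree with `n_tips` leaves.
#' @export
simulate_yule_tree <- function(cfg) {
  stopifnot(inherits(cfg, "tree_sim_config"))
  withr::with_seed(cfg$seed,
                   ape::rphylo(cfg$n_tips, birth = cfg$birth_rate, death = 0))
}

#' Simulate a (lambda-transformed) Brownian trait on a tree
#'
#' Draws tip values from a multivariate normal with mean `root_state` and
#' covariance `sigma2 * C(lambda_true)`, where `C` is the shared-path-length
#' matrix of the tree and `C(lambda)` scales its off-diagonals by lambda.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param params a [bm_params()].
#' @return named numeric vector of tip trait values (names = tip labels).
#' @export
simulate_bm_trait <- function(tree, params) {
  stopifnot(inherits(params, "bm_params"))
  C <- phylo_vcv(tree)
  if (params$lambda_true < 1) {
    d <- diag(C)
    C <- params$lambda_true * C
    diag(C) <- d
  }
  n <- nrow(C)
  if (params$sigma2 == 0) {
    return(setNames(rep(params$root_state, n), rownames(C)))
  }
  L <- chol(params$sigma2 * C)
  z <- withr::with_seed(params$seed, rnorm(n))
  setNames(params$root_state + as.numeric(crossprod(L, z)), rownames(C))
}
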