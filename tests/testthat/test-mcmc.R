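# small regression design shared across sampler tests
wgr_toy <- function(n = 60, m = 8, seed = 31, b = NULL) {
  set.seed(seed)
  Z <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
              n, m, dimnames = list(paste0("i", 1:n), paste0("s", 1:m)))
  b <- b %||% c(1, -0.5, rep(0, m - 2))
  y <- stats::setNames(as.vector(Z %*% b) + rnorm(n, 0, 1), rownames(Z))
  list(Z = Z, y = y, b = b)
}

test_that("the sampler executes the published cycle schedule", {
  toy <- wgr_toy(n = 25, m = 2)
  post <- run_chain(toy$y, toy$Z, prior_spec("bayesa", df = 4),
                    chain_config(10000, 10000, 20), seed = 1)
  expect_equal(post$n_cycles, 210000)
  expect_equal(nrow(post$trace), 10000)

  # estimating df stretches burn-in and thinning five-fold
  sched <- chain_schedule(chain_config(10000, 10000, 20),
                          prior_spec("bayesa", df = "estimate"))
  expect_equal(sched$total_cycles, 1050000)
  post5 <- run_chain(toy$y, toy$Z, prior_spec("bbt"),
                     chain_config(40, 50, 2), seed = 1)
  expect_equal(post5$n_cycles, 40 * 5 + 50 * 2 * 5)
})

test_that("posterior means match conjugate and quadrature oracles", {
  set.seed(8)
  n <- 40
  z <- rbinom(n, 2, 0.5)
  y <- stats::setNames(0.5 * z + rnorm(n, 0, 0.8), paste0("i", 1:n))
  Z <- matrix(z, ncol = 1, dimnames = list(names(y), "s1"))
  s2e <- 0.64
  v1 <- 0.25

  # normal slab, pi = 1, everything else fixed: conjugate normal posterior
  post <- run_chain(y, Z, prior_spec("bbn", lambda = v1, pi = 1),
                    chain_config(500, 4000, 2), seed = 2,
                    fix_mu = 0, fix_sigma2_e = s2e)
  bhat <- post$snp_effects$beta
  conj_mean <- sum(z * y) / (sum(z^2) + s2e / v1)
  conj_sd <- sqrt(s2e / (sum(z^2) + s2e / v1))
  expect_lt(abs(bhat - conj_mean), 3 * conj_sd / sqrt(4000))

  # quadrature oracle for a non-conjugate prior: p(b|y) ~ L(b) prior(b)
  quad_mean <- function(logprior) {
    bg <- seq(-2, 3, by = 1e-3)
    ll <- -colSums((y - outer(z, bg))^2) / (2 * s2e) + logprior(bg)
    w <- exp(ll - max(ll))
    sum(bg * w) / sum(w)
  }

  # Laplace prior (Bayesian LASSO), rate fixed
  lam <- 2
  postL <- run_chain(y, Z, prior_spec("lasso", lambda = lam),
                     chain_config(1000, 4000, 2), seed = 3,
                     fix_mu = 0, fix_sigma2_e = s2e)
  oracleL <- quad_mean(function(b) -lam * abs(b))
  expect_lt(abs(postL$snp_effects$beta - oracleL), 0.02)

  # scaled-t prior (Bayes A), df and scale fixed
  df <- 4
  S <- 0.2
  postA <- run_chain(y, Z, prior_spec("bayesa", lambda = S, df = df),
                     chain_config(1000, 4000, 2), seed = 4,
                     fix_mu = 0, fix_sigma2_e = s2e)
  oracleA <- quad_mean(function(b) {
    -(df + 1) / 2 * log(1 + b^2 / (df * S))
  })
  expect_lt(abs(postA$snp_effects$beta - oracleA), 0.02)

  # spike-and-slab with t slab: mixture of a point mass and the t branch
  pi0 <- 0.3
  postT <- run_chain(y, Z, prior_spec("bbt", lambda = S, df = df, pi = pi0),
                     chain_config(1000, 6000, 2), seed = 5,
                     fix_mu = 0, fix_sigma2_e = s2e)
  bg <- seq(-2, 3, by = 1e-3)
  ll <- -colSums((y - outer(z, bg))^2) / (2 * s2e)
  tdens <- exp(lgamma((df + 1) / 2) - lgamma(df / 2)) /
    sqrt(pi * df * S) * (1 + bg^2 / (df * S))^(-(df + 1) / 2)
  slab_int <- sum(exp(ll) * tdens) * 1e-3
  spike_lik <- exp(-sum(y^2) / (2 * s2e))
  w_slab <- pi0 * slab_int / (pi0 * slab_int + (1 - pi0) * spike_lik)
  oracleT <- w_slab * sum(bg * exp(ll) * tdens) / sum(exp(ll) * tdens)
  expect_lt(abs(postT$snp_effects$beta - oracleT), 0.03)
  expect_lt(abs(mean(postT$snp_effects$inclusion_prob) - w_slab), 0.05)
})

test_that("prior families reduce to one another at boundary settings", {
  toy <- wgr_toy(n = 100, m = 50, seed = 17,
                 b = c(rnorm(5, 0, 0.6), rep(0, 45)))
  cc <- chain_config(1000, 1000, 2)

  # BBt with pi = 1 is Bayes A
  pa <- run_chain(toy$y, toy$Z, prior_spec("bayesa", df = 4), cc, seed = 7)
  pt1 <- run_chain(toy$y, toy$Z, prior_spec("bbt", df = 4, pi = 1), cc,
                   seed = 7)
  expect_gt(cor(pa$gebv, pt1$gebv), 0.99)

  # Bayes A with a huge fixed df is ridge, i.e. BBn with pi = 1
  pa6 <- run_chain(toy$y, toy$Z, prior_spec("bayesa", df = 1e6), cc,
                   seed = 8)
  pn1 <- run_chain(toy$y, toy$Z, prior_spec("bbn", pi = 1), cc, seed = 8)
  expect_gt(cor(pa6$snp_effects$beta, pn1$snp_effects$beta), 0.99)
  expect_gt(cor(pa6$gebv, pn1$gebv), 0.995)

  # LASSO with a vanishing rate approaches ordinary least squares
  toy2 <- wgr_toy(n = 80, m = 5, seed = 23, b = c(0.8, -0.6, 0.3, 0, 0))
  pl <- run_chain(toy2$y, toy2$Z, prior_spec("lasso", lambda = 1e-4),
                  chain_config(1000, 2000, 2), seed = 9)
  ols <- coef(lm(toy2$y ~ toy2$Z))[-1]
  expect_lt(max(abs(pl$snp_effects$beta - ols)), 0.05)
})

test_that("hyperparameter conditionals are the stated distributions", {
  # pi | indicators ~ Beta(1 + m1, 1 + m - m1)
  set.seed(12)
  draws <- replicate(4000, gsbench:::cpp_draw_pi(0L, 100L))
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - 1 / 102), 4 * sqrt(1 / 102 * 101 / 102 / 103) /
              sqrt(4000))
  draws2 <- replicate(4000, gsbench:::cpp_draw_pi(40L, 100L))
  expect_lt(abs(mean(draws2) - 41 / 102), 0.01)

  # df Metropolis respects its bounds and the log-posterior shape
  set.seed(13)
  s2 <- 0.1 * 4 / rchisq(200, 4)   # true df = 4, S = 0.1
  lp <- vapply(seq(0.5, 9, by = 0.1), gsbench:::cpp_df_logpost,
               numeric(1), S = 0.1, sigma2 = s2)
  expect_lt(abs(seq(0.5, 9, by = 0.1)[which.max(lp)] - 4), 2)
  d <- 4
  for (i in 1:200) {
    st <- gsbench:::cpp_df_mh_step(d, 0.1, s2, 0.4, 0.5, 9)
    d <- st$df
    expect_true(d >= 0.5 && d <= 9)
  }
})

test_that("spike-and-slab recovers a sparse inclusion proportion", {
  hits <- 0
  for (r in 1:10) {
    set.seed(600 + r)
    n <- 400
    m <- 500
    p <- runif(m, 0.1, 0.9)
    Z <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                dimnames = list(paste0("i", 1:n), paste0("s", 1:m)))
    causal <- sample(m, 25)  # true pi = 0.05
    b <- numeric(m)
    b[causal] <- rnorm(25, 0, 0.35)
    y <- stats::setNames(as.vector(Z %*% b) + rnorm(n), rownames(Z))
    post <- run_chain(y, Z, prior_spec("bbn"), chain_config(600, 400, 2),
                      seed = r)
    pi_hat <- post$hyper_estimates$pi
    if (pi_hat >= 0.01 && pi_hat <= 0.15) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("chains are deterministic and stay inside parameter supports", {
  toy <- wgr_toy(n = 50, m = 10)
  cc <- chain_config(300, 300, 2)
  a <- run_chain(toy$y, toy$Z, prior_spec("bbt"), cc, seed = 99)
  b <- run_chain(toy$y, toy$Z, prior_spec("bbt"), cc, seed = 99)
  expect_identical(a$gebv, b$gebv)
  expect_identical(a$trace, b$trace)
  expect_true(all(a$trace$sigma2_e > 0))
  expect_true(all(a$trace$pi > 0 & a$trace$pi < 1))
  expect_true(all(a$trace$df >= 0.5 & a$trace$df <= 9))
  expect_true(all(a$pev >= 0))
  expect_true(is.finite(a$df_acceptance) && a$df_acceptance > 0)

  # incremental residual updating does not drift: replaying the stored
  # effects reproduces the chain's own genomic values
  replay <- gebv_from_effects(toy$Z, a$snp_effects)
  expect_equal(unname(replay), unname(a$gebv), tolerance = 1e-8)
})

test_that("genomic values are linear in the stored effects", {
  Z <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s1"))
  expect_equal(unname(gebv_from_effects(Z, c(s1 = 2))), c(0, 2, 4))
  expect_true(all(gebv_from_effects(Z, c(s1 = 0)) == 0))
  expect_equal(unname(gebv_from_effects(Z, c(s1 = 1), mu_hat = 5,
                                        scale = "trait")),
               c(5, 6, 7))
  expect_error(gebv_from_effects(Z, c(s1 = 1, nope = 2)),
               "alignment.*nope")
})

test_that("constant SNP columns are dropped with a warning", {
  toy <- wgr_toy(n = 30, m = 4)
  toy$Z[, 2] <- 1
  expect_warning(
    post <- run_chain(toy$y, toy$Z, prior_spec("lasso"),
                      chain_config(100, 100, 1), seed = 1),
    "zero-variance")
  expect_equal(post$snp_effects$beta[2], 0)
  expect_error(run_chain(stats::setNames(c(NA, Inf, 1), paste0("i", 1:3)),
                         matrix(0:2, 3, 1,
                                dimnames = list(paste0("i", 1:3), "s")),
                         prior_spec("lasso"), chain_config(10, 10, 1)),
               "finite|phenotyped")
})
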