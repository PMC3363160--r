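#' Prior specification for Bayesian whole-genome regression
#'
#' Four prior families for SNP effects are supported: `"lasso"` (Laplace,
#' via its normal-exponential scale mixture), `"bayesa"` (scaled Student-t,
#' via a per-SNP scaled-inverse-chi-square variance), `"bbn"`
#' (spike-and-slab with a shared-variance normal slab, also known as
#' Bayes C) and `"bbt"` (spike-and-slab with a scaled-t slab). The
#' hyperparameters are the scale/rate `lambda` (Laplace rate for the LASSO,
#' t scale for Bayes A/BBt, slab variance for BBn), the t shape `df`
#' (Bayes A/BBt) and the inclusion proportion `pi` (BBn/BBt). Each may be
#' fixed to a number or set to `"estimate"` to be sampled from the data
#' under flat priors; `df` estimation uses a bounded flat prior on
#' `df_bounds` (default \[0.5, 9\]).
#'
#' @param method One of `"lasso"`, `"bayesa"`, `"bbn"`, `"bbt"`.
#' @param lambda `"estimate"` (default) or a fixed positive value.
#' @param df `"estimate"` (default for Bayes A/BBt) or a fixed value such
#'   as 4.
#' @param pi `"estimate"` (default for BBn/BBt) or a fixed value in (0, 1].
#' @param df_bounds Bounds of the flat prior on `df`.
#' @return A `gs_prior` list.
#' @export
prior_spec <- function(method = c("lasso", "bayesa", "bbn", "bbt"),
                       lambda = "estimate", df = "estimate",
                       pi = "estimate", df_bounds = c(0.5, 9)) {
  method <- match.arg(method)
  est <- function(x) identical(x, "estimate")
  uses_df <- method %in% c("bayesa", "bbt")
  uses_pi <- method %in% c("bbn", "bbt")
  if (!est(df) && uses_df) {
    df <- as.numeric(df)
    if (!is.finite(df) || df <= 0) stop("df must be positive", call. = FALSE)
  }
  if (!est(pi) && uses_pi) {
    pi <- as.numeric(pi)
    if (!is.finite(pi) || pi <= 0 || pi > 1) {
      stop("pi must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!est(lambda)) {
    lambda <- as.numeric(lambda)
    if (!is.finite(lambda) || lambda <= 0) {
      stop("lambda must be positive", call. = FALSE)
    }
  }
  pr <- list(method = method,
             lambda = if (est(lambda)) NA_real_ else lambda,
             estimate_lambda = est(lambda),
             df = if (!uses_df) NA_real_ else if (est(df)) NA_real_ else df,
             estimate_df = uses_df && est(df),
             pi = if (!uses_pi) NA_real_ else if (est(pi)) NA_real_ else pi,
             estimate_pi = uses_pi && est(pi),
             df_bounds = df_bounds)
  class(pr) <- "gs_prior"
  pr
}

#' MCMC schedule for the Gibbs samplers
#'
#' The default schedule discards `burn_in = 10000` cycles, then retains
#' `n_samples = 10000` realisations separated by `thin = 20` cycles, i.e.
#' 210000 cycles in total. When the t shape `df` is estimated, the burn-in
#' and thinning interval are multiplied by `df_multiplier` (default 5), so
#' the chain is five times longer while still retaining `n_samples`
#' realisations.
#'
#' @param burn_in Discarded initial cycles.
#' @param n_samples Retained realisations.
#' @param thin Cycles between retained realisations.
#' @param df_multiplier Schedule multiplier applied when `df` is estimated.
#' @param verbose Print progress every 10000 cycles.
#' @return A `gs_chain` list.
#' @export
chain_config <- function(burn_in = 10000, n_samples = 10000, thin = 20,
                         df_multiplier = 5, verbose = FALSE) {
  stopifnot(burn_in >= 0, n_samples >= 1, thin >= 1, df_multiplier >= 1)
  cfg <- list(burn_in = as.integer(burn_in),
              n_samples = as.integer(n_samples), thin = as.integer(thin),
              df_multiplier = as.integer(df_multiplier),
              verbose = isTRUE(verbose))
  class(cfg) <- "gs_chain"
  cfg
}

#' Effective schedule of a chain under a prior
#'
#' @param config A `gs_chain`.
#' @param prior A `gs_prior`.
#' @return List with `burn_in`, `thin`, `n_samples`, `total_cycles`.
#' @export
chain_schedule <- function(config, prior) {
  mult <- if (isTRUE(prior$estimate_df)) config$df_multiplier else 1L
  burn <- config$burn_in * mult
  thin <- config$thin * mult
  list(burn_in = burn, thin = thin, n_samples = config$n_samples,
       total_cycles = burn + config$n_samples * thin)
}

#' Run a Gibbs sampler for Bayesian whole-genome regression
#'
#' Samples from the posterior of `y = mu + Z beta + e` under the prior
#' family in `prior`, with single-site updates of each SNP effect from its
#' normal full conditional, per-SNP mixing variances, inclusion indicators
#' (spike-and-slab methods, updated with the effect integrated out),
#' the residual variance, and the hyperparameters `lambda`, `pi`,
#' `sigma2_SNP` (Gibbs under flat priors) and `df` (random-walk Metropolis
#' on the log scale with reflection at its bounds, adapted during burn-in
#' towards 20-40 percent acceptance and then frozen). Posterior means are
#' reported for every parameter; the prediction error variance of an
#' individual is the across-sample variance of its genomic value
#' `sum_j z_ij beta_j`.
#'
#' @param y Named phenotypes (or `gs_pheno`); `NA` rows are excluded from
#'   the likelihood.
#' @param Z Dosage matrix (individuals x SNP) with rownames matching the
#'   phenotype names; genomic values are predicted for every row.
#' @param prior A `gs_prior`.
#' @param config A `gs_chain`.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param fix_mu Optional fixed value of the mean (otherwise sampled).
#' @param fix_sigma2_e Optional fixed residual variance (otherwise
#'   sampled). Both fixing options exist for validation against closed-form
#'   posteriors.
#' @return A `gs_posterior` list: `snp_effects` (`snp_id`, `beta`,
#'   `inclusion_prob`), `mu_hat`, `sigma2_e_hat`, `hyper_estimates`,
#'   `gebv`, `pev`, `trace` (retained hyperparameter samples), `n_cycles`,
#'   `schedule`, `df_acceptance`.
#' @export
run_chain <- function(y, Z, prior, config = chain_config(), seed = NULL,
                      fix_mu = NULL, fix_sigma2_e = NULL) {
  stopifnot(inherits(prior, "gs_prior"), inherits(config, "gs_chain"))
  y <- as_named_pheno(y)
  Z <- as.matrix(Z)
  if (is.null(rownames(Z))) {
    if (nrow(Z) == length(y)) rownames(Z) <- names(y)
    else stop("Z must carry rownames matching the phenotype names",
              call. = FALSE)
  }
  obs <- names(y)[!is.na(y)]
  if (!length(obs)) stop("no phenotyped individuals", call. = FALSE)
  ridx <- match(obs, rownames(Z))
  if (anyNA(ridx)) stop("phenotyped rows of Z must match y", call. = FALSE)
  yv <- as.numeric(y[obs])
  if (any(!is.finite(yv))) stop("non-finite phenotype", call. = FALSE)
  Zp <- Z[ridx, , drop = FALSE]

  # drop zero-variance columns among phenotyped individuals
  cv <- matrixStats_colVars(Zp)
  keep <- which(cv > 0)
  if (length(keep) < ncol(Z)) {
    warning(ncol(Z) - length(keep),
            " zero-variance SNP columns dropped from the chain")
  }
  if (!length(keep)) stop("no polymorphic SNP", call. = FALSE)
  Zp <- Zp[, keep, drop = FALSE]
  Zall <- Z[, keep, drop = FALSE]

  sched <- chain_schedule(config, prior)
  method_code <- match(prior$method, c("lasso", "bayesa", "bbn", "bbt")) - 1L

  # method-of-moments style initial values
  p <- colMeans(Zp) / 2
  sumpq <- sum(2 * p * (1 - p))
  pi0 <- if (is.na(prior$pi)) 0.5 else prior$pi
  df0 <- if (is.na(prior$df)) 4 else prior$df
  v0 <- 0.5 * stats::var(yv) / max(sumpq, 1e-8)
  lambda0 <- if (!prior$estimate_lambda) prior$lambda else switch(
    prior$method,
    lasso = sqrt(2 / v0),
    bayesa = , bbt = if (df0 > 2) v0 * (df0 - 2) / df0 else v0 / 2,
    bbn = v0 / pi0)
  s2snp0 <- if (prior$method == "bbn") lambda0 else v0

  if (!is.null(seed)) set.seed(seed)
  out <- cpp_wgr_chain(
    yv, Zp, Zall, method_code,
    lambda0, prior$estimate_lambda,
    df0, prior$estimate_df, prior$df_bounds[1], prior$df_bounds[2],
    pi0, prior$estimate_pi,
    s2snp0,
    sched$burn_in, sched$n_samples, sched$thin,
    !is.null(fix_mu), fix_mu %||% 0,
    !is.null(fix_sigma2_e), fix_sigma2_e %||% 0,
    as.integer(config$verbose))

  beta <- numeric(ncol(Z))
  incl <- numeric(ncol(Z))
  beta[keep] <- out$beta
  incl[keep] <- out$inclusion_prob
  trace <- as.data.frame(out$trace)
  hyper <- list(lambda = mean(trace$lambda))
  if (prior$method %in% c("bbn", "bbt")) hyper$pi <- mean(trace$pi)
  if (prior$method %in% c("bayesa", "bbt")) hyper$df <- mean(trace$df)
  if (prior$method == "bbn") hyper$sigma2_snp <- mean(trace$sigma2_snp)
  res <- list(
    snp_effects = data.frame(
      snp_id = colnames(Z) %||% paste0("snp", seq_len(ncol(Z))),
      beta = beta,
      inclusion_prob = if (prior$method %in% c("bbn", "bbt")) incl else NA_real_),
    mu_hat = mean(trace$mu),
    sigma2_e_hat = mean(trace$sigma2_e),
    hyper_estimates = hyper,
    gebv = stats::setNames(out$gebv, rownames(Zall)),
    pev = stats::setNames(out$pev, rownames(Zall)),
    trace = trace,
    n_cycles = out$n_cycles,
    schedule = sched,
    df_acceptance = out$df_acceptance,
    prior = prior)
  class(res) <- "gs_posterior"
  res
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Genomic values from stored SNP effects
#'
#' `GEBV = Z beta` (plus `mu_hat` on the trait scale), with SNP columns
#' aligned to the effect table by snp id.
#'
#' @param Z_new Dosage matrix with colnames.
#' @param effects Either the `snp_effects` data frame of a
#'   [run_chain()] result (columns `snp_id`, `beta`) or a named numeric
#'   vector of effects.
#' @param mu_hat Mean added when `scale = "trait"`.
#' @param scale `"genetic"` (default; no intercept) or `"trait"`.
#' @return Named numeric vector of genomic values.
#' @export
gebv_from_effects <- function(Z_new, effects, mu_hat = 0,
                              scale = c("genetic", "trait")) {
  scale <- match.arg(scale)
  if (is.data.frame(effects)) {
    effects <- stats::setNames(effects$beta, effects$snp_id)
  }
  Z_new <- as.matrix(Z_new)
  if (is.null(colnames(Z_new)) && ncol(Z_new) == length(effects)) {
    colnames(Z_new) <- names(effects)
  }
  miss <- setdiff(names(effects), colnames(Z_new))
  if (length(miss)) {
    stop("alignment error: SNP absent from genotypes: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  }
  g <- (Z_new[, names(effects), drop = FALSE] %*% effects)[, 1]
  if (scale == "trait") g <- g + mu_hat
  g
}

#' @export
print.gs_posterior <- function(x, ...) {
  cat(sprintf("Whole-genome regression posterior (%s): %d SNP, %d cycles\n",
              x$prior$method, nrow(x$snp_effects), x$n_cycles))
  h <- unlist(x$hyper_estimates)
  cat("  hyperparameter posterior means: ",
      paste(sprintf("%s = %.4g", names(h), h), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  mu = %.4g, sigma2_e = %.4g\n", x$mu_hat, x$sigma2_e_hat))
  invisible(x)
}
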