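#' Fit a genomic prediction model
#'
#' Single front-end for the six predictors compared by the package:
#' pedigree BLUP (`"pblup"`), genomic BLUP (`"gblup"`), and the four
#' Bayesian whole-genome regressions — Bayesian LASSO (`"lasso"`),
#' Bayes A (`"bayesa"`), and the spike-and-slab Bayes B variants with
#' normal (`"bbn"`) and scaled-t (`"bbt"`) slabs. BLUP methods estimate
#' variance components by REML first and then solve the mixed model
#' (two-step); regression methods run a Gibbs sampler and report posterior
#' means.
#'
#' @param y Phenotypes: a named numeric vector (`NA` for unphenotyped
#'   individuals) or a `gs_pheno` data frame.
#' @param method One of `"pblup"`, `"gblup"`, `"lasso"`, `"bayesa"`,
#'   `"bbn"`, `"bbt"`.
#' @param geno Dosage matrix (individuals x SNP, rownames = ids) or a
#'   `gs_geno`; required for all methods except `"pblup"` (unless `K` is
#'   given for `"gblup"`).
#' @param pedigree A `gs_pedigree`; required for `"pblup"`.
#' @param K Optional pre-computed relationship matrix for BLUP methods.
#' @param prior A `gs_prior`; defaults to `prior_spec(method)` with all
#'   hyperparameters estimated.
#' @param chain A `gs_chain` MCMC schedule (regression methods).
#' @param seed Integer seed for the sampler.
#' @param ... Passed to [run_chain()] (e.g. `fix_mu`, `fix_sigma2_e`).
#' @return An object of class `gsfit` with components `method`, `gebv`
#'   (named, all individuals), `pev`, `mu_hat`, `sigma2_e`, `h2`
#'   (REML estimate for BLUP methods, variance-explained approximation for
#'   regression methods), `beta` (SNP effect table, regression methods),
#'   `hyper`, `vc`, `trace`, `map` (when available), `y`.
#' @seealso [accuracy()], [evaluate_methods()], [grammar_scan()]
#' @examples
#' sim <- sim_gsdata(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 6,
#'                   snps_per_chrom = 40, ne = 20, n_hist_generations = 10,
#'                   seed = 2)
#' fit <- gsfit(sim$pheno, method = "gblup", geno = sim$Z)
#' fit
#' cor(fit$gebv, sim$pheno$tbv)
#' @export
gsfit <- function(y, method = c("gblup", "pblup", "lasso", "bayesa", "bbn",
                                "bbt"),
                  geno = NULL, pedigree = NULL, K = NULL, prior = NULL,
                  chain = chain_config(), seed = NULL, ...) {
  method <- match.arg(method)
  cl <- match.call()
  yn <- as_named_pheno(y)
  Z <- NULL
  map <- NULL
  if (!is.null(geno)) {
    if (inherits(geno, "gs_geno")) {
      map <- geno$map
      Z <- dosages(geno)
    } else {
      Z <- as.matrix(geno)
    }
  }
  if (method %in% c("pblup", "gblup")) {
    if (is.null(K)) {
      K <- if (method == "pblup") {
        if (is.null(pedigree)) stop("pblup requires a pedigree",
                                    call. = FALSE)
        compute_nrm(pedigree)
      } else {
        if (is.null(Z)) stop("gblup requires genotypes or K", call. = FALSE)
        compute_grm(Z)
      }
    }
    vc <- reml_fit(yn, K)
    bl <- blup_solve(yn, K, vc)
    res <- list(method = method, gebv = bl$gebv, pev = bl$pev,
                mu_hat = bl$mu_hat, sigma2_e = vc$sigma2_e,
                sigma2_g = vc$sigma2_g, h2 = vc$h2, beta = NULL,
                hyper = NULL, vc = vc, trace = NULL, map = map, y = yn,
                call = cl)
  } else {
    if (is.null(Z)) stop("regression methods require genotypes",
                         call. = FALSE)
    if (is.null(prior)) prior <- prior_spec(method)
    if (prior$method != method) stop("prior method mismatch", call. = FALSE)
    post <- run_chain(yn, Z, prior, chain, seed = seed, ...)
    ve <- variance_explained(post$gebv, post$pev, post$sigma2_e_hat)
    res <- list(method = method, gebv = post$gebv, pev = post$pev,
                mu_hat = post$mu_hat, sigma2_e = post$sigma2_e_hat,
                sigma2_g = ve$sigma2_g_hat, h2 = ve$h2_hat,
                beta = post$snp_effects, hyper = post$hyper_estimates,
                vc = NULL, trace = post$trace, map = map, y = yn,
                n_cycles = post$n_cycles, schedule = post$schedule,
                df_acceptance = post$df_acceptance, call = cl)
  }
  class(res) <- "gsfit"
  res
}

method_label <- function(m) {
  c(pblup = "pedigree BLUP", gblup = "GBLUP", lasso = "Bayesian LASSO",
    bayesa = "Bayes A", bbn = "Bayes B (normal slab)",
    bbt = "Bayes B (t slab)")[[m]]
}

#' @export
print.gsfit <- function(x, ...) {
  cat(sprintf("%s fit: %d individuals (%d phenotyped)\n",
              method_label(x$method), length(x$gebv), sum(!is.na(x$y))))
  cat(sprintf("  mu = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$mu_hat, x$sigma2_e, x$h2))
  if (!is.null(x$hyper)) {
    h <- unlist(x$hyper)
    cat("  hyperparameters: ",
        paste(sprintf("%s = %.4g", names(h), h), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.gsfit <- function(object, ...) {
  s <- list(method = object$method, n = length(object$gebv),
            n_phenotyped = sum(!is.na(object$y)), mu_hat = object$mu_hat,
            sigma2_e = object$sigma2_e, sigma2_g = object$sigma2_g,
            h2 = object$h2, hyper = object$hyper,
            gebv_summary = summary(object$gebv),
            n_cycles = object$n_cycles)
  if (!is.null(object$beta)) {
    ab <- abs(object$beta$beta)
    s$top_snps <- object$beta[order(-ab), ][seq_len(min(5, nrow(object$beta))), ]
  }
  class(s) <- "summary.gsfit"
  s
}

#' @export
print.summary.gsfit <- function(x, ...) {
  cat(sprintf("%s: %d individuals, %d phenotyped\n",
              method_label(x$method), x$n, x$n_phenotyped))
  cat(sprintf("  mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$mu_hat, x$sigma2_g, x$sigma2_e, x$h2))
  if (!is.null(x$hyper)) {
    h <- unlist(x$hyper)
    cat("  hyperparameters: ",
        paste(sprintf("%s = %.4g", names(h), h), collapse = ", "), "\n",
        sep = "")
  }
  cat("  GEBV distribution:\n")
  print(x$gebv_summary)
  if (!is.null(x$top_snps)) {
    cat("  largest SNP effects:\n")
    print(x$top_snps, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gsfit <- function(object, ...) {
  if (is.null(object$beta)) object$gebv
  else stats::setNames(object$beta$beta, object$beta$snp_id)
}

#' @export
fitted.gsfit <- function(object, ...) {
  obs <- names(object$y)[!is.na(object$y)]
  object$mu_hat + object$gebv[obs]
}

#' @export
residuals.gsfit <- function(object, ...) {
  obs <- names(object$y)[!is.na(object$y)]
  object$y[obs] - object$mu_hat - object$gebv[obs]
}

#' Predict genomic values for new individuals
#'
#' For regression methods the stored SNP effects are applied to the new
#' dosages; for BLUP methods predictions exist only for individuals in the
#' fitted relationship matrix, so `newdata` must be omitted.
#'
#' @param object A `gsfit`.
#' @param newdata Dosage matrix for new individuals (regression methods).
#' @param type `"genetic"` (no intercept) or `"trait"` (adds `mu_hat`).
#' @param ... Unused.
#' @export
predict.gsfit <- function(object, newdata = NULL,
                          type = c("genetic", "trait"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    g <- object$gebv
    return(if (type == "trait") g + object$mu_hat else g)
  }
  if (is.null(object$beta)) {
    stop("BLUP fits predict only individuals present in the relationship ",
         "matrix; refit including the new individuals", call. = FALSE)
  }
  if (inherits(newdata, "gs_geno")) newdata <- dosages(newdata)
  gebv_from_effects(newdata, object$beta, mu_hat = object$mu_hat,
                    scale = type)
}

#' Plot a genomic prediction fit
#'
#' For regression fits, `which = "effects"` draws the normalised absolute
#' SNP-effect profile along the genome ([effect_profile()]) and
#' `which = "trace"` the retained hyperparameter traces; BLUP fits show a
#' GEBV histogram.
#'
#' @param x A `gsfit`.
#' @param which `"effects"` or `"trace"`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.gsfit <- function(x, which = c("effects", "trace"), ...) {
  which <- match.arg(which)
  if (is.null(x$beta)) {
    graphics::hist(x$gebv, main = paste(method_label(x$method), "GEBV"),
                   xlab = "GEBV", ...)
    return(invisible(x))
  }
  if (which == "effects") {
    pr <- effect_profile(x$beta, x$map)
    xc <- if (!is.null(pr$position)) seq_len(nrow(pr)) else seq_len(nrow(pr))
    graphics::plot(xc, pr$abs_effect_proportion, type = "h",
                   xlab = "SNP index (map order)",
                   ylab = "|effect| / max |effect|",
                   main = method_label(x$method), ...)
  } else {
    tr <- x$trace[, colSums(!is.na(x$trace)) > 0, drop = FALSE]
    op <- graphics::par(mfrow = c(ceiling(ncol(tr) / 2), 2),
                        mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (nm in colnames(tr)) {
      graphics::plot(tr[[nm]], type = "l", xlab = "retained sample",
                     ylab = nm, ...)
    }
  }
  invisible(x)
}
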