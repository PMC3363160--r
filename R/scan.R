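#' GRAMMAR polygenic-adjusted single-SNP association scan
#'
#' Two-step association test: first the phenotypes are adjusted for the
#' polygenic (family) effect by fitting `y = mu + g + e`,
#' `g ~ N(0, K sigma2_g)`, via [reml_fit()] and [blup_solve()] and taking
#' the residuals `y - mu_hat - g_hat`; second, the residuals are regressed
#' on each SNP dosage under an additive model, with a two-sided p-value
#' from the t statistic. By default the polygenic step uses the pedigree
#' numerator relationship matrix (the original GRAMMAR formulation); pass a
#' genomic `K` to substitute the realised relationship matrix. The test is
#' conservative: null rejection rates sit at or below the nominal level.
#'
#' @param y Named phenotypes (or `gs_pheno`).
#' @param Z Dosage matrix (rownames = ids).
#' @param pedigree A `gs_pedigree` used to build `K` when `K` is missing.
#' @param K Optional relationship matrix overriding the pedigree.
#' @param map Optional `gs_map` restricted to the columns of `Z`; adds
#'   `chromosome`/`position` columns.
#' @return A `data.frame` of class `gs_scan`: `snp_id`, (`chromosome`,
#'   `position`,) `beta_scan`, `p_value`, `neg_log10_p`, `tested`
#'   (monomorphic or near-empty SNP are flagged untested with `NA`
#'   statistics).
#' @export
grammar_scan <- function(y, Z, pedigree = NULL, K = NULL, map = NULL) {
  y <- as_named_pheno(y)
  if (is.null(K)) {
    if (is.null(pedigree)) stop("supply a pedigree or a relationship matrix",
                                call. = FALSE)
    K <- compute_nrm(pedigree)
  }
  vc <- reml_fit(y, K)
  bl <- blup_solve(y, K, vc)
  obs <- names(y)[!is.na(y)]
  res <- y[obs] - bl$mu_hat - bl$gebv[obs]
  Z <- as.matrix(Z)
  ridx <- match(obs, rownames(Z))
  if (anyNA(ridx)) stop("phenotyped individuals missing from genotypes",
                        call. = FALSE)
  Zp <- Z[ridx, , drop = FALSE]
  n <- length(res)
  zm <- colMeans(Zp)
  szz <- colSums(Zp^2) - n * zm^2
  tested <- szz > 0 & n >= 3
  b <- rep(NA_real_, ncol(Zp))
  pv <- rep(NA_real_, ncol(Zp))
  rc <- res - mean(res)
  szy <- as.vector(crossprod(Zp, rc))
  b[tested] <- szy[tested] / szz[tested]
  sse <- sum(rc^2) - b[tested]^2 * szz[tested]
  se <- sqrt(pmax(sse, 0) / ((n - 2) * szz[tested]))
  tstat <- b[tested] / se
  pv[tested] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pv[tested] <- pmax(pv[tested], .Machine$double.xmin)
  out <- data.frame(snp_id = colnames(Z) %||% paste0("snp", seq_len(ncol(Z))),
                    beta_scan = b, p_value = pv,
                    neg_log10_p = -log10(pv), tested = tested)
  if (!is.null(map)) {
    mi <- match(out$snp_id, map$snp_id)
    out$chromosome <- map$chromosome[mi]
    out$position <- map$position[mi]
    out <- out[, c("snp_id", "chromosome", "position", "beta_scan",
                   "p_value", "neg_log10_p", "tested")]
  }
  attr(out, "vc") <- vc
  class(out) <- c("gs_scan", "data.frame")
  out
}

#' Normalised absolute SNP-effect profile
#'
#' Expresses each SNP effect as a proportion of the largest absolute
#' effect, the standard way to overlay effect profiles of different
#' methods for QTL localisation.
#'
#' @param effects `snp_effects` data frame from a regression fit
#'   (columns `snp_id`, `beta`) or a named numeric vector.
#' @param map Optional `gs_map` supplying positions (rows aligned by
#'   snp id).
#' @return A `data.frame`: `snp_id`, (`chromosome`, `position`,)
#'   `abs_effect_proportion` in \[0, 1\]. An all-zero effect vector yields
#'   an all-zero profile with a warning.
#' @export
effect_profile <- function(effects, map = NULL) {
  if (is.data.frame(effects)) {
    beta <- stats::setNames(effects$beta, effects$snp_id)
  } else {
    beta <- effects
    if (is.null(names(beta))) names(beta) <- paste0("snp", seq_along(beta))
  }
  ab <- abs(beta)
  mx <- max(ab)
  if (mx == 0) {
    warning("all SNP effects are zero; profile is identically zero")
    prop <- ab
  } else {
    prop <- ab / mx
  }
  out <- data.frame(snp_id = names(beta), abs_effect_proportion = unname(prop))
  if (!is.null(map)) {
    mi <- match(out$snp_id, map$snp_id)
    if (anyNA(mi)) stop("alignment error: effects and map differ",
                        call. = FALSE)
    out$chromosome <- map$chromosome[mi]
    out$position <- map$position[mi]
    out <- out[order(mi), c("snp_id", "chromosome", "position",
                            "abs_effect_proportion")]
    rownames(out) <- NULL
  }
  out
}
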