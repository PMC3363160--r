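#' Genomic relationship matrix (realised relationships from SNP dosages)
#'
#' VanRaden's first method: `G = W W' / (2 * sum_j p_j (1 - p_j))` with `W`
#' the dosage matrix column-centred by twice the allele frequency.
#' Monomorphic SNP are skipped; missing dosages are imputed with `2 p_j`
#' before centring. For a large panel of unrelated individuals the mean
#' diagonal is close to 1.
#'
#' @param Z Dosage matrix (individuals x SNP, entries 0/1/2 or `NA`).
#' @param allele_frequencies Optional vector of allele frequencies; defaults
#'   to observed column means / 2.
#' @return Symmetric relationship matrix with `kind` attribute `"genomic"`.
#' @export
compute_grm <- function(Z, allele_frequencies = NULL) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2 || ncol(Z) < 1) {
    stop("need at least 2 individuals and 1 SNP", call. = FALSE)
  }
  p <- allele_frequencies %||% (colMeans(Z, na.rm = TRUE) / 2)
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) {
    stop("degenerate matrix: all SNP monomorphic", call. = FALSE)
  }
  Z <- Z[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(Z)) {
    na_idx <- which(is.na(Z), arr.ind = TRUE)
    Z[na_idx] <- 2 * p[na_idx[, 2]]
  }
  W <- sweep(Z, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(Z), rownames(Z))
  attr(G, "kind") <- "genomic"
  G
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' `A_ii = 1 + 0.5 A[sire, dam]` and
#' `A_ij = 0.5 (A[j, sire(i)] + A[j, dam(i)])` for `j` preceding `i`;
#' unknown parents contribute zero.
#'
#' @param pedigree A `gs_pedigree` (or data frame with `id`, `sire`, `dam`),
#'   sorted parents before offspring.
#' @return Symmetric relationship matrix with `kind` attribute `"pedigree"`.
#' @export
compute_nrm <- function(pedigree) {
  n <- nrow(pedigree)
  pos <- stats::setNames(seq_len(n), pedigree$id)
  s <- ifelse(is.na(pedigree$sire), 0L, pos[as.character(pedigree$sire)])
  d <- ifelse(is.na(pedigree$dam), 0L, pos[as.character(pedigree$dam)])
  if (any(s >= seq_len(n) & s > 0) || any(d >= seq_len(n) & d > 0)) {
    stop("ordering error: offspring precedes parent", call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (si > 0) aj <- aj + A[j, si]
      if (di > 0) aj <- aj + A[j, di]
      A[j, i] <- A[i, j] <- 0.5 * aj
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  attr(A, "kind") <- "pedigree"
  A
}

# restricted log-likelihood of y = 1 mu + g + e at heritability h2, profiled
# over the total variance; d, yr, xr are the eigenvalues and rotated y / 1.
reml_loglik <- function(h2, d, yr, xr) {
  n <- length(yr)
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  xwx <- sum(xr^2 / w)
  mu <- sum(xr * yr / w) / xwx
  rss <- sum((yr - xr * mu)^2 / w)
  s2p <- rss / (n - 1)
  -0.5 * ((n - 1) * log(s2p) + sum(log(w)) + log(xwx) + (n - 1))
}

#' REML variance components for a single-random-effect animal model
#'
#' Fits `y = 1 mu + g + e`, `g ~ N(0, K sigma2_g)`, by eigendecomposition of
#' the phenotyped submatrix of `K` followed by a one-dimensional profile
#' restricted-likelihood search over the heritability: a coarse grid then
#' golden-section refinement to tolerance `1e-6`.
#'
#' @param y Named numeric phenotypes (`NA` allowed; names must match
#'   `rownames(K)`), or a `gs_pheno` data frame.
#' @param K Relationship matrix ([compute_grm()] or [compute_nrm()]).
#' @return A `gs_vc` list: `sigma2_g`, `sigma2_e`, `h2`, `log_likelihood`.
#' @export
reml_fit <- function(y, K) {
  y <- as_named_pheno(y)
  y <- y[!is.na(y)]
  if (length(y) < 10) stop("need at least 10 phenotyped individuals",
                           call. = FALSE)
  if (stats::var(y) <= 0) stop("degeneracy error: zero phenotypic variance",
                               call. = FALSE)
  idx <- match(names(y), rownames(K))
  if (anyNA(idx)) stop("phenotyped individuals missing from K", call. = FALSE)
  Kp <- K[idx, idx]
  eg <- eigen(Kp, symmetric = TRUE)
  d <- eg$values
  jit <- 1e-8 * mean(diag(Kp))
  for (esc in 0:4) {
    if (min(d) > -1e-8 * max(abs(d))) break
    if (esc == 4L) stop("matrix error: K not positive semidefinite beyond ",
                        "jitter", call. = FALSE)
    d <- eg$values + jit
    jit <- jit * 10
  }
  d <- pmax(d, 0)
  yr <- crossprod(eg$vectors, y)[, 1]
  xr <- colSums(eg$vectors)
  obj <- function(h2) reml_loglik(h2, d, yr, xr)
  grid <- seq(0.001, 0.999, length.out = 99)
  ll <- vapply(grid, obj, numeric(1))
  i0 <- which.max(ll)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
  h2 <- opt$maximum
  if (ll[i0] > opt$objective) { # guard: grid beat the local refine
    h2 <- grid[i0]
    opt$objective <- ll[i0]
  }
  w <- h2 * d + (1 - h2)
  mu <- sum(xr * yr / w) / sum(xr^2 / w)
  s2p <- sum((yr - xr * mu)^2 / w) / (length(y) - 1)
  vc <- list(sigma2_g = h2 * s2p, sigma2_e = (1 - h2) * s2p, h2 = h2,
             log_likelihood = opt$objective)
  class(vc) <- "gs_vc"
  vc
}

#' @export
print.gs_vc <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

as_named_pheno <- function(y) {
  if (inherits(y, "gs_pheno") || (is.data.frame(y) && all(c("id", "y") %in%
                                                          names(y)))) {
    return(stats::setNames(y$y, as.character(y$id)))
  }
  if (is.null(names(y))) stop("phenotypes must be named by individual id",
                              call. = FALSE)
  y
}

chol_jitter <- function(V) {
  jit <- 0
  for (esc in 0:4) {
    R <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-8 * mean(diag(V)) else jit * 10
  }
  stop("matrix error: coefficient matrix not positive definite", call. = FALSE)
}

#' Best linear unbiased prediction of genetic values
#'
#' Solves the mixed model `y = 1 mu + g + e` at the variance components in
#' `vc`, predicting genetic values for every individual in `K` (including
#' unphenotyped ones) through their relationships with the phenotyped set.
#' Prediction error variances are the diagonal of the sampling covariance
#' of `g - ghat`, equivalent to the genetic block of the inverted
#' mixed-model coefficient matrix.
#'
#' @inheritParams reml_fit
#' @param vc A `gs_vc` from [reml_fit()].
#' @return A `gs_blup` list: `gebv` (named, all individuals), `mu_hat`,
#'   `pev`, `vc`.
#' @export
blup_solve <- function(y, K, vc) {
  y <- as_named_pheno(y)
  y <- y[!is.na(y)]
  idx <- match(names(y), rownames(K))
  if (anyNA(idx)) stop("phenotyped individuals missing from K", call. = FALSE)
  s2g <- vc$sigma2_g
  s2e <- vc$sigma2_e
  n <- length(y)
  if (s2g <= 0) {
    z <- stats::setNames(numeric(nrow(K)), rownames(K))
    res <- list(gebv = z, mu_hat = mean(y), pev = z, vc = vc)
    class(res) <- "gs_blup"
    return(res)
  }
  V <- s2g * K[idx, idx] + diag(s2e, n)
  R <- chol_jitter(V)
  Vinv <- chol2inv(R)
  v1 <- rowSums(Vinv)
  denom <- sum(v1)
  mu <- sum(v1 * y) / denom
  P <- Vinv - tcrossprod(v1) / denom
  Py <- P %*% y
  Q <- s2g * K[, idx, drop = FALSE]
  gebv <- (Q %*% Py)[, 1]
  pev <- s2g * diag(K) - rowSums((Q %*% P) * Q)
  pev <- pmax(pev, 0)
  res <- list(gebv = stats::setNames(gebv, rownames(K)), mu_hat = mu,
              pev = stats::setNames(pev, rownames(K)), vc = vc)
  class(res) <- "gs_blup"
  res
}
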