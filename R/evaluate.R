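#' Prediction accuracy (correlation between true and estimated values)
#'
#' @param tbv True breeding values.
#' @param gebv Estimated genomic values, paired with `tbv`.
#' @return Pearson correlation.
#' @export
accuracy <- function(tbv, gebv) {
  if (length(tbv) != length(gebv) || length(tbv) < 3) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  ok <- is.finite(tbv) & is.finite(gebv)
  tbv <- tbv[ok]
  gebv <- gebv[ok]
  if (stats::var(tbv) <= 0 || stats::var(gebv) <= 0) {
    stop("degeneracy error: zero variance", call. = FALSE)
  }
  stats::cor(tbv, gebv)
}

#' Accuracy improvement over the pedigree-BLUP baseline
#'
#' `100 (r_method - r_blup) / r_blup`, the percentage gain in accuracy of a
#' marker-based method over traditional pedigree BLUP.
#'
#' @param r_method Accuracy of the method.
#' @param r_blup Accuracy of pedigree BLUP (must be positive).
#' @return Percentage improvement.
#' @export
improvement_over_blup <- function(r_method, r_blup) {
  if (any(r_blup <= 0)) {
    stop("undefined baseline: pedigree-BLUP accuracy must be positive",
         call. = FALSE)
  }
  100 * (r_method - r_blup) / r_blup
}

#' Variance explained by genomic information
#'
#' Infinitesimal-model approximation relating estimated breeding values,
#' their prediction error variance and the genetic variance:
#' `Var(EBV) = r2 sigma2_g`, `PEV = (1 - r2) sigma2_g`, hence
#' `sigma2_g = Var(EBV) + PEV`. The implied heritability uses the method's
#' own residual variance estimate.
#'
#' @param gebv Estimated genomic values.
#' @param pev Per-individual prediction error variances (>= 0).
#' @param sigma2_e_hat Residual variance estimate.
#' @return List with `sigma2_g_hat`, `r2`, `h2_hat`.
#' @export
variance_explained <- function(gebv, pev, sigma2_e_hat) {
  if (any(pev < 0)) stop("PEV must be non-negative", call. = FALSE)
  v_ebv <- stats::var(gebv)
  s2g <- v_ebv + mean(pev)
  if (s2g <= 0) stop("degeneracy error: zero explained variance",
                     call. = FALSE)
  list(sigma2_g_hat = s2g, r2 = v_ebv / s2g,
       h2_hat = s2g / (s2g + sigma2_e_hat))
}

#' Pairwise concordance of GEBV across methods
#'
#' @param gebv_by_method Named list of GEBV vectors over identical
#'   individual sets.
#' @return A `gs_concordance` list: `correlations` (symmetric matrix),
#'   `min`, `max` (over off-diagonal entries).
#' @export
concordance <- function(gebv_by_method) {
  if (length(gebv_by_method) < 2) stop("need at least 2 methods",
                                       call. = FALSE)
  ns <- lapply(gebv_by_method, names)
  base <- ns[[1]]
  for (k in seq_along(ns)[-1]) {
    if (!is.null(base) && !is.null(ns[[k]]) && !identical(sort(base),
                                                          sort(ns[[k]]))) {
      stop("alignment error: methods cover different individual sets",
           call. = FALSE)
    }
    if (length(gebv_by_method[[k]]) != length(gebv_by_method[[1]])) {
      stop("alignment error: methods cover different individual sets",
           call. = FALSE)
    }
  }
  M <- sapply(gebv_by_method, function(g) {
    if (!is.null(names(g)) && !is.null(base)) g[base] else g
  })
  C <- stats::cor(M)
  off <- C[lower.tri(C)]
  res <- list(methods = names(gebv_by_method), correlations = C,
              min = min(off), max = max(off))
  class(res) <- "gs_concordance"
  res
}

#' @export
print.gs_concordance <- function(x, ...) {
  cat("GEBV concordance between methods (Pearson r):\n")
  print(round(x$correlations, 3))
  cat(sprintf("  off-diagonal range: %.3f to %.3f\n", x$min, x$max))
  invisible(x)
}

#' Tabulate accuracy, improvement over pedigree BLUP and implied h2
#'
#' Builds the standard comparison table for a set of fitted methods:
#' accuracy (correlation between TBV and GEBV over the evaluation set),
#' percentage improvement over the pedigree-BLUP baseline, and the
#' heritability implied by each method (REML for BLUP fits, the
#' variance-explained approximation for regression fits), plus the
#' cross-method GEBV concordance matrix.
#'
#' @param fits Named list of `gsfit` objects.
#' @param tbv Named vector of true breeding values.
#' @param blup_fit A pedigree-BLUP `gsfit` supplying the baseline
#'   accuracy, or `NULL` to omit the improvement column.
#' @param ids Evaluation individuals (default: all names of `tbv`).
#' @return A `gs_report` list: `table` (data frame with `method`, `r`,
#'   `improvement_pct`, `h2_hat`, `sigma2_g_hat`), `concordance`,
#'   `r_blup`.
#' @export
evaluate_methods <- function(fits, tbv, blup_fit = NULL, ids = NULL) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ids <- ids %||% names(tbv)
  r_blup <- if (!is.null(blup_fit)) {
    accuracy(tbv[ids], blup_fit$gebv[ids])
  } else NA_real_
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    r <- accuracy(tbv[ids], f$gebv[ids])
    data.frame(method = nm, r = r,
               improvement_pct = if (is.na(r_blup)) NA_real_
                                 else improvement_over_blup(r, r_blup),
               h2_hat = f$h2, sigma2_g_hat = f$sigma2_g)
  })
  tab <- do.call(rbind, rows)
  conc <- if (length(fits) >= 2) {
    concordance(lapply(fits, function(f) f$gebv[ids]))
  } else NULL
  res <- list(table = tab, concordance = conc, r_blup = r_blup, ids = ids)
  class(res) <- "gs_report"
  res
}

#' @export
print.gs_report <- function(x, digits = 3, ...) {
  cat("Genomic prediction evaluation",
      if (!is.na(x$r_blup)) sprintf("(pedigree-BLUP baseline r = %.3f)",
                                    x$r_blup), "\n")
  tab <- x$table
  tab$r <- round(tab$r, digits)
  tab$improvement_pct <- round(tab$improvement_pct, 1)
  tab$h2_hat <- round(tab$h2_hat, digits)
  tab$sigma2_g_hat <- round(tab$sigma2_g_hat, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$concordance)) {
    cat(sprintf("GEBV concordance range: %.3f to %.3f\n",
                x$concordance$min, x$concordance$max))
  }
  invisible(x)
}
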