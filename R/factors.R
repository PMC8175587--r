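# Dimensionality structure of layer roughness: PCA variance shares and
# maximum-likelihood two-factor models with sampling-adequacy diagnostics.

check_corr <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop_domain("correlation matrix must be square")
  if (anyNA(R))
    stop_domain("correlation matrix has undefined entries (constant column?)")
  if (max(abs(R - t(R))) > 1e-8)
    stop_domain("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop_domain("correlation matrix must have unit diagonal")
  invisible(R)
}

#' Variance explained by principal components
#'
#' Eigenvalue shares of a correlation matrix: component k explains
#' `lambda_k / p` of the total variance.  The cumulative share of the first
#' two components is the quantity used to judge whether two factors can
#' summarize the ten layer-roughness variables.
#'
#' @param R Correlation matrix (symmetric, unit diagonal).
#' @return List with `proportions` (descending), `cumulative`, and
#'   `two_component_share` (per cent).
#' @export
pca_explained <- function(R) {
  check_corr(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  prop <- ev / ncol(R)
  list(proportions = prop, cumulative = cumsum(prop),
       two_component_share = 100 * sum(prop[1:2]))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares zero-order correlations to partial correlations (obtained from
#' the inverse correlation matrix): values near 1 mean the variables share
#' enough common variance for factor analysis; below 0.5 is usually judged
#' inadequate.
#'
#' @param R Invertible correlation matrix.
#' @return Overall KMO index in `[0, 1]`.
#' @export
kmo_index <- function(R) {
  check_corr(R)
  Ri <- tryCatch(solve(R), error = function(e)
    stop_domain("correlation matrix is singular; KMO undefined"))
  d <- 1 / sqrt(diag(Ri))
  partial <- -Ri * outer(d, d)               # partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(partial[off]^2))
}

#' Bartlett test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi^2 = -(n - 1 - (2p + 5)/6) ln det(R)` with `p (p - 1) / 2` degrees of
#' freedom (45 for 10 variables, 78 for 13).
#'
#' @param R Correlation matrix.
#' @param n Number of observations behind `R`.
#' @return A `c("rr_test", "htest")`.
#' @export
bartlett_sphericity <- function(R, n) {
  check_corr(R)
  p <- ncol(R)
  detR <- det(R)
  if (detR <= 0) stop_domain("det(R) <= 0; Bartlett statistic undefined")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  as_rr_test(c(chi2 = chi2),
             stats::pchisq(chi2, df, lower.tail = FALSE),
             "Bartlett test of sphericity", "two.sided",
             parameter = c(df = df))
}

#' @rdname bartlett_sphericity
#' @export
corr_determinant <- function(R) {
  check_corr(R)
  det(R)
}

# df of the ML factor-model sufficiency test: ((p - k)^2 - p - k) / 2.
sufficiency_df <- function(p, k) ((p - k)^2 - p - k) / 2

#' Two-factor model of layer roughness
#'
#' Maximum-likelihood factor extraction with orthogonal (varimax) rotation
#' on the layer-roughness columns, optionally including the clinical
#' covariates (MMSE, visual acuity, age; 13 variables).  Reports the chi^2
#' sufficiency test that `n_factors` factors suffice (df
#' `((p - k)^2 - p - k)/2`: 26 for 10 variables and 2 factors, 53 for 13),
#' the KMO index, the Bartlett sphericity test and the determinant of the
#' input correlation matrix.  Loading columns are sign-aligned so each
#' factor's largest-magnitude loading is positive; factor order follows
#' explained common variance, not interpretation.  Heywood-adjacent
#' solutions (uniqueness at the optimizer's lower bound) are flagged.
#'
#' @param table Cohort `data.frame` with `fd_1` .. `fd_10` columns and,
#'   if `include_covariates`, `mmse`, `visual_acuity`, `age`.
#' @param n_factors Number of factors (default 2).
#' @param include_covariates Add the three clinical variables.
#' @return Object of class `rr_factor_model`: loadings, per-factor
#'   explained-variance proportions, `chi2_sufficiency`, `kmo`, `bartlett`,
#'   `corr_det`, `heywood`, `n`.
#' @export
fit_two_factor <- function(table, n_factors = 2L, include_covariates = FALSE) {
  cols <- paste0("fd_", 1:10)
  if (include_covariates) cols <- c(cols, "mmse", "visual_acuity", "age")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop_domain("table lacks columns: ", paste(missing_cols, collapse = ", "))
  dat <- table[stats::complete.cases(table[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  if (n < 15L) stop_domain("need at least 15 complete rows; got ", n)
  p <- length(cols)

  R <- suppressWarnings(stats::cor(dat))
  if (anyNA(R))
    stop_domain("constant column: correlation matrix undefined")
  fa <- tryCatch(
    stats::factanal(covmat = R, n.obs = n, factors = n_factors,
                    rotation = "varimax"),
    error = function(e) stop_domain("factor extraction failed: ",
                                    conditionMessage(e)))
  L <- matrix(as.numeric(fa$loadings), p, n_factors,
              dimnames = list(cols, paste0("F", seq_len(n_factors))))
  for (j in seq_len(n_factors))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]

  chi2 <- if (!is.null(fa$STATISTIC)) unname(fa$STATISTIC) else NA_real_
  df <- sufficiency_df(p, n_factors)
  pval <- if (!is.na(chi2)) stats::pchisq(chi2, df, lower.tail = FALSE)
          else NA_real_

  structure(list(
    loadings = L,
    variance_explained = colSums(L^2) / p,
    chi2_sufficiency = list(chi2 = chi2, df = df, p = pval),
    kmo = kmo_index(R),
    bartlett = bartlett_sphericity(R, n),
    corr_det = det(R),
    heywood = any(fa$uniquenesses <= 0.005 + 1e-12),
    uniquenesses = fa$uniquenesses,
    n = n, variables = cols),
    class = "rr_factor_model")
}

#' @export
print.rr_factor_model <- function(x, digits = 2, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("ML factor model, %d variables, %d orthogonal (varimax) factors, n = %d\n",
              nrow(x$loadings), k, x$n))
  cat(sprintf("  sufficiency: chi^2 = %.2f, df = %d, p = %.3g\n",
              x$chi2_sufficiency$chi2, x$chi2_sufficiency$df,
              x$chi2_sufficiency$p))
  cat(sprintf("  KMO = %.2f; Bartlett chi^2 = %.2f (df = %d, p = %.3g); det(R) = %.2g\n",
              x$kmo, unname(x$bartlett$statistic),
              unname(x$bartlett$parameter), x$bartlett$p.value, x$corr_det))
  if (x$heywood) cat("  warning: Heywood-adjacent solution (uniqueness at bound)\n")
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  cat("\nLoadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Tucker congruence between loading vectors
#'
#' Cosine similarity of two loading columns, used to check that a fitted
#' factor reproduces a generating pattern (values above 0.9 are
#' conventionally read as factor identity).
#'
#' @param a,b Numeric loading vectors.
#' @return Congruence coefficient in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
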