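# Cohort-level inference.  Standard tests are delegated to base R (t.test,
# var.test, shapiro.test, ks.test); the exact Mann-Whitney rank-sum test and
# the one-sided correlation matrix are authored here.  All results are
# returned as c("rr_test", "htest") so base print methods apply.

as_rr_test <- function(statistic, p.value, method, alternative,
                       parameter = NULL, data.name = "cohort data",
                       extra = NULL) {
  out <- c(list(statistic = statistic, p.value = p.value, method = method,
                alternative = alternative, parameter = parameter,
                data.name = data.name), extra)
  class(out) <- c("rr_test", "htest")
  out
}

#' Exact Mann-Whitney rank-sum test
#'
#' Compares two independent samples by the Wilcoxon-Mann-Whitney statistic,
#' reporting both conventions: the first sample's rank sum
#' `W = sum(rank(x))` and the U statistic `U = W - n1 (n1 + 1) / 2`
#' (`0 <= U <= n1 n2`).  The p-value is exact: the permutation distribution
#' of the rank sum over all `choose(n1 + n2, n1)` group labelings is
#' computed by dynamic programming over doubled mid-ranks (integers even
#' under ties), so ties are handled by mid-ranks inside the exact
#' distribution rather than by approximation.  For combined samples larger
#' than `exact_limit` the normal approximation with tie correction is used.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"` means x tends to exceed y.
#' @param exact_limit Largest combined sample size for the exact
#'   distribution (default 60).
#' @return A `c("rr_test", "htest")` with statistic `W`, parameter `U`, and
#'   fields `exact` (logical) and `n` (`c(n1, n2)`).
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4), alternative = "less")$p.value  # 1/6
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("two.sided", "greater", "less"),
                               exact_limit = 60L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_domain("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2

  if (n <= exact_limit) {
    d <- as.integer(round(2 * r))            # doubled mid-ranks
    S <- sum(d)
    # f[j + 1, t + 1] = #subsets of size j with doubled-rank sum t
    f <- matrix(0, n1 + 1L, S + 1L)
    f[1L, 1L] <- 1
    for (di in d) {
      jmax <- min(n1, n1)                    # cap at subset size n1
      for (j in jmax:1) {
        nzi <- which(f[j, ] > 0)
        if (length(nzi))
          f[j + 1L, nzi + di] <- f[j + 1L, nzi + di] + f[j, nzi]
      }
    }
    dist <- f[n1 + 1L, ]
    total <- sum(dist)                       # = choose(n, n1)
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(dist[(w2 + 1L):(S + 1L)]) / total
    p_le <- sum(dist[1L:(w2 + 1L)]) / total
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    exact <- TRUE
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  as_rr_test(c(W = W), p, paste0(if (exact) "Exact " else "Approximate ",
                                 "Mann-Whitney rank-sum test"),
             alternative, parameter = c(U = U),
             extra = list(exact = exact, n = c(n1 = n1, n2 = n2)))
}

#' Student t tests (paired and independent)
#'
#' Thin wrappers around the classical formulas (delegated to
#' [stats::t.test()]) returning the package's test-result class.  The
#' paired version compares matched series (e.g. the per-layer group mean
#' roughness of diseased vs control retinas); the independent version
#' assumes equal variances (classical Student t).
#'
#' @param x,y Numeric vectors (equal length for the paired test).
#' @param alternative Sidedness; `"greater"` means x exceeds y.
#' @return A `c("rr_test", "htest")`.
#' @export
paired_t <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop_domain("paired series must have equal length")
  if (length(x) < 2L) stop_domain("need at least 2 pairs")
  if (stats::var(x - y) == 0)
    stop_domain("zero variance of paired differences")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  as_rr_test(ht$statistic, ht$p.value, "Paired Student t test",
             alternative, parameter = ht$parameter)
}

#' @rdname paired_t
#' @export
independent_t <- function(x, y,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop_domain("need n >= 2 per group")
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = alternative)
  as_rr_test(ht$statistic, ht$p.value, "Independent-samples Student t test",
             alternative, parameter = ht$parameter)
}

#' Distributional checks: Shapiro-Wilk, variance ratio, two-sample KS,
#' two-proportion z
#'
#' `shapiro_wilk()` tests normality (Royston approximation via
#' [stats::shapiro.test()]; restricted here to `3 <= n <= 50`, the range the
#' cohort analyses use).  `fisher_variance_ratio()` is the F test of
#' homoscedasticity `F = var(x)/var(y)` with df `(n1-1, n2-1)`.
#' `ks_two_sample()` reports the Z-normalized two-sample Kolmogorov-Smirnov
#' statistic `Z = D sqrt(n1 n2 / (n1 + n2))`.  `proportions_z()` is the
#' two-sided two-proportion z test without continuity correction.
#'
#' @param x,y Numeric samples (counts for `proportions_z`).
#' @param alternative Sidedness where meaningful.
#' @param x_success,x_total,y_success,y_total Counts for the proportion
#'   test.
#' @return A `c("rr_test", "htest")`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3L || n > 50L)
    stop_domain("shapiro_wilk supports 3 <= n <= 50; got n = ", n)
  ht <- stats::shapiro.test(x)
  as_rr_test(ht$statistic, ht$p.value, "Shapiro-Wilk normality test",
             "two.sided")
}

#' @rdname shapiro_wilk
#' @export
fisher_variance_ratio <- function(x, y,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop_domain("need n >= 2 per sample")
  ht <- stats::var.test(x, y, alternative = alternative)
  as_rr_test(c(F = unname(ht$statistic)), ht$p.value,
             "F test of equality of variances", alternative,
             parameter = ht$parameter)
}

#' @rdname shapiro_wilk
#' @export
ks_two_sample <- function(x, y) {
  ht <- suppressWarnings(stats::ks.test(x, y))
  n1 <- length(x); n2 <- length(y)
  Z <- unname(ht$statistic) * sqrt(n1 * n2 / (n1 + n2))
  as_rr_test(c(Z = Z), ht$p.value,
             "Two-sample Kolmogorov-Smirnov test (Z-normalized)",
             "two.sided", parameter = c(D = unname(ht$statistic)))
}

#' @rdname shapiro_wilk
#' @export
proportions_z <- function(x_success, x_total, y_success, y_total) {
  stopifnot(x_total > 0, y_total > 0,
            x_success >= 0, x_success <= x_total,
            y_success >= 0, y_success <= y_total)
  p1 <- x_success / x_total; p2 <- y_success / y_total
  pp <- (x_success + y_success) / (x_total + y_total)
  se <- sqrt(pp * (1 - pp) * (1 / x_total + 1 / y_total))
  if (se == 0) stop_domain("degenerate proportions (pooled p is 0 or 1)")
  z <- (p1 - p2) / se
  as_rr_test(c(z = z), 2 * stats::pnorm(-abs(z)),
             "Two-proportion z test (no continuity correction)", "two.sided")
}

#' One-sided Pearson correlation matrix of roughness and AD-related
#' variables
#'
#' Computes the Pearson correlation matrix over the roughness columns
#' (`fd_1` .. `fd_10`, plus `fd_total` when present) and the clinical
#' covariates `mmse`, `visual_acuity`, `age`, with significance flagged at
#' p < 0.05 using one-sided tests in the direction predicted for roughness:
#' positive among layers and with age, negative with MMSE and visual
#' acuity.  Pairs not involving a roughness column are tested two-sided.
#' No multiple-testing correction is applied (raw p-values are flagged).
#'
#' @param table Cohort `data.frame` (see [roughness_table()] and
#'   [generate_cohort()]); must contain the fd columns and covariates.
#' @param subset `"all"` or `"AD"` (restricts to `group == "AD"`).
#' @return Object of class `rr_corr`: list with matrices `r`, `p`,
#'   `significant`, the direction matrix and `n`.
#' @export
correlation_matrix <- function(table, subset = c("all", "AD")) {
  subset <- match.arg(subset)
  if (subset == "AD") table <- table[table$group == "AD", , drop = FALSE]
  fd_cols <- intersect(c(paste0("fd_", 1:10), "fd_total"), names(table))
  cov_cols <- intersect(c("mmse", "visual_acuity", "age"), names(table))
  cols <- c(fd_cols, cov_cols)
  if (length(cols) < 2L) stop_domain("no analyzable columns in table")
  dat <- table[, cols, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 3L) stop_domain("need at least 3 complete rows")

  p_count <- length(cols)
  direction <- matrix("two.sided", p_count, p_count,
                      dimnames = list(cols, cols))
  is_fd <- cols %in% fd_cols
  direction[is_fd, is_fd] <- "greater"
  for (cv in cov_cols) {
    dir <- if (cv == "age") "greater" else "less"
    direction[is_fd, cv] <- dir
    direction[cv, is_fd] <- dir
  }
  diag(direction) <- "none"

  r <- suppressWarnings(stats::cor(dat))   # NA for constant columns, flagged below
  pmat <- matrix(NA_real_, p_count, p_count, dimnames = list(cols, cols))
  for (i in seq_len(p_count)) for (j in seq_len(p_count)) {
    if (i == j) next
    rij <- r[i, j]
    if (is.na(rij)) next                     # constant column: undefined
    tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    pmat[i, j] <- switch(direction[i, j],
                         greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
                         less = stats::pt(tstat, n - 2),
                         two.sided = 2 * stats::pt(-abs(tstat), n - 2))
  }
  structure(list(r = r, p = pmat, significant = !is.na(pmat) & pmat < 0.05,
                 direction = direction, n = n, subset = subset),
            class = "rr_corr")
}

#' @export
print.rr_corr <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix (%s sample, n = %d complete rows)\n",
              x$subset, x$n))
  disp <- format(round(x$r, digits))
  disp[x$significant] <- paste0(disp[x$significant], "*")
  diag(disp) <- "."
  print(disp, quote = FALSE)
  cat("* one/two-sided p < 0.05 in the predicted direction (uncorrected)\n")
  invisible(x)
}
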