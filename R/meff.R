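# Effective number of tests from the eigenvalues of a correlation matrix.
#
# MEff = 1 + (k - 1) * (1 - Var(eigenvalues) / k)
#
# where Var is the SAMPLE variance of the k eigenvalues (denominator
# k - 1). The denominator convention matters: for a 6x6 equicorrelated
# matrix at r = .4 the eigenvalues are (3, .6, .6, .6, .6, .6), whose
# sample variance is 0.96 (= 4.8/5) and population variance 0.8; only the
# sample variance reproduces the published reference values. When the
# outcomes are uncorrelated all eigenvalues equal 1, the variance is 0 and
# MEff = k (Bonferroni); when they are perfectly correlated the variance
# is k and MEff = 1 (a single effective test).

corr_eigenvalues <- function(m, validate = TRUE) {
  if (validate) validate_corr_matrix(m)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0) # clip numerical zeros
}

#' Sample variance of a correlation matrix's eigenvalues
#'
#' The dispersion of the eigenvalues measures how far the outcomes are
#' from independence: 0 for an identity matrix, `k` for an all-ones
#' matrix. The sample variance (denominator `k - 1`) is used.
#'
#' @param m a correlation matrix (validated on entry).
#' @param validate set to `FALSE` to skip validation (used in tight
#'   Monte-Carlo loops where the matrix is a sample correlation matrix).
#' @return the sample variance of the `k` eigenvalues.
#' @examples
#' eigen_variance(equicorrelated_matrix(6, 0.8)) # 3.84
#' @export
eigen_variance <- function(m, validate = TRUE) {
  stats::var(corr_eigenvalues(m, validate = validate))
}

#' Effective number of independent tests (MEff)
#'
#' Computes `MEff = 1 + (k - 1) * (1 - Var(eigen) / k)` where `Var` is the
#' sample variance of the eigenvalues of the correlation matrix `m`. MEff
#' ranges from 1 (all outcomes perfectly correlated) to `k` (independent
#' outcomes).
#'
#' @inheritParams eigen_variance
#' @return the effective number of tests, in `[1, k]`.
#' @examples
#' meff(equicorrelated_matrix(6, 0.4)) # 5.2
#' meff(diag(6))                        # 6
#' @export
meff <- function(m, validate = TRUE) {
  ev <- corr_eigenvalues(m, validate = validate)
  k <- length(ev)
  1 + (k - 1) * (1 - stats::var(ev) / k)
}

#' MEff-adjusted significance threshold
#'
#' The nominal familywise alpha divided by the effective number of tests.
#' Each outcome is declared significant when its p-value falls strictly
#' below this threshold.
#'
#' @inheritParams eigen_variance
#' @param nominal_alpha familywise alpha to control, in (0, 1).
#' @return the adjusted per-outcome alpha, between `nominal_alpha / k`
#'   (Bonferroni) and `nominal_alpha`.
#' @examples
#' alpha_meff(equicorrelated_matrix(6, 0.8)) # ~0.018
#' @export
alpha_meff <- function(m, nominal_alpha = 0.05, validate = TRUE) {
  stopifnot(length(nominal_alpha) == 1,
            nominal_alpha > 0, nominal_alpha < 1)
  nominal_alpha / meff(m, validate = validate)
}

#' Full MEff decomposition of a correlation matrix
#'
#' Bundles the eigenvalues (sorted descending), their sample variance,
#' MEff and the adjusted alpha into one object with a printed layout
#' mirroring the reference table for equicorrelated matrices.
#'
#' @inheritParams alpha_meff
#' @return an object of class `meff_result` with fields `k`,
#'   `eigenvalues`, `eigen_variance`, `meff`, `nominal_alpha`,
#'   `alpha_meff`.
#' @examples
#' meff_result(equicorrelated_matrix(6, 0.6))
#' @export
meff_result <- function(m, nominal_alpha = 0.05) {
  ev <- sort(corr_eigenvalues(m), decreasing = TRUE)
  k <- length(ev)
  v <- stats::var(ev)
  me <- 1 + (k - 1) * (1 - v / k)
  structure(
    list(k = k, eigenvalues = ev, eigen_variance = v, meff = me,
         nominal_alpha = nominal_alpha, alpha_meff = nominal_alpha / me),
    class = "meff_result"
  )
}

#' @export
print.meff_result <- function(x, ...) {
  cat("Effective number of tests (", x$k, " outcomes)\n", sep = "")
  df <- data.frame(
    t(c(round_half_up(x$eigenvalues, 1),
        round_half_up(x$eigen_variance, 2),
        round_half_up(x$meff, 1),
        round_half_up(x$alpha_meff, 3)))
  )
  names(df) <- c(paste0("Eigen", seq_len(x$k)), "Var", "MEff", "AlphaMEff")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted alpha
#'
#' @param k number of tests (>= 1).
#' @param nominal_alpha familywise alpha.
#' @return `nominal_alpha / k`.
#' @examples
#' bonferroni_alpha(12) # 0.004...
#' @export
bonferroni_alpha <- function(k, nominal_alpha = 0.05) {
  stopifnot(all(k >= 1), all(k == round(k)))
  nominal_alpha / k
}

#' Sidak-adjusted alpha
#'
#' Exact familywise control for independent tests:
#' `1 - (1 - alpha)^(1/k)`.
#'
#' @inheritParams bonferroni_alpha
#' @examples
#' sidak_alpha(4) # ~0.013
#' @export
sidak_alpha <- function(k, nominal_alpha = 0.05) {
  stopifnot(all(k >= 1), all(k == round(k)))
  1 - (1 - nominal_alpha)^(1 / k)
}

#' Familywise error rate for independent tests
#'
#' Probability of at least one false positive among `k` independent tests
#' each run at `per_test_alpha`: `1 - (1 - alpha)^k`. With six outcomes at
#' alpha .05 this is 1 - .95^6 = .265.
#'
#' @param k number of independent tests (>= 1).
#' @param per_test_alpha per-test significance level, in (0, 1).
#' @examples
#' fwer_independent(6, 0.05) # 0.265
#' @export
fwer_independent <- function(k, per_test_alpha = 0.05) {
  stopifnot(all(k >= 1), all(k == round(k)),
            all(per_test_alpha > 0), all(per_test_alpha < 1))
  1 - (1 - per_test_alpha)^k
}

#' Round half away from zero
#'
#' Presentation rounding used for all published-table comparisons.
#' `base::round()` rounds half to even; the reference tables round half
#' up (e.g. an adjusted alpha of exactly .0125 is shown as .013). A guard
#' of 1e-9 absorbs binary representation error in values that are exactly
#' on a half boundary in decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
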