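# Monte-Carlo power / familywise error for the competing decision rules.
#
# Each replication draws a fresh two-group dataset, computes one-tailed
# per-outcome p-values (alternative: intervention > control) and declares
# the study "significant" under each rule:
#
#   uncorrected - any outcome p < alpha
#   bonferroni  - any outcome p < alpha / k
#   meff        - any outcome p < alpha / MEff(R), with R either the
#                 pooled within-group sample correlation matrix (default;
#                 group means are removed before correlating so a true
#                 effect does not inflate the correlations) or the known
#                 generative matrix
#   pca         - one-tailed comparison of first-principal-component
#                 scores at the unadjusted alpha
#
# With effect_size = 0 the estimated "power" is the familywise type-I
# error rate.

POWER_METHODS <- c("bonferroni", "meff", "pca", "uncorrected")

# column-wise one-tailed two-sample t p-values (alternative mi > mc)
t_p_columns <- function(xc, xi, var_equal = FALSE) {
  nc <- nrow(xc); ni <- nrow(xi)
  mc <- colMeans(xc); mi <- colMeans(xi)
  vc <- colSums(sweep(xc, 2, mc)^2) / (nc - 1)
  vi <- colSums(sweep(xi, 2, mi)^2) / (ni - 1)
  if (var_equal) {
    sp2 <- ((nc - 1) * vc + (ni - 1) * vi) / (nc + ni - 2)
    se <- sqrt(sp2 * (1 / nc + 1 / ni))
    df <- nc + ni - 2
  } else {
    se <- sqrt(vc / nc + vi / ni)
    df <- (vc / nc + vi / ni)^2 /
      ((vc / nc)^2 / (nc - 1) + (vi / ni)^2 / (ni - 1))
  }
  if (any(se == 0)) {
    stop("zero variance in both groups for at least one outcome",
         call. = FALSE)
  }
  stats::pt((mi - mc) / se, df, lower.tail = FALSE)
}

#' One-tailed two-sample t-test p-value
#'
#' Tests the directional alternative "intervention mean exceeds control
#' mean". The unequal-variance (Welch) form is the default; the generative
#' models have equal variances in both arms, so the choice is
#' inconsequential there, but it is fixed and switchable.
#'
#' @param control numeric scores of the control group (>= 2 values).
#' @param intervention numeric scores of the intervention group.
#' @param var_equal use the pooled-variance (Student) form.
#' @return the one-tailed p-value.
#' @examples
#' one_tailed_t(rnorm(20), rnorm(20) + 1)
#' @export
one_tailed_t <- function(control, intervention, var_equal = FALSE) {
  stopifnot(length(control) >= 2, length(intervention) >= 2)
  t_p_columns(matrix(control, ncol = 1), matrix(intervention, ncol = 1),
              var_equal = var_equal)[[1]]
}

#' Monte-Carlo power (or familywise error) of the decision rules
#'
#' Runs `cfg$n_sims` replications of the latent-factor model in `cfg` and
#' estimates, for each requested method, the proportion of replications in
#' which the study is declared significant. When `cfg$effect_size = 0`
#' this proportion is the familywise type-I error rate.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds the whole run (one
#'   generator, replications drawn sequentially).
#' @param methods subset of `"bonferroni"`, `"meff"`, `"pca"`,
#'   `"uncorrected"`.
#' @param nominal_alpha familywise alpha to control (default .05).
#' @param meff_corr `"sample"` (default) recomputes the MEff alpha in each
#'   replication from the pooled within-group sample correlation matrix;
#'   `"population"` uses the known generative matrix once.
#' @param var_equal passed to the per-outcome t-tests.
#' @return a data frame (one row per method) with columns `model`, `k`,
#'   `target_mean_r`, `effect_size`, `n_per_group`, `method`, `power`,
#'   `mc_se` (`sqrt(power (1 - power) / n_sims)`) and `n_sims`.
#' @examples
#' cfg <- sim_config("L1", 4, 50, 0.5, 0.4, n_sims = 200, seed = 1)
#' run_power(cfg)
#' @export
run_power <- function(cfg, methods = c("bonferroni", "meff", "pca"),
                      nominal_alpha = 0.05,
                      meff_corr = c("sample", "population"),
                      var_equal = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), length(methods) >= 1)
  methods <- match.arg(methods, POWER_METHODS, several.ok = TRUE)
  meff_corr <- match.arg(meff_corr)
  stopifnot(nominal_alpha > 0, nominal_alpha < 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  k <- cfg$k
  alpha_bonf <- nominal_alpha / k
  alpha_meff_pop <- if ("meff" %in% methods && meff_corr == "population") {
    alpha_meff(population_corr(cfg), nominal_alpha)
  }
  ctrl <- seq_len(cfg$n_per_group)

  hits <- matrix(0L, nrow = cfg$n_sims, ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_len(cfg$n_sims)) {
    d <- simulate_dataset(cfg, seed = NULL)
    xc <- d$outcomes[ctrl, , drop = FALSE]
    xi <- d$outcomes[-ctrl, , drop = FALSE]
    pv <- NULL
    if (any(methods != "pca")) pv <- t_p_columns(xc, xi, var_equal)
    for (m in methods) {
      hit <- switch(
        m,
        uncorrected = any(pv < nominal_alpha),
        bonferroni = any(pv < alpha_bonf),
        meff = {
          a <- if (meff_corr == "population") alpha_meff_pop else {
            res <- rbind(sweep(xc, 2, colMeans(xc)),
                         sweep(xi, 2, colMeans(xi)))
            alpha_meff(stats::cor(res), nominal_alpha, validate = FALSE)
          }
          any(pv < a)
        },
        pca = {
          s <- pca_first_component(d)
          one_tailed_t(s[ctrl], s[-ctrl], var_equal) < nominal_alpha
        }
      )
      hits[i, m] <- as.integer(hit)
    }
  }
  power <- colMeans(hits)
  data.frame(
    model = cfg$model, k = k, target_mean_r = cfg$target_mean_r,
    effect_size = cfg$effect_size, n_per_group = cfg$n_per_group,
    method = methods, power = unname(power),
    mc_se = unname(sqrt(power * (1 - power) / cfg$n_sims)),
    n_sims = cfg$n_sims, row.names = NULL
  )
}

#' Analytic power for a single outcome
#'
#' One-tailed two-sample t-test power from the noncentral t distribution:
#' noncentrality `E * sqrt(n / 2)` on `2n - 2` degrees of freedom.
#'
#' @param effect_size standardized mean difference E (>= 0).
#' @param n_per_group subjects per arm.
#' @param alpha one-tailed significance level.
#' @return the power; equals `alpha` when `effect_size = 0`.
#' @examples
#' single_outcome_power(0.5, 50) # ~0.80
#' @export
single_outcome_power <- function(effect_size, n_per_group, alpha = 0.05) {
  stopifnot(all(effect_size >= 0), all(n_per_group >= 2))
  df <- 2 * n_per_group - 2
  ncp <- effect_size * sqrt(n_per_group / 2)
  stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
}

#' Single-outcome reference power under a half-affected outcome mix
#'
#' When half of the candidate outcomes respond to the intervention and
#' half do not (model L2x), a researcher picking one primary outcome at
#' random has average power equal to the mean of the powered and null
#' cases.
#'
#' @inheritParams single_outcome_power
#' @return `(single_outcome_power(E) + single_outcome_power(0)) / 2`.
#' @examples
#' l2x_reference_power(0.5, 50) # ~0.42
#' @export
l2x_reference_power <- function(effect_size, n_per_group, alpha = 0.05) {
  (single_outcome_power(effect_size, n_per_group, alpha) +
     single_outcome_power(0, n_per_group, alpha)) / 2
}
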