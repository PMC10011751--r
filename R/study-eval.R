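# Re-evaluation of a published study's per-outcome p-values.
#
# Given the reported p-values, the number of outcomes and either the full
# outcome correlation matrix or an estimate of the mean inter-outcome
# correlation (e.g. from a test manual), flags each outcome as significant
# or not under uncorrected, Bonferroni, Sidak and MEff-adjusted alphas.
# All comparisons are strict: significant means p strictly below the
# threshold. The scalar-correlation path computes the MEff alpha exactly
# from the equicorrelated matrix rather than reading the rounded lookup
# table.

#' Evaluate a published study's p-values under multiplicity corrections
#'
#' @param p_values reported per-outcome p-values, each in (0, 1].
#' @param mean_r estimated mean inter-outcome correlation. May be a single
#'   value or a length-2 range (e.g. `c(0.70, 0.78)` when a test manual
#'   reports a range); with a range, MEff alphas and flags are reported at
#'   both endpoints (`meff_low`, `meff_high`) rather than at a silently
#'   chosen point. Ignored when `corr_matrix` is supplied.
#' @param corr_matrix full outcome correlation matrix, if available.
#' @param outcome_names optional labels (default `V1..Vk`).
#' @param nominal_alpha familywise alpha (default .05).
#' @return an object of class `study_evaluation`: list with `alphas`
#'   (named adjusted thresholds), `flags` (outcomes x methods logical
#'   matrix), `counts` (significant outcomes per method), and the inputs.
#' @examples
#' evaluate_study(c(0.002, 0.022, 0.002, 0.011, 0.062), mean_r = 0.6)
#' @export
evaluate_study <- function(p_values, mean_r = NULL, corr_matrix = NULL,
                           outcome_names = NULL, nominal_alpha = 0.05) {
  k <- length(p_values)
  if (k == 1) {
    stop("a single outcome needs no multiplicity correction: compare its ",
         "p-value to the nominal alpha directly", call. = FALSE)
  }
  stopifnot(k >= 2, is.numeric(p_values))
  if (any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(nominal_alpha > 0, nominal_alpha < 1)
  if (is.null(mean_r) == is.null(corr_matrix)) {
    stop("supply exactly one of mean_r or corr_matrix", call. = FALSE)
  }
  if (is.null(outcome_names)) {
    outcome_names <- if (!is.null(names(p_values))) names(p_values)
    else paste0("V", seq_len(k))
  }
  stopifnot(length(outcome_names) == k)

  alphas <- c(uncorrected = nominal_alpha,
              bonferroni = bonferroni_alpha(k, nominal_alpha),
              sidak = sidak_alpha(k, nominal_alpha))
  if (!is.null(corr_matrix)) {
    stopifnot(nrow(corr_matrix) == k)
    alphas["meff"] <- alpha_meff(corr_matrix, nominal_alpha)
  } else if (length(mean_r) == 1) {
    alphas["meff"] <- alpha_from_lookup(k, mean_r, nominal_alpha)
  } else if (length(mean_r) == 2) {
    lo <- min(mean_r); hi <- max(mean_r)
    alphas["meff_low"] <- alpha_from_lookup(k, lo, nominal_alpha)
    alphas["meff_high"] <- alpha_from_lookup(k, hi, nominal_alpha)
  } else {
    stop("mean_r must have length 1 or 2", call. = FALSE)
  }

  flags <- outer(p_values, alphas, `<`)
  dimnames(flags) <- list(outcome_names, names(alphas))
  structure(
    list(alphas = alphas, flags = flags, counts = colSums(flags),
         p_values = stats::setNames(p_values, outcome_names),
         mean_r = mean_r, nominal_alpha = nominal_alpha),
    class = "study_evaluation"
  )
}

#' @export
print.study_evaluation <- function(x, ...) {
  cat("Study evaluation (", length(x$p_values), " outcomes, familywise alpha ",
      x$nominal_alpha, ")\n", sep = "")
  cat("Adjusted alphas:\n")
  print(round_half_up(x$alphas, 3))
  tab <- data.frame(p = x$p_values,
                    ifelse(x$flags, "*", ""),
                    check.names = FALSE)
  print(tab)
  cat("Significant outcomes per method:\n")
  print(x$counts)
  invisible(x)
}

#' Read per-outcome p-values from CSV
#'
#' Expects columns `outcome` and `p` (header required).
#'
#' @param path CSV file path.
#' @return named numeric vector of p-values.
#' @export
read_study_pvalues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("outcome", "p") %in% names(df))) {
    stop(path, ": expected columns 'outcome' and 'p'", call. = FALSE)
  }
  stats::setNames(as.numeric(df$p), df$outcome)
}
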