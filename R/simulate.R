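# Latent-factor simulation of correlated two-group outcomes.
#
# Each outcome is an indicator of a latent factor L:
#
#   V_j = a * L + sqrt(1 - a^2) * e_j,   L, e_j ~ N(0, 1) independent
#
# so every outcome has unit variance and any two outcomes sharing a factor
# correlate at a^2. To hit a target mean inter-outcome correlation r the
# loading is a = sqrt(r); a target of 0 is not attainable this way (the
# outcomes would no longer be indicators of a common factor), so
# target_mean_r must be strictly positive. The intervention acts on the
# latent factor: group I's latent mean is shifted by E_l = E / sqrt(r),
# which propagates to a standardized mean difference of exactly E on each
# affected outcome (a * E_l = sqrt(r) * E / sqrt(r) = E).
#
# Models:
#   L1  - one factor, all k outcomes load on it, factor shifted by E_l.
#   L2  - two independent factors, outcomes split into two blocks, both
#         factors shifted by E_l.
#   L2x - as L2 but only the first factor is shifted; block-2 outcomes
#         are pure noise with respect to the intervention.

SIM_MODELS <- c("L1", "L2", "L2x")

#' Factor loading for a target mean inter-outcome correlation
#'
#' Outcomes generated as indicators of a common factor with loading `a`
#' intercorrelate at `a^2`, so the loading that yields a target mean
#' correlation `r` is `sqrt(r)`.
#'
#' @param target_mean_r target mean inter-outcome correlation, in (0, 1].
#' @return the loading `sqrt(target_mean_r)`.
#' @examples
#' loading_from_target(0.4) # 0.632...
#' @export
loading_from_target <- function(target_mean_r) {
  stopifnot(length(target_mean_r) == 1)
  if (target_mean_r <= 0) {
    stop("target_mean_r must be > 0: uncorrelated outcomes cannot be ",
         "indicators of a common latent factor", call. = FALSE)
  }
  if (target_mean_r > 1) stop("target_mean_r must be <= 1", call. = FALSE)
  sqrt(target_mean_r)
}

#' Latent effect size for a target outcome effect size
#'
#' The factor shift needed so that each affected outcome shows a
#' standardized mean difference of `effect_size`: the outcome inherits
#' only `loading` times the factor shift, so the factor must be shifted by
#' `effect_size / sqrt(target_mean_r)`.
#'
#' @param effect_size standardized mean difference on each affected
#'   outcome (E >= 0).
#' @inheritParams loading_from_target
#' @return the latent shift `E / sqrt(target_mean_r)`.
#' @examples
#' latent_effect(0.5, 0.4) # 0.791...
#' @export
latent_effect <- function(effect_size, target_mean_r) {
  stopifnot(length(effect_size) == 1, effect_size >= 0)
  effect_size / loading_from_target(target_mean_r)
}

block_split <- function(k) {
  # two-factor models: first block gets the extra outcome when k is odd,
  # consistent with "the first factor is the affected one" in L2x
  c(ceiling(k / 2), floor(k / 2))
}

#' Simulation configuration
#'
#' Validates and bundles the generative settings for
#' [simulate_dataset()] and [run_power()].
#'
#' @param model one of `"L1"`, `"L2"`, `"L2x"`.
#' @param k number of outcomes, 2 to 12.
#' @param n_per_group subjects per arm (>= 2).
#' @param effect_size standardized mean difference E on each affected
#'   outcome (>= 0; 0 simulates the null).
#' @param target_mean_r target mean inter-outcome correlation within a
#'   factor's block, in (0, 1].
#' @param n_sims Monte-Carlo replications for power runs.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `sim_config`.
#' @examples
#' sim_config("L1", k = 6, n_per_group = 50, effect_size = 0.5,
#'            target_mean_r = 0.4)
#' @export
sim_config <- function(model, k, n_per_group, effect_size = 0,
                       target_mean_r = 0.4, n_sims = 2000, seed = NULL) {
  model <- match.arg(model, SIM_MODELS)
  stopifnot(length(k) == 1, k >= 2, k <= 12, k == round(k),
            length(n_per_group) == 1, n_per_group >= 2,
            n_per_group == round(n_per_group),
            length(effect_size) == 1, effect_size >= 0,
            length(n_sims) == 1, n_sims >= 1, n_sims == round(n_sims))
  loading_from_target(target_mean_r) # validates the range
  if (!is.null(seed)) stopifnot(length(seed) == 1, seed == round(seed))
  structure(
    list(model = model, k = as.integer(k),
         n_per_group = as.integer(n_per_group),
         effect_size = effect_size, target_mean_r = target_mean_r,
         n_sims = as.integer(n_sims),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: model ", x$model, ", k = ", x$k,
      ", n/group = ", x$n_per_group, ", E = ", x$effect_size,
      ", target mean r = ", x$target_mean_r,
      ", n_sims = ", x$n_sims,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Population correlation matrix implied by a simulation config
#'
#' L1 gives an equicorrelated matrix at the target correlation; L2/L2x
#' give a two-block matrix (within-block at the target, zero across).
#'
#' @param cfg a [sim_config()].
#' @return a correlation matrix.
#' @export
population_corr <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$model == "L1") {
    equicorrelated_matrix(cfg$k, cfg$target_mean_r)
  } else {
    block_matrix(block_split(cfg$k), cfg$target_mean_r, 0)
  }
}

#' Simulate one two-group multivariate outcome dataset
#'
#' Draws `2 * n_per_group` subjects (control group C, intervention group
#' I) with `k` unit-variance outcomes generated from the latent-factor
#' model in `cfg`. A single value is simulated per subject (no pre/post
#' structure).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this draw; defaults to `cfg$seed`. Use
#'   `NULL` to continue from the current RNG state (as [run_power()] does
#'   across replications).
#' @return an object of class `outcome_dataset`: a list with `group`
#'   (factor, levels C and I), `outcomes` (matrix, columns `V1..Vk`) and
#'   `config`.
#' @examples
#' d <- simulate_dataset(sim_config("L1", 4, 20, 0.5, 0.4, seed = 1))
#' colMeans(d$outcomes[d$group == "I", ])
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * cfg$n_per_group
  group <- factor(rep(c("C", "I"), each = cfg$n_per_group),
                  levels = c("C", "I"))
  a <- loading_from_target(cfg$target_mean_r)
  el <- latent_effect(cfg$effect_size, cfg$target_mean_r)
  shift <- as.numeric(group == "I") * el
  k <- cfg$k
  if (cfg$model == "L1") {
    L <- rnorm(n) + shift
    factor_of <- rep(1L, k)
    latents <- matrix(L, n, 1)
  } else {
    sizes <- block_split(k)
    L1v <- rnorm(n) + shift
    L2v <- rnorm(n) + if (cfg$model == "L2") shift else 0
    factor_of <- rep(c(1L, 2L), times = sizes)
    latents <- cbind(L1v, L2v)
  }
  noise <- matrix(rnorm(n * k), n, k)
  outcomes <- a * latents[, factor_of, drop = FALSE] +
    sqrt(1 - a^2) * noise
  colnames(outcomes) <- paste0("V", seq_len(k))
  structure(list(group = group, outcomes = outcomes, config = cfg),
            class = "outcome_dataset")
}

#' @export
print.outcome_dataset <- function(x, ...) {
  cat("Outcome dataset: ", length(x$group), " subjects (",
      sum(x$group == "C"), " C / ", sum(x$group == "I"), " I), ",
      ncol(x$outcomes), " outcomes, model ", x$config$model, "\n", sep = "")
  invisible(x)
}

#' First-principal-component composite scores
#'
#' Computes the first principal component of the first `m` outcome
#' columns, on both groups combined, centered but not rescaled (the
#' outcomes are unit-variance by construction). The component is oriented
#' so that its loadings sum to a positive value: all outcomes are keyed so
#' that improvement is positive, which makes a one-tailed comparison of
#' the composite well defined.
#'
#' @param data an `outcome_dataset` or a numeric outcome matrix.
#' @param m number of leading outcome columns to use (default: all).
#' @return numeric vector of per-subject PC1 scores.
#' @export
pca_first_component <- function(data, m = NULL) {
  x <- if (inherits(data, "outcome_dataset")) data$outcomes else data
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(m)) m <- ncol(x)
  stopifnot(length(m) == 1, m >= 2, m <= ncol(x))
  p <- stats::prcomp(x[, seq_len(m), drop = FALSE],
                     center = TRUE, scale. = FALSE)
  s <- if (sum(p$rotation[, 1]) < 0) -1 else 1
  s * p$x[, 1]
}

#' Export a simulated dataset to CSV with a config sidecar
#'
#' Writes `subject_id, group, V1..Vk` rows, plus a `<path>.meta.txt`
#' sidecar recording the generative settings (model, loading, latent
#' effect, seed) as flat `key = value` lines.
#'
#' @param data an `outcome_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_dataset <- function(data, path) {
  stopifnot(inherits(data, "outcome_dataset"))
  cfg <- data$config
  df <- data.frame(subject_id = seq_along(data$group),
                   group = as.character(data$group),
                   data$outcomes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(
    paste0("package_version = ", as.character(utils::packageVersion("meffpower"))),
    paste0("model = ", cfg$model),
    paste0("k = ", cfg$k),
    paste0("n_per_group = ", cfg$n_per_group),
    paste0("effect_size = ", cfg$effect_size),
    paste0("target_mean_r = ", cfg$target_mean_r),
    paste0("loading = ", loading_from_target(cfg$target_mean_r)),
    paste0("latent_effect = ", latent_effect(cfg$effect_size, cfg$target_mean_r)),
    paste0("seed = ", if (is.null(cfg$seed)) "NA" else cfg$seed)
  )
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}
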