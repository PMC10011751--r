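# Deterministic fixture generation for tests and demonstrations.

#' Generate small deterministic example inputs
#'
#' Writes a set of plain-text fixtures into `dir`:
#' \itemize{
#'   \item `pvalues_reading_intervention.csv` — the five primary-outcome
#'     p-values of a published reading/language intervention trial in
#'     children with Down syndrome (outcome, p columns);
#'   \item `corr_equicorrelated_k6_r0.6.csv` — a 6x6 equicorrelated
#'     matrix;
#'   \item `corr_block_k4_r0.5.csv` — a 4-outcome two-block matrix
#'     (within-block correlation .5, zero across; mean off-diagonal 1/6);
#'   \item `sim_L1.csv`, `sim_L2.csv`, `sim_L2x.csv` — one small
#'     simulated dataset per latent model (k = 4, 20 per group), each
#'     with a `.meta.txt` sidecar recording the generative settings.
#' }
#' Outputs are byte-identical across calls with the same `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the simulated datasets.
#' @return invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p <- file.path(dir, "pvalues_reading_intervention.csv")
  utils::write.csv(
    data.frame(
      outcome = c("Letter-Sound knowledge", "Phoneme blending",
                  "Single word reading", "Taught expressive Vocabulary",
                  "Taught receptive Vocabulary"),
      p = c(0.002, 0.022, 0.002, 0.011, 0.062)
    ),
    p, row.names = FALSE
  )
  paths <- c(paths, p)

  p <- file.path(dir, "corr_equicorrelated_k6_r0.6.csv")
  write_corr_matrix(equicorrelated_matrix(6, 0.6), p)
  paths <- c(paths, p)

  p <- file.path(dir, "corr_block_k4_r0.5.csv")
  write_corr_matrix(block_matrix(c(2, 2), 0.5), p)
  paths <- c(paths, p)

  models <- c("L1", "L2", "L2x")
  for (i in seq_along(models)) {
    cfg <- sim_config(models[i], k = 4, n_per_group = 20,
                      effect_size = 0.5, target_mean_r = 0.4,
                      seed = seed + i)
    p <- file.path(dir, paste0("sim_", models[i], ".csv"))
    write_outcome_dataset(simulate_dataset(cfg), p)
    paths <- c(paths, p, paste0(p, ".meta.txt"))
  }
  invisible(paths)
}
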