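# Closed-form spectrum oracles, independent of the package's numeric
# eigendecomposition path.

# equicorrelated k x k with off-diagonal r: 1 + (k-1) r once, 1 - r
# with multiplicity k - 1
equicorr_spectrum <- function(k, r) {
  sort(c(1 + (k - 1) * r, rep(1 - r, k - 1)), decreasing = TRUE)
}

# block matrix with zero cross-block correlation: union of block spectra
block_spectrum <- function(block_sizes, within_r) {
  sort(unlist(lapply(block_sizes, function(s) {
    if (s == 1) 1 else equicorr_spectrum(s, within_r)
  })), decreasing = TRUE)
}

# MEff computed from a spectrum supplied directly (bypasses eigen())
meff_from_spectrum <- function(ev) {
  k <- length(ev)
  1 + (k - 1) * (1 - var(ev) / k)
}

# mean off-diagonal of a two-equal-block matrix, by pair counting
block_mean_offdiag <- function(k, within_r) {
  sizes <- c(ceiling(k / 2), floor(k / 2))
  within_pairs <- sum(choose(sizes, 2))
  within_pairs * within_r / choose(k, 2)
}

sample_eigenvalues <- function(m) {
  eigen(m, symmetric = TRUE, only.values = TRUE)$values
}
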