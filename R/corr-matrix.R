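# Correlation-matrix construction and validation.
#
# All downstream MEff computations take a validated correlation matrix:
# square, symmetric, unit diagonal, off-diagonals in [-1, 1], and positive
# semi-definite up to a small numerical tolerance. Matrices supplied by
# users (e.g. estimated from real data) are validated but never repaired;
# eigenvalues in (-1e-8, 0) are treated as exact zeros, anything more
# negative is rejected.

PSD_TOL <- 1e-8

#' Validate a correlation matrix
#'
#' Checks that `m` is a square symmetric numeric matrix with unit diagonal,
#' off-diagonal entries in `[-1, 1]`, and no eigenvalue below `-tol`.
#' Eigenvalues in `(-tol, 0)` are accepted as numerical zeros. The matrix
#' is returned unchanged; no nearest-PSD repair is attempted.
#'
#' @param m numeric matrix to validate.
#' @param tol symmetry and positive-semi-definiteness tolerance.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @examples
#' validate_corr_matrix(equicorrelated_matrix(4, 0.5))
#' @export
validate_corr_matrix <- function(m, tol = PSD_TOL) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("correlation matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop("correlation matrix must be square, got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  if (nrow(m) < 2) {
    stop("correlation matrix must be at least 2x2", call. = FALSE)
  }
  if (anyNA(m)) stop("correlation matrix contains missing values", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-6) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop("correlation matrix diagonal must be 1", call. = FALSE)
  }
  if (max(abs(m)) > 1 + tol) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")", call. = FALSE)
  }
  invisible(m)
}

#' Equicorrelated correlation matrix
#'
#' Builds the k x k matrix with unit diagonal and a single common
#' off-diagonal correlation `r`. Its eigenvalues are `1 + (k - 1) r` (once)
#' and `1 - r` (`k - 1` times), which makes it the canonical test bed for
#' the effective-number-of-tests correction.
#'
#' @param k number of outcomes (>= 2).
#' @param r common off-diagonal correlation; must satisfy
#'   `-1/(k - 1) <= r <= 1` for positive semi-definiteness.
#' @return a `k` x `k` correlation matrix.
#' @examples
#' equicorrelated_matrix(6, 0.4)
#' @export
equicorrelated_matrix <- function(k, r) {
  stopifnot(length(k) == 1, k >= 2, k == round(k), length(r) == 1)
  if (r < -1 / (k - 1) - PSD_TOL || r > 1 + PSD_TOL) {
    stop("r = ", r, " gives a non-positive-semi-definite matrix for k = ", k,
         " (need -1/(k-1) <= r <= 1)", call. = FALSE)
  }
  m <- matrix(r, k, k)
  diag(m) <- 1
  m
}

#' Block-equicorrelated correlation matrix
#'
#' Builds a correlation matrix in which outcomes fall into blocks: each
#' block is equicorrelated at `within_r` and all cross-block correlations
#' equal `between_r`. With `between_r = 0` this is the correlation
#' structure induced by independent latent factors, one per block (the
#' two-factor models L2/L2x use two blocks).
#'
#' @param block_sizes integer vector of block sizes (each >= 1).
#' @param within_r correlation inside each block, in `[0, 1)` or 1.
#' @param between_r correlation across blocks (default 0).
#' @return a `sum(block_sizes)` square correlation matrix.
#' @examples
#' block_matrix(c(4, 4), within_r = 0.5)
#' @export
block_matrix <- function(block_sizes, within_r, between_r = 0) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 1),
            all(block_sizes == round(block_sizes)),
            length(within_r) == 1, length(between_r) == 1)
  k <- sum(block_sizes)
  if (k < 2) stop("need at least 2 outcomes in total", call. = FALSE)
  m <- matrix(between_r, k, k)
  ends <- cumsum(block_sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (b in seq_along(block_sizes)) {
    idx <- starts[b]:ends[b]
    m[idx, idx] <- within_r
  }
  diag(m) <- 1
  validate_corr_matrix(m)
  m
}

#' Mean off-diagonal correlation
#'
#' Arithmetic mean of the `k(k-1)/2` distinct pairwise correlations. Used
#' to summarise a non-uniform correlation structure by a single value: the
#' MEff alpha of an equicorrelated matrix at this mean is close to that of
#' the original matrix.
#'
#' @param m a correlation matrix.
#' @return the mean of the upper-triangle entries.
#' @examples
#' mean_offdiag(block_matrix(c(2, 2), 0.5)) # 1/6 of the pairs drop out
#' @export
mean_offdiag <- function(m) {
  validate_corr_matrix(m)
  mean(m[upper.tri(m)])
}

#' Read a correlation matrix from CSV
#'
#' Accepts a plain square numeric grid, optionally with a header row and/or
#' a leading column of outcome names. The matrix is validated (squareness,
#' symmetry within 1e-6, unit diagonal, positive semi-definiteness) before
#' being returned.
#'
#' @param path CSV file path.
#' @return a named correlation matrix.
#' @export
read_corr_matrix <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  # detect a header row / name column: non-numeric first row or column
  first_row_numeric <- !anyNA(suppressWarnings(as.numeric(unlist(raw[1, ]))))
  if (!first_row_numeric) {
    header <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
  } else {
    header <- NULL
  }
  first_col_numeric <- !anyNA(suppressWarnings(as.numeric(raw[[1]])))
  if (!first_col_numeric) {
    rn <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (!is.null(header)) header <- header[-1]
  } else {
    rn <- NULL
  }
  m <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric entry at row ", bad[1], ", column ", bad[2],
         " of ", path, call. = FALSE)
  }
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop(path, ": matrix is not square (", nrow(m), "x", ncol(m), ")",
         call. = FALSE)
  }
  nms <- if (!is.null(rn)) rn else header
  if (!is.null(nms) && length(nms) == ncol(m)) dimnames(m) <- list(nms, nms)
  validate_corr_matrix(m)
  m
}

#' Write a correlation matrix to CSV
#'
#' @param m a correlation matrix.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_corr_matrix <- function(m, path) {
  validate_corr_matrix(m)
  utils::write.csv(as.data.frame(m), path,
                   row.names = !is.null(rownames(m)))
  invisible(path)
}
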