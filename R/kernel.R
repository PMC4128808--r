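#' Gaussian kernel parameters
#'
#' @param mu Positive width of the Gaussian kernel
#'   exp(-mu * ||x - y||^2), in inverse squared (normalized) contact-count
#'   units.
#' @return Object of class `kernel_params`.
#' @export
kernel_params <- function(mu) {
  mu <- as.numeric(mu)
  if (!is.finite(mu) || mu <= 0) stop("mu must be a positive real")
  structure(list(mu = mu), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> Gaussian, mu = %g\n", x$mu))
  invisible(x)
}

#' Gaussian kernel between two contact vectors
#'
#' k(x, y) = exp(-mu ||x - y||^2); symmetric, with values in (0, 1] and
#' k(x, x) = 1.
#'
#' @param x,y Numeric vectors of equal dimension (210 for contact
#'   vectors).
#' @param params [kernel_params()].
#' @return Scalar kernel value.
#' @export
gaussian_kernel <- function(x, y, params) {
  if (length(x) != length(y)) {
    stop("dimension mismatch: ", length(x), " vs ", length(y))
  }
  exp(-params$mu * sum((as.numeric(x) - as.numeric(y))^2))
}

#' Rectangular kernel matrix between a pool and a basis set
#'
#' Evaluates the Gaussian kernel between every row of the training pool
#' `A` (m rows) and every row of the basis set `Abar` (m-bar rows),
#' giving the m x m-bar rectangular kernel matrix that replaces the full
#' m x m kernel of a conventional SVM. Rows are processed blockwise so
#' peak memory stays at O(block x m-bar) beyond the result itself.
#'
#' @param A m x d matrix of pool vectors (rows).
#' @param Abar m-bar x d matrix of basis vectors (rows).
#' @param params [kernel_params()].
#' @param block Row-block size for the evaluation (default 4096).
#' @return m x m-bar matrix; `dimnames` carry row/column ids when the
#'   inputs have rownames.
#' @export
rect_kernel <- function(A, Abar, params, block = 4096L) {
  A <- as.matrix(A)
  Abar <- as.matrix(Abar)
  if (nrow(Abar) == 0L) stop("empty basis set")
  if (ncol(A) != ncol(Abar)) {
    stop("dimension mismatch: pool ", ncol(A), " vs basis ", ncol(Abar))
  }
  m <- nrow(A)
  K <- matrix(0, m, nrow(Abar), dimnames = list(rownames(A), rownames(Abar)))
  bs <- rowSums(Abar^2)
  for (start in seq(1L, m, by = block)) {
    rows <- start:min(m, start + block - 1L)
    Ab <- A[rows, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), bs, "+") - 2 * tcrossprod(Ab, Abar)
    d2[d2 < 0] <- 0 # numerical guard
    K[rows, ] <- exp(-params$mu * d2)
  }
  K
}

#' Median-heuristic kernel width
#'
#' Default width mu = 1 / median(||x - y||^2) over a random subsample of
#' pairs from the pool: a standard scale heuristic that puts typical
#' pair distances at one kernel length-scale.
#'
#' @param A Pool matrix (rows = vectors).
#' @param n_pairs Number of sampled pairs (default 1000).
#' @param seed Seed for the pair subsample.
#' @return [kernel_params()] with the heuristic mu.
#' @export
median_heuristic_mu <- function(A, n_pairs = 1000L, seed = 1L) {
  A <- as.matrix(A)
  m <- nrow(A)
  if (m < 2L) stop("need at least 2 vectors")
  withr::with_seed(as.integer(seed), {
    i <- sample.int(m, n_pairs, replace = TRUE)
    j <- sample.int(m, n_pairs, replace = TRUE)
    keep <- i != j
    d2 <- rowSums((A[i[keep], , drop = FALSE] - A[j[keep], , drop = FALSE])^2)
    med <- stats::median(d2[d2 > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    kernel_params(mu = 1 / med)
  })
}
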