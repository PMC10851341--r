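#' RPCA solver configuration
#'
#' Parameters of the inexact augmented Lagrangian (ALM) solver used to split
#' the pixels-by-lags coherence matrix into a low-rank part `A` and a sparse
#' part `E`.  The sparsity penalty defaults to `lambda = 1` (the value used
#' for the breast-imaging application, not the generic `1/sqrt(max(dim))`
#' convention); the initial `mu` is `1.25 / ||D||_2` and grows geometrically.
#'
#' @param sparsity_lambda sparsity penalty `lambda` (> 0), default 1.
#' @param mu_growth multiplicative growth factor per iteration (default 1.5).
#' @param tolerance relative Frobenius reconstruction error for convergence
#'   (default 1e-7).
#' @param max_iterations iteration cap (default 1000).
#' @return an object of class `rpca_config`.
#' @export
rpca_config <- function(sparsity_lambda = 1, mu_growth = 1.5,
                        tolerance = 1e-7, max_iterations = 1000L) {
  if (!is.finite(sparsity_lambda) || sparsity_lambda <= 0) {
    stopf("rpca_config: sparsity_lambda must be > 0")
  }
  if (tolerance <= 0) stopf("rpca_config: tolerance must be > 0")
  if (max_iterations < 1) stopf("rpca_config: max_iterations must be >= 1")
  if (mu_growth <= 1) stopf("rpca_config: mu_growth must be > 1")
  structure(list(sparsity_lambda = sparsity_lambda, mu_growth = mu_growth,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "rpca_config")
}

#' Vectorize a coherence stack into a pixels-by-lags matrix
#'
#' Column `m` of the result is the flattened (column-major) lag-`m` coherence
#' image; [unvectorize()] reverses the operation exactly.
#'
#' @param stack a [coherence_stack()].
#' @return an object of class `lag_matrix`: the matrix `D` with the image
#'   shape stored in attribute `image_dim`.
#' @export
vectorize_stack <- function(stack) {
  if (!inherits(stack, "coherence_stack")) stopf("vectorize_stack: need a coherence_stack")
  d <- dim(stack$lag_images)
  D <- matrix(stack$lag_images, nrow = d[1L] * d[2L], ncol = d[3L])
  structure(D, image_dim = d[1:2], class = c("lag_matrix", "matrix", "array"))
}

#' Reverse the vectorization of a lag matrix
#'
#' @param matrix a [vectorize_stack()] result (or any pixels-by-lags matrix).
#' @param shape `c(axial, lateral)` image shape; defaults to the stored
#'   attribute.
#' @return a 3-D (axial, lateral, lag) array.
#' @export
unvectorize <- function(matrix, shape = attr(matrix, "image_dim")) {
  if (is.null(shape) || length(shape) != 2L) {
    stopf("unvectorize: image shape unknown; pass shape = c(axial, lateral)")
  }
  if (nrow(matrix) != prod(shape)) {
    stopf("unvectorize: %d rows cannot be reshaped to %d x %d",
          nrow(matrix), shape[1L], shape[2L])
  }
  array(as.numeric(matrix), dim = c(shape, ncol(matrix)))
}

#' Robust PCA by the inexact augmented Lagrangian method
#'
#' Solves `min ||A||_* + lambda ||E||_1 s.t. D = A + E` approximately by
#' alternating singular-value thresholding of `D - E + Y/mu` (threshold
#' `1/mu`) and entrywise soft thresholding of `D - A + Y/mu` (threshold
#' `lambda/mu`), with multiplier update `Y <- Y + mu (D - A - E)` and
#' geometric growth of `mu` from `1.25 / ||D||_2`.  Terminates when the
#' relative Frobenius residual `||D - A - E||_F / ||D||_F` drops below the
#' configured tolerance.
#'
#' @param D numeric matrix (or [vectorize_stack()] result) with finite
#'   entries.
#' @param config an [rpca_config()].
#' @param track_objective record the Lagrangian target `||A||_* + lambda
#'   ||E||_1` at every iteration (returned as `objective`).
#' @return list with `A` (low rank), `E` (sparse), `iterations`, `converged`,
#'   `residual` (final relative Frobenius residual), `rank` (of `A`) and,
#'   optionally, `objective`.
#' @export
inexact_alm_rpca <- function(D, config = rpca_config(), track_objective = FALSE) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stopf("inexact_alm_rpca: non-finite input")
  lambda <- config$sparsity_lambda
  d_norm <- sqrt(sum(D^2))
  if (d_norm == 0) {
    return(list(A = D, E = D, iterations = 0L, converged = TRUE,
                residual = 0, rank = 0L))
  }
  sv <- svd(D)
  norm_two <- sv$d[1L]
  # dual-norm scaling of the initial multiplier (Lin et al. inexact ALM)
  J <- max(norm_two, max(abs(D)) / lambda)
  Y <- D / J
  mu <- 1.25 / norm_two
  mu_bar <- mu * 1e7
  rho <- config$mu_growth
  A <- matrix(0, nrow(D), ncol(D))
  E <- matrix(0, nrow(D), ncol(D))
  converged <- FALSE
  resid <- Inf
  it <- 0L
  r <- 0L
  objective <- if (track_objective) numeric(0) else NULL
  while (it < config$max_iterations) {
    it <- it + 1L
    E <- soft_threshold(D - A + Y / mu, lambda / mu)
    sv <- svd(D - E + Y / mu)
    keep <- sv$d > 1 / mu
    r <- sum(keep)
    A <- if (r == 0L) {
      matrix(0, nrow(D), ncol(D))
    } else {
      sv$u[, keep, drop = FALSE] %*%
        ((sv$d[keep] - 1 / mu) * t(sv$v[, keep, drop = FALSE]))
    }
    Z <- D - A - E
    resid <- sqrt(sum(Z^2)) / d_norm
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
    if (track_objective) {
      nuc <- if (r == 0L) 0 else sum(svd(A, nu = 0, nv = 0)$d)
      objective <- c(objective, nuc + lambda * sum(abs(E)))
    }
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("inexact_alm_rpca: no convergence in %d iterations (residual %.3g)",
                    it, resid), call. = FALSE)
  }
  out <- list(A = A, E = E, iterations = it, converged = converged,
              residual = resid, rank = as.integer(r))
  if (track_objective) out$objective <- objective
  out
}

#' RPCA-denoise a coherence stack
#'
#' Vectorizes the stack, runs [inexact_alm_rpca()] and reverses the
#' vectorization of the low-rank part.
#'
#' @param stack a [coherence_stack()].
#' @param config an [rpca_config()].
#' @return list with `denoised` (axial x lateral x lag array from `A`),
#'   `diagnostics` (solver diagnostics) and the input `stack` metadata.
#' @export
rpca_denoise_stack <- function(stack, config = rpca_config()) {
  D <- vectorize_stack(stack)
  fit <- inexact_alm_rpca(D, config)
  den <- unvectorize(fit$A, attr(D, "image_dim"))
  list(denoised = den,
       diagnostics = fit[c("iterations", "converged", "residual", "rank")],
       M = stack$M, band = stack$band, geometry = stack$geometry)
}

#' r-SLSC image (RPCA-denoised SLSC, no lag weighting)
#'
#' RPCA is applied to the pixels-by-lags matrix; the denoised low-rank part is
#' summed across the lag dimension, the vectorization reversed, and negative
#' pixels zeroed after summation.
#'
#' @param stack a [coherence_stack()] (M = 20 by convention).
#' @param config an [rpca_config()].
#' @param denoised optional precomputed [rpca_denoise_stack()] result (so one
#'   RPCA solve can feed both r-SLSC and R-SLSC).
#' @return a linear-state [beamformed_image()] with mode `"r-SLSC"`.
#' @export
r_slsc_image <- function(stack, config = rpca_config(), denoised = NULL) {
  den <- denoised %||% rpca_denoise_stack(stack, config)
  v <- lag_sum(den$denoised, dim(den$denoised)[3L])
  v[v < 0] <- 0
  out <- beamformed_image(v, "r-SLSC", den$band, den$geometry)
  attr(out, "rpca_diagnostics") <- den$diagnostics
  out
}

#' R-SLSC image (RPCA-denoised, M-weighted SLSC)
#'
#' Combines the RPCA step with lag weighting: the per-lag denoised images are
#' zeroed (negatives to 0), then summed with the linearly decreasing weights
#' `1 - (m - 1)/M`.
#'
#' @inheritParams r_slsc_image
#' @param M weighting cutoff, default the stack's lag count.
#' @return a linear-state [beamformed_image()] with mode `"R-SLSC"`.
#' @export
R_slsc_image <- function(stack, config = rpca_config(), M = NULL,
                         denoised = NULL) {
  den <- denoised %||% rpca_denoise_stack(stack, config)
  M <- as.integer(M %||% dim(den$denoised)[3L])
  if (M < 1L || M > dim(den$denoised)[3L]) {
    stopf("R_slsc_image: M must be in 1..%d", dim(den$denoised)[3L])
  }
  v <- weighted_lag_sum(pmax(den$denoised[, , seq_len(M), drop = FALSE], 0), M)
  out <- beamformed_image(v, "R-SLSC", den$band, den$geometry)
  attr(out, "rpca_diagnostics") <- den$diagnostics
  out
}
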