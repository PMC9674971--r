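#' Local-linear Gaussian kernel regression with derivative estimates
#'
#' At each grid point `g`, fits a weighted straight line to `(t, y)` with
#' Gaussian weights `exp(-((t-g)/h_bw)^2 / 2)` and reports the local intercept
#' (the smoothed value) and the local slope (the derivative estimate). The
#' local-linear form reproduces straight lines exactly and yields derivative
#' estimates directly from the slope coefficient; the fit is deterministic.
#'
#' @param t observation times (hours); at least 5 distinct values.
#' @param y observed values (same length as `t`).
#' @param grid evaluation grid.
#' @param h_bw kernel bandwidth in hours (> 0); default 1.5.
#' @param weights optional nonnegative case weights (e.g. bootstrap
#'   multiplicities), default all 1.
#' @return a list with `grid`, `fit` (smoothed values) and `deriv`
#'   (local-slope derivative estimates).
#' @export
kernel_smooth <- function(t, y, grid, h_bw = 1.5, weights = NULL) {
  .assert(length(t) == length(y), "t and y must have equal length")
  .assert(h_bw > 0, "h_bw must be > 0")
  .assert(length(unique(t)) >= 5, "need >= 5 distinct t values")
  ks <- .kernel_design(t, grid, h_bw)
  res <- .kernel_solve(ks, y, weights %||% rep(1, length(t)))
  if (anyNA(res$fit)) {
    stop("kernel_smooth: grid point(s) with no effective neighbors at ",
         "bandwidth ", h_bw, call. = FALSE)
  }
  list(grid = grid, fit = res$fit, deriv = res$deriv)
}

# Precompute the kernel design for repeated (bootstrap) solves on a fixed
# (t, grid, bandwidth): K = kernel weights, KD = K * (t - g), KD2 = K * (t-g)^2.
.kernel_design <- function(t, grid, h_bw) {
  D <- outer(grid, t, "-") * -1  # (t_j - g_i)
  K <- exp(-0.5 * (D / h_bw)^2)
  list(t = t, grid = grid, K = K, KD = K * D, KD2 = K * D * D)
}

# Weighted local-linear solve for one response under case weights m.
# Returns NA at grid points whose weighted design is (near-)singular.
.kernel_solve <- function(ks, y, m) {
  my <- m * y
  S0 <- drop(ks$K %*% m)
  S1 <- drop(ks$KD %*% m)
  S2 <- drop(ks$KD2 %*% m)
  T0 <- drop(ks$K %*% my)
  T1 <- drop(ks$KD %*% my)
  den <- S0 * S2 - S1 * S1
  bad <- !(is.finite(den)) | S0 < 1e-300 | den <= 1e-12 * pmax(S0 * S2, 1e-300)
  fit <- (S2 * T0 - S1 * T1) / den
  deriv <- (S0 * T1 - S1 * T0) / den
  fit[bad] <- NA_real_
  deriv[bad] <- NA_real_
  list(fit = fit, deriv = deriv)
}
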