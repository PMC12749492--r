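#' Physical and thermodynamic constants
#'
#' Central registry of the physical constants and default gas properties used
#' by the kinetics and bioenergetics functions. Gas-phase activities are
#' expressed as partial pressure relative to the standard state p0 = 1 atm.
#'
#' @format A list with elements:
#' \describe{
#'   \item{R_J_per_mol_K}{Universal gas constant, 8.31446 J mol-1 K-1.}
#'   \item{atm_Pa}{Standard atmosphere, 101325 Pa.}
#'   \item{T0_K}{Reference temperature, 298.15 K.}
#'   \item{maintenance_W_per_cell}{Empirical maintenance-power window,
#'     c(lower = 1e-17, upper = 1e-12) W per cell.}
#' }
#' @export
foreland_constants <- list(
  R_J_per_mol_K = 8.31446,
  atm_Pa = 101325,
  T0_K = 298.15,
  maintenance_W_per_cell = c(lower = 1e-17, upper = 1e-12)
)

# Derive a reproducible sub-seed for a named random stream from one global
# seed, so that adding a pipeline stage never perturbs the draws of another.
# Polynomial string hash folded into [0, 2^31 - 2].
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr under a locally seeded RNG, restoring global RNG state after.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# Gaussian AIC with maximum-likelihood residual variance and k free
# parameters (slope, intercept, variance => k = 3 for the two-parameter
# regressions used throughout).
gaussian_aic <- function(residuals, k = 3) {
  n <- length(residuals)
  # floor the ML variance so numerically exact fits (residual sd below
  # 1e-12, far under any measurement scale here) compare as equal rather
  # than racing to -Inf
  sigma2 <- max(sum(residuals^2) / n, 1e-24)
  n * log(2 * pi * sigma2) + n + 2 * k
}

# Small-sample corrected variant, offered behind a flag for n of 5-9.
gaussian_aicc <- function(residuals, k = 3) {
  n <- length(residuals)
  gaussian_aic(residuals, k) + 2 * k * (k + 1) / (n - k - 1)
}
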