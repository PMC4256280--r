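# Poisson Random Field selection inference ("single point mass" model): the
# expected site-frequency spectrum under a single scaled selection
# coefficient gamma in a stationary population, and its maximum-likelihood
# fit to an observed spectrum.
#
# Convention: gamma is the scaled coefficient of the stationary diffusion
# density g(q; gamma) = (1 - exp(-2 gamma (1 - q))) /
# ((1 - exp(-2 gamma)) q (1 - q)), the 2*gamma form. Under the alternative
# (4Ns) convention fitted values differ by a factor of 2.

# sojourn density up to the constant absorbed by the mutation intensity;
# expm1 keeps it stable near gamma = 0, where g -> 1/q
.prf_density <- function(q, gamma) {
  if (gamma == 0) return(1 / q)
  expm1(-2 * gamma * (1 - q)) / (expm1(-2 * gamma) * q * (1 - q))
}

#' Expected site-frequency spectrum under the PRF model
#'
#' Proportions p_i, i = 1 .. n-1, of segregating sites with i copies of the
#' derived (non-reference) allele among n sampled chromosomes:
#' p_i is proportional to the integral over q of g(q; gamma) multiplied by
#' the binomial sampling kernel C(n,i) q^i (1-q)^(n-i). The neutral case
#' gamma = 0 uses the closed form p_i proportional to 1/i. Integration uses
#' Gauss-Legendre quadrature with node doubling until the spectrum changes
#' by less than `rel_tol` relatively, componentwise.
#'
#' @param gamma Scaled selection coefficient.
#' @param n Number of sampled chromosomes (>= 2).
#' @param rel_tol Relative convergence tolerance of the quadrature.
#' @return Numeric vector p_1 .. p_(n-1) summing to 1.
#' @export
expected_sfs <- function(gamma, n, rel_tol = 1e-8) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  if (gamma == 0) {
    p <- 1 / i
    return(p / sum(p))
  }
  prev <- NULL
  m <- 128
  repeat {
    gl <- pracma::gaussLegendre(m, 0, 1)
    gq <- .prf_density(gl$x, gamma)
    B <- outer(gl$x, i, function(q, k) stats::dbinom(k, n, q))
    raw <- as.numeric(crossprod(B, gl$w * gq))
    p <- raw / sum(raw)
    if (!is.null(prev) && max(abs(p - prev) / pmax(prev, 1e-300)) < rel_tol) {
      return(p)
    }
    prev <- p
    m <- m * 2
    if (m > 16384) {
      stop("PRF quadrature failed to converge (gamma = ", gamma,
           ", n = ", n, ", nodes = ", m, ")")
    }
  }
}

# cache of log expected-SFS matrices over a gamma grid, keyed by (n, grid)
.prf_cache <- new.env(parent = emptyenv())

.prf_grid_logp <- function(n, grid) {
  key <- paste(n, grid[1], grid[length(grid)], length(grid), sep = ":")
  if (!is.null(.prf_cache[[key]])) return(.prf_cache[[key]])
  logp <- vapply(grid, function(g) log(expected_sfs(g, n)), numeric(n - 1))
  .prf_cache[[key]] <- logp
  logp
}

#' Fit the scaled selection coefficient to a spectrum
#'
#' Maximizes the multinomial log-likelihood sum(X_i log p_i(gamma)) over a
#' gamma grid (the mutation intensity theta is profiled out by conditioning
#' on the number of segregating sites), then refines the maximum by
#' golden-section search within the bracketing grid cell. The 95\%
#' confidence interval is the likelihood-ratio set
#' 2 (l(gamma_hat) - l(gamma)) <= 3.84, with ends interpolated linearly
#' between grid points; an end clipped at the grid boundary sets the
#' `boundary` flag.
#'
#' @param sfs A `cnv_sfs` object (see [sfs()]).
#' @param gamma_grid Length-2 inclusive range searched.
#' @param gamma_step Grid step.
#' @return List of class `prf_fit`: `gamma_hat`, `ci_low`, `ci_high`,
#'   `log_likelihood`, `converged`, `boundary`.
#' @export
fit_gamma <- function(sfs, gamma_grid = c(-20, 10), gamma_step = 0.1) {
  stopifnot(inherits(sfs, "cnv_sfs"))
  X <- sfs$X
  if (sum(X) <= 0) stop("spectrum has no segregating sites")
  grid <- seq(gamma_grid[1], gamma_grid[2], by = gamma_step)
  logp <- .prf_grid_logp(sfs$n, grid)
  ll <- as.numeric(crossprod(logp, X))
  k <- which.max(ll)

  loglik <- function(g) sum(X * log(expected_sfs(g, sfs$n)))
  boundary <- k == 1 || k == length(grid)
  if (!boundary) {
    opt <- stats::optimize(loglik, lower = grid[k - 1], upper = grid[k + 1],
                           maximum = TRUE, tol = 1e-4)
    gamma_hat <- opt$maximum
    ll_max <- opt$objective
  } else {
    gamma_hat <- grid[k]
    ll_max <- ll[k]
  }

  # likelihood-ratio CI on the grid, linear interpolation at the crossing
  crit <- ll_max - stats::qchisq(0.95, df = 1) / 2
  inside <- ll >= crit
  lo_edge <- hi_edge <- FALSE
  i_in <- which(inside)
  if (length(i_in) == 0) i_in <- k
  lo <- min(i_in); hi <- max(i_in)
  if (lo == 1) {
    ci_low <- grid[1]; lo_edge <- TRUE
  } else {
    f <- (ll[lo] - crit) / (ll[lo] - ll[lo - 1])
    ci_low <- grid[lo] - f * gamma_step
  }
  if (hi == length(grid)) {
    ci_high <- grid[length(grid)]; hi_edge <- TRUE
  } else {
    f <- (ll[hi] - crit) / (ll[hi] - ll[hi + 1])
    ci_high <- grid[hi] + f * gamma_step
  }
  structure(list(
    gamma_hat = gamma_hat,
    ci_low = min(ci_low, gamma_hat),
    ci_high = max(ci_high, gamma_hat),
    log_likelihood = ll_max,
    converged = TRUE,
    boundary = boundary || lo_edge || hi_edge
  ), class = "prf_fit")
}

#' Simulate a site-frequency spectrum
#'
#' Draws `n_sites` segregating sites from the expected PRF spectrum at the
#' given gamma (multinomial sampling).
#'
#' @param gamma Scaled selection coefficient.
#' @param n Number of sampled chromosomes.
#' @param n_sites Number of segregating sites to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return A `cnv_sfs` object.
#' @export
simulate_sfs <- function(gamma, n, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- expected_sfs(gamma, n)
  X <- if (n_sites == 0) rep(0, n - 1) else as.numeric(stats::rmultinom(1, n_sites, p))
  sfs(X, n)
}

#' @export
print.prf_fit <- function(x, ...) {
  cat(sprintf("PRF fit: gamma = %.3f (95%% CI %.3f to %.3f)%s\n",
              x$gamma_hat, x$ci_low, x$ci_high,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
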