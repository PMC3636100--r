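#' Two-groups mixture log-likelihood
#'
#' Log-likelihood of z-scores under the zero-mean scale mixture
#' `pi0 N(0, sigma0_sq) + (1 - pi0) N(0, sigma0_sq + sigma1_sq)`.
#'
#' @param z Numeric vector of z-scores.
#' @param pi0 Null proportion in \[0, 1\].
#' @param sigma0_sq Null variance (> 0).
#' @param sigma1_sq Extra non-null variance (>= 0).
#' @return Scalar log-likelihood.
#' @export
two_groups_loglik <- function(z, pi0, sigma0_sq, sigma1_sq) {
  l0 <- log(pi0) + stats::dnorm(z, 0, sqrt(sigma0_sq), log = TRUE)
  l1 <- log(1 - pi0) + stats::dnorm(z, 0, sqrt(sigma0_sq + sigma1_sq),
                                    log = TRUE)
  if (pi0 >= 1) return(sum(stats::dnorm(z, 0, sqrt(sigma0_sq), log = TRUE)))
  if (pi0 <= 0) return(sum(stats::dnorm(z, 0, sqrt(sigma0_sq + sigma1_sq),
                                        log = TRUE)))
  m <- pmax(l0, l1)
  sum(m + log(exp(l0 - m) + exp(l1 - m)))
}

new_two_groups_fit <- function(pi0, sigma0_sq, sigma1_sq, loglik, n_iter,
                               boundary, loglik_trace = numeric()) {
  structure(
    list(pi0 = pi0, sigma0_sq = sigma0_sq, sigma1_sq = sigma1_sq,
         loglik = loglik, n_iter = n_iter, boundary = boundary,
         loglik_trace = loglik_trace),
    class = "two_groups_fit"
  )
}

#' @export
print.two_groups_fit <- function(x, ...) {
  cat(sprintf(
    "<two_groups_fit> pi0 = %.4f, sigma0^2 = %.4f, sigma1^2 = %.4f\n",
    x$pi0, x$sigma0_sq, x$sigma1_sq))
  cat(sprintf("  loglik = %.3f after %d EM iteration(s)%s\n", x$loglik,
              x$n_iter, if (x$boundary) " [boundary fit]" else ""))
  invisible(x)
}

#' Fit the two-groups Gaussian mixture to z-scores
#'
#' Maximum likelihood fit of `f(z) = pi0 N(0, s0) + (1 - pi0) N(0, s0 + s1)`
#' by expectation-maximisation with multiple random restarts. Signs are not
#' informative under this zero-mean symmetric model, so fitting uses z as
#' given (magnitudes and signed values are equivalent). Degenerate solutions
#' (vanishing non-null variance or mixing proportion) are flagged via
#' `boundary`, not raised as errors.
#'
#' @param z Numeric vector of finite z-scores (n >= 1000 recommended).
#' @param init Optional list with `pi0`, `sigma0_sq`, `sigma1_sq` used as one
#'   additional (first) start.
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed for the restart draws.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 10000).
#' @return A `two_groups_fit`: `pi0`, `sigma0_sq`, `sigma1_sq`, `loglik`,
#'   `n_iter`, `boundary` flag and the per-iteration `loglik_trace` of the
#'   winning start (non-decreasing).
#' @export
fit_two_groups <- function(z, init = NULL, n_restarts = 5, seed = 1,
                           tol = 1e-8, max_iter = 10000) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  n <- length(z)
  z2 <- z^2
  vz <- stats::var(z)

  run_em <- function(pi0, v0, v1) {
    trace <- numeric(0)
    ll_old <- -Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      l0 <- log(pi0) + stats::dnorm(z, 0, sqrt(v0), log = TRUE)
      l1 <- log1p(-pi0) + stats::dnorm(z, 0, sqrt(v1), log = TRUE)
      m <- pmax(l0, l1)
      den <- m + log(exp(l0 - m) + exp(l1 - m))
      ll <- sum(den)
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
      if (iter >= max_iter) break
      ll_old <- ll
      g0 <- exp(l0 - den)
      s0 <- sum(g0)
      s1 <- n - s0
      pi0 <- min(max(s0 / n, 1e-12), 1 - 1e-12)
      v0 <- max(sum(g0 * z2) / s0, 1e-12)
      v1 <- max(sum((1 - g0) * z2) / s1, 1e-12)
      if (v1 < v0) {  # label switching: null is the smaller-variance group
        tmp <- v0; v0 <- v1; v1 <- tmp
        pi0 <- 1 - pi0
      }
    }
    list(pi0 = pi0, v0 = v0, v1 = v1, loglik = ll, n_iter = iter,
         trace = trace)
  }

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- list(pi0 = init$pi0, v0 = init$sigma0_sq,
                        v1 = init$sigma0_sq + init$sigma1_sq)
  }
  rng <- local_rng(seed)
  for (k in seq_len(n_restarts)) {
    starts[[length(starts) + 1L]] <- list(
      pi0 = rng$runif(1, 0.5, 0.999),
      v0 = vz * rng$runif(1, 0.3, 1.0),
      v1 = vz * rng$runif(1, 1.5, 10)
    )
  }
  best <- NULL
  for (s in starts) {
    fit <- run_em(s$pi0, s$v0, s$v1)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  sigma1_sq <- max(best$v1 - best$v0, 0)
  pi0 <- best$pi0
  loglik <- best$loglik
  boundary <- sigma1_sq < 1e-6 || pi0 > 1 - 1e-4 || pi0 < 1e-4
  # parsimony collapse of the non-identified ridge: if a single Gaussian
  # explains the data within an AIC-like 2 loglik units, the non-null
  # proportion is arbitrary — report the pure-null fit, flagged boundary
  v_single <- mean(z2)
  ll_single <- sum(stats::dnorm(z, 0, sqrt(v_single), log = TRUE))
  if (ll_single >= loglik - 2) {
    pi0 <- 1
    sigma1_sq <- 0
    best$v0 <- v_single
    loglik <- ll_single
    boundary <- TRUE
  }
  new_two_groups_fit(pi0, best$v0, sigma1_sq, loglik, best$n_iter,
                     boundary, best$trace)
}

# run random draws without touching the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    s
  })
  draw <- function(fun) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fun(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
      out
    }
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       sample_int = draw(sample.int))
}

#' Local false discovery rate under a two-groups fit
#'
#' `fdr(z) = pi0 f0(z) / f(z)`: the posterior probability that a SNP is null
#' given its z-score. Symmetric in z and non-increasing in |z| whenever the
#' non-null variance component is positive.
#'
#' @param z Numeric vector of z-scores.
#' @param fit A `two_groups_fit`.
#' @return Local fdr values in (0, 1].
#' @export
local_fdr <- function(z, fit) {
  stopifnot(inherits(fit, "two_groups_fit"))
  if (fit$pi0 >= 1) return(rep(1, length(z)))
  if (fit$sigma1_sq <= 0) return(rep(fit$pi0, length(z)))
  # log-space ratio keeps the tail stable where both densities underflow
  l0 <- log(fit$pi0) + stats::dnorm(z, 0, sqrt(fit$sigma0_sq), log = TRUE)
  l1 <- log1p(-fit$pi0) +
    stats::dnorm(z, 0, sqrt(fit$sigma0_sq + fit$sigma1_sq), log = TRUE)
  1 / (1 + exp(l1 - l0))
}

#' |z| cut-point where the local fdr reaches a level
#'
#' Smallest |z| with `local_fdr(z) <= level`, found by bisection to 1e-6.
#' Under the two-groups model with positive non-null variance the local fdr is
#' continuous and strictly decreasing in |z|, so the cut-point is unique.
#'
#' @param fit A `two_groups_fit` with `sigma1_sq > 0`.
#' @param level Local fdr level (default 0.05).
#' @return The |z| threshold; `Inf` with attribute `unattainable = TRUE` when
#'   the local fdr never dips below `level`.
#' @export
fdr_cutpoint <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "two_groups_fit"))
  if (local_fdr(0, fit) <= level) return(0)
  # closed form for where the log-density ratio crosses the level gives the
  # bracket; no crossing exists when the non-null variance vanishes
  s0 <- fit$sigma0_sq
  s1 <- fit$sigma1_sq
  slope <- if (s1 > 0) 0.5 * (1 / s0 - 1 / (s0 + s1)) else 0
  if (slope <= 0 || fit$pi0 >= 1 || level <= 0) {
    out <- Inf
    attr(out, "unattainable") <- TRUE
    return(out)
  }
  z2 <- (log((1 - level) / level) - log((1 - fit$pi0) / fit$pi0) -
           0.5 * log(s0 / (s0 + s1))) / slope
  hi <- sqrt(max(z2, 0)) + 1
  if (local_fdr(hi, fit) > level) {
    out <- Inf
    attr(out, "unattainable") <- TRUE
    return(out)
  }
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (local_fdr(mid, fit) <= level) hi <- mid else lo <- mid
  }
  hi
}

#' Rescale a fit to a hypothetical effective sample size
#'
#' The non-null variance component of a z-score scales linearly with effective
#' sample size, while the null component does not; scaling by `factor`
#' emulates a `factor`-fold change in effective n.
#'
#' @param fit A `two_groups_fit`.
#' @param factor Positive scaling factor (2 = doubling).
#' @return A `two_groups_fit` with `sigma1_sq` multiplied by `factor`.
#' @export
scale_effective_n <- function(fit, factor) {
  stopifnot(inherits(fit, "two_groups_fit"), is.finite(factor), factor > 0)
  new_two_groups_fit(fit$pi0, fit$sigma0_sq, fit$sigma1_sq * factor,
                     NA_real_, 0L, fit$boundary)
}

## ---- four-groups bivariate mixture ----------------------------------------

# component covariance matrices from the structured parameter vector
four_groups_sigmas <- function(s01, s02, t1, t2, rho) {
  c3_cov <- rho * sqrt(t1 * t2)
  list(
    matrix(c(s01, 0, 0, s02), 2),
    matrix(c(s01 + t1, 0, 0, s02), 2),
    matrix(c(s01, 0, 0, s02 + t2), 2),
    matrix(c(s01 + t1, c3_cov, c3_cov, s02 + t2), 2)
  )
}

# log density of (z1, z2) under a zero-mean bivariate normal, vectorised
bvn_logdens <- function(z1, z2, sigma) {
  a <- sigma[1, 1]; d <- sigma[2, 2]; cc <- sigma[1, 2]
  det <- a * d - cc^2
  q <- (d * z1^2 - 2 * cc * z1 * z2 + a * z2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Four-groups bivariate mixture log-likelihood
#'
#' Log-likelihood of paired z-scores under the four-component zero-mean
#' bivariate Gaussian mixture (null/null, non-null trait 1 only, non-null
#' trait 2 only, non-null both).
#'
#' @param z1,z2 Paired z-score vectors.
#' @param pi Four mixing proportions summing to 1.
#' @param sigma0_sq Length-2 null variances (trait 1, trait 2).
#' @param sigma1_sq Length-2 extra non-null variances.
#' @param rho3 Correlation of the two non-null effect components in the
#'   pleiotropic group.
#' @return Scalar log-likelihood.
#' @export
four_groups_loglik <- function(z1, z2, pi, sigma0_sq, sigma1_sq, rho3) {
  sig <- four_groups_sigmas(sigma0_sq[1], sigma0_sq[2],
                            sigma1_sq[1], sigma1_sq[2], rho3)
  lp <- log(pi)
  ls <- vapply(1:4, function(k) {
    if (pi[k] <= 0) return(rep(-Inf, length(z1)))
    lp[k] + bvn_logdens(z1, z2, sig[[k]])
  }, numeric(length(z1)))
  ls <- matrix(ls, ncol = 4)
  m <- apply(ls, 1, max)
  sum(m + log(rowSums(exp(ls - m))))
}

new_four_groups_fit <- function(pi, sigma0_sq, sigma1_sq, rho3, loglik,
                                n_iter, boundary, loglik_trace = numeric()) {
  structure(
    list(pi = pi, sigma0_sq = sigma0_sq, sigma1_sq = sigma1_sq, rho3 = rho3,
         sigmas = four_groups_sigmas(sigma0_sq[1], sigma0_sq[2],
                                     sigma1_sq[1], sigma1_sq[2], rho3),
         loglik = loglik, n_iter = n_iter, boundary = boundary,
         loglik_trace = loglik_trace),
    class = "four_groups_fit"
  )
}

#' @export
print.four_groups_fit <- function(x, ...) {
  cat("<four_groups_fit>\n")
  cat(sprintf("  pi      = (%.4f, %.4f, %.4f, %.4f)\n", x$pi[1], x$pi[2],
              x$pi[3], x$pi[4]))
  cat(sprintf("  sigma0^2 = (%.3f, %.3f); sigma1^2 = (%.3f, %.3f); rho3 = %.3f\n",
              x$sigma0_sq[1], x$sigma0_sq[2], x$sigma1_sq[1], x$sigma1_sq[2],
              x$rho3))
  cat(sprintf("  loglik = %.3f after %d iteration(s)%s\n", x$loglik, x$n_iter,
              if (x$boundary) " [boundary fit]" else ""))
  invisible(x)
}

#' Fit the four-groups bivariate Gaussian mixture
#'
#' Maximum-likelihood fit of the bivariate mixture with components null/null,
#' non-null trait 1 only, non-null trait 2 only, and non-null both. Components
#' 0-2 are diagonal (each trait's variance is its null variance, plus the
#' trait's extra variance where non-null); the pleiotropic component allows a
#' free correlation `rho3` between the two non-null effect components.
#'
#' Fitting is by generalised EM: the mixing proportions have their exact
#' closed-form update, and the five variance parameters are updated by a
#' numerical maximisation of the expected complete-data log-likelihood on
#' per-component sufficient statistics (accepted only when it improves, so the
#' observed log-likelihood is non-decreasing).
#'
#' @param z1,z2 Paired z-score vectors (n >= 10^4 recommended).
#' @param init Optional list with `pi` (length 4), `sigma0_sq`, `sigma1_sq`
#'   (length 2 each) and `rho3`, used as one additional (first) start.
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed for restart draws.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 2000).
#' @return A `four_groups_fit` with fields `pi`, `sigma0_sq`, `sigma1_sq`,
#'   `rho3`, the four component covariance matrices (`sigmas`), `loglik`,
#'   `boundary` flag and `loglik_trace`.
#' @export
fit_four_groups <- function(z1, z2, init = NULL, n_restarts = 5, seed = 1,
                            tol = 1e-8, max_iter = 2000) {
  stopifnot(length(z1) == length(z2))
  if (any(!is.finite(z1)) || any(!is.finite(z2))) {
    stop("z must be finite", call. = FALSE)
  }
  n <- length(z1)

  # expected complete-data loglik from per-component sufficient statistics
  q_of_theta <- function(theta, S, A, B, C) {
    s01 <- exp(theta[1]); s02 <- exp(theta[2])
    t1 <- exp(theta[3]); t2 <- exp(theta[4])
    rho <- tanh(theta[5])
    if (!all(is.finite(c(s01, s02, t1, t2)))) return(-1e300)
    sig <- four_groups_sigmas(s01, s02, t1, t2, rho)
    q <- 0
    for (k in 1:4) {
      if (S[k] <= 0) next
      a <- sig[[k]][1, 1]; d <- sig[[k]][2, 2]; cc <- sig[[k]][1, 2]
      det <- a * d - cc^2
      if (!is.finite(det) || det <= 0) return(-1e300)
      q <- q - S[k] * (log(2 * pi) + 0.5 * log(det)) -
        0.5 * (d * A[k] - 2 * cc * C[k] + a * B[k]) / det
    }
    if (!is.finite(q)) q <- -1e300  # overflow guard for optim line searches
    q
  }

  run_em <- function(pi, s01, s02, t1, t2, rho) {
    theta <- c(log(s01), log(s02), log(t1), log(t2), atanh(rho))
    ll_old <- -Inf
    trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      sig <- four_groups_sigmas(exp(theta[1]), exp(theta[2]), exp(theta[3]),
                                exp(theta[4]), tanh(theta[5]))
      ls <- matrix(-Inf, n, 4)
      for (k in 1:4) {
        if (pi[k] > 0) ls[, k] <- log(pi[k]) + bvn_logdens(z1, z2, sig[[k]])
      }
      m <- ls[, 1]
      for (k in 2:4) m <- pmax(m, ls[, k])
      den <- m + log(rowSums(exp(ls - m)))
      ll <- sum(den)
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
      if (iter >= max_iter) break
      ll_old <- ll
      g <- exp(ls - den)  # responsibilities, n x 4
      S <- colSums(g)
      A <- colSums(g * z1^2)
      B <- colSums(g * z2^2)
      C <- colSums(g * z1 * z2)
      pi <- pmax(S / n, 1e-12)
      pi <- pi / sum(pi)
      q0 <- q_of_theta(theta, S, A, B, C)
      opt <- try(stats::optim(theta, q_of_theta, S = S, A = A, B = B, C = C,
                              method = "BFGS",
                              control = list(fnscale = -1, maxit = 50)),
                 silent = TRUE)
      if (!inherits(opt, "try-error") && opt$value > q0) {
        theta <- opt$par
      }
    }
    list(pi = pi, theta = theta, loglik = ll, n_iter = iter, trace = trace)
  }

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- list(pi = init$pi, s01 = init$sigma0_sq[1],
                        s02 = init$sigma0_sq[2], t1 = init$sigma1_sq[1],
                        t2 = init$sigma1_sq[2], rho = init$rho3)
  }
  rng <- local_rng(seed)
  for (k in seq_len(n_restarts)) {
    pw <- rng$runif(4, 0, 1) * c(30, 1, 1, 1) + c(5, 0, 0, 0)
    starts[[length(starts) + 1L]] <- list(
      pi = pw / sum(pw),
      s01 = stats::var(z1) * rng$runif(1, 0.4, 1),
      s02 = stats::var(z2) * rng$runif(1, 0.4, 1),
      t1 = rng$runif(1, 0.5, 8),
      t2 = rng$runif(1, 0.5, 8),
      rho = rng$runif(1, -0.5, 0.5)
    )
  }
  best <- NULL
  for (s in starts) {
    fit <- run_em(s$pi, s$s01, s$s02, s$t1, s$t2, s$rho)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  s0 <- exp(best$theta[1:2])
  s1 <- exp(best$theta[3:4])
  rho <- tanh(best$theta[5])
  pi <- best$pi
  loglik <- best$loglik

  # Parsimony collapse of the non-identified ridge: when a non-null
  # component's extra variance is too small for the data to distinguish it
  # from null, its mixing proportion is arbitrary. Fold out every subset of
  # non-null components whose removal costs less than an AIC-like 2 loglik
  # units per component, preferring the most parsimonious model.
  subsets <- list(c(2, 3, 4), c(2, 3), c(2, 4), c(3, 4), 2, 3, 4)
  collapsed <- FALSE
  for (drop in subsets) {
    pi_c <- pi
    pi_c[1] <- pi_c[1] + sum(pi_c[drop])
    pi_c[drop] <- 0
    ll_c <- four_groups_loglik(z1, z2, pi_c, s0, s1, rho)
    if (ll_c >= loglik - 2 * length(drop)) {
      pi <- pi_c
      loglik <- ll_c
      collapsed <- TRUE
      break
    }
  }
  boundary <- collapsed || any(s1 < 1e-6) || any(best$pi < 1e-6)
  new_four_groups_fit(pi, s0, s1, rho, loglik, best$n_iter,
                      boundary, best$trace)
}

#' Conditional local fdr from a four-groups fit
#'
#' Posterior probability that a SNP is null for trait 1 given both z-scores:
#' `(pi0 f0 + pi2 f2) / f` evaluated at `(z1, z2)` (components where trait 1
#' is null, over the full mixture density). Swap roles via `trait = 2`.
#'
#' @param z1,z2 Paired z-score vectors.
#' @param fit A `four_groups_fit`.
#' @param trait Which trait's nullness is assessed (1 or 2).
#' @return Conditional local fdr values in (0, 1].
#' @export
conditional_local_fdr <- function(z1, z2, fit, trait = 1) {
  stopifnot(inherits(fit, "four_groups_fit"))
  dens <- vapply(1:4, function(k) {
    fit$pi[k] * exp(bvn_logdens(z1, z2, fit$sigmas[[k]]))
  }, numeric(length(z1)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  null_comps <- if (trait == 1) c(1, 3) else c(1, 2)
  pmin(rowSums(dens[, null_comps, drop = FALSE]) / rowSums(dens), 1)
}

#' Marginal two-groups model implied by a four-groups fit
#'
#' The marginal distribution of one trait's z-scores under the four-groups
#' model is itself a two-groups model: null with probability
#' `pi0 + pi_other`, with the trait's null variance, and non-null otherwise
#' with the extra variance added.
#'
#' @param fit A `four_groups_fit`.
#' @param trait Trait index (1 or 2).
#' @return A `two_groups_fit` (loglik is `NA`; it is a derived object).
#' @export
marginal_two_groups <- function(fit, trait = 1) {
  stopifnot(inherits(fit, "four_groups_fit"))
  pi0 <- if (trait == 1) fit$pi[1] + fit$pi[3] else fit$pi[1] + fit$pi[2]
  new_two_groups_fit(pi0, fit$sigma0_sq[trait], fit$sigma1_sq[trait],
                     NA_real_, 0L, fit$boundary)
}

#' Sensitivity versus local-fdr level (power/ROC curve)
#'
#' The proportion of non-null SNPs declared significant (sensitivity) at each
#' local-fdr cutoff, computed by numeric integration of the non-null density
#' over the rejection region. For a `two_groups_fit`, or for
#' `mode = "unconditional"` on a `four_groups_fit`, the univariate marginal
#' local fdr is used; `mode = "conditional"` uses the bivariate conditional
#' local fdr, integrating over the trait's non-null components.
#'
#' @param fit A `two_groups_fit` or `four_groups_fit`.
#' @param mode `"unconditional"` or `"conditional"` (four-groups only).
#' @param levels Local-fdr cutoffs (default `seq(0.01, 1, by = 0.01)`).
#' @param trait Trait index for four-groups fits.
#' @param grid_limit,grid_step Integration grid over z (default \[-15, 15\],
#'   step 0.02 univariate / 0.06 bivariate).
#' @return Tibble with columns `level`, `sensitivity`, `mode`.
#' @export
power_curve <- function(fit, mode = c("unconditional", "conditional"),
                        levels = seq(0.01, 1, by = 0.01), trait = 1,
                        grid_limit = 15, grid_step = NULL) {
  mode <- match.arg(mode)
  if (inherits(fit, "two_groups_fit") && mode == "conditional") {
    stop("conditional mode requires a four_groups_fit", call. = FALSE)
  }
  if (mode == "unconditional") {
    tg <- if (inherits(fit, "four_groups_fit")) {
      marginal_two_groups(fit, trait)
    } else fit
    step <- if (is.null(grid_step)) 0.02 else grid_step
    zg <- seq(-grid_limit, grid_limit, by = step)
    dens <- stats::dnorm(zg, 0, sqrt(tg$sigma0_sq + tg$sigma1_sq))
    dens <- dens / sum(dens)  # normalised weights on the grid
    fdr <- local_fdr(zg, tg)
    sens <- vapply(levels, function(lv) sum(dens[fdr <= lv]), numeric(1))
  } else {
    stopifnot(inherits(fit, "four_groups_fit"))
    step <- if (is.null(grid_step)) 0.06 else grid_step
    zg <- seq(-grid_limit, grid_limit, by = step)
    grid <- expand.grid(z1 = zg, z2 = zg)
    nn_comps <- if (trait == 1) c(2, 4) else c(3, 4)
    w <- fit$pi[nn_comps] / sum(fit$pi[nn_comps])
    dens <- w[1] * exp(bvn_logdens(grid$z1, grid$z2,
                                   fit$sigmas[[nn_comps[1]]])) +
      w[2] * exp(bvn_logdens(grid$z1, grid$z2, fit$sigmas[[nn_comps[2]]]))
    dens <- dens / sum(dens)
    fdr <- conditional_local_fdr(grid$z1, grid$z2, fit, trait = trait)
    sens <- vapply(levels, function(lv) sum(dens[fdr <= lv]), numeric(1))
  }
  tibble::tibble(level = levels, sensitivity = sens, mode = mode)
}
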