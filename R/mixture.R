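# Gaussian mixture with known per-observation variances.
#
# The consensus model treats each projected QTL as a noisy reading of one of
# K unknown true positions on the chromosome: x_i ~ N(mu_{z_i}, sd_i^2),
# with sd_i known (derived from the QTL's confidence-interval width) and
# mixing proportions pi_k. Components differ only in their means. K is
# chosen by AIC with p = 2K - 1 free parameters (K means + K-1 proportions;
# all variances known).

#' Convert a confidence-interval width to a standard deviation
#'
#' Under a Gaussian positional error, a central confidence interval of
#' coverage c has width `2 * z * sd` with `z = qnorm((1+c)/2)`; for 95%
#' coverage, `sd = width / 3.92`. A floor `sd_min` guards against zero-width
#' literature intervals producing infinite weights.
#'
#' @param ci_width interval width (> 0), any length unit; the result is in
#'   the same unit.
#' @param coverage interval coverage, default 0.95.
#' @param sd_min lower floor on the result, default 0.01 (Mb when widths are
#'   in Mb).
#' @return standard deviation, same unit as `ci_width`.
#' @export
ci_to_sd <- function(ci_width, coverage = 0.95, sd_min = 0.01) {
  if (any(!is.finite(ci_width)) || any(ci_width <= 0)) {
    stop("ci_width must be positive")
  }
  # the conventional 2-digit z is used at 95% so that width/3.92 holds exactly
  z <- if (abs(coverage - 0.95) < 1e-12) 1.96 else stats::qnorm((1 + coverage) / 2)
  pmax(ci_width / (2 * z), sd_min)
}

# n x K matrix of log(pi_k) + log phi(x_i; mu_k, sd_i^2)
.log_component_matrix <- function(x, sd, means, proportions) {
  K <- length(means)
  m <- matrix(0, nrow = length(x), ncol = K)
  for (k in seq_len(K)) {
    m[, k] <- log(proportions[k]) + stats::dnorm(x, means[k], sd, log = TRUE)
  }
  m
}

#' Log-likelihood of the known-variance Gaussian mixture
#'
#' `logL = sum_i log sum_k pi_k * phi(x_i; mu_k, sd_i^2)`, computed with
#' log-sum-exp stabilization. The component variance is each observation's
#' own `sd_i^2`; components differ only in mean.
#'
#' @param x observation positions.
#' @param sd per-observation standard deviations (same length as `x`).
#' @param means K component means.
#' @param proportions K mixing proportions summing to 1.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(x, sd, means, proportions) {
  stopifnot(length(x) == length(sd),
            length(means) == length(proportions),
            length(means) >= 1L)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  sum(.row_logsumexp(.log_component_matrix(x, sd, means, proportions)))
}

# One EM run from given initial means. Returns list(means, proportions,
# loglik, converged, n_iter). logL is non-decreasing by construction.
.em_once <- function(x, sd, means0, tol, max_iter) {
  K <- length(means0)
  w <- 1 / sd^2
  means <- means0
  proportions <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lm <- .log_component_matrix(x, sd, means, proportions)
    lse <- .row_logsumexp(lm)
    ll <- sum(lse)
    # EM guarantee; a decrease beyond numerical jitter is a bug
    if (ll < ll_old - 1e-9 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    }
    r <- exp(lm - lse)                      # responsibilities
    # M-step: precision-weighted means; proportions from responsibilities
    rw <- r * w
    denom <- colSums(rw)
    nz <- denom > 0
    means[nz] <- colSums(rw * x)[nz] / denom[nz]
    proportions <- pmax(colMeans(r), 1e-12)
    proportions <- proportions / sum(proportions)
    if (ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  lm <- .log_component_matrix(x, sd, means, proportions)
  ll <- sum(.row_logsumexp(lm))
  list(means = means, proportions = proportions, loglik = ll,
       converged = converged, n_iter = iter)
}

#' Fit the K-component known-variance mixture by EM
#'
#' E-step responsibilities `r_ik ~ pi_k phi(x_i; mu_k, sd_i^2)`; M-step
#' precision-weighted means `mu_k = sum_i r_ik x_i / sd_i^2 / sum_i r_ik /
#' sd_i^2` and `pi_k = mean_i r_ik`. The first restart uses deterministic
#' quantile initialization; the remaining `n_restarts - 1` draw K distinct
#' observations as initial means from a seeded stream, and the best
#' log-likelihood wins. `K = 1` bypasses EM: the maximum-likelihood mean is
#' the inverse-variance weighted mean in closed form.
#'
#' @param x observation positions.
#' @param sd per-observation standard deviations.
#' @param K number of components (>= 1, <= length(x)).
#' @param n_restarts total EM starts, default 10.
#' @param tol convergence threshold on the log-likelihood increase.
#' @param max_iter iteration cap per start.
#' @param seed integer seed for the random restarts.
#' @return object of class `mqtl_mixture`: list with `K`, `means` (sorted
#'   ascending), `proportions` (matching order), `log_likelihood`,
#'   `n_free_params` (= 2K - 1), `aic`, `converged`, `n_iter`, `seed`.
#' @export
fit_em <- function(x, sd, K, n_restarts = 10L, tol = 1e-8,
                   max_iter = 500L, seed = 17L) {
  n <- length(x)
  stopifnot(length(sd) == n, all(sd > 0), K >= 1L)
  if (K > n) stop("K exceeds observations")
  if (K == 1L) {
    mu <- sum(x / sd^2) / sum(1 / sd^2)
    ll <- mixture_loglik(x, sd, mu, 1)
    fit <- list(means = mu, proportions = 1, loglik = ll,
                converged = TRUE, n_iter = 0L)
  } else {
    inits <- list(unname(stats::quantile(x, (seq_len(K) - 0.5) / K,
                                         type = 7)))
    if (n_restarts > 1L) {
      extra <- with_seed(.child_seed(seed, K), {
        lapply(seq_len(n_restarts - 1L), function(r) {
          x[sample.int(n, K, replace = FALSE)]
        })
      })
      inits <- c(inits, extra)
    }
    fits <- lapply(inits, function(m0) .em_once(x, sd, m0, tol, max_iter))
    fit <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  }
  ord <- order(fit$means)
  p <- 2L * K - 1L
  structure(list(K = K,
                 means = fit$means[ord],
                 proportions = fit$proportions[ord],
                 log_likelihood = fit$loglik,
                 n_free_params = p,
                 aic = -2 * fit$loglik + 2 * p,
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 seed = seed),
            class = "mqtl_mixture")
}

#' @export
print.mqtl_mixture <- function(x, ...) {
  cat(sprintf("Known-variance Gaussian mixture: K = %d, logL = %.4f, AIC = %.4f\n",
              x$K, x$log_likelihood, x$aic))
  cat("  means:", paste(sprintf("%.4f", x$means), collapse = ", "), "\n")
  cat("  proportions:", paste(sprintf("%.3f", x$proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of mixture components by AIC
#'
#' Fits `K = 1 .. K_max` (capped at the number of observations) and returns
#' the fit with the lowest AIC; ties go to the smaller K. The full AIC trace
#' is attached as the `trace` attribute (data.frame K, log_likelihood, aic).
#'
#' @inheritParams fit_em
#' @param K_max largest K to consider.
#' @return the selected `mqtl_mixture`, with attribute `trace`.
#' @export
select_K <- function(x, sd, K_max = 5L, n_restarts = 10L, tol = 1e-8,
                     max_iter = 500L, seed = 17L) {
  n <- length(x)
  if (!n) stop("no observations")
  K_max <- min(K_max, n)
  fits <- lapply(seq_len(K_max), function(K) {
    fit_em(x, sd, K, n_restarts = n_restarts, tol = tol,
           max_iter = max_iter, seed = seed)
  })
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- fits[[which.min(aics)]]          # which.min takes the first == smallest K
  attr(best, "trace") <- data.frame(
    K = seq_len(K_max),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    aic = aics
  )
  best
}

#' Maximum-a-posteriori component assignment
#'
#' @param x,sd observations.
#' @param model an `mqtl_mixture`.
#' @return integer vector of component indices (1..K, in the model's
#'   ascending-mean order); ties go to the lower index.
#' @export
map_assign <- function(x, sd, model) {
  lm <- .log_component_matrix(x, sd, model$means, model$proportions)
  apply(lm, 1L, which.max)
}

#' Inverse-variance weighted consensus of co-assigned observations
#'
#' `position = sum(x_i / sd_i^2) / sum(1 / sd_i^2)`,
#' `sd = sqrt(1 / sum(1 / sd_i^2))` (never larger than the smallest member
#' sd, with equality only for singletons), `ci95 = position +/- 1.96 * sd`.
#'
#' @param x member positions (nonempty).
#' @param sd member standard deviations.
#' @return list: position, sd, ci95_start, ci95_end.
#' @export
consensus <- function(x, sd) {
  stopifnot(length(x) >= 1L, length(sd) == length(x), all(sd > 0))
  w <- 1 / sd^2
  pos <- sum(w * x) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- 1.96
  list(position = pos, sd = s,
       ci95_start = pos - z * s, ci95_end = pos + z * s)
}
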