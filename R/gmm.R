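#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Multi-start expectation-maximization for the two-component mixture
#' \eqn{w_1 N(\mu_1, \sigma_1^2) + w_2 N(\mu_2, \sigma_2^2)}. The first
#' start splits the data at the median and uses per-half moments; three
#' further deterministic starts split at the 0.75 / 0.90 / 0.95 quantiles
#' (useful when the upper component is a small minority, as for
#' fusion-site scores); remaining starts draw random responsibilities from
#' the seeded generator. The best log-likelihood fit is retained and
#' components are relabeled so means ascend. Component standard deviations
#' are floored at `1e-6 * sd(values)` to prevent variance collapse.
#'
#' @param values numeric vector; at least 10 finite values with positive
#'   variance. Non-finite values are dropped.
#' @param max_iter maximum EM iterations per start.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param n_starts number of initializations (>= 1).
#' @param seed integer seed for the random-responsibility starts.
#' @return an object of class `gmm2_fit`: list with `weights`, `means`,
#'   `sds`, `log_likelihood`, `n_iter`, `converged`, `n`, `sd_floor` and
#'   the per-iteration log-likelihood trace `ll_trace` of the winning
#'   start.
#' @export
fit_gmm2 <- function(values, max_iter = 500, tol = 1e-8, n_starts = 8,
                     seed = 1) {
  x <- values[is.finite(values)]
  if (length(x) < 10)
    stop("degenerate input: need at least 10 finite values, got ", length(x))
  if (var(x) <= 0) stop("degenerate input: sample variance is zero")
  n <- length(x)
  sd_floor <- 1e-6 * sd(x)

  run_em <- function(w, mu, s) {
    ll_old <- -Inf
    trace <- numeric(0)
    conv <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], s[1])
      d2 <- w[2] * dnorm(x, mu[2], s[2])
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll) && abs(ll - ll_old) < tol) { conv <- TRUE; break }
      ll_old <- ll
      r2 <- d2 / tot
      n2 <- sum(r2); n1 <- n - n2
      if (n1 < 1e-10 || n2 < 1e-10) break
      w <- c(n1, n2) / n
      mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
      s <- sqrt(pmax(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                       sum(r2 * (x - mu[2])^2) / n2), sd_floor^2))
    }
    list(w = w, mu = mu, s = s, ll = trace[length(trace)], it = it,
         conv = conv, trace = trace)
  }

  starts <- list()
  half_start <- function(q) {
    cut <- quantile(x, q, names = FALSE)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(hi) < 2) hi <- tail(sort(x), 2)
    if (length(lo) < 2) lo <- head(sort(x), 2)
    list(w = c(length(lo), length(hi)) / (length(lo) + length(hi)),
         mu = c(mean(lo), mean(hi)),
         s = pmax(c(sd(lo), sd(hi)), sd_floor))
  }
  for (q in c(0.5, 0.75, 0.9, 0.95)[seq_len(min(4, n_starts))])
    starts[[length(starts) + 1]] <- half_start(q)
  if (n_starts > length(starts)) {
    set.seed(seed)
    while (length(starts) < n_starts) {
      r2 <- runif(n)
      n2 <- sum(r2); n1 <- n - n2
      mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
      s <- pmax(sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                       sum(r2 * (x - mu[2])^2) / n2)), sd_floor)
      starts[[length(starts) + 1]] <- list(w = c(n1, n2) / n, mu = mu, s = s)
    }
  }

  best <- NULL
  for (st in starts) {
    f <- run_em(st$w, st$mu, st$s)
    if (is.null(best) || (is.finite(f$ll) && f$ll > best$ll)) best <- f
  }
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$s <- rev(best$s); best$w <- rev(best$w)
  }
  structure(list(weights = best$w, means = best$mu, sds = best$s,
                 log_likelihood = best$ll, n_iter = best$it,
                 converged = best$conv, n = n, sd_floor = sd_floor,
                 ll_trace = best$trace),
            class = "gmm2_fit")
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit (n =", x$n, ")\n")
  cat(sprintf("  weights: %.3f / %.3f\n", x$weights[1], x$weights[2]))
  cat(sprintf("  means:   %.4g / %.4g\n", x$means[1], x$means[2]))
  cat(sprintf("  sds:     %.4g / %.4g\n", x$sds[1], x$sds[2]))
  cat(sprintf("  logLik %.3f after %d iterations (converged: %s)\n",
              x$log_likelihood, x$n_iter, x$converged))
  invisible(x)
}

#' Intersection threshold of the two fitted components
#'
#' Returns the point `x` strictly between the component means where the
#' weighted component densities cross,
#' \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)}
#' (a quadratic in `x`). If no root lies in the open interval between the
#' means, the weighted midpoint \eqn{w_2 \mu_1 + w_1 \mu_2} is returned.
#'
#' @param fit a converged [fit_gmm2()] object.
#' @return scalar threshold.
#' @export
gmm_threshold <- function(fit) {
  if (!inherits(fit, "gmm2_fit")) stop("fit must be a gmm2_fit")
  if (!fit$converged) stop("invalid fit: EM did not converge")
  w <- fit$weights; mu <- fit$means; s <- fit$sds
  fallback <- w[2] * mu[1] + w[1] * mu[2]
  if (mu[1] == mu[2]) return(fallback)
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log((w[1] * s[2]) / (w[2] * s[1]))
  roots <- if (abs(a) < 1e-300) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots > mu[1] & roots < mu[2]]
  if (length(roots) == 0) return(fallback)
  if (length(roots) == 1) return(roots)
  # keep the root where density dominance actually flips from comp 1 to 2
  eps <- (mu[2] - mu[1]) * 1e-6
  ok <- vapply(roots, function(r) {
    w[1] * dnorm(r - eps, mu[1], s[1]) > w[2] * dnorm(r - eps, mu[2], s[2]) &&
    w[1] * dnorm(r + eps, mu[1], s[1]) < w[2] * dnorm(r + eps, mu[2], s[2])
  }, logical(1))
  if (any(ok)) roots[which(ok)[1]] else roots[1]
}

#' Did the mixture actually partition the data?
#'
#' Operationalizes the "failed to partition" judgement: the two-component
#' fit partitions the data iff its BIC improves on a single Gaussian and
#' the component means are at least `min_separation` pooled standard
#' deviations apart (pooled sd = sqrt(w1*s1^2 + w2*s2^2)). Equal means are
#' declared unpartitioned.
#'
#' @param values the data the fit was computed from.
#' @param fit a [fit_gmm2()] object.
#' @param min_separation minimum mean separation in pooled-sd units.
#' @return object of class `partition_decision`: list with `partitioned`,
#'   `threshold` (defined iff partitioned, else `NA`), `delta_bic`
#'   (BIC1 - BIC2; positive favors two components) and `separation`.
#' @export
assess_partition <- function(values, fit, min_separation = 1.0) {
  x <- values[is.finite(values)]
  n <- length(x)
  mu0 <- mean(x); s0 <- sqrt(mean((x - mu0)^2))
  ll1 <- sum(dnorm(x, mu0, max(s0, fit$sd_floor), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * fit$log_likelihood + 5 * log(n)
  pooled <- sqrt(sum(fit$weights * fit$sds^2))
  separation <- if (pooled > 0) (fit$means[2] - fit$means[1]) / pooled else 0
  partitioned <- fit$converged && fit$means[1] != fit$means[2] &&
    (bic2 < bic1) && separation >= min_separation
  structure(list(partitioned = partitioned,
                 threshold = if (partitioned) gmm_threshold(fit) else NA_real_,
                 delta_bic = bic1 - bic2, separation = separation),
            class = "partition_decision")
}

#' @export
print.partition_decision <- function(x, ...) {
  cat("Partition decision:", if (x$partitioned) "partitioned" else
      "NOT partitioned", "\n")
  cat(sprintf("  delta BIC (1 - 2 comp): %.2f, separation: %.2f pooled sd\n",
              x$delta_bic, x$separation))
  if (x$partitioned) cat(sprintf("  threshold: %.4g\n", x$threshold))
  invisible(x)
}

#' Classify values into the upper mixture component
#'
#' `above_threshold` asserts values strictly greater than the component
#' intersection ([gmm_threshold()]); `posterior` asserts values whose
#' responsibility under the higher-mean component exceeds 0.5 (component
#' membership).
#'
#' @param values numeric vector.
#' @param fit a [fit_gmm2()] object.
#' @param rule `"above_threshold"` or `"posterior"`.
#' @param decision optional precomputed [assess_partition()] result; it is
#'   an error to classify against an unpartitioned fit.
#' @return logical vector (`NA` for non-finite values).
#' @export
classify_upper <- function(values, fit,
                           rule = c("above_threshold", "posterior"),
                           decision = NULL) {
  rule <- match.arg(rule)
  if (is.null(decision)) decision <- assess_partition(values, fit)
  if (!decision$partitioned)
    stop("invalid use: mixture did not partition the data")
  out <- rep(NA, length(values))
  ok <- is.finite(values)
  if (rule == "above_threshold") {
    out[ok] <- values[ok] > decision$threshold
  } else {
    d1 <- fit$weights[1] * dnorm(values[ok], fit$means[1], fit$sds[1])
    d2 <- fit$weights[2] * dnorm(values[ok], fit$means[2], fit$sds[2])
    out[ok] <- d2 / (d1 + d2) > 0.5
  }
  out
}
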