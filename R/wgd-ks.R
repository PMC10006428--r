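# Gaussian-mixture analysis of paralog Ks distributions. A shared burst of
# synonymous distances marks a whole-genome duplication; the mixture is
# fitted by EM on the raw Ks scale within a truncation window (out-of-range
# values are discarded rather than modelled with a truncated likelihood; the
# approximation is adequate for locating the density summit). The EM
# log-likelihood is asserted non-decreasing at every iteration.

#' Fit a Gaussian mixture to a Ks distribution
#'
#' EM with `n_starts` seeded restarts (initial means drawn from data
#' quantiles with jitter), keeping the best fit by log-likelihood.
#' Components are returned ordered by mean. Convergence is declared when the
#' log-likelihood improves by less than `tol`.
#'
#' @param ks numeric vector of Ks values, or a data.frame with a `ks` column.
#' @param n_components number of Gaussian components.
#' @param fit_range values outside `[fit_range[1], fit_range[2]]` are
#'   discarded before fitting (default `c(0.05, 5)`: the lower cutoff
#'   excludes allelic/recent-duplicate noise, the upper matches the plotted
#'   Ks range).
#' @param n_starts number of EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed optional RNG seed for the restarts.
#' @return object of class `ks_mixture_fit`: list with `n_components`,
#'   `weights`, `means`, `sds`, `log_likelihood`, `bic`, `converged`, `n`,
#'   `fit_range` and `summit` (Ks at maximum fitted density over the fit
#'   range).
#' @export
fit_ks_mixture <- function(ks, n_components = 2, fit_range = c(0.05, 5),
                           n_starts = 10, max_iter = 1000, tol = 1e-8,
                           seed = NULL) {
  if (is.data.frame(ks)) ks <- ks$ks
  if (is.null(ks) || length(ks) == 0L) stop("empty Ks input", call. = FALSE)
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop("Ks values must be finite and >= 0", call. = FALSE)
  }
  k <- as.integer(n_components)
  x <- ks[ks >= fit_range[1] & ks <= fit_range[2]]
  n <- length(x)
  if (n < 10L * k) {
    stop("need at least ", 10L * k, " Ks values inside the fit range, got ",
         n, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(mu0) {
    w <- rep(1 / k, k)
    mu <- mu0
    sg <- rep(max(stats::sd(x) / k, 1e-3), k)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E-step in log space for stability
      lp <- vapply(seq_len(k), function(j) {
        log(w[j]) + dnorm(x, mu[j], sg[j], log = TRUE)
      }, numeric(n))
      m <- apply(lp, 1L, max)
      lse <- m + log(rowSums(exp(lp - m)))
      ll <- sum(lse)
      if (ll < ll_prev - 1e-6) {
        stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
      }
      resp <- exp(lp - lse)
      if (is.finite(ll_prev) && ll - ll_prev < tol) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
      # M-step
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      sg <- pmax(sg, 1e-4)
    }
    list(weights = w, means = mu, sds = sg, log_likelihood = ll_prev,
         converged = converged)
  }

  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  best <- NULL
  for (s in seq_len(n_starts)) {
    mu0 <- if (s == 1L) qs else
      pmin(pmax(qs + rnorm(k, 0, stats::sd(x) / 4), fit_range[1]), fit_range[2])
    fit <- tryCatch(run_em(sort(mu0)), error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all EM starts failed", call. = FALSE)
  if (!best$converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  o <- order(best$means)
  res <- structure(list(n_components = k, weights = best$weights[o],
                        means = best$means[o], sds = best$sds[o],
                        log_likelihood = best$log_likelihood,
                        bic = -2 * best$log_likelihood +
                          (3 * k - 1) * log(n),
                        converged = best$converged, n = n,
                        fit_range = fit_range, summit = NA_real_),
                   class = "ks_mixture_fit")
  res$summit <- density_summit(res, search_range = fit_range)
  res
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat("ks_mixture_fit:", x$n_components, "component(s), n =", x$n, "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("  means:  ", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  sds:    ", paste(sprintf("%.3f", x$sds), collapse = " "), "\n")
  cat(sprintf("  logLik %.3f  BIC %.3f  summit %.3f  converged %s\n",
              x$log_likelihood, x$bic, x$summit, x$converged))
  invisible(x)
}

#' Choose the number of mixture components by BIC
#'
#' Fits k = 1..`k_max` components and returns the minimum-BIC fit; BIC ties
#' break toward smaller k.
#'
#' @inheritParams fit_ks_mixture
#' @param k_max largest component count to try.
#' @return the selected `ks_mixture_fit`.
#' @export
select_components <- function(ks, k_max = 4, fit_range = c(0.05, 5),
                              n_starts = 10, seed = NULL) {
  if (k_max < 1) stop("'k_max' must be >= 1", call. = FALSE)
  fits <- lapply(seq_len(k_max), function(k) {
    fit_ks_mixture(ks, n_components = k, fit_range = fit_range,
                   n_starts = n_starts, seed = seed)
  })
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  fits[[which.min(bics)]]  # which.min returns the first (smallest k) on ties
}

#' Fitted mixture density
#'
#' @param fit a `ks_mixture_fit`.
#' @param x numeric vector of Ks values.
#' @return mixture density at `x`.
#' @export
mixture_density <- function(fit, x) {
  rowSums(vapply(seq_len(fit$n_components), function(j) {
    fit$weights[j] * dnorm(x, fit$means[j], fit$sds[j])
  }, numeric(length(x))))
}

#' Locate the summit of a fitted Ks density
#'
#' Grid argmax of the fitted mixture density over a search range (the WGD
#' signature is reported as the summit of the Ks peak, e.g. a summit at 1.4
#' inside the 1-2 peak).
#'
#' @param fit a `ks_mixture_fit`.
#' @param search_range length-2 numeric range; defaults to the fit range.
#' @param grid_step grid resolution (default 0.01).
#' @return the Ks value at maximum fitted density; a warning is issued when
#'   the summit falls on a range boundary.
#' @export
density_summit <- function(fit, search_range = fit$fit_range,
                           grid_step = 0.01) {
  if (length(search_range) != 2L || search_range[2] <= search_range[1]) {
    stop("empty search range", call. = FALSE)
  }
  grid <- seq(search_range[1], search_range[2], by = grid_step)
  dens <- mixture_density(fit, grid)
  s <- grid[which.max(dens)]
  if (s == grid[1] || s == grid[length(grid)]) {
    warning("density summit at a search-range boundary")
  }
  s
}

#' Common-binned Ks densities for several species/tables
#'
#' Bins every table on one common grid for overlay plotting of ortholog Ks
#' distributions between species pairs (divergence ordering).
#'
#' @param tables named list; each element a numeric vector of Ks values or a
#'   data.frame with a `ks` column.
#' @param bins common bin breaks (default `seq(0, 5, 0.05)`).
#' @return data.frame with `set`, `bin_mid`, `density` (histogram density:
#'   counts normalized by n and bin width).
#' @export
compare_ortholog_ks <- function(tables, bins = seq(0, 5, by = 0.05)) {
  if (length(tables) < 1L || is.null(names(tables))) {
    stop("'tables' must be a non-empty named list", call. = FALSE)
  }
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  bw <- diff(bins)
  out <- lapply(names(tables), function(nm) {
    v <- tables[[nm]]
    if (is.data.frame(v)) v <- v$ks
    v <- v[v >= bins[1] & v <= bins[length(bins)]]
    cnt <- tabulate(findInterval(v, bins, rightmost.closed = TRUE),
                    nbins = length(mids))
    data.frame(set = nm, bin_mid = mids,
               density = if (length(v)) cnt / (length(v) * bw) else
                 rep(0, length(mids)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
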