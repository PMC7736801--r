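degenerate_fit_error <- function(msg) {
  stop(structure(class = c("dropseqr_degenerate_fit", "error", "condition"),
                 list(message = paste0(
                   msg, "; occupancy is indeterminate for this channel"),
                   call = sys.call(-1))))
}

## Weighted component densities on the log10-intensity scale.
mix_dens <- function(y, fit) {
  cbind(unoccupied = fit$weights[1] * dnorm(y, fit$location[1], fit$scale[1]),
        occupied   = fit$weights[2] * dnorm(y, fit$location[2], fit$scale[2]))
}

## Root(s) of the weighted-density difference between the two component
## locations; the root nearest the location midpoint wins (ties in the
## pathological multi-root case are warned about).
find_crossing <- function(weights, location, scale) {
  g <- function(y) weights[1] * dnorm(y, location[1], scale[1]) -
    weights[2] * dnorm(y, location[2], scale[2])
  grid <- seq(location[1], location[2], length.out = 512L)
  gv <- g(grid)
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  if (length(flips) == 0L) {
    exact <- which(gv == 0)
    if (length(exact)) return(grid[exact[1]])
    stop("no crossing point between the component locations")
  }
  roots <- vapply(flips, function(i)
    uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-12)$root, numeric(1))
  if (length(roots) > 1L) {
    warning("multiple density crossings between component locations; ",
            "using the root nearest their midpoint")
    roots <- roots[which.min(abs(roots - mean(location)))]
  }
  roots
}

overlap_rates <- function(weights, location, scale, crossing) {
  c(fp = pnorm(crossing, location[1], scale[1], lower.tail = FALSE),
    fn = pnorm(crossing, location[2], scale[2]))
}

#' Construct a two-component mixture fit from known parameters
#'
#' Builds the same object that [fit_mixture()] estimates, directly from
#' component parameters — useful for calling occupancy under a known
#' generating model and for closed-form calibration work.
#'
#' @param weights Length-2 numeric `(unoccupied, occupied)`, positive,
#'   summing to 1.
#' @param location,scale Length-2 numerics, `(unoccupied, occupied)`
#'   order, on the log10-intensity scale.
#' @param family Component family tag (only `"lognormal"` supported).
#'
#' @return An object of class `mixture_fit` with the crossing point and
#'   overlap false-positive/false-negative tail masses filled in.
#' @export
mixture_fit <- function(weights, location, scale, family = "lognormal") {
  stopifnot(length(weights) == 2, length(location) == 2, length(scale) == 2)
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be positive and sum to 1")
  if (any(scale <= 0)) stop("scales must be > 0")
  if (location[2] <= location[1])
    stop("occupied location must exceed unoccupied location")
  if (!identical(family, "lognormal"))
    stop("unsupported mixture family: ", family)
  crossing <- find_crossing(weights, location, scale)
  ov <- overlap_rates(weights, location, scale, crossing)
  structure(list(weights = as.numeric(weights),
                 location = as.numeric(location),
                 scale = as.numeric(scale),
                 family = family,
                 crossing_point = crossing,
                 crossing_intensity = 10^crossing,
                 fp_overlap = unname(ov["fp"]),
                 fn_overlap = unname(ov["fn"]),
                 loglik = NA_real_, loglik_trace = numeric(0),
                 n_iter = 0L, converged = TRUE, n_obs = 0L),
            class = "mixture_fit")
}

#' Fit a two-component heavy-tailed intensity mixture by EM
#'
#' Fits a two-component log-normal mixture (Gaussian on log10 intensity)
#' to droplet fluorescence intensities for one channel. The component
#' with the higher location is labelled "occupied". Initialization splits
#' the log-intensities at their 60th percentile, which is deterministic
#' and robust across the 3--40% occupancy range seen in practice.
#'
#' @param intensities Positive fluorescence intensities (>= 50 values).
#' @param family Component family tag; only `"lognormal"` is implemented.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence threshold on the relative log-likelihood change
#'   (default 1e-8).
#'
#' @return A `mixture_fit` with estimated weights, locations and scales,
#'   the density crossing point, overlap tail masses [estimate_error_rates()],
#'   the log-likelihood trace (non-decreasing under EM), iteration count
#'   and convergence flag. Non-convergence yields `converged = FALSE`, not
#'   an error; effectively single-population data raise a degenerate-fit
#'   error.
#' @export
fit_mixture <- function(intensities, family = "lognormal",
                        max_iter = 500L, tol = 1e-8) {
  if (!identical(family, "lognormal"))
    stop("unsupported mixture family: ", family)
  x <- as.numeric(intensities)
  if (length(x) < 50L) stop("need at least 50 observations")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be finite and positive")
  y <- log10(x)
  if (diff(range(y)) < .Machine$double.eps * 10)
    degenerate_fit_error("all observations are identical")

  split <- quantile(y, 0.6, names = FALSE)
  lo <- y[y <= split]; hi <- y[y > split]
  if (length(hi) < 2L) { hi <- sort(y)[(length(y) - 1L):length(y)]; }
  mu <- c(mean(lo), mean(hi))
  sigma <- pmax(c(sd(lo), sd(hi)), 1e-3)
  w <- c(length(lo), length(y) - length(lo)) / length(y)

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d0 <- w[1] * dnorm(y, mu[1], sigma[1])
    d1 <- w[2] * dnorm(y, mu[2], sigma[2])
    tot <- d0 + d1
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * (abs(loglik) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    loglik <- ll
    r1 <- d1 / tot
    n1 <- sum(r1); n0 <- length(y) - n1
    if (min(n0, n1) / length(y) < 1e-4)
      degenerate_fit_error("one mixture weight collapsed below 1e-4")
    mu <- c(sum((1 - r1) * y) / n0, sum(r1 * y) / n1)
    sigma <- sqrt(c(sum((1 - r1) * (y - mu[1])^2) / n0,
                    sum(r1 * (y - mu[2])^2) / n1))
    sigma <- pmax(sigma, 1e-6)
    w <- c(n0, n1) / length(y)
  }
  loglik <- trace[length(trace)]

  ord <- order(mu) # lower location = unoccupied
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]
  if (min(w) < 1e-4)
    degenerate_fit_error("one mixture weight collapsed below 1e-4")
  if (mu[2] - mu[1] < 1e-8)
    degenerate_fit_error("component locations coincide")

  crossing <- tryCatch(find_crossing(w, mu, sigma), error = function(e)
    degenerate_fit_error(
      "no density crossing between component locations (single population?)"))
  ov <- overlap_rates(w, mu, sigma, crossing)
  structure(list(weights = w, location = mu, scale = sigma,
                 family = family,
                 crossing_point = crossing,
                 crossing_intensity = 10^crossing,
                 fp_overlap = unname(ov["fp"]),
                 fn_overlap = unname(ov["fn"]),
                 loglik = loglik, loglik_trace = trace,
                 n_iter = iter, converged = converged,
                 n_obs = length(y)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Two-component %s mixture fit (n = %d)\n", x$family, x$n_obs))
  cat(sprintf("  unoccupied: w = %.4f, location = %.4f, scale = %.4f\n",
              x$weights[1], x$location[1], x$scale[1]))
  cat(sprintf("  occupied:   w = %.4f, location = %.4f, scale = %.4f\n",
              x$weights[2], x$location[2], x$scale[2]))
  cat(sprintf("  crossing: %.4f log10 units (intensity %.4g)\n",
              x$crossing_point, x$crossing_intensity))
  cat(sprintf("  overlap: FP %.3g (unoccupied mass above crossing), FN %.3g (occupied mass below)\n",
              x$fp_overlap, x$fn_overlap))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

check_fit_usable <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) stop("mixture fit did not converge")
  if (min(fit$weights) < 1e-4)
    degenerate_fit_error("fit is effectively single-population")
  invisible(fit)
}

#' Posterior probability of occupancy at given intensities
#'
#' @param intensity Positive intensities.
#' @param fit A converged `mixture_fit`.
#' @return Posterior probabilities in \[0, 1\].
#' @export
occupancy_posterior <- function(intensity, fit) {
  check_fit_usable(fit)
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("invalid record: intensities must be finite and positive")
  d <- mix_dens(log10(intensity), fit)
  tot <- d[, 1] + d[, 2]
  post <- ifelse(tot > 0, d[, 2] / tot,
                 # deep in a tail both densities underflow; fall back to
                 # the crossing-point threshold
                 as.numeric(log10(intensity) > fit$crossing_point))
  unname(post)
}

## Strict "posterior > 0.5" with a guard band of 1e-9 so that an
## intensity exactly at the density crossing always resolves to the
## unoccupied tie rule despite roundoff in the crossing root.
is_occupied <- function(posterior) posterior - 0.5 > 1e-9

#' Call per-droplet per-channel occupancy
#'
#' A droplet is called occupied in a channel when the weighted occupied
#' density exceeds the unoccupied one at its intensity, i.e. posterior
#' > 0.5; a tie at exactly 0.5 is called unoccupied (conservative against
#' insertions).
#'
#' @param records Droplet record data frame (`index`, intensity column
#'   per channel).
#' @param fits Named list of converged `mixture_fit`s, one per channel
#'   column of `records`.
#' @return Long data frame `index`, `channel`, `occupied`, `posterior`.
#' @export
call_occupancy <- function(records, fits) {
  stopifnot(is.data.frame(records), "index" %in% names(records))
  if (is.null(names(fits)) || !all(names(fits) %in% names(records)))
    stop("fits must be a named list matching intensity columns of records")
  out <- lapply(names(fits), function(ch) {
    post <- occupancy_posterior(records[[ch]], fits[[ch]])
    data.frame(index = records$index, channel = ch,
               occupied = is_occupied(post), posterior = post,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$index, calls$channel), ]
  rownames(calls) <- NULL
  calls
}

#' Overlap false-positive and false-negative rates of a fit
#'
#' The crossing point of the weighted component densities acts as the
#' effective call threshold; miscalls attributable to distribution
#' overlap are estimated as the unoccupied component's mass above the
#' crossing point (false positives, per droplet per colour) and the
#' occupied component's mass below it (false negatives, per base per
#' colour). Both are component tail masses, not mixture masses.
#'
#' @param fit A converged `mixture_fit`.
#' @return Named numeric `c(fp_overlap, fn_overlap)`.
#' @export
estimate_error_rates <- function(fit) {
  check_fit_usable(fit)
  ov <- overlap_rates(fit$weights, fit$location, fit$scale,
                      fit$crossing_point)
  c(fp_overlap = unname(ov["fp"]), fn_overlap = unname(ov["fn"]))
}

#' Estimate the stochastic false-positive rate from blank droplets
#'
#' Blank arrays (droplets never passed over the DNA) should contain no
#' dNTPs; their occupancy rate measures stochastic contamination per
#' droplet per colour.
#'
#' @param calls Occupancy calls ([call_occupancy()]) for droplets known
#'   to be blanks.
#' @param conf.level Confidence level of the per-colour Clopper-Pearson
#'   interval.
#' @return Data frame with one row per channel: `channel`, `n`,
#'   `n_occupied`, `rate`, `ci_lo`, `ci_hi`; the across-colour mean rate
#'   is attached as attribute `mean_rate`.
#' @export
estimate_stochastic_fp <- function(calls, conf.level = 0.95) {
  if (NROW(calls) == 0L) stop("no blank calls supplied")
  stopifnot(all(c("channel", "occupied") %in% names(calls)))
  per <- lapply(split(calls$occupied, calls$channel), function(occ) {
    bt <- binom.test(sum(occ), length(occ), conf.level = conf.level)
    c(n = length(occ), n_occupied = sum(occ), rate = mean(occ),
      ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2])
  })
  out <- data.frame(channel = names(per),
                    do.call(rbind, per), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "mean_rate") <- mean(out$rate)
  out
}
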