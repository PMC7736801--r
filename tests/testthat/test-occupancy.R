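test_that("EM recovers generating mixture parameters within 5%", {
  withr::with_seed(7, {
    n <- 1e5
    occ <- runif(n) < 0.3
    y <- ifelse(occ, rnorm(n, 3.2, 0.25), rnorm(n, 2.0, 0.15))
  })
  fit <- fit_mixture(10^y)
  expect_true(fit$converged)
  truth <- list(weights = c(0.7, 0.3), location = c(2.0, 3.2),
                scale = c(0.15, 0.25))
  for (p in names(truth))
    expect_lt(max(abs(fit[[p]] - truth[[p]]) / truth[[p]]), 0.05)
})

test_that("degenerate inputs raise a degenerate-fit error", {
  expect_error(fit_mixture(rep(100, 1000)), class = "dropseqr_degenerate_fit")
  # a single population collapses one weight
  withr::with_seed(1, x <- 10^rnorm(5000, 2, 0.1))
  expect_error(fit_mixture(x), class = "dropseqr_degenerate_fit")
  expect_error(fit_mixture(c(1, 2, 3)), "at least 50")
  expect_error(fit_mixture(c(rep(1, 100), -1)), "positive")
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  for (s in 1:3) {
    withr::with_seed(s, {
      occ <- runif(5000) < runif(1, 0.1, 0.5)
      y <- ifelse(occ, rnorm(5000, 3.2, 0.3), rnorm(5000, 2, 0.12))
    })
    fit <- fit_mixture(10^y)
    expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
  }
})

known_fit <- function() mixture_fit(c(0.7, 0.3), c(2.0, 3.2),
                                    c(0.08561896, 0.43621195))

test_that("occupancy calls threshold at the density crossing with ties unoccupied", {
  fit <- known_fit()
  rec <- data.frame(index = 0:3,
                    ch = c(10^2, 10^3.2, fit$crossing_intensity,
                           fit$crossing_intensity * 1.01))
  calls <- call_occupancy(rec, list(ch = fit))
  expect_identical(calls$occupied, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(calls$posterior[3], 0.5, tolerance = 1e-9)
  # posteriors of the two complementary events sum to one
  post <- calls$posterior
  d <- dropseqr:::mix_dens(log10(rec$ch), fit)
  expect_equal(post + d[, 1] / (d[, 1] + d[, 2]), rep(1, 4))
  expect_error(call_occupancy(data.frame(index = 0, ch = -1),
                              list(ch = fit)), "positive")
})

test_that("posterior is monotone in intensity above the unoccupied location", {
  fit <- known_fit()
  y <- seq(fit$location[1], fit$location[2] + 3, length.out = 400)
  post <- occupancy_posterior(10^y, fit)
  expect_true(all(diff(post) > -1e-12))
})

test_that("posterior probabilities are calibrated against simulation truth", {
  fit <- known_fit()
  withr::with_seed(21, {
    n <- 1e5
    occ <- runif(n) < 0.3
    y <- ifelse(occ, rnorm(n, fit$location[2], fit$scale[2]),
                rnorm(n, fit$location[1], fit$scale[1]))
  })
  post <- occupancy_posterior(10^y, fit)
  bins <- cut(post, seq(0, 1, 0.05), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    if (sum(idx) < 200) next
    p_hat <- mean(occ[idx])
    p_exp <- mean(post[idx])
    expect_lt(abs(p_hat - p_exp),
              3 * sqrt(p_exp * (1 - p_exp) / sum(idx)) + 1e-3)
  }
})

test_that("overlap tail masses match quadrature and the separation limit", {
  fit <- known_fit()
  rates <- estimate_error_rates(fit)
  up <- integrate(function(y) dnorm(y, fit$location[1], fit$scale[1]),
                  fit$crossing_point, Inf, rel.tol = 1e-12)$value
  lo <- integrate(function(y) dnorm(y, fit$location[2], fit$scale[2]),
                  -Inf, fit$crossing_point, rel.tol = 1e-12)$value
  expect_lt(abs(rates["fp_overlap"] - up), 1e-8)
  expect_lt(abs(rates["fn_overlap"] - lo), 1e-8)

  # arbitrary valid fits agree with quadrature too
  for (s in 1:5) {
    withr::with_seed(s, {
      lo <- runif(1, 1, 3)
      f <- mixture_fit(weights = {w <- runif(1, 0.2, 0.8); c(w, 1 - w)},
                       location = c(lo, lo + runif(1, 1, 1.8)),
                       scale = runif(2, 0.05, 0.4))
    })
    r <- estimate_error_rates(f)
    up <- integrate(function(y) dnorm(y, f$location[1], f$scale[1]),
                    f$crossing_point, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(r["fp_overlap"] - up), 1e-8)
  }

  # widely separated components have vanishing overlap
  far <- mixture_fit(c(0.7, 0.3), c(2, 4), c(0.1, 0.1))
  r <- estimate_error_rates(far)
  expect_lt(r["fp_overlap"], 1e-12)
  expect_lt(r["fn_overlap"], 1e-12)
})

test_that("crossing point lies strictly between the component locations", {
  for (s in 1:10) {
    withr::with_seed(s, {
      lo <- runif(1, 1, 3)
      f <- suppressWarnings(
        mixture_fit(weights = {w <- runif(1, 0.1, 0.9); c(w, 1 - w)},
                    location = c(lo, lo + runif(1, 0.8, 1.6)),
                    scale = runif(2, 0.05, 0.5)))
    })
    expect_gt(f$crossing_point, f$location[1])
    expect_lt(f$crossing_point, f$location[2])
  }
})

test_that("overlap estimates predict realized classification error", {
  fit <- known_fit()
  withr::with_seed(31, {
    n <- 1e5
    y0 <- rnorm(n, fit$location[1], fit$scale[1])
    y1 <- rnorm(n, fit$location[2], fit$scale[2])
  })
  fp_real <- mean(occupancy_posterior(10^y0, fit) > 0.5)
  fn_real <- mean(occupancy_posterior(10^y1, fit) <= 0.5)
  expect_lt(abs(fp_real - fit$fp_overlap),
            3 * sqrt(fit$fp_overlap * (1 - fit$fp_overlap) / n))
  expect_lt(abs(fn_real - fit$fn_overlap),
            3 * sqrt(fit$fn_overlap * (1 - fit$fn_overlap) / n))
})

test_that("stochastic false-positive estimation is exact on clean calls and covers the truth", {
  calls <- data.frame(index = rep(0:99, 2),
                      channel = rep(c("ch1", "ch2"), each = 100),
                      occupied = FALSE, posterior = 0)
  est <- estimate_stochastic_fp(calls)
  expect_equal(est$rate, c(0, 0))
  expect_error(estimate_stochastic_fp(calls[0, ]), "no blank calls")

  # 99% Clopper-Pearson interval covers the true rate in >= 97% of reps
  covered <- withr::with_seed(17, {
    vapply(1:200, function(i) {
      occ <- runif(2000) < 0.031
      e <- estimate_stochastic_fp(
        data.frame(index = seq_along(occ) - 1, channel = "ch1",
                   occupied = occ, posterior = as.numeric(occ)),
        conf.level = 0.99)
      e$ci_lo <= 0.031 && 0.031 <= e$ci_hi
    }, logical(1))
  })
  expect_gte(mean(covered), 0.97)
})
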