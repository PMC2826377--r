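# direct multivariate-normal log-density (oracle for likelihood tests)
dmvnorm_log <- function(y, mu, V) {
  L <- chol(V)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

test_that("IOU kernel: closed form, limits, symmetry, positive-definiteness", {
  expect_equal(iou_kernel(0, 2.7, 1, 1), 0)
  expect_equal(iou_kernel(1, 1, 1, 1), exp(-1))
  expect_equal(iou_kernel(0.7, 2.1, 3, 5), iou_kernel(2.1, 0.7, 3, 5))
  # alpha -> 0 with sigma2 = 2 alpha tau^2: random-slope covariance tau^2 s t
  tau <- 5; a <- 1e-4
  expect_equal(iou_kernel(2, 3, a, 2 * a * tau^2) / (tau^2 * 2 * 3), 1,
               tolerance = 1e-3)
  # alpha -> infinity with sigma2 / alpha^2 = kappa: Brownian kappa min(s,t)
  kap <- 1.7; a <- 1e6
  expect_equal(iou_kernel(2, 3, a, kap * a^2) / (kap * 2), 1, tolerance = 1e-4)
  expect_error(iou_kernel(1, 1, 0, 1), "alpha")
  expect_error(iou_kernel(-1, 1, 1, 1), "non-negative")

  # PSD on random grids
  set.seed(5)
  for (r in 1:5) {
    tg <- sort(runif(8, 0, 6))
    K <- iou_kernel(matrix(tg, 8, 8), matrix(tg, 8, 8, byrow = TRUE),
                    alpha = exp(runif(1, -2, 3)), sigma2 = exp(runif(1, 0, 4)))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(K)))
  }
})

test_that("IOU log-likelihood matches brute-force density oracles", {
  pars <- list(beta0 = 600, beta1 = -50, sd_b0 = 100, alpha = 2,
               sigma2 = 400, sd_eps = 30)
  # single point: univariate normal with variance sd_b0^2 + k(t,t) + sd_eps^2
  m1 <- data.frame(patient_id = "a", time = 1.3, cd4 = 480)
  v <- pars$sd_b0^2 + iou_kernel(1.3, 1.3, 2, 400) + pars$sd_eps^2
  expect_equal(loglik_iou(m1, pars),
               dnorm(480, 600 - 50 * 1.3, sqrt(v), log = TRUE))
  # three-point patient vs explicit covariance matrix
  tt <- c(0.5, 1.5, 3)
  m3 <- data.frame(patient_id = "a", time = tt, cd4 = c(560, 510, 380))
  V <- iou_kernel(matrix(tt, 3, 3), matrix(tt, 3, 3, byrow = TRUE), 2, 400) +
    pars$sd_b0^2 + diag(rep(pars$sd_eps^2, 3))
  expect_equal(loglik_iou(m3, pars),
               dmvnorm_log(c(560, 510, 380), 600 - 50 * tt, V))
  # two patients sum
  m2 <- rbind(m3, data.frame(patient_id = "b", time = 1.3, cd4 = 480))
  expect_equal(loglik_iou(m2, pars), loglik_iou(m3, pars) + loglik_iou(m1, pars))
})

test_that("alpha -> 0 recovers the random-slope model's likelihood", {
  m <- make_panel(25, c(0.5, 1, 2, 3), "linear", sd_b1 = 20, sd_eps = 40,
                  seed = 31)
  tau <- 20; a <- 1e-3
  ll_iou <- loglik_iou(m, list(beta0 = 620, beta1 = -60, sd_b0 = 150,
                               alpha = a, sigma2 = 2 * a * tau^2,
                               sd_eps = 40))
  # oracle: exact random-slope marginal covariance tau^2 s t
  tt <- c(0.5, 1, 2, 3)
  V <- 150^2 + tau^2 * outer(tt, tt) + diag(rep(40^2, 4))
  mu <- 620 - 60 * tt
  ll_rs <- sum(vapply(split(m$cd4, m$patient_id),
                      function(y) dmvnorm_log(y, mu, V), 1))
  expect_equal(ll_iou, ll_rs, tolerance = 0.5)
})

test_that("slope autocorrelation decays as exp(-alpha lag)", {
  expect_equal(slope_autocorrelation(3, 0), 1)
  expect_equal(slope_autocorrelation(36, 0.5), exp(-18))
  expect_lt(slope_autocorrelation(36, 0.5), 1e-6)  # "essentially zero"
  # empirical: velocity increments of exact draws decorrelate at the rate
  cfg <- simulation_config(n_patients = 2, seed = 1, trajectory = "iou",
                           alpha = 2, tau = 1, sd_b0 = 0)
  set.seed(41)
  h <- 0.05
  tg <- seq(h, 3, h)
  V <- matrix(0, 2000, length(tg))
  for (i in 1:2000) {
    W <- draw_trajectory_iou(tg, 0, cfg) - (cfg$beta0 + cfg$beta1 * tg)
    V[i, ] <- c(W[1] / h, diff(W) / h)  # crude velocity estimates
  }
  lag_steps <- 20  # 1 year
  emp <- cor(as.vector(V[, 1:(length(tg) - lag_steps)]),
             as.vector(V[, (lag_steps + 1):length(tg)]))
  expect_equal(emp, exp(-2 * 1), tolerance = 0.05)
})

test_that("ML fit recovers IOU parameters on an informative design", {
  # early visits at the velocity decorrelation scale 1/alpha identify alpha
  grid <- c(seq(0.05, 0.5, 0.05), seq(0.6, 2, 0.1))
  m <- make_panel(500, grid, "iou", alpha = 20, tau = 60,
                  sd_eps = 5, seed = 302)
  f <- fit_iou(m)
  expect_lt(abs(f$alpha - 20) / 20, 0.30)
  expect_lt(abs(f$beta1 - (-60)), 5)
  expect_equal(f$n_params, 6L)
  expect_true(is.finite(f$loglik))
})

test_that("profile CI: degenerate at level 0, unbounded under Brownian-like data", {
  m <- make_panel(150, seq(0.25, 3, 0.25), "iou", alpha = 50, tau = 60,
                  sd_eps = 10, seed = 33)
  f <- fit_iou(m)
  f0 <- profile_ci_alpha(f, m, level = 0)
  expect_equal(unname(f0$alpha_ci), c(f$alpha, f$alpha))
  f95 <- profile_ci_alpha(f, m, level = 0.95, upper_bound = 1e5)
  expect_gt(f95$alpha_ci["lower"], 1)    # nontrivial finite lower bound
  expect_true(is.infinite(f95$alpha_ci["upper"]))
  expect_true(f95$alpha_ci["lower"] < f$alpha)
})

test_that("AIC comparison prefers the generating model family", {
  # data from the linear random-slope family: IOU must not win by > chance
  wins_lmm <- 0
  for (s in 1:3) {
    m <- make_panel(100, seq(0.5, 4, 0.5), "linear", sd_b1 = 25, sd_eps = 60,
                    seed = 50 + s)
    lmm <- fit_lmm(m, reml = FALSE)
    iou <- fit_iou(m)
    cmp <- compare_models(lmm, iou)
    if (cmp$preferred == "lmm" || cmp$delta_aic < 2) wins_lmm <- wins_lmm + 1
  }
  expect_gte(wins_lmm, 2)
  # data from the IOU family with strong slope variation: IOU wins
  wins_iou <- 0
  for (s in 1:3) {
    m <- make_panel(150, seq(0.25, 3, 0.25), "iou", alpha = 20, tau = 60,
                    sd_eps = 20, seed = 60 + s)
    lmm <- fit_lmm(m, reml = FALSE)
    iou <- fit_iou(m)
    if (compare_models(lmm, iou)$preferred == "iou") wins_iou <- wins_iou + 1
  }
  expect_gte(wins_iou, 2)
})
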