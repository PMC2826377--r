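# Joint model for the CD4 trajectory and time to cART initiation.
#
# Longitudinal part: the random-intercept/random-slope linear model.
# Initiation part: piecewise-constant baseline hazard (4 pieces on quartiles
# of observed initiation times) multiplied by exp(association * (b0, b1)),
# optionally with a linear calendar-year covariate.  The shared random
# effects are marginalised by pseudo-adaptive Gauss-Hermite quadrature
# centred at each patient's longitudinal posterior mode.  The initiation
# hazard acts as the missing-data mechanism: low-CD4 patients start therapy
# (truncating their series) more often, which biases a naive mixed model;
# modelling initiation jointly corrects the slope estimates.

# Gauss-Hermite nodes/weights by Golub-Welsch, converted to probabilists'
# convention: sum(w) = 1, nodes for a standard normal.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = sqrt(2) * e$values[ord],
       weights = (e$vectors[1, ord])^2)
}

# per-patient longitudinal posterior mean/covariance of (b0, b1) given the
# variance components (used only to centre the quadrature)
joint_centering <- function(pdat, beta, D, sd_eps) {
  lapply(pdat, function(d) {
    Z <- cbind(1, d$t)
    r <- d$y - beta[1] - beta[2] * d$t
    Vinv_diag <- 1 / sd_eps^2
    A <- solve(solve(D) + crossprod(Z) * Vinv_diag)
    m <- drop(A %*% crossprod(Z, r) * Vinv_diag)
    L <- t(chol(A))
    list(mean = m, L = L, logdetL = sum(log(diag(L))))
  })
}

#' Fit the joint longitudinal / time-to-treatment-initiation model
#'
#' Maximum likelihood with the shared random effects `(b0, b1)` integrated
#' out by `quadrature_points^2` pseudo-adaptive Gauss-Hermite nodes.  A
#' doubling check guards against quadrature under-resolution: if the
#' log-likelihood at the optimum shifts by more than 0.1 when the number of
#' nodes per dimension is doubled, the model is refitted at the doubled
#' resolution (and an error is raised if the refit still fails the check).
#'
#' @param cohort a `cd4_cohort` (`era = "cart"`); patients without a cART
#'   date are treated as censored at their last visit.
#' @param quadrature_points nodes per random-effect dimension.
#' @param calendar include a linear calendar covariate (seroconversion year,
#'   centred) in the initiation hazard.
#' @param scale `"raw"` or `"sqrt"` CD4.
#' @param control optim control list.
#' @return class `cd4_joint_fit`: longitudinal fields as in [fit_lmm()],
#'   `association` (log-hazard of initiation per unit random intercept and
#'   per unit random slope), `lambda` (baseline hazard pieces), `breaks`,
#'   `calendar_coef`, `loglik`, and corrected `blups` (posterior means).
#' @export
fit_joint <- function(cohort, quadrature_points = 9, calendar = FALSE,
                      scale = c("raw", "sqrt"), control = list()) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort, "cd4_cohort"))
  meas <- pre_cart_measurements(cohort)
  p <- cohort$patients
  y <- if (scale == "sqrt") sqrt(meas$cd4) else meas$cd4

  sp <- split(data.frame(t = meas$time, y = y), meas$patient_id)
  ids <- names(sp)
  p <- p[match(ids, p$patient_id), , drop = FALSE]
  # time to initiation (from seroconversion) or censoring at last visit
  U <- ifelse(is.na(p$cart_date),
              vapply(sp, function(d) max(d$t), 1),
              years_between(p$seroconversion_date, p$cart_date))
  U <- pmax(U, 1e-3)
  delta <- !is.na(p$cart_date)
  cal <- as.numeric(format(p$seroconversion_date, "%Y"))
  cal <- cal - mean(cal)

  # baseline pieces on quartiles of observed initiation times
  obsU <- U[delta]
  if (length(obsU) < 4) stop("joint model needs at least 4 observed initiation times")
  breaks <- unique(c(0, unname(quantile(obsU, c(0.25, 0.5, 0.75))), Inf))
  K <- length(breaks) - 1
  exposure <- t(vapply(U, function(u) {
    pmax(pmin(u, breaks[-1]) - breaks[-length(breaks)], 0)
  }, numeric(K)))
  piece <- findInterval(U, breaks, rightmost.closed = TRUE)
  piece_ind <- matrix(0, length(U), K)
  piece_ind[cbind(seq_along(U), piece)] <- 1

  # initial values from the marginal (ML) LMM and a crude exponential rate
  lmm <- fit_lmm(meas, scale = scale, reml = FALSE)
  n_i <- vapply(sp, nrow, 1L)
  S_t <- vapply(sp, function(d) sum(d$t), 1)
  S_t2 <- vapply(sp, function(d) sum(d$t^2), 1)
  S_y <- vapply(sp, function(d) sum(d$y), 1)
  S_ty <- vapply(sp, function(d) sum(d$t * d$y), 1)
  npat <- length(sp)

  gh <- gauss_hermite(quadrature_points)
  grid <- expand.grid(z1 = gh$nodes, z2 = gh$nodes)
  logw <- as.vector(log(outer(gh$weights, gh$weights)))
  Q <- nrow(grid)
  logphi <- -0.5 * (grid$z1^2 + grid$z2^2) - log(2 * pi)

  # pseudo-adaptive centres (held fixed within each optimisation round,
  # re-centred at the fitted solution between rounds)
  node_matrices <- function(cen, grid, logw, logphi) {
    B0 <- B1 <- LOGJ <- matrix(0, npat, nrow(grid))
    for (i in seq_len(npat)) {
      b <- cen[[i]]$mean + cen[[i]]$L %*% rbind(grid$z1, grid$z2)
      B0[i, ] <- b[1, ]
      B1[i, ] <- b[2, ]
      LOGJ[i, ] <- cen[[i]]$logdetL + logw - logphi
    }
    list(B0 = B0, B1 = B1, LOGJ = LOGJ)
  }
  cen <- joint_centering(sp, c(lmm$beta0, lmm$beta1), re_cov(lmm),
                         max(lmm$sd_eps, 1e-3))
  nm <- node_matrices(cen, grid, logw, logphi)
  B0 <- nm$B0; B1 <- nm$B1; LOGJ <- nm$LOGJ

  yscale <- max(lmm$sd_eps, 1)
  # parameters: beta0, beta1, log sd_b0, log sd_b1, atanh corr, log sd_eps,
  # gamma0 (per 100-cell b0... internally scaled), gamma1 (per 10 units b1),
  # log lambda_1..K, [calendar]
  unpack <- function(th) {
    list(beta = th[1:2], sd_b0 = exp(th[3]), sd_b1 = exp(th[4]),
         corr = tanh(th[5]), sd_eps = exp(th[6]),
         g0 = th[7] / 100, g1 = th[8] / 10,
         loglam = th[9:(8 + K)],
         calcoef = if (calendar) th[9 + K] else 0)
  }
  negll <- function(th) {
    pr <- unpack(th)
    s0 <- pr$sd_b0; s1 <- pr$sd_b1; rho <- pr$corr; se <- pr$sd_eps
    det_fac <- s0^2 * s1^2 * (1 - rho^2)
    if (det_fac <= 0 || se <= 0) return(1e10)
    # longitudinal: sum_j (y - Xb - Zb)^2 expanded in per-patient sums
    r_s <- S_y - n_i * pr$beta[1] - pr$beta[2] * S_t
    rt_s <- S_ty - pr$beta[1] * S_t - pr$beta[2] * S_t2
    ss0 <- vapply(sp, function(d) sum((d$y - pr$beta[1] - pr$beta[2] * d$t)^2), 1)
    SS <- ss0 - 2 * B0 * r_s - 2 * B1 * rt_s +
      n_i * B0^2 + 2 * B0 * B1 * S_t + B1^2 * S_t2
    ll_long <- -SS / (2 * se^2) - n_i * (log(se) + 0.5 * log(2 * pi))
    # random-effect prior
    qf <- (B0^2 / s0^2 - 2 * rho * B0 * B1 / (s0 * s1) + B1^2 / s1^2) /
      (1 - rho^2)
    ll_prior <- -0.5 * qf - 0.5 * log((2 * pi)^2 * det_fac)
    # initiation hazard
    gb <- pr$g0 * B0 + pr$g1 * B1 + pr$calcoef * cal
    H0 <- drop(exposure %*% exp(pr$loglam))
    logh0 <- drop(piece_ind %*% pr$loglam)
    ll_surv <- delta * (logh0 + gb) - H0 * exp(gb)
    M <- ll_long + ll_prior + ll_surv + LOGJ
    mrow <- apply(M, 1, max)
    ll <- sum(mrow + log(rowSums(exp(M - mrow))))
    if (!is.finite(ll)) 1e10 else -ll
  }

  th0 <- c(lmm$beta0, lmm$beta1, log(max(lmm$sd_b0, 1)),
           log(max(lmm$sd_b1, 0.5)), atanh(max(min(lmm$corr_b0b1, 0.99), -0.99)),
           log(max(lmm$sd_eps, 1)), 0, 0,
           rep(log(max(sum(delta) / sum(U), 1e-3)), K),
           if (calendar) 0 else NULL)
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-9), control)
  op <- optim(th0, negll, method = "BFGS", control = ctrl)
  # adaptation round: re-centre the quadrature at the fitted longitudinal
  # solution, so the node grids cover the posterior mass implied by the
  # final (not the initial) parameters, then re-optimise
  for (round in 1:2) {
    pr <- unpack(op$par)
    Dhat <- matrix(c(pr$sd_b0^2, pr$corr * pr$sd_b0 * pr$sd_b1,
                     pr$corr * pr$sd_b0 * pr$sd_b1, pr$sd_b1^2), 2)
    cen <- joint_centering(sp, pr$beta, Dhat, max(pr$sd_eps, 1e-3))
    nm <- node_matrices(cen, grid, logw, logphi)
    B0 <- nm$B0; B1 <- nm$B1; LOGJ <- nm$LOGJ
    prev <- op$value
    op <- optim(op$par, negll, method = "BFGS", control = ctrl)
    if (abs(prev - op$value) < 0.05) break
  }

  make_fit <- function(op, gh_n) {
    pr <- unpack(op$par)
    # posterior-mean random effects at the MLE (corrected BLUPs)
    s0 <- pr$sd_b0; s1 <- pr$sd_b1; rho <- pr$corr; se <- pr$sd_eps
    r_s <- S_y - n_i * pr$beta[1] - pr$beta[2] * S_t
    rt_s <- S_ty - pr$beta[1] * S_t - pr$beta[2] * S_t2
    ss0 <- vapply(sp, function(d) sum((d$y - pr$beta[1] - pr$beta[2] * d$t)^2), 1)
    SS <- ss0 - 2 * B0 * r_s - 2 * B1 * rt_s +
      n_i * B0^2 + 2 * B0 * B1 * S_t + B1^2 * S_t2
    ll_long <- -SS / (2 * se^2) - n_i * (log(se) + 0.5 * log(2 * pi))
    qf <- (B0^2 / s0^2 - 2 * rho * B0 * B1 / (s0 * s1) + B1^2 / s1^2) /
      (1 - rho^2)
    ll_prior <- -0.5 * qf - 0.5 * log((2 * pi)^2 * s0^2 * s1^2 * (1 - rho^2))
    gb <- pr$g0 * B0 + pr$g1 * B1 + pr$calcoef * cal
    H0 <- drop(exposure %*% exp(pr$loglam))
    logh0 <- drop(piece_ind %*% pr$loglam)
    ll_surv <- delta * (logh0 + gb) - H0 * exp(gb)
    M <- ll_long + ll_prior + ll_surv + LOGJ
    mrow <- apply(M, 1, max)
    Wn <- exp(M - mrow)
    Wn <- Wn / rowSums(Wn)
    b0_hat <- rowSums(Wn * B0)
    b1_hat <- rowSums(Wn * B1)
    blups <- data.frame(patient_id = ids, b0 = b0_hat, b1 = b1_hat,
                        slope = pr$beta[2] + b1_hat, stringsAsFactors = FALSE)
    structure(list(beta0 = pr$beta[1], beta1 = pr$beta[2],
                   sd_b0 = pr$sd_b0, sd_b1 = pr$sd_b1,
                   corr_b0b1 = pr$corr, sd_eps = pr$sd_eps,
                   association = c(per_b0 = pr$g0, per_b1 = pr$g1),
                   lambda = exp(pr$loglam), breaks = breaks,
                   calendar_coef = if (calendar) pr$calcoef else NA_real_,
                   loglik = -op$value, n_params = length(op$par),
                   quadrature_points = gh_n,
                   blups = blups, scale = scale,
                   convergence = op$convergence),
              class = "cd4_joint_fit")
  }

  # doubling check on quadrature resolution
  rebuild <- function(gh_n) {
    gh2 <- gauss_hermite(gh_n)
    grid2 <- expand.grid(z1 = gh2$nodes, z2 = gh2$nodes)
    logw2 <- as.vector(log(outer(gh2$weights, gh2$weights)))
    logphi2 <- -0.5 * (grid2$z1^2 + grid2$z2^2) - log(2 * pi)
    B0_2 <- B1_2 <- LOGJ_2 <- matrix(0, npat, nrow(grid2))
    for (i in seq_len(npat)) {
      b <- cen[[i]]$mean + cen[[i]]$L %*% rbind(grid2$z1, grid2$z2)
      B0_2[i, ] <- b[1, ]; B1_2[i, ] <- b[2, ]
      LOGJ_2[i, ] <- cen[[i]]$logdetL + logw2 - logphi2
    }
    list(B0 = B0_2, B1 = B1_2, LOGJ = LOGJ_2)
  }
  env <- environment()
  ll_at <- function(th, nodes) {
    old <- list(B0 = B0, B1 = B1, LOGJ = LOGJ)
    nb <- rebuild(nodes)
    assign("B0", nb$B0, envir = env); assign("B1", nb$B1, envir = env)
    assign("LOGJ", nb$LOGJ, envir = env)
    out <- -negll(th)
    assign("B0", old$B0, envir = env); assign("B1", old$B1, envir = env)
    assign("LOGJ", old$LOGJ, envir = env)
    out
  }
  shift <- abs(ll_at(op$par, 2 * quadrature_points) - (-op$value))
  if (shift > 0.1) {
    nb <- rebuild(2 * quadrature_points)
    B0 <- nb$B0; B1 <- nb$B1; LOGJ <- nb$LOGJ
    op <- optim(op$par, negll, method = "BFGS", control = ctrl)
    shift2 <- abs(ll_at(op$par, 4 * quadrature_points) - (-op$value))
    if (shift2 > 0.1) {
      stop("joint-model quadrature under-resolved even after doubling ",
           "(loglik shift ", signif(shift2, 3), ")")
    }
    return(make_fit(op, 2 * quadrature_points))
  }
  make_fit(op, quadrature_points)
}

# random-effect covariance matrix of an LMM fit
re_cov <- function(lmm) {
  s0 <- max(lmm$sd_b0, 1e-3); s1 <- max(lmm$sd_b1, 1e-3)
  rho <- lmm$corr_b0b1
  matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2, 2)
}

#' @export
print.cd4_joint_fit <- function(x, ...) {
  cat(sprintf(paste0("joint CD4 / time-to-cART model (%s scale, %d^2 ",
                     "quadrature nodes)\n  beta0 = %.2f, beta1 = %.2f; ",
                     "sd_b0 = %.2f, sd_b1 = %.2f, corr = %.2f, sd_eps = %.2f\n",
                     "  initiation log-HR: %.4f per unit b0, %.4f per unit b1\n",
                     "  loglik = %.2f\n"),
              x$scale, x$quadrature_points, x$beta0, x$beta1, x$sd_b0,
              x$sd_b1, x$corr_b0b1, x$sd_eps,
              x$association["per_b0"], x$association["per_b1"], x$loglik))
  invisible(x)
}
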