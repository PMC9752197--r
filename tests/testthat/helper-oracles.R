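# Independent numerical oracles and small fixture builders used across the
# test files. The oracles deliberately avoid the package's closed-form code
# paths: kinetics are checked against brute-force ODE integration (deSolve)
# and the Laplace objective against closed-form / quadrature marginals.

example_params <- function(...) {
  args <- list(CL = 15, V1 = 40, Q2 = 8, V2 = 60, Q3 = 2.5, V3 = 220,
               ka_fed = 0.7, ka_fasted = 1.5, ktr = 2, n_transit = 3L,
               F = 0.8)
  args[names(list(...))] <- list(...)
  do.call(structural_params, args)
}

random_params <- function() {
  structural_params(
    CL = runif(1, 2, 40), V1 = runif(1, 10, 80), Q2 = runif(1, 1, 30),
    V2 = runif(1, 20, 150), Q3 = runif(1, 0.5, 10), V3 = runif(1, 50, 400),
    ka_fed = runif(1, 0.2, 2), ka_fasted = runif(1, 0.5, 3),
    ktr = runif(1, 0.5, 4), n_transit = sample(0:4, 1),
    F = runif(1, 0.3, 1))
}

# brute-force adaptive-step ODE solution of the full linear system
# (transit chain + depot + 3-cmt disposition), one dose at a time
ode_one_dose <- function(p, route, amount, duration, fed, u_times) {
  n <- p$n_transit
  k10 <- p$CL / p$V1; k12 <- p$Q2 / p$V1; k21 <- p$Q2 / p$V2
  k13 <- p$Q3 / p$V1; k31 <- p$Q3 / p$V3
  ka <- if (isTRUE(fed)) p$ka_fed else p$ka_fasted
  if (route == "IV") {
    rhs <- function(t, y, parms) {
      inp <- if (duration > 0 && t < duration) amount / duration else 0
      list(c(inp - (k10 + k12 + k13) * y[1] + k21 * y[2] + k31 * y[3],
             k12 * y[1] - k21 * y[2],
             k13 * y[1] - k31 * y[3]))
    }
    y0 <- c(if (duration == 0) amount else 0, 0, 0)
    tt <- sort(unique(c(0, duration, u_times)))
    out <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-11, atol = 1e-13)
    out[match(u_times, tt), 2] / p$V1
  } else {
    nst <- n + 4L
    rhs <- function(t, y, parms) {
      dy <- numeric(nst)
      if (n > 0) {
        dy[1] <- -p$ktr * y[1]
        if (n > 1) for (j in 2:n) dy[j] <- p$ktr * (y[j - 1] - y[j])
        dy[n + 1] <- p$ktr * y[n] - ka * y[n + 1]
      } else {
        dy[1] <- -ka * y[1]
      }
      cen <- n + 2L
      dy[cen] <- ka * y[n + 1] - (k10 + k12 + k13) * y[cen] +
        k21 * y[cen + 1] + k31 * y[cen + 2]
      dy[cen + 1] <- k12 * y[cen] - k21 * y[cen + 1]
      dy[cen + 2] <- k13 * y[cen] - k31 * y[cen + 2]
      list(dy)
    }
    y0 <- numeric(nst)
    y0[1] <- p$F * amount
    tt <- sort(unique(c(0, u_times)))
    out <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-11, atol = 1e-13)
    out[match(u_times, tt), n + 3L] / p$V1
  }
}

ode_profile <- function(p, doses, times) {
  conc <- numeric(length(times))
  for (r in seq_len(nrow(doses))) {
    idx <- which(times > doses$time[r])
    if (!length(idx)) next
    u <- times[idx] - doses$time[r]
    conc[idx] <- conc[idx] +
      ode_one_dose(p, doses$route[r], doses$amount[r], doses$duration[r],
                   doses$fed[r], u)
  }
  conc
}

# exact -2 log marginal likelihood of the linearized mixed model
# y ~ N(c(0), sigma^2 I + J Omega J'), J = dc/deta at eta = 0
linearized_mvn_ofv <- function(pop, data) {
  prep <- ebopk:::.prep_subjects(data)
  omega_act <- pop$omega[pop$omega > 0]
  ofv <- 0
  for (s in prep) {
    c0 <- ebopk:::.subject_conc(pop, s, NULL)
    q <- length(omega_act)
    J <- matrix(0, length(c0), q)
    h <- 1e-6
    for (k in seq_len(q)) {
      eta <- stats::setNames(numeric(q), names(omega_act))
      eta[k] <- h
      J[, k] <- (ebopk:::.subject_conc(pop, s, eta) - c0) / h
    }
    V <- J %*% (omega_act * t(J)) +
      diag(pop$sigma_add^2 + (pop$sigma_prop * c0)^2, length(c0))
    r <- s$dv - c0
    ofv <- ofv + as.numeric(t(r) %*% solve(V, r)) +
      determinant(V, logarithm = TRUE)$modulus[1] +
      length(c0) * log(2 * pi)
  }
  ofv
}

# high-accuracy 1-D quadrature of the true marginal likelihood for a model
# with a single active random effect
quadrature_ofv <- function(pop, data) {
  prep <- ebopk:::.prep_subjects(data)
  omega_act <- pop$omega[pop$omega > 0]
  stopifnot(length(omega_act) == 1)
  w <- sqrt(omega_act)
  ofv <- 0
  for (s in prep) {
    f <- function(eta_vec) {
      vapply(eta_vec, function(e) {
        eta <- stats::setNames(e, names(omega_act))
        conc <- ebopk:::.subject_conc(pop, s, eta)
        s2 <- (pop$sigma_prop * conc)^2 + pop$sigma_add^2
        exp(sum(stats::dnorm(s$dv, conc, sqrt(s2), log = TRUE)) +
              stats::dnorm(e, 0, w, log = TRUE))
      }, 0)
    }
    lik <- stats::integrate(f, -8 * w, 8 * w, rel.tol = 1e-10)$value
    ofv <- ofv - 2 * log(lik)
  }
  ofv
}

# small rich-design roster used by the fitting tests
small_roster <- function(n_iv = 6, n_po = 6, n_samp = 12) {
  rich <- c(0.5, 1, 1.5, 2, 4, 6, 8, 12, 16, 24, 36, 48)[seq_len(n_samp)]
  studies <- list()
  if (n_iv > 0)
    studies <- c(studies, list(
      study_design("T-IV", "1", "IV", n_iv, dose_times = 0, dose_amt = 500,
                   duration = 1, sampling_times = rich)))
  if (n_po > 0)
    studies <- c(studies, list(
      study_design("T-PO", "1", "PO", n_po, dose_times = 0, dose_amt = 500,
                   fed = FALSE, sampling_times = rich)))
  program_roster(studies)
}
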