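## Nonlinear mixed-effects estimation by the Laplace approximation.
##
## The marginal likelihood of each subject's data is approximated by a
## second-order expansion of the joint log-density about the subject's
## conditional mode (empirical Bayes estimate). The expansion Hessian is the
## Gauss-Newton form J' W J + Omega^-1 (exact for additive-error linear
## models, FOCE-with-interaction-like behaviour for the proportional
## component). Residual variance depends on the individual prediction,
## i.e. the interaction term is carried.

.default_fit_control <- function(control = list()) {
  ctl <- list(inner_tol = 1e-8, inner_maxit = 40L, fd_step = 1e-6,
              iter.max = 150L, eval.max = 800L, rel.tol = 1e-8,
              se = FALSE, trace = 0L)
  ctl[names(control)] <- control
  ctl
}

## IV and unit-bioavailability PO concentration contributions at the
## observation times of one prepared subject. conc = civ + F_i * cpo.
.conc_parts <- function(pop, s, eta) {
  # inlined individual_params (hot path: called by every inner iteration)
  th <- pop$theta
  fcl <- (s$wt / pop$ref_wt)^pop$allo_exp_cl
  fv <- (s$wt / pop$ref_wt)^pop$allo_exp_v
  pars <- list(CL = th$CL * fcl, V1 = th$V1 * fv, Q2 = th$Q2 * fcl,
               V2 = th$V2 * fv, Q3 = th$Q3 * fcl, V3 = th$V3 * fv,
               ka_fed = th$ka_fed, ka_fasted = th$ka_fasted, ktr = th$ktr,
               n_transit = pop$n_transit, F = th$F)
  if (length(eta))
    for (nm in names(eta)) pars[[nm]] <- pars[[nm]] * exp(eta[[nm]])
  eg <- .disp_eigen(pars)
  nt <- length(s$obs_time)
  civ <- numeric(nt)
  cpo <- numeric(nt)
  d <- s$doses
  Fi <- pars$F
  pars$F <- 1
  for (r in seq_len(nrow(d))) {
    idx <- which(s$obs_time > d$time[r])
    if (!length(idx)) next
    u <- s$obs_time[idx] - d$time[r]
    if (d$route[r] == "IV") {
      civ[idx] <- civ[idx] +
        .dose_conc(pars, eg, "IV", d$amount[r], d$duration[r], NA, u)
    } else {
      cpo[idx] <- cpo[idx] +
        .dose_conc(pars, eg, "PO", d$amount[r], 0, d$fed[r], u)
    }
  }
  list(civ = civ, cpo = cpo, F = Fi)
}

.subject_conc <- function(pop, s, eta) {
  parts <- .conc_parts(pop, s, eta)
  pmax(parts$civ + parts$F * parts$cpo, 0)
}

## joint -log density (data + prior) of one subject at eta
.joint_m <- function(pop, s, eta, omega_act) {
  parts <- .conc_parts(pop, s, eta)
  conc <- pmax(parts$civ + parts$F * parts$cpo, 0)
  if (any(!is.finite(conc)))
    return(list(m = 1e10, conc = conc, parts = parts, ok = FALSE))
  s2 <- pmax((pop$sigma_prop * conc)^2 + pop$sigma_add^2, 1e-20)
  r <- s$dv - conc
  m <- 0.5 * sum(r^2 / s2 + log(2 * pi * s2))
  if (length(eta))
    m <- m + 0.5 * sum(eta^2 / omega_act) +
      0.5 * sum(log(2 * pi * omega_act))
  list(m = m, conc = conc, s2 = s2, r = r, parts = parts, ok = TRUE)
}

## Conditional-mode (empirical Bayes) Newton search for one subject,
## returning the mode, the Gauss-Newton Hessian there, and the subject's
## -2 log marginal-likelihood contribution.
.inner_laplace <- function(pop, s, eta0, omega_act, ctl) {
  act <- names(omega_act)
  q <- length(act)
  eta <- stats::setNames(as.numeric(eta0), act)
  f <- .joint_m(pop, s, eta, omega_act)
  Oinv <- diag(x = 1 / omega_act, nrow = q)
  H <- Oinv
  nobs <- length(s$dv)
  for (it in seq_len(ctl$inner_maxit)) {
    if (!f$ok) break
    J <- matrix(0, nobs, q)
    conc0 <- f$parts$civ + f$parts$F * f$parts$cpo
    for (k in seq_len(q)) {
      if (act[k] == "F") {
        J[, k] <- f$parts$F * f$parts$cpo
      } else {
        h <- ctl$fd_step
        ep <- eta; ep[k] <- ep[k] + h
        pp <- .conc_parts(pop, s, ep)
        J[, k] <- ((pp$civ + pp$F * pp$cpo) - conc0) / h
      }
    }
    dmdc <- -f$r / f$s2 +
      pop$sigma_prop^2 * f$conc * (1 / f$s2 - f$r^2 / f$s2^2)
    g <- as.vector(crossprod(J, dmdc)) + eta / omega_act
    H <- crossprod(J / sqrt(f$s2)) + Oinv
    if (max(abs(g)) < ctl$inner_tol) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    improved <- FALSE
    for (ls in 1:12) {
      etan <- eta - alpha * step
      fn <- .joint_m(pop, s, etan, omega_act)
      if (fn$ok && fn$m <= f$m - 1e-13) {
        eta <- etan; f <- fn; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  ldetH <- determinant(H, logarithm = TRUE)$modulus[1L]
  list(eta = eta, ofv_i = 2 * f$m - q * log(2 * pi) + ldetH,
       ipred = f$conc, H = H, ok = f$ok)
}

#' Laplace objective function value of a population model on a dataset
#'
#' Minus twice the approximate marginal log-likelihood (OFV), summing each
#' subject's Laplace-approximated contribution about its conditional mode.
#' Deterministic given the data and model (inner Newton iterations to a
#' gradient tolerance of 1e-8). Effects with a zero omega variance are
#' treated as absent.
#'
#' @param pop a \code{\link{population_model}}
#' @param data a \code{pk_dataset}
#' @param control list overriding inner optimizer settings (\code{inner_tol},
#'   \code{inner_maxit}, \code{fd_step})
#' @return the OFV, with per-subject empirical Bayes eta estimates attached
#'   as attribute \code{"etas"} and a diagnostic attribute \code{"flagged"}
#'   that is TRUE when any subject hit the non-finite-prediction penalty
#' @export
conditional_objective <- function(pop, data, control = list()) {
  ctl <- .default_fit_control(control)
  prep <- .prep_subjects(data)
  res <- .ofv_prepped(pop, prep, ctl, warm = NULL)
  structure(res$ofv, etas = res$etas, flagged = res$flagged)
}

.ofv_prepped <- function(pop, prep, ctl, warm = NULL) {
  omega_act <- pop$omega[pop$omega > 0]
  q <- length(omega_act)
  etas <- matrix(0, length(prep), q,
                 dimnames = list(vapply(prep, function(s) as.character(s$id),
                                        ""), names(omega_act)))
  ofv <- 0
  flagged <- FALSE
  for (i in seq_along(prep)) {
    s <- prep[[i]]
    if (!length(s$dv)) next
    if (q == 0L) {
      f <- .joint_m(pop, s, numeric(0), numeric(0))
      ofv <- ofv + 2 * f$m
      flagged <- flagged || !f$ok
      next
    }
    eta0 <- if (!is.null(warm) && !is.null(warm$etas) &&
                nrow(warm$etas) == length(prep)) warm$etas[i, ] else
                  stats::setNames(numeric(q), names(omega_act))
    r <- .inner_laplace(pop, s, eta0, omega_act, ctl)
    etas[i, ] <- r$eta
    ofv <- ofv + r$ofv_i
    flagged <- flagged || !r$ok
  }
  if (!is.null(warm)) warm$etas <- etas
  list(ofv = ofv, etas = etas, flagged = flagged)
}

## ---- outer parameter transforms ------------------------------------------

.par_names <- function(pop) {
  c(names(pop$theta), paste0("omega_", names(pop$omega)),
    "sigma_prop", "sigma_add")
}

.pack_pop <- function(pop, free) {
  v <- c(unlist(pop$theta), pop$omega, pop$sigma_prop, pop$sigma_add)
  names(v) <- .par_names(pop)
  log(v[free])
}

.unpack_pop <- function(pop, x, free) {
  v <- exp(x)
  names(v) <- free
  th <- pop$theta
  om <- pop$omega
  sp <- pop$sigma_prop
  sa <- pop$sigma_add
  for (nm in free) {
    if (nm %in% names(th)) th[[nm]] <- v[[nm]]
    else if (startsWith(nm, "omega_")) om[[sub("^omega_", "", nm)]] <- v[[nm]]
    else if (nm == "sigma_prop") sp <- v[[nm]]
    else if (nm == "sigma_add") sa <- v[[nm]]
  }
  population_model(theta = th, omega = om, sigma_prop = sp, sigma_add = sa,
                   allo_exp_cl = pop$allo_exp_cl, allo_exp_v = pop$allo_exp_v,
                   ref_wt = pop$ref_wt, n_transit = pop$n_transit)
}

#' Fit the population model to a PK dataset
#'
#' Maximizes the Laplace-approximate marginal likelihood over the free
#' population parameters. All positive parameters (typical values, omega
#' variances, residual SDs) are optimized on the log scale, which enforces
#' the model invariants by construction. Parameters named in \code{fixed}
#' are held at their \code{init} values. Parameters that the data cannot
#' inform (oral parameters with an IV-only dataset, an absorption rate with
#' no dose in that food state) are detected and fixed with a warning.
#'
#' @param data a \code{pk_dataset} with at least one observation
#' @param init a \code{\link{population_model}} of starting values
#' @param fixed character vector of parameter names to hold fixed, from
#'   \code{CL, V1, Q2, V2, Q3, V3, ka_fed, ka_fasted, ktr, F, omega_<effect>,
#'   sigma_prop, sigma_add}; \code{"all"} fixes everything (evaluation-only)
#' @param control optimizer control list; notable entries \code{iter.max},
#'   \code{eval.max}, \code{se} (finite-difference standard errors, default
#'   off), plus the inner-optimizer settings of
#'   \code{\link{conditional_objective}}
#' @return an object of class \code{poppk_fit}: the estimated model
#'   (\code{$pop}), \code{$ofv}, empirical Bayes \code{$etas}, shrinkage
#'   estimates, convergence information
#' @export
fit_poppk <- function(data, init, fixed = character(), control = list()) {
  ctl <- .default_fit_control(control)
  prep <- .prep_subjects(data)
  if (!length(prep) || all(vapply(prep, function(s) length(s$dv), 0L) == 0L))
    stop("dataset contains no usable observations")
  all_names <- .par_names(init)
  if (identical(fixed, "all")) fixed <- all_names
  bad <- setdiff(fixed, all_names)
  if (length(bad))
    stop("unknown parameter name(s) in fixed: ", paste(bad, collapse = ", "))

  routes <- unlist(lapply(prep, function(s) s$doses$route))
  feds <- unlist(lapply(prep, function(s) s$doses$fed))
  po_any <- any(routes == "PO")
  auto_fix <- character()
  if (!po_any)
    auto_fix <- intersect(c("F", "ka_fed", "ka_fasted", "ktr", "omega_F"),
                          all_names)
  else {
    if (!any(feds %in% TRUE)) auto_fix <- c(auto_fix, "ka_fed")
    if (!any(feds %in% FALSE)) auto_fix <- c(auto_fix, "ka_fasted")
  }
  v0 <- c(unlist(init$theta), init$omega, init$sigma_prop, init$sigma_add)
  names(v0) <- all_names
  auto_fix <- c(auto_fix, all_names[v0 == 0])  # log scale cannot leave zero
  auto_fix <- setdiff(unique(auto_fix), fixed)
  if (length(auto_fix)) {
    warning("not identifiable from the dosing design, holding fixed: ",
            paste(auto_fix, collapse = ", "), call. = FALSE)
    fixed <- c(fixed, auto_fix)
  }
  free <- setdiff(all_names, fixed)

  warm <- new.env(parent = emptyenv())
  ofv_init <- .ofv_prepped(init, prep, ctl, warm)$ofv

  if (!length(free)) {
    fit <- structure(list(pop = init, ofv = ofv_init, ofv_init = ofv_init,
                          etas = NULL, shrinkage_eta = NULL,
                          shrinkage_eps = NULL, se = NULL,
                          convergence = 0L, message = "all parameters fixed",
                          iterations = 0L, evaluations = 1L,
                          fixed = fixed, free = free, init = init),
                     class = "poppk_fit")
    return(ebe_and_shrinkage(fit, data))
  }

  x0 <- .pack_pop(init, free)
  obj <- function(x) {
    pop <- tryCatch(.unpack_pop(init, x, free), error = function(e) NULL)
    if (is.null(pop)) return(1e10)
    .ofv_prepped(pop, prep, ctl, warm)$ofv
  }
  opt <- stats::nlminb(x0, obj,
                       control = list(iter.max = ctl$iter.max,
                                      eval.max = ctl$eval.max,
                                      rel.tol = ctl$rel.tol,
                                      trace = ctl$trace))
  # never report a point worse than the start
  if (opt$objective <= ofv_init) {
    pop_hat <- .unpack_pop(init, opt$par, free)
    ofv_hat <- opt$objective
  } else {
    pop_hat <- init
    ofv_hat <- ofv_init
  }
  se <- NULL
  if (isTRUE(ctl$se)) se <- .fit_se(obj, .pack_pop(pop_hat, free), pop_hat)
  fit <- structure(list(pop = pop_hat, ofv = ofv_hat, ofv_init = ofv_init,
                        etas = NULL, shrinkage_eta = NULL,
                        shrinkage_eps = NULL, se = se,
                        convergence = opt$convergence,
                        message = opt$message,
                        iterations = opt$iterations,
                        evaluations = opt$evaluations[["function"]],
                        fixed = fixed, free = free, init = init),
                   class = "poppk_fit")
  ebe_and_shrinkage(fit, data)
}

## finite-difference asymptotic standard errors on the natural scale
.fit_se <- function(obj, xhat, pop_hat) {
  p <- length(xhat)
  h <- 1e-3
  H <- matrix(0, p, p)
  f0 <- obj(xhat)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    xi <- xhat; xi[i] <- xi[i] + h; fp[i] <- obj(xi)
    xi <- xhat; xi[i] <- xi[i] - h; fm[i] <- obj(xi)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h^2
  }
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    xi <- xhat; xi[c(i, j)] <- xi[c(i, j)] + h; fpp <- obj(xi)
    xi <- xhat; xi[c(i, j)] <- xi[c(i, j)] - h; fmm <- obj(xi)
    H[i, j] <- H[j, i] <-
      (fpp + fmm - fp[i] - fm[i] - fp[j] - fm[j] + 2 * f0) / (2 * h^2)
  }
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se_log <- sqrt(pmax(diag(cov), 0))
  est <- exp(xhat)
  stats::setNames(est * se_log, names(xhat))  # delta method, log scale
}

#' Empirical Bayes estimates and shrinkage diagnostics
#'
#' Recomputes each subject's conditional-mode random effects under the
#' (fitted) model, and reports eta-shrinkage per effect,
#' \code{100 * (1 - SD(eta_hat) / omega)}, and epsilon-shrinkage,
#' \code{100 * (1 - SD(IWRES))}. High shrinkage means individual data are
#' too sparse to separate that subject from the typical profile, so EBE-based
#' diagnostics lose information.
#'
#' @param fit a \code{poppk_fit}, or a \code{\link{population_model}} to
#'   evaluate EBEs under a fixed model without fitting
#' @param data a \code{pk_dataset}
#' @return the updated \code{poppk_fit} (or, given a population model, a list
#'   with \code{etas}, \code{shrinkage_eta}, \code{shrinkage_eps},
#'   \code{ipred})
#' @export
ebe_and_shrinkage <- function(fit, data) {
  pop <- if (inherits(fit, "poppk_fit")) fit$pop else fit
  ctl <- .default_fit_control()
  prep <- .prep_subjects(data)
  omega_act <- pop$omega[pop$omega > 0]
  if (any(pop$omega == 0))
    warning("omega is zero for ",
            paste(names(pop$omega)[pop$omega == 0], collapse = ", "),
            "; eta-shrinkage undefined for these effects", call. = FALSE)
  q <- length(omega_act)
  ids <- vapply(prep, function(s) as.character(s$id), "")
  etas <- matrix(0, length(prep), q, dimnames = list(ids, names(omega_act)))
  iwres <- numeric(0)
  ipred_all <- rep(NA_real_, nrow(data))
  for (i in seq_along(prep)) {
    s <- prep[[i]]
    if (!length(s$dv)) next
    if (q > 0L) {
      r <- .inner_laplace(pop, s, stats::setNames(numeric(q),
                                                  names(omega_act)),
                          omega_act, ctl)
      etas[i, ] <- r$eta
      ipred <- r$ipred
    } else {
      ipred <- .subject_conc(pop, s, NULL)
    }
    ipred_all[s$obs_rows] <- ipred
    iwres <- c(iwres, (s$dv - ipred) / .res_sd(ipred, pop))
  }
  shr_eta <- stats::setNames(rep(NA_real_, length(pop$omega)),
                             names(pop$omega))
  for (nm in names(omega_act))
    shr_eta[nm] <- 100 * (1 - stats::sd(etas[, nm]) / sqrt(omega_act[[nm]]))
  shr_eps <- 100 * (1 - stats::sd(iwres))
  if (inherits(fit, "poppk_fit")) {
    fit$etas <- etas
    fit$shrinkage_eta <- shr_eta
    fit$shrinkage_eps <- shr_eps
    fit$ipred <- ipred_all
    fit
  } else {
    list(etas = etas, shrinkage_eta = shr_eta, shrinkage_eps = shr_eps,
         ipred = ipred_all)
  }
}

#' @export
print.poppk_fit <- function(x, ...) {
  cat("Population PK fit (Laplace approximation)\n")
  cat(sprintf("OFV: %.4f (initial %.4f), convergence code %d\n",
              x$ofv, x$ofv_init, x$convergence))
  cat(sprintf("Free parameters: %s\n",
              if (length(x$free)) paste(x$free, collapse = ", ") else "none"))
  print(fit_parameter_table(x))
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' @param fit a \code{poppk_fit}
#' @return data.frame with one row per parameter: estimate, scale
#'   (omega rows also on the CV\% scale), fixed flag, shrinkage for etas
#' @export
fit_parameter_table <- function(fit) {
  pop <- fit$pop
  nm <- .par_names(pop)
  est <- c(unlist(pop$theta), pop$omega, pop$sigma_prop, pop$sigma_add)
  tab <- data.frame(parameter = nm, estimate = as.numeric(est),
                    fixed = nm %in% fit$fixed)
  tab$cv_percent <- NA_real_
  om_rows <- startsWith(nm, "omega_")
  tab$cv_percent[om_rows] <- iiv_cv_percent(est[om_rows])
  tab$shrinkage_percent <- NA_real_
  if (!is.null(fit$shrinkage_eta)) {
    for (k in names(fit$shrinkage_eta))
      tab$shrinkage_percent[tab$parameter == paste0("omega_", k)] <-
        fit$shrinkage_eta[[k]]
  }
  if (!is.null(fit$se)) {
    tab$se <- NA_real_
    tab$se[match(names(fit$se), tab$parameter)] <- fit$se
  }
  tab
}

#' Write a plain-text fit report and a machine-readable JSON result
#'
#' @param fit a \code{poppk_fit}
#' @param path output path of the text report; a JSON file with the same
#'   content is written alongside as \code{<path>.json}
#' @return invisibly, the report path
#' @export
write_fit_report <- function(fit, path) {
  tab <- fit_parameter_table(fit)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Population PK fit report",
               sprintf("OFV: %.6f", fit$ofv),
               sprintf("Convergence code: %d (%s)", fit$convergence,
                       fit$message),
               sprintf("Epsilon shrinkage: %.1f%%", fit$shrinkage_eps),
               ""), con)
  utils::write.csv(tab, con, row.names = FALSE)
  jsonlite::write_json(
    list(ofv = fit$ofv, convergence = fit$convergence,
         parameters = tab, shrinkage_eta = as.list(fit$shrinkage_eta),
         shrinkage_eps = fit$shrinkage_eps),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
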