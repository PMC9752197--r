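#' Population pharmacokinetic model
#'
#' Bundles the typical-value parameter vector, allometric body-weight scaling,
#' the interindividual-variability (IIV) covariance, and the residual-error
#' model. Clearance-type parameters (CL, Q2, Q3) scale with body weight to the
#' power \code{allo_exp_cl}; volumes (V1, V2, V3) to the power
#' \code{allo_exp_v}; absorption rate constants are not weight-scaled.
#' Random effects are log-normal and multiplicative, by default on CL and F.
#'
#' @param theta named list or vector of typical values; must contain CL, V1,
#'   Q2, V2, Q3, V3, ka_fed, ka_fasted, ktr, F (and optionally n_transit)
#' @param omega named numeric vector of IIV variances on the log scale
#'   (diagonal covariance). Names must be a subset of the theta parameter
#'   names; default effects are CL and F. Entries must be >= 0 (0 switches the
#'   effect off).
#' @param sigma_prop proportional residual error SD (fraction of the
#'   prediction)
#' @param sigma_add additive residual error SD (mg/L)
#' @param allo_exp_cl allometric exponent applied to CL, Q2, Q3 (default 0.75)
#' @param allo_exp_v allometric exponent applied to V1, V2, V3 (default 1)
#' @param ref_wt reference body weight (kg, default 70)
#' @param n_transit number of transit compartments (model setting, default 3)
#' @return an object of class \code{population_model}
#' @export
population_model <- function(theta,
                             omega = c(CL = cv_percent_to_omega(7.9),
                                       F = cv_percent_to_omega(32.7)),
                             sigma_prop = 0.15, sigma_add = 0.02,
                             allo_exp_cl = 0.75, allo_exp_v = 1,
                             ref_wt = 70, n_transit = 3L) {
  theta <- as.list(theta)
  need <- c("CL", "V1", "Q2", "V2", "Q3", "V3", "ka_fed", "ka_fasted",
            "ktr", "F")
  miss <- setdiff(need, names(theta))
  if (length(miss))
    stop("theta is missing parameters: ", paste(miss, collapse = ", "))
  if (!is.null(theta$n_transit)) n_transit <- as.integer(theta$n_transit)
  theta <- theta[need]
  if (is.null(names(omega)) || !all(names(omega) %in% need))
    stop("omega must be a named vector with names among the theta parameters")
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("omega variances must be finite and >= 0")
  if (sigma_prop < 0 || sigma_add < 0)
    stop("residual error SDs must be >= 0")
  if (sigma_prop == 0 && sigma_add == 0)
    stop("at least one residual error component must be positive")
  if (ref_wt <= 0) stop("ref_wt must be positive")
  pop <- list(theta = theta, omega = omega,
              sigma_prop = sigma_prop, sigma_add = sigma_add,
              allo_exp_cl = allo_exp_cl, allo_exp_v = allo_exp_v,
              ref_wt = ref_wt, n_transit = as.integer(n_transit))
  # validate typical values by constructing the typical individual
  validate_structural_params(c(theta, list(n_transit = pop$n_transit)))
  class(pop) <- "population_model"
  pop
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (3-cmt, transit absorption, allometric scaling)\n")
  cat("Typical values:\n")
  print(round(unlist(x$theta), 4))
  cat(sprintf("Allometry: CL-type ^%g, V-type ^%g, reference weight %g kg\n",
              x$allo_exp_cl, x$allo_exp_v, x$ref_wt))
  cat("IIV (CV%):",
      paste(sprintf("%s = %.1f%%", names(x$omega), iiv_cv_percent(x$omega)),
            collapse = ", "), "\n")
  cat(sprintf("Residual error: proportional %.3g, additive %.3g mg/L\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Individual parameters from population model, covariates and random effects
#'
#' Applies allometric weight scaling and log-normal random effects to the
#' typical values: clearance-type parameters are multiplied by
#' \code{(WT/ref_wt)^allo_exp_cl}, volumes by \code{(WT/ref_wt)^allo_exp_v},
#' and each parameter named in \code{eta} by \code{exp(eta)}.
#'
#' @param pop a \code{\link{population_model}}
#' @param wt body weight (kg)
#' @param eta named numeric vector of random effects; names must match
#'   \code{names(pop$omega)} (pass \code{NULL} or zeros for the typical
#'   subject)
#' @return a \code{\link{structural_params}} object
#' @export
individual_params <- function(pop, wt, eta = NULL) {
  if (!is.finite(wt) || wt <= 0) stop("body weight must be positive")
  if (is.null(eta)) eta <- stats::setNames(numeric(length(pop$omega)),
                                           names(pop$omega))
  if (is.null(names(eta)) || !all(names(eta) %in% names(pop$omega)))
    stop("eta must be named with a subset of the omega effects: ",
         paste(names(pop$omega), collapse = ", "))
  th <- pop$theta
  fcl <- (wt / pop$ref_wt)^pop$allo_exp_cl
  fv <- (wt / pop$ref_wt)^pop$allo_exp_v
  p <- list(CL = th$CL * fcl, V1 = th$V1 * fv,
            Q2 = th$Q2 * fcl, V2 = th$V2 * fv,
            Q3 = th$Q3 * fcl, V3 = th$V3 * fv,
            ka_fed = th$ka_fed, ka_fasted = th$ka_fasted, ktr = th$ktr,
            n_transit = pop$n_transit, F = th$F)
  for (nm in names(eta)) p[[nm]] <- p[[nm]] * exp(eta[[nm]])
  class(p) <- "structural_params"
  validate_structural_params(p)
  p
}

#' Convert a log-normal variance to a coefficient of variation in percent
#'
#' For a log-normally distributed parameter with log-scale variance
#' \code{omega_kk}, the coefficient of variation is
#' \code{100 * sqrt(exp(omega_kk) - 1)}. This is the scale on which IIV
#' magnitudes are reported.
#'
#' @param omega_kk log-scale variance(s), >= 0
#' @return CV in percent
#' @seealso \code{\link{cv_percent_to_omega}} for the inverse
#' @export
iiv_cv_percent <- function(omega_kk) {
  if (any(!is.finite(omega_kk)) || any(omega_kk < 0))
    stop("omega variances must be finite and >= 0")
  100 * sqrt(expm1(omega_kk))
}

#' @rdname iiv_cv_percent
#' @param cv CV in percent, >= 0
#' @export
cv_percent_to_omega <- function(cv) {
  if (any(!is.finite(cv)) || any(cv < 0)) stop("cv must be finite and >= 0")
  log1p((cv / 100)^2)
}

#' Apply the residual-error model to a true concentration
#'
#' Combined proportional + additive error:
#' \code{DV = conc * (1 + sigma_prop * eps1) + sigma_add * eps2}, so that
#' \code{Var(DV | conc) = (sigma_prop * conc)^2 + sigma_add^2}.
#'
#' @param true_conc model-predicted concentration(s), >= 0 (mg/L)
#' @param eps matrix (n x 2) or length-2 vector of standard-normal draws
#' @param pop a \code{\link{population_model}} supplying sigma_prop/sigma_add
#' @return observed concentration(s) (mg/L)
#' @export
residual_observe <- function(true_conc, eps, pop) {
  if (any(true_conc < 0)) stop("true_conc must be >= 0")
  eps <- matrix(eps, ncol = 2L)
  if (nrow(eps) != length(true_conc))
    stop("eps must provide two standard normals per concentration")
  true_conc * (1 + pop$sigma_prop * eps[, 1L]) + pop$sigma_add * eps[, 2L]
}

## residual SD given predicted concentration, floored away from zero
.res_sd <- function(conc, pop) {
  pmax(sqrt((pop$sigma_prop * conc)^2 + pop$sigma_add^2), 1e-10)
}
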