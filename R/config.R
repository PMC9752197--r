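#' Default synthetic truth model
#'
#' The population model used as simulation truth throughout the package's
#' examples, tests and the shipped trial-program generator. The typical
#' values are explicit synthetic placeholders chosen to be pharmacologically
#' plausible for an orally available antibacterial dosed at 500 mg q24h
#' (they are not published estimates). The IIV magnitudes correspond to a
#' CV of 7.9\% on clearance and 32.7\% on bioavailability on the log-normal
#' CV scale.
#'
#' @return a \code{\link{population_model}}
#' @export
default_truth_model <- function() {
  population_model(
    theta = list(CL = 15, V1 = 40, Q2 = 8, V2 = 60, Q3 = 2.5, V3 = 220,
                 ka_fed = 0.7, ka_fasted = 1.5, ktr = 2, F = 0.8),
    omega = c(CL = cv_percent_to_omega(7.9), F = cv_percent_to_omega(32.7)),
    sigma_prop = 0.15, sigma_add = 0.02,
    allo_exp_cl = 0.75, allo_exp_v = 1, ref_wt = 70, n_transit = 3L)
}

#' Read and write population-model configuration files
#'
#' The configuration is a YAML file with blocks \code{theta} (typical
#' values), \code{omega} (per effect, either \code{var:} log-scale variance
#' or \code{cv:} percent), \code{sigma} (\code{prop}, \code{add}) and
#' \code{allometry} (\code{exp_cl}, \code{exp_v}, \code{ref_wt}), plus an
#' optional top-level \code{n_transit}.
#'
#' @param path YAML file path
#' @return \code{read_model_config}: a \code{\link{population_model}}
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$theta)) stop("config is missing the theta block")
  om <- vapply(cfg$omega, function(e) {
    if (!is.null(e$var)) as.numeric(e$var)
    else if (!is.null(e$cv)) cv_percent_to_omega(as.numeric(e$cv))
    else stop("each omega entry needs 'var' or 'cv'")
  }, 0)
  allo <- cfg$allometry
  population_model(
    theta = cfg$theta, omega = om,
    sigma_prop = cfg$sigma$prop %||% 0.15,
    sigma_add = cfg$sigma$add %||% 0.02,
    allo_exp_cl = allo$exp_cl %||% 0.75,
    allo_exp_v = allo$exp_v %||% 1,
    ref_wt = allo$ref_wt %||% 70,
    n_transit = cfg$n_transit %||% 3L)
}

#' @rdname read_model_config
#' @param pop a \code{\link{population_model}} to serialize
#' @export
write_model_config <- function(pop, path) {
  cfg <- list(
    theta = pop$theta,
    omega = lapply(as.list(pop$omega), function(v) list(var = v)),
    sigma = list(prop = pop$sigma_prop, add = pop$sigma_add),
    allometry = list(exp_cl = pop$allo_exp_cl, exp_v = pop$allo_exp_v,
                     ref_wt = pop$ref_wt),
    n_transit = pop$n_transit)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Read and write trial-program roster configuration files
#'
#' A roster YAML file holds a list of studies, each with the fields of
#' \code{\link{study_design}}.
#'
#' @param path YAML file path
#' @return \code{read_roster_config}: a \code{\link{program_roster}}
#' @export
read_roster_config <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  cfg <- yaml::read_yaml(path)
  program_roster(lapply(cfg$studies, function(st) {
    study_design(id = st$id, phase = as.character(st$phase %||% "1"),
                 route = st$route, n_subjects = st$n_subjects,
                 dose_times = unlist(st$dose_times),
                 dose_amt = unlist(st$dose_amt),
                 duration = st$duration %||% 0,
                 fed = if (is.null(st$fed)) NA else unlist(st$fed),
                 sampling_times = unlist(st$sampling_times),
                 population = st$population %||% "healthy",
                 wt_median = st$wt_median %||% 75,
                 wt_cv = st$wt_cv %||% 15)
  }))
}

#' @rdname read_roster_config
#' @param roster a \code{\link{program_roster}} to serialize
#' @export
write_roster_config <- function(roster, path) {
  yaml::write_yaml(list(studies = lapply(roster, function(st)
    st[c("id", "phase", "route", "n_subjects", "dose_times", "dose_amt",
         "duration", "fed", "sampling_times", "population", "wt_median",
         "wt_cv")])), path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
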