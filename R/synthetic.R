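#' Study designs and trial-program rosters
#'
#' A \code{study_design} describes one study arm template applied to every
#' subject in the study: the dosing schedule, sampling times, and the
#' body-weight distribution of the enrolled population. A
#' \code{program_roster} is an ordered collection of study designs that
#' together emulate a pooled clinical program.
#'
#' @param id unique study label
#' @param phase development phase label (e.g. "1", "2")
#' @param route "IV" or "PO"
#' @param n_subjects number of subjects enrolled
#' @param dose_times dose administration times (h) per subject
#' @param dose_amt dose amount (mg), recycled over \code{dose_times}
#' @param duration infusion duration (h), 0 for bolus/oral
#' @param fed logical vector recycled over doses (PO only; NA for IV)
#' @param sampling_times PK sampling times (h) per subject
#' @param population "healthy" or "patient" (labels the weight distribution)
#' @param wt_median median body weight (kg)
#' @param wt_cv body-weight coefficient of variation (percent)
#' @return \code{study_design}: a list with class \code{study_design}
#' @export
study_design <- function(id, phase, route, n_subjects,
                         dose_times, dose_amt, duration = 0, fed = NA,
                         sampling_times,
                         population = c("healthy", "patient"),
                         wt_median = 75, wt_cv = 15) {
  route <- match.arg(route, c("IV", "PO"))
  population <- match.arg(population)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (any(sampling_times < 0)) stop("sampling times must be non-negative")
  if (any(dose_amt <= 0)) stop("doses must be positive")
  fed <- rep_len(fed, length(dose_times))
  if (route == "PO" && any(is.na(fed)))
    stop("fed status must be given for PO studies")
  if (route == "IV") fed <- rep(NA, length(dose_times))
  structure(list(id = id, phase = phase, route = route,
                 n_subjects = as.integer(n_subjects),
                 dose_times = dose_times,
                 dose_amt = rep_len(dose_amt, length(dose_times)),
                 duration = duration, fed = fed,
                 sampling_times = sort(sampling_times),
                 population = population,
                 wt_median = wt_median, wt_cv = wt_cv),
            class = "study_design")
}

#' @rdname study_design
#' @param ... study_design objects
#' @export
program_roster <- function(...) {
  studies <- list(...)
  if (length(studies) == 1L && is.list(studies[[1L]]) &&
      !inherits(studies[[1L]], "study_design"))
    studies <- studies[[1L]]
  ids <- vapply(studies, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("study ids must be unique")
  structure(studies, class = "program_roster")
}

#' Default pooled program roster
#'
#' A reconstruction of a pooled Phase 1 / Phase 2 development program:
#' five Phase 1 studies in healthy volunteers (three IV, two PO — one
#' fed/fasted crossover and one multiple-dose fed study) with rich sampling,
#' and two Phase 2 studies in MAC lung disease patients (IV only) with sparse
#' sampling (3-4 samples per patient) and a lower body-weight distribution.
#' The per-study enrollments and schedules are explicit synthetic choices
#' constrained to pool to exactly 138 subjects contributing 2637 PK samples.
#'
#' @return a \code{\link{program_roster}} of 7 studies
#' @export
default_program <- function() {
  rich_sad <- c(0.5, 1, 1.25, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 24, 36, 48,
                72, 96, 120)
  mad_day1 <- c(0.5, 1, 1.5, 2, 4, 6, 8, 12)
  program_roster(
    study_design("P1-101", "1", "IV", 16, dose_times = 0, dose_amt = 500,
                 duration = 1, sampling_times = rich_sad),
    study_design("P1-102", "1", "IV", 18, dose_times = (0:6) * 24,
                 dose_amt = 500, duration = 1,
                 sampling_times = c(mad_day1, (1:6) * 24,
                                    144 + c(0.5, 1, 1.5, 2, 4, 6, 8, 12, 16,
                                            24, 36, 48, 72, 96, 120, 144,
                                            168, 192, 216, 240))),
    study_design("P1-103", "1", "IV", 12, dose_times = 0, dose_amt = 250,
                 duration = 1, sampling_times = rich_sad),
    study_design("P1-104", "1", "PO", 18, dose_times = c(0, 168),
                 dose_amt = 500, fed = c(FALSE, TRUE),
                 sampling_times = c(outer(c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                            12, 16, 24, 48, 72),
                                          c(0, 168), "+"))),
    study_design("P1-105", "1", "PO", 24, dose_times = (0:13) * 24,
                 dose_amt = 500, fed = TRUE,
                 sampling_times = c(mad_day1[-(5:6)], 2.5, 3,
                                    c(24, 72, 120, 168, 216, 264),
                                    312 + c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                            12, 16, 24),
                                    312 + c(36, 48, 72, 96, 120, 144, 168,
                                            192, 216))),
    study_design("P2-201", "2", "IV", 23, dose_times = (0:13) * 24,
                 dose_amt = 500, duration = 1,
                 sampling_times = c(1, 168, 170),
                 population = "patient", wt_median = 55),
    study_design("P2-202", "2", "IV", 27, dose_times = (0:13) * 24,
                 dose_amt = 500, duration = 1,
                 sampling_times = c(1, 4, 168, 170),
                 population = "patient", wt_median = 55)
  )
}

## deterministic per-subject random substream seed; stable under edits to
## other studies in the roster
.subject_seed <- function(seed, study_id, i) {
  h <- sum(utf8ToInt(as.character(study_id)) * 131)
  as.integer((as.numeric(seed) * 104729 + h * 7919 + i * 524287) %%
               2147483629) + 1L
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.draw_eta <- function(pop) {
  stats::setNames(stats::rnorm(length(pop$omega), 0, sqrt(pop$omega)),
                  names(pop$omega))
}

#' Generate a synthetic pooled trial dataset
#'
#' Simulates every subject of a program roster under a truth population
#' model: body weights are drawn log-normally per study, individual
#' parameters from the IIV model, concentrations from the closed-form
#' kinetics, and observations from the residual-error model. The result is a
#' validated \code{pk_dataset}. Generation is deterministic given
#' \code{seed}, with an independent substream per subject.
#'
#' @param roster a \code{\link{program_roster}}
#' @param truth a \code{\link{population_model}} used as simulation truth
#' @param seed integer seed
#' @return a \code{pk_dataset} data.frame
#' @export
generate_dataset <- function(roster, truth, seed = 1L) {
  if (!length(roster)) {
    empty <- as.data.frame(matrix(nrow = 0L, ncol = length(.pk_columns),
                                  dimnames = list(NULL, .pk_columns)))
    class(empty) <- c("pk_dataset", class(empty))
    return(empty)
  }
  out <- vector("list", sum(vapply(roster, `[[`, 0L, "n_subjects")))
  next_id <- 1L
  k <- 0L
  for (st in roster) {
    sdlog <- sqrt(log1p((st$wt_cv / 100)^2))
    for (i in seq_len(st$n_subjects)) {
      k <- k + 1L
      rows <- .with_seed(.subject_seed(seed, st$id, i), {
        wt <- round(st$wt_median * exp(stats::rnorm(1L, 0, sdlog)), 1)
        eta <- .draw_eta(truth)
        pars <- individual_params(truth, wt, eta)
        doses <- data.frame(time = st$dose_times, amount = st$dose_amt,
                            route = st$route, duration = st$duration,
                            fed = st$fed)
        conc <- solve_profile(pars, doses, st$sampling_times)$conc
        eps <- matrix(stats::rnorm(2L * length(conc)), ncol = 2L)
        dv <- residual_observe(conc, eps, truth)
        .assemble_rows(next_id, st, wt, doses, st$sampling_times, dv)
      })
      out[[k]] <- rows
      next_id <- next_id + 1L
    }
  }
  validate_pk_dataset(do.call(rbind, out))
}

.assemble_rows <- function(id, st, wt, doses, obs_time, dv) {
  drow <- data.frame(ID = id, TIME = doses$time, AMT = doses$amount,
                     RATE = ifelse(doses$duration > 0,
                                   doses$amount / doses$duration, 0),
                     EVID = 1L, CMT = ifelse(doses$route == "PO", 1L, 2L),
                     DV = NA_real_, MDV = 1L, WT = wt,
                     FED = ifelse(is.na(doses$fed), 0L,
                                  as.integer(doses$fed)),
                     ROUTE = doses$route, STUDY = st$id)
  orow <- data.frame(ID = id, TIME = obs_time, AMT = NA_real_, RATE = NA_real_,
                     EVID = 0L, CMT = 2L, DV = round(dv, 6), MDV = 0L,
                     WT = wt, FED = 0L, ROUTE = st$route, STUDY = st$id)
  all <- rbind(orow, drow)
  # observations at a dose time are pre-dose draws: order them first
  all[order(all$TIME, all$EVID), , drop = FALSE]
}

#' Re-simulate the observations of an existing dataset design
#'
#' Keeps every subject's dosing history, sampling times and covariates and
#' replaces the observed concentrations with a fresh simulation under
#' \code{pop}. Used by the visual predictive check.
#'
#' @param pop a \code{\link{population_model}}
#' @param data a \code{pk_dataset}
#' @param seed integer seed
#' @return a \code{pk_dataset} with simulated DV
#' @export
simulate_dataset <- function(pop, data, seed = 1L) {
  prep <- .prep_subjects(data)
  out <- data
  for (i in seq_along(prep)) {
    s <- prep[[i]]
    if (!length(s$obs_time)) next
    dv <- .with_seed(.subject_seed(seed, "resim", i), {
      eta <- .draw_eta(pop)
      pars <- individual_params(pop, s$wt, eta)
      conc <- solve_profile(pars, s$doses, s$obs_time)$conc
      eps <- matrix(stats::rnorm(2L * length(conc)), ncol = 2L)
      residual_observe(conc, eps, pop)
    })
    out$DV[s$obs_rows] <- dv
  }
  out
}

#' Simulate steady-state exposures under a dosing regimen
#'
#' Draws \code{n_subjects} individuals from the population model (IIV and,
#' optionally, a body-weight distribution) and computes each subject's
#' steady-state AUC over the dosing interval, peak and trough concentration.
#'
#' @param pop a \code{\link{population_model}}
#' @param regimen a single \code{\link{dose_event}} template
#' @param interval dosing interval (h)
#' @param n_subjects number of simulated subjects
#' @param seed integer seed
#' @param wt either NULL (all subjects at the reference weight) or
#'   \code{c(median, cv_percent)} of a log-normal weight distribution
#' @return data.frame with per-subject \code{id}, \code{WT}, \code{AUC_tau},
#'   \code{Cmax}, \code{Cmin}; the 5th/50th/95th exposure percentiles are
#'   attached as attribute \code{"summary"}
#' @export
simulate_regimen_exposures <- function(pop, regimen, interval = 24,
                                       n_subjects = 1000L, seed = 1L,
                                       wt = NULL) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  res <- .with_seed(seed, {
    sdlog <- if (is.null(wt)) 0 else sqrt(log1p((wt[2L] / 100)^2))
    med <- if (is.null(wt)) pop$ref_wt else wt[1L]
    wts <- med * exp(stats::rnorm(n_subjects, 0, sdlog))
    rows <- lapply(seq_len(n_subjects), function(i) {
      eta <- .draw_eta(pop)
      pars <- individual_params(pop, wts[i], eta)
      m <- steady_state_metrics(pars, regimen, interval, n_grid = 501L)
      data.frame(id = i, WT = wts[i], AUC_tau = m$AUC_tau,
                 Cmax = m$Cmax, Cmin = m$Cmin)
    })
    do.call(rbind, rows)
  })
  qs <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), type = 7)
  attr(res, "summary") <- rbind(AUC_tau = qs(res$AUC_tau),
                                Cmax = qs(res$Cmax), Cmin = qs(res$Cmin))
  res
}
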