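# Goodness-of-fit residuals and the prediction-corrected VPC

test_that("prediction correction is an identity for uniform predictions", {
  expect_equal(prediction_correct(c(1, 2, 3), c(4, 4, 4), c(4, 4, 4)),
               c(1, 2, 3))
  expect_equal(prediction_correct(2, 4, 2), 1)  # pred = 2 * ref -> dv / 2
  expect_warning(out <- prediction_correct(c(1, 2), c(0, 5), c(1, 1)),
                 "non-positive")
  expect_true(is.na(out[1]) && !is.na(out[2]))
})

test_that("prediction correction collapses dose groups under linear PK", {
  # two dose groups, no IIV, no residual noise: after correction the
  # pc-observations of the 100 mg and 500 mg arms coincide exactly
  truth <- default_truth_model()
  no_var <- population_model(truth$theta, omega = c(CL = 0, F = 0),
                             sigma_prop = 1e-12, sigma_add = 0)
  mk <- function(amt, id0) {
    roster <- program_roster(list(
      study_design(paste0("D", amt), "1", "PO", 5, dose_times = 0,
                   dose_amt = amt, fed = TRUE,
                   sampling_times = c(1, 2, 4, 8, 12, 24))))
    ds <- generate_dataset(roster, no_var, seed = 2)
    ds$ID <- ds$ID + id0
    ds
  }
  ds <- validate_pk_dataset(rbind(mk(100, 0), mk(500, 100)))
  prep <- ebopk:::.prep_subjects(ds)
  pred <- unlist(lapply(prep, function(s)
    ebopk:::.subject_conc(no_var, s, NULL)))
  time <- unlist(lapply(prep, `[[`, "obs_time"))
  dv <- unlist(lapply(prep, `[[`, "dv"))
  ref <- stats::ave(pred, time, FUN = median)
  pc <- prediction_correct(dv, pred, ref)
  for (tt in unique(time))  # only DV rounding (1e-6 mg/L) separates them
    expect_lt(diff(range(pc[time == tt])) / max(pc[time == tt]), 1e-4)
})

test_that("residual tables have the stated degenerate behaviour", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 3, 8), truth, seed = 12)
  # omega = 0, additive-only error: CWRES equals ordinary standardized
  # residuals and IPRED equals PRED
  pop0 <- population_model(truth$theta, omega = c(CL = 0, F = 0),
                           sigma_prop = 1e-12, sigma_add = 0.05)
  suppressWarnings(g0 <- gof_residuals(pop0, ds))
  expect_equal(g0$IPRED, g0$PRED)
  expect_equal(g0$CWRES, (g0$DV - g0$PRED) / 0.05, tolerance = 1e-6)
  # IWRES uses the interaction residual SD evaluated at IPRED
  g <- gof_residuals(truth, ds)
  expect_equal(g$IWRES,
               (g$DV - g$IPRED) /
                 sqrt((truth$sigma_prop * g$IPRED)^2 + truth$sigma_add^2),
               tolerance = 1e-12)
  # observations sitting exactly on the model prediction give IWRES = 0
  ds_on <- ds
  ds_on$DV[ds_on$EVID == 0] <- g0$PRED
  suppressWarnings(g_on <- gof_residuals(pop0, ds_on))
  expect_equal(g_on$IWRES, rep(0, nrow(g_on)))
})

test_that("CWRES are calibrated on self-simulated data", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(50, 50, 8), truth, seed = 88)
  g <- gof_residuals(truth, ds)
  expect_lt(abs(mean(g$CWRES)), 0.1)
  expect_gt(sd(g$CWRES), 0.85)
  expect_lt(sd(g$CWRES), 1.15)
})

test_that("the pcVPC is deterministic given the seed", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(8, 8, 8), truth, seed = 30)
  v1 <- run_pcvpc(truth, ds, n_sim = 100, seed = 7)
  v2 <- run_pcvpc(truth, ds, n_sim = 100, seed = 7)
  expect_identical(v1, v2)
  v3 <- run_pcvpc(truth, ds, n_sim = 100, seed = 8)
  expect_false(identical(v1$stats$band_lo, v3$stats$band_lo))
  # serialization round-trip is stable
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_vpc_csv(v1, f1); write_vpc_csv(v2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2, paste0(c(f1, f2), ".json")))
})

test_that("pcVPC bands are ordered and bins partition the observations", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(8, 8, 10), truth, seed = 31)
  v <- run_pcvpc(truth, ds, n_sim = 100, seed = 5)
  expect_true(all(v$stats$band_lo <= v$stats$band_med + 1e-12))
  expect_true(all(v$stats$band_med <= v$stats$band_hi + 1e-12))
  expect_gte(min(v$bins$n_obs), 10)
  expect_equal(sum(v$bins$n_obs), sum(ds$EVID == 0 & ds$MDV == 0))
  p5 <- v$stats$observed[v$stats$stat == "p5"]
  p50 <- v$stats$observed[v$stats$stat == "p50"]
  p95 <- v$stats$observed[v$stats$stat == "p95"]
  expect_true(all(p5 <= p50 & p50 <= p95))
  expect_error(run_pcvpc(truth, ds, n_sim = 50, seed = 1), ">= 100")
})

test_that("pcVPC comparisons are invariant to dose rescaling of a subgroup", {
  # the correction's purpose: scaling one arm's doses (and, by linearity,
  # its observations) must not change where the observed percentiles sit
  # relative to the simulation bands. A purely proportional error model
  # makes the scaling exact.
  truth <- default_truth_model()
  prop_only <- population_model(truth$theta, omega = truth$omega,
                                sigma_prop = 0.15, sigma_add = 1e-10)
  roster <- program_roster(list(
    study_design("A", "1", "IV", 6, dose_times = 0, dose_amt = 500,
                 duration = 1, sampling_times = c(1, 2, 4, 8, 16, 24)),
    study_design("B", "1", "IV", 6, dose_times = 0, dose_amt = 250,
                 duration = 1, sampling_times = c(1, 2, 4, 8, 16, 24))))
  ds <- generate_dataset(roster, prop_only, seed = 44)
  v <- run_pcvpc(prop_only, ds, n_sim = 100, seed = 3, bins = 6, min_bin = 5)
  ds2 <- ds
  b <- ds2$STUDY == "B"
  ds2$AMT[b] <- ds2$AMT[b] * 2
  ds2$RATE[b] <- ds2$RATE[b] * 2
  ds2$DV[b] <- ds2$DV[b] * 2
  v2 <- run_pcvpc(prop_only, ds2, n_sim = 100, seed = 3, bins = 6,
                  min_bin = 5)
  # observed percentiles relative to their simulation bands are unchanged
  # (DV values are stored rounded, hence the loose-ish tolerance)
  expect_equal(v2$stats$observed / v2$stats$band_med,
               v$stats$observed / v$stats$band_med, tolerance = 1e-4)
  inside <- function(v) with(v$stats, observed >= band_lo &
                                        observed <= band_hi)
  expect_identical(inside(v2), inside(v))
})
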