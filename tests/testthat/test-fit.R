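# Laplace objective and population fitting

test_that("with omega -> 0 the OFV reduces to the fixed-effect WRSS", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 3, 8), truth, seed = 21)
  tiny <- population_model(truth$theta, omega = c(CL = 1e-12, F = 1e-12),
                           sigma_prop = truth$sigma_prop,
                           sigma_add = truth$sigma_add)
  ofv <- as.numeric(conditional_objective(tiny, ds))
  # independent least-squares oracle: eta pinned at zero
  prep <- ebopk:::.prep_subjects(ds)
  oracle <- 0
  for (s in prep) {
    conc <- ebopk:::.subject_conc(tiny, s, NULL)
    s2 <- (tiny$sigma_prop * conc)^2 + tiny$sigma_add^2
    oracle <- oracle + sum((s$dv - conc)^2 / s2 + log(2 * pi * s2))
  }
  expect_equal(ofv, oracle, tolerance = 1e-6)
})

test_that("OFV matches the closed-form marginal MVN in the linear regime", {
  # near-one-compartment kinetics, additive-only error, a single tiny
  # CL random effect: the model is linear in eta to well below the
  # comparison tolerance, so the Laplace OFV must agree with the exact
  # multivariate-normal -2 log-likelihood of the linearized model
  theta <- list(CL = 10, V1 = 30, Q2 = 1e-6, V2 = 50, Q3 = 1e-6, V3 = 100,
                ka_fed = 1, ka_fasted = 1, ktr = 1, F = 1)
  pop <- population_model(theta, omega = c(CL = 1e-6),
                          sigma_prop = 0, sigma_add = 0.05)
  roster <- program_roster(list(
    study_design("LIN", "1", "IV", 5, dose_times = 0, dose_amt = 100,
                 duration = 0.5, sampling_times = c(1, 2, 4, 8, 12, 16, 24))))
  ds <- generate_dataset(roster, pop, seed = 33)
  ofv <- as.numeric(conditional_objective(pop, ds))
  oracle <- linearized_mvn_ofv(pop, ds)
  expect_equal(ofv, oracle, tolerance = 1e-4)
  expect_lt(abs(ofv - oracle), 1e-4)
})

test_that("OFV agrees with adaptive quadrature at a realistic omega", {
  theta <- list(CL = 12, V1 = 35, Q2 = 6, V2 = 50, Q3 = 2, V3 = 150,
                ka_fed = 1, ka_fasted = 1, ktr = 1, F = 0.8)
  pop <- population_model(theta, omega = c(CL = cv_percent_to_omega(25)),
                          sigma_prop = 0.1, sigma_add = 0.02)
  roster <- program_roster(list(
    study_design("QD", "1", "IV", 4, dose_times = 0, dose_amt = 250,
                 duration = 1, sampling_times = c(1, 2, 4, 8, 16, 24))))
  ds <- generate_dataset(roster, pop, seed = 14)
  ofv <- as.numeric(conditional_objective(pop, ds))
  oracle <- quadrature_ofv(pop, ds)
  # Laplace is an approximation; at this sample size it is close but not exact
  expect_equal(ofv, oracle, tolerance = 0.01)
})

test_that("duplicating every subject doubles the OFV", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 3, 6), truth, seed = 17)
  ds2 <- ds
  ds2$ID <- ds2$ID + 1000L
  both <- validate_pk_dataset(rbind(ds, ds2))
  o1 <- as.numeric(conditional_objective(truth, ds))
  o2 <- as.numeric(conditional_objective(truth, both))
  expect_equal(o2, 2 * o1, tolerance = 1e-8)
})

test_that("the OFV is invariant to subject ordering and relabeling", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 3, 6), truth, seed = 29)
  ids <- unique(ds$ID)
  perm <- rev(ids)
  ds2 <- do.call(rbind, lapply(perm, function(id) {
    d <- ds[ds$ID == id, ]
    d$ID <- d$ID + 500L  # relabel
    d
  }))
  ds2 <- validate_pk_dataset(ds2)
  expect_equal(as.numeric(conditional_objective(truth, ds)),
               as.numeric(conditional_objective(truth, ds2)),
               tolerance = 1e-9)
})

test_that("fixing all parameters returns the init with its evaluated OFV", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(2, 2, 6), truth, seed = 4)
  fit <- fit_poppk(ds, truth, fixed = "all")
  expect_equal(fit$pop$theta, truth$theta)
  expect_equal(fit$pop$omega, truth$omega)
  expect_equal(fit$ofv, as.numeric(conditional_objective(truth, ds)),
               tolerance = 1e-8)
})

test_that("starting at the truth the optimizer stays near the truth", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(4, 4, 10), truth, seed = 51)
  free <- c("CL", "V1", "F", "omega_CL", "omega_F", "sigma_prop")
  fit <- fit_poppk(ds, truth,
                   fixed = setdiff(ebopk:::.par_names(truth), free),
                   control = list(iter.max = 60))
  ofv_truth <- as.numeric(conditional_objective(truth, ds))
  expect_lte(fit$ofv, ofv_truth + 1e-6)
  # the ML improvement over the true generating values is a likelihood-ratio
  # statistic, ~ chi-square with one df per freed parameter: bound it by the
  # 99.9% quantile rather than a fixed constant
  expect_gt(fit$ofv, ofv_truth - qchisq(0.999, length(free)))
  expect_lt(abs(fit$pop$theta$CL / truth$theta$CL - 1), 0.2)
})

test_that("an IV-only dataset cannot inform oral parameters", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 0, 6), truth, seed = 6)
  expect_warning(
    fit <- fit_poppk(ds, truth, fixed = setdiff(ebopk:::.par_names(truth),
                                                c("F", "CL"))),
    "not identifiable")
  expect_equal(fit$pop$theta$F, truth$theta$F)  # F was frozen at init
})

test_that("shrinkage has the stated degenerate limits and design ordering", {
  truth <- default_truth_model()
  # matched simulations: same study id and seed give identical subjects
  # (weights and etas); only the sampling differs. Sparse = two trough-type
  # late samples, the typical limited-PK patient contribution.
  mk <- function(times) program_roster(list(
    study_design("SP", "2", "PO", 20, dose_times = 0, dose_amt = 500,
                 fed = FALSE, sampling_times = times)))
  rich <- generate_dataset(mk(c(0.5, 1, 1.5, 2, 4, 6, 8, 12, 16, 24, 36, 48)),
                           truth, seed = 61)
  sparse <- generate_dataset(mk(c(24, 48)), truth, seed = 61)
  eb_rich <- ebe_and_shrinkage(truth, rich)
  eb_sparse <- ebe_and_shrinkage(truth, sparse)
  # sparse sampling shrinks the EBEs harder, for every effect
  expect_gt(eb_sparse$shrinkage_eta[["CL"]], eb_rich$shrinkage_eta[["CL"]])
  expect_gt(eb_sparse$shrinkage_eta[["F"]], eb_rich$shrinkage_eta[["F"]])
  # all EBEs at zero -> exactly 100%
  fake <- list(etas = matrix(0, 10, 1, dimnames = list(NULL, "CL")))
  expect_equal(100 * (1 - sd(fake$etas[, 1]) / sqrt(truth$omega[["CL"]])),
               100)
  # SD(EBE) equal to omega -> exactly 0%
  om <- truth$omega[["CL"]]
  etas <- sqrt(om) * scale(rnorm(50))  # unit sample SD
  expect_equal(100 * (1 - sd(etas) / sqrt(om)), 0, tolerance = 1e-10)
})

test_that("a missing random effect is reported as missing shrinkage", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(3, 3, 6), truth, seed = 9)
  pop0 <- population_model(truth$theta, omega = c(CL = truth$omega[["CL"]],
                                                  F = 0),
                           sigma_prop = 0.15, sigma_add = 0.02)
  expect_warning(eb <- ebe_and_shrinkage(pop0, ds), "undefined")
  expect_true(is.na(eb$shrinkage_eta[["F"]]))
  expect_false(is.na(eb$shrinkage_eta[["CL"]]))
})

test_that("nested models are ordered: freeing a parameter cannot hurt", {
  truth <- default_truth_model()
  ds <- generate_dataset(small_roster(4, 4, 8), truth, seed = 77)
  base_fixed <- c("Q2", "V2", "Q3", "V3", "ka_fed", "ka_fasted", "ktr",
                  "sigma_add", "V1")
  f_small <- fit_poppk(ds, truth, fixed = c(base_fixed, "F"),
                       control = list(iter.max = 60))
  f_big <- fit_poppk(ds, truth, fixed = base_fixed,
                     control = list(iter.max = 60))
  expect_lte(f_big$ofv, f_small$ofv + 0.1)
  expect_lte(f_small$ofv, f_small$ofv_init)
})
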