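#' Prediction correction of observed concentrations
#'
#' Normalizes each observation by the ratio of its bin's reference
#' (median) population prediction to the observation's own population
#' prediction, \code{pcDV = DV * pred_bin_ref / pred_ij}. For a linear,
#' lower-bound-free model this removes systematic differences in dose and
#' design between subjects pooled in one bin.
#'
#' @param dv observed concentrations
#' @param pred_ij population prediction for each observation (must be > 0;
#'   non-positive predictions yield NA with a warning)
#' @param pred_bin_ref the bin reference prediction for each observation
#' @return prediction-corrected observations
#' @export
prediction_correct <- function(dv, pred_ij, pred_bin_ref) {
  out <- dv * pred_bin_ref / pred_ij
  bad <- !(pred_ij > 0)
  if (any(bad)) {
    warning(sum(bad), " observation(s) with non-positive population ",
            "prediction excluded from prediction correction", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

## single quantile definition shared by the observed and simulated sides
.vpc_quantile <- function(x, probs) {
  stats::quantile(x, probs, type = 7, names = FALSE, na.rm = TRUE)
}

## quantile-based time bins with small-bin merging; returns integer bin index
.time_bins <- function(time, bins = 8L, min_bin = 10L) {
  if (length(bins) > 1L) {
    edges <- sort(unique(bins))
  } else {
    probs <- seq(0, 1, length.out = bins + 1L)
    edges <- unique(.vpc_quantile(time, probs))
  }
  edges[1L] <- -Inf
  edges[length(edges)] <- Inf
  idx <- findInterval(time, edges, rightmost.closed = TRUE)
  idx <- match(idx, sort(unique(idx)))
  n_before <- max(idx)
  # merge undersized bins into the neighbour to the left (right for bin 1);
  # each merge removes one bin, so this terminates
  repeat {
    counts <- tabulate(idx)
    small <- which(counts < min_bin)
    if (!length(small) || max(idx) <= 1L) break
    b <- small[1L]
    idx[idx == b] <- if (b > 1L) b - 1L else 2L
    idx <- match(idx, sort(unique(idx)))
  }
  if (max(idx) < n_before)
    message("merged ", n_before - max(idx), " undersized time bin(s); ",
            max(idx), " bins retained")
  idx
}

#' Prediction-corrected visual predictive check
#'
#' Simulates \code{n_sim} replicates of the dataset's design under the model,
#' applies the identical binning, prediction correction and percentile
#' computation to the observed and the simulated data, and summarizes, per
#' time bin, the observed 5th/50th/95th percentiles against the
#' inter-simulation 90\% interval of each percentile.
#'
#' @param object a \code{poppk_fit} or a \code{\link{population_model}}
#' @param data a \code{pk_dataset}
#' @param n_sim number of simulation replicates (>= 100)
#' @param seed integer seed; the result is deterministic given the seed
#' @param bins target number of quantile-based time bins, or an explicit
#'   vector of bin edges
#' @param min_bin minimum observations per bin (smaller bins are merged)
#' @return a \code{vpc_result}: list with \code{bins} (bin table),
#'   \code{stats} (per bin and percentile: observed value, simulation band),
#'   \code{n_sim}, \code{seed}
#' @export
run_pcvpc <- function(object, data, n_sim = 200L, seed = 1L, bins = 8L,
                      min_bin = 10L) {
  pop <- if (inherits(object, "poppk_fit")) object$pop else object
  if (n_sim < 100L) stop("n_sim must be >= 100")
  prep <- .prep_subjects(data)
  has_obs <- vapply(prep, function(s) length(s$dv) > 0L, TRUE)
  prep <- prep[has_obs]
  if (!length(prep)) stop("dataset contains no observations")

  time <- unlist(lapply(prep, `[[`, "obs_time"))
  dv <- unlist(lapply(prep, `[[`, "dv"))
  pred <- unlist(lapply(prep, function(s) .subject_conc(pop, s, NULL)))

  keep <- pred > 0
  if (!all(keep))
    warning(sum(!keep), " observation(s) with non-positive population ",
            "prediction excluded from the pcVPC", call. = FALSE)

  bin_id <- .time_bins(time[keep], bins, min_bin)
  nb <- max(bin_id)
  ref <- vapply(seq_len(nb), function(b)
    stats::median(pred[keep][bin_id == b]), 0)

  pc_obs <- dv[keep] * ref[bin_id] / pred[keep]
  probs <- c(0.05, 0.5, 0.95)
  obs_q <- vapply(seq_len(nb), function(b)
    .vpc_quantile(pc_obs[bin_id == b], probs), numeric(3L))

  # simulated replicates: same design, fresh etas and residuals
  sim_q <- array(NA_real_, c(3L, nb, n_sim))
  nobs_per <- vapply(prep, function(s) length(s$obs_time), 0L)
  for (r in seq_len(n_sim)) {
    dv_sim <- numeric(sum(nobs_per))
    pos <- 0L
    for (i in seq_along(prep)) {
      s <- prep[[i]]
      sim <- .with_seed(.subject_seed(seed, paste0("vpc", r), i), {
        eta <- .draw_eta(pop)
        pars <- individual_params(pop, s$wt, eta)
        conc <- solve_profile(pars, s$doses, s$obs_time)$conc
        eps <- matrix(stats::rnorm(2L * length(conc)), ncol = 2L)
        residual_observe(conc, eps, pop)
      })
      dv_sim[pos + seq_along(sim)] <- sim
      pos <- pos + length(sim)
    }
    pc_sim <- dv_sim[keep] * ref[bin_id] / pred[keep]
    sim_q[, , r] <- vapply(seq_len(nb), function(b)
      .vpc_quantile(pc_sim[bin_id == b], probs), numeric(3L))
  }

  t_keep <- time[keep]
  bins_df <- data.frame(
    bin = seq_len(nb),
    t_lo = vapply(seq_len(nb), function(b) min(t_keep[bin_id == b]), 0),
    t_hi = vapply(seq_len(nb), function(b) max(t_keep[bin_id == b]), 0),
    t_mid = vapply(seq_len(nb), function(b)
      stats::median(t_keep[bin_id == b]), 0),
    n_obs = as.integer(table(factor(bin_id, levels = seq_len(nb)))),
    pred_ref = ref)
  stats_df <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(bin = b, stat = c("p5", "p50", "p95"),
               observed = obs_q[, b],
               band_lo = apply(sim_q[, b, , drop = FALSE], 1L,
                               .vpc_quantile, probs = 0.05),
               band_med = apply(sim_q[, b, , drop = FALSE], 1L,
                                .vpc_quantile, probs = 0.5),
               band_hi = apply(sim_q[, b, , drop = FALSE], 1L,
                               .vpc_quantile, probs = 0.95))
  }))
  structure(list(bins = bins_df, stats = stats_df, n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC: %d bins, %d simulations, seed %d\n",
              nrow(x$bins), x$n_sim, x$seed))
  med <- x$stats[x$stats$stat == "p50", ]
  inside <- med$observed >= med$band_lo & med$observed <= med$band_hi
  cat(sprintf("Observed medians inside the 90%% simulation band: %d/%d\n",
              sum(inside), nrow(med)))
  invisible(x)
}

#' Serialize a VPC result
#'
#' Writes the per-bin statistics as CSV and a compact JSON summary
#' (\code{<path>.json}).
#'
#' @param vpc a \code{vpc_result}
#' @param path CSV output path
#' @return invisibly, the CSV path
#' @export
write_vpc_csv <- function(vpc, path) {
  out <- merge(vpc$stats, vpc$bins[, c("bin", "t_lo", "t_hi", "n_obs")],
               by = "bin")
  out <- out[order(out$bin, out$stat), ]
  utils::write.csv(out, path, row.names = FALSE)
  med <- vpc$stats[vpc$stats$stat == "p50", ]
  jsonlite::write_json(
    list(n_bins = nrow(vpc$bins), n_sim = vpc$n_sim, seed = vpc$seed,
         median_inside_band = sum(med$observed >= med$band_lo &
                                    med$observed <= med$band_hi)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Goodness-of-fit residual table
#'
#' Per observation: the population prediction (PRED, random effects at
#' zero), individual prediction (IPRED, at the empirical Bayes mode),
#' individual weighted residual IWRES = (DV - IPRED) / SD(DV | IPRED), and
#' the conditional weighted residual CWRES from the first-order
#' linearization of the model about the conditional mode.
#'
#' @param fit a \code{poppk_fit} or a \code{\link{population_model}}
#' @param data a \code{pk_dataset}
#' @return data.frame with ID, TIME, DV, PRED, IPRED, IWRES, CWRES
#' @export
gof_residuals <- function(fit, data) {
  pop <- if (inherits(fit, "poppk_fit")) fit$pop else fit
  ctl <- .default_fit_control()
  prep <- .prep_subjects(data)
  omega_act <- pop$omega[pop$omega > 0]
  q <- length(omega_act)
  out <- vector("list", length(prep))
  for (i in seq_along(prep)) {
    s <- prep[[i]]
    if (!length(s$dv)) next
    predi <- .subject_conc(pop, s, NULL)
    if (q > 0L) {
      r <- .inner_laplace(pop, s, stats::setNames(numeric(q),
                                                  names(omega_act)),
                          omega_act, ctl)
      eta <- r$eta
      ipred <- r$ipred
      # linearization about the EBE
      J <- matrix(0, length(s$dv), q)
      parts <- .conc_parts(pop, s, eta)
      for (k in seq_len(q)) {
        if (names(omega_act)[k] == "F") {
          J[, k] <- parts$F * parts$cpo
        } else {
          h <- ctl$fd_step
          ep <- eta; ep[k] <- ep[k] + h
          em <- eta; em[k] <- em[k] - h
          pp <- .conc_parts(pop, s, ep)
          pm <- .conc_parts(pop, s, em)
          J[, k] <- ((pp$civ + pp$F * pp$cpo) -
                       (pm$civ + pm$F * pm$cpo)) / (2 * h)
        }
      }
      rstar <- (s$dv - ipred) + as.vector(J %*% eta)
      V <- J %*% (omega_act * t(J)) + diag(.res_sd(ipred, pop)^2,
                                           length(ipred))
      cwres <- tryCatch(
        as.vector(forwardsolve(t(chol(V)), rstar)),
        error = function(e) rep(NA_real_, length(rstar)))
    } else {
      ipred <- predi
      cwres <- (s$dv - ipred) / .res_sd(ipred, pop)
    }
    out[[i]] <- data.frame(ID = s$id, TIME = s$obs_time, DV = s$dv,
                           PRED = predi, IPRED = ipred,
                           IWRES = (s$dv - ipred) / .res_sd(ipred, pop),
                           CWRES = cwres)
  }
  do.call(rbind, out)
}
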