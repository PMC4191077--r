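#' Maximum observed concentration
#'
#' The greatest observed plasma concentration after dosing and its time;
#' ties are resolved to the earliest time.
#'
#' @param profile Data frame with columns `time_h` and `conc_uM` (missing
#'   values allowed), e.g. one analyte of [simulate_subject()].
#' @return List with `cmax_uM` and `tmax_h`.
#' @export
cmax <- function(profile) {
  t <- profile$time_h
  c <- profile$conc_uM
  ok <- !is.na(c)
  if (!any(ok)) stop("profile has no observations")
  i <- which(ok)[which.max(c[ok])]
  list(cmax_uM = c[i], tmax_h = t[i])
}

#' Linear trapezoidal AUC to the last measurable concentration
#'
#' Sums `(t_{i+1} - t_i) * (C_i + C_{i+1}) / 2` over consecutive non-missing
#' observations (below-LOQ samples enter as `NA` and are skipped, so missing
#' intermediate samples are spanned by a single trapezoid; recorded zeros,
#' including the t = 0 baseline, are integrated as observations).
#'
#' @param times_h Increasing sampling times, hours.
#' @param conc_uM Concentrations, uM (`NA` = missing/below LOQ).
#' @return AUC in h uM.
#' @export
auc_linear_trapezoid <- function(times_h, conc_uM) {
  stopifnot(length(times_h) == length(conc_uM))
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  keep <- which(!is.na(conc_uM))
  if (length(keep) < 2) stop("need at least 2 non-missing points")
  t <- times_h[keep]
  c <- conc_uM[keep]
  sum(diff(t) * (c[-length(c)] + c[-1]) / 2)
}

# r-squared of ln(C) ~ t without lm() summary machinery (avoids warnings on
# exact fits); returns slope, r2 and adjusted r2.
loglinear_fit <- function(t, c) {
  y <- log(c)
  n <- length(t)
  fit <- stats::lm.fit(cbind(1, t), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (!is.na(r2) && n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = fit$coefficients[2], r2 = r2, adj_r2 = adj)
}

#' Terminal slope (lambda-z) of the log-linear concentration decay
#'
#' Ordinary least-squares regression of `ln(C)` on time over the selected
#' terminal points; `k` is the negative of the slope. The default selection
#' searches the last 3 to `n_max` positive observations at or after tmax and
#' keeps the subset with the best adjusted r-squared (ties resolved toward
#' more points); `n_fixed` instead regresses over exactly the last n
#' positive observations.
#'
#' @param times_h,conc_uM Observation vectors (`NA` = missing).
#' @param selection List: `n_fixed` (use exactly the last n points) or
#'   `n_min`/`n_max` bounds for the best-r-squared search (defaults 3 and 8).
#' @return List with `k` (1/h), `r_squared`, `n_points`, and `c_last_uM`,
#'   `t_last_h` (the last measurable observation). If the best fit has
#'   non-positive `k` the result carries `k = NA` and `flag =
#'   "nonpositive_terminal_slope"`.
#' @export
terminal_slope <- function(times_h, conc_uM, selection = list()) {
  stopifnot(length(times_h) == length(conc_uM))
  pos <- which(!is.na(conc_uM) & conc_uM > 0)
  if (length(pos) < 3) stop("need at least 3 positive terminal points")
  imax <- pos[which.max(conc_uM[pos])]
  cand <- pos[pos >= imax]
  if (length(cand) < 3) cand <- utils::tail(pos, 3)
  res <- function(idx, fit) {
    k <- -fit$slope
    if (!is.finite(k) || k <= 0) {
      list(k = NA_real_, r_squared = fit$r2, n_points = length(idx),
           c_last_uM = conc_uM[max(pos)], t_last_h = times_h[max(pos)],
           flag = "nonpositive_terminal_slope")
    } else {
      list(k = unname(k), r_squared = unname(fit$r2),
           n_points = length(idx), c_last_uM = conc_uM[max(pos)],
           t_last_h = times_h[max(pos)], flag = NA_character_)
    }
  }
  if (!is.null(selection$n_fixed)) {
    idx <- utils::tail(pos, selection$n_fixed)
    if (length(idx) < 3) stop("fewer than 3 points available")
    return(res(idx, loglinear_fit(times_h[idx], conc_uM[idx])))
  }
  n_min <- if (is.null(selection$n_min)) 3L else selection$n_min
  n_max <- if (is.null(selection$n_max)) 8L else selection$n_max
  best <- NULL
  best_idx <- NULL
  for (n in seq(n_min, min(n_max, length(cand)))) {
    idx <- utils::tail(cand, n)
    fit <- loglinear_fit(times_h[idx], conc_uM[idx])
    if (is.na(fit$adj_r2)) next
    if (is.null(best) || fit$adj_r2 >= best$adj_r2 - 1e-12) {
      best <- fit
      best_idx <- idx
    }
  }
  if (is.null(best)) stop("terminal regression failed")
  res(best_idx, best)
}

#' Extrapolated AUC beyond the last measurable concentration
#'
#' `C_last / k`, the area of the terminal mono-exponential tail.
#'
#' @param c_last_uM Last measurable concentration, uM.
#' @param k Terminal slope, 1/h (> 0).
#' @return AUC contribution in h uM.
#' @export
auc_extrapolate <- function(c_last_uM, k) {
  if (!is.finite(k) || k <= 0) stop("terminal slope must be positive")
  stopifnot(c_last_uM >= 0)
  c_last_uM / k
}

#' Non-compartmental analysis of one subject profile
#'
#' Composes [cmax()], [auc_linear_trapezoid()], [terminal_slope()] and
#' [auc_extrapolate()] into the standard parameter set:
#' `AUC_0-inf = AUC_0-Clast + AUC_Clast-inf`, `CL = dose / AUC_0-inf`,
#' `Vc = dose / Cmax`, and `t1/2 = ln(2) * Vc / CL` (the study's reporting
#' convention; algebraically `ln(2) * AUC_0-inf / Cmax`). The conventional
#' `ln(2)/k` half-life is reported alongside as `t_half_lambda_h`. All four
#' identities hold exactly by construction.
#'
#' Any component failure (too few terminal points, non-positive slope, ...)
#' yields a diagnostic record of class `hemopk_nca_failure` instead of an
#' error, so group-level analyses can continue.
#'
#' @param profile Data frame with `time_h`, `conc_uM`.
#' @param dose_umol_heme Administered dose in umol heme (> 0).
#' @param selection Terminal-point selection, see [terminal_slope()].
#' @return A list of class `hemopk_pk` (or `hemopk_nca_failure`).
#' @export
nca_subject <- function(profile, dose_umol_heme, selection = list()) {
  if (!is.numeric(dose_umol_heme) || dose_umol_heme <= 0) {
    stop("dose must be positive")
  }
  subject <- if (!is.null(profile$subject_id)) profile$subject_id[1] else NA
  analyte <- if (!is.null(profile$analyte)) profile$analyte[1] else NA
  out <- try({
    cm <- cmax(profile)
    auc_obs <- auc_linear_trapezoid(profile$time_h, profile$conc_uM)
    ts <- terminal_slope(profile$time_h, profile$conc_uM, selection)
    if (!is.na(ts$flag)) stop(ts$flag)
    auc_ext <- auc_extrapolate(ts$c_last_uM, ts$k)
    auc_inf <- auc_obs + auc_ext
    cl <- dose_umol_heme / auc_inf
    vc <- dose_umol_heme / cm$cmax_uM
    structure(list(
      subject_id = subject, analyte = analyte,
      cmax_uM = cm$cmax_uM, tmax_h = cm$tmax_h,
      auc_0_clast = auc_obs, auc_clast_inf = auc_ext, auc_0_inf = auc_inf,
      k_terminal = ts$k, r_squared = ts$r_squared,
      n_terminal_points = ts$n_points,
      cl_L_per_h = cl, vc_L = vc,
      t_half_h = log(2) * vc / cl,
      t_half_lambda_h = log(2) / ts$k,
      pct_extrapolated = 100 * auc_ext / auc_inf,
      dose_umol = dose_umol_heme), class = "hemopk_pk")
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    structure(list(subject_id = subject, analyte = analyte,
                   message = conditionMessage(attr(out, "condition"))),
              class = "hemopk_nca_failure")
  } else {
    out
  }
}

#' Aggregate per-subject PK parameters to a group summary
#'
#' Mean and SEM (`sd / sqrt(n)`, sample sd) per parameter over the subjects
#' with a successful analysis; failed subjects are counted but excluded.
#' With a single subject the SEM is reported missing.
#'
#' @param params List of [nca_subject()] results.
#' @return Data frame with one row per parameter: `parameter`, `mean`,
#'   `sem`, `n`. The number of excluded (failed) subjects is attached as
#'   attribute `n_failed`.
#' @export
aggregate_group <- function(params) {
  if (length(params) == 0) stop("empty parameter list")
  ok <- params[vapply(params, inherits, logical(1), "hemopk_pk")]
  n_failed <- length(params) - length(ok)
  if (length(ok) == 0) stop("no successful subjects to aggregate")
  fields <- c("cmax_uM", "auc_0_inf", "cl_L_per_h", "vc_L", "t_half_h",
              "auc_0_clast", "auc_clast_inf", "k_terminal",
              "t_half_lambda_h", "pct_extrapolated")
  rows <- lapply(fields, function(f) {
    v <- vapply(ok, function(p) p[[f]], numeric(1))
    data.frame(parameter = f, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}
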