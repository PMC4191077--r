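#' The default blood-sampling schedule (hours)
#'
#' Baseline (t = 0) plus 21 post-dose samples: 5 min, 0.25, 0.5, 0.75, 1.0,
#' 1.5, 2.0, 2.5, 3, 3.5, 4.0, 5.0, 6.0, 8.0, 12, 16, 24, 32, 36, 48 and
#' 60 h.
#'
#' @return Numeric vector of 22 strictly increasing times in hours.
#' @export
default_schedule_h <- function() {
  c(0, 1 / 12, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4,
    5, 6, 8, 12, 16, 24, 32, 36, 48, 60)
}

#' Build a validated study-arm configuration
#'
#' Defines one dosing arm of an intravascular Hb exposure study: a zero-order
#' Hb infusion, an optional Hp infusion starting when the Hb infusion ends,
#' irreversible second-order Hb:Hp binding, first-order disappearance of
#' unbound Hb (lumping renal loss and extravasation), and clearance of the
#' complex that is either first-order or saturable (Michaelis-Menten).
#'
#' Haptoglobin is expressed in micromolar heme-binding-site equivalents, so
#' 1:1 binding with heme collapses to a single bimolecular term. Binding is
#' treated as irreversible (the Hb:Hp interaction is effectively
#' non-dissociating on the study time scale).
#'
#' @param hb_dose_g Hb dose in grams.
#' @param hp_dose_g Hp dose in grams (0 for no exogenous Hp).
#' @param hb_infusion_min,hp_infusion_min Infusion durations in minutes; the
#'   Hp infusion starts when the Hb infusion ends.
#' @param plasma_volume_L Plasma volume in liters (default 0.8, Beagle-scale).
#' @param basal_hp_uM Endogenous Hp at t = 0, in uM binding-site equivalents.
#' @param k_on Bimolecular association rate, L/(umol h).
#' @param k_el_free First-order elimination of unbound Hb, 1/h.
#' @param complex_clearance_mode `"first_order"` or `"michaelis_menten"`.
#' @param k_el_complex First-order complex clearance rate, 1/h (default
#'   `log(2)/12`, a 12 h half-life).
#' @param vmax,km Saturable clearance parameters, umol/(L h) and umol/L.
#' @param noise_cv Proportional (lognormal) measurement error CV.
#' @param loq_uM Limit of quantification; sampled values below it are
#'   reported missing (`NA`).
#' @param n_subjects Subjects in the arm.
#' @param seed Integer study seed; per-subject seeds are `seed + index`.
#' @param schedule_h Sampling times in hours, strictly increasing, starting
#'   at 0.
#' @param hb_mw_g_per_mol,hemes_per_tetramer Conversion constants for the
#'   heme-equivalent dose.
#' @param hp_umol_sites_per_g Hp binding capacity per gram (default: one gram
#'   Hp binds one gram Hb).
#' @return A list of class `hemopk_config`.
#' @export
study_config <- function(hb_dose_g = 4,
                         hp_dose_g = 0,
                         hb_infusion_min = 10,
                         hp_infusion_min = 10,
                         plasma_volume_L = 0.8,
                         basal_hp_uM = 90,
                         k_on = 0.2,
                         k_el_free = 0.8,
                         complex_clearance_mode = c("first_order",
                                                    "michaelis_menten"),
                         k_el_complex = log(2) / 12,
                         vmax = 13,
                         km = 150,
                         noise_cv = 0.1,
                         loq_uM = 1,
                         n_subjects = 6,
                         seed = 1L,
                         schedule_h = default_schedule_h(),
                         hb_mw_g_per_mol = 64458,
                         hemes_per_tetramer = 4,
                         hp_umol_sites_per_g = NULL) {
  complex_clearance_mode <- match.arg(complex_clearance_mode)
  if (is.null(hp_umol_sites_per_g)) {
    hp_umol_sites_per_g <- hb_grams_to_umol_heme(1, hb_mw_g_per_mol,
                                                 hemes_per_tetramer)
  }
  nonneg <- c(hb_dose_g = hb_dose_g, hp_dose_g = hp_dose_g,
              plasma_volume_L = plasma_volume_L, basal_hp_uM = basal_hp_uM,
              k_on = k_on, k_el_free = k_el_free, k_el_complex = k_el_complex,
              vmax = vmax, km = km, noise_cv = noise_cv, loq_uM = loq_uM)
  if (any(nonneg < 0)) {
    stop("negative value for: ", paste(names(nonneg)[nonneg < 0],
                                       collapse = ", "))
  }
  if (plasma_volume_L <= 0) stop("plasma_volume_L must be positive")
  if (hb_infusion_min <= 0 || hp_infusion_min <= 0) {
    stop("infusion durations must be positive")
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(schedule_h) < 2 || any(diff(schedule_h) <= 0)) {
    stop("schedule_h must be strictly increasing")
  }
  if (schedule_h[1] != 0) stop("schedule_h must start at the t = 0 baseline")
  cfg <- list(
    hb_dose_g = hb_dose_g, hp_dose_g = hp_dose_g,
    hb_infusion_min = hb_infusion_min, hp_infusion_min = hp_infusion_min,
    plasma_volume_L = plasma_volume_L, basal_hp_uM = basal_hp_uM,
    k_on = k_on, k_el_free = k_el_free,
    complex_clearance_mode = complex_clearance_mode,
    k_el_complex = k_el_complex, vmax = vmax, km = km,
    noise_cv = noise_cv, loq_uM = loq_uM,
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    schedule_h = as.numeric(schedule_h),
    hb_mw_g_per_mol = hb_mw_g_per_mol,
    hemes_per_tetramer = hemes_per_tetramer,
    hp_umol_sites_per_g = hp_umol_sites_per_g,
    hb_dose_umol = hb_grams_to_umol_heme(hb_dose_g, hb_mw_g_per_mol,
                                         hemes_per_tetramer),
    hp_dose_umol_sites = hp_grams_to_umol_sites(hp_dose_g,
                                                hp_umol_sites_per_g)
  )
  class(cfg) <- "hemopk_config"
  cfg
}

#' Zero-order infusion rate
#'
#' Rate of drug input at time `t` for a constant-rate infusion of
#' `dose_umol_heme` starting at `start_h` and lasting `duration_h`: the rate
#' is `dose/duration` inside `[start, start + duration)` and 0 outside, so
#' its time integral equals the dose.
#'
#' @param t Time(s) in hours (vectorized).
#' @param dose_umol_heme Total dose, umol heme.
#' @param start_h Infusion start, hours.
#' @param duration_h Infusion duration, hours (> 0).
#' @return Infusion rate(s) in umol/h.
#' @export
infusion_rate <- function(t, dose_umol_heme, start_h = 0, duration_h = 1 / 6) {
  if (duration_h <= 0) stop("duration_h must be positive")
  if (dose_umol_heme < 0) stop("dose must be non-negative")
  ifelse(t >= start_h & t < start_h + duration_h,
         dose_umol_heme / duration_h, 0)
}

# Cumulative amount infused by time t (analytic; used for mass-balance checks).
cumulative_infused <- function(t, dose_umol, start_h, duration_h) {
  pmin(pmax(t - start_h, 0), duration_h) / duration_h * dose_umol
}

# Right-hand side of the kinetic model. States in uM (plasma concentration)
# except `elim`, the cumulative eliminated heme also expressed as uM
# equivalents of the plasma volume. Infusion rates (`in_hb`, `in_hp`, uM/h)
# are constant within an integration segment.
hemopk_rhs <- function(t, y, p) {
  in_hb <- p$in_hb
  in_hp <- p$in_hp
  bind <- p$k_on * y[["hb"]] * y[["hp"]]
  el_c <- if (p$mode == "first_order") {
    p$k_el_complex * y[["complex"]]
  } else {
    p$vmax * y[["complex"]] / (p$km + y[["complex"]])
  }
  el_f <- p$k_el_free * y[["hb"]]
  list(c(hb = in_hb - bind - el_f,
         hp = in_hp - bind,
         complex = bind - el_c,
         elim = el_f + el_c))
}

# Integrate the model on a dense grid that contains the sampling schedule and
# the infusion breakpoints. Integration is done piecewise between rate
# discontinuities so the stiff solver never steps across a jump.
integrate_model <- function(config, rtol = 1e-8, atol = 1e-10) {
  p <- list(hb_dose_umol = config$hb_dose_umol,
            hp_dose_umol_sites = config$hp_dose_umol_sites,
            hb_dur_h = config$hb_infusion_min / 60,
            hp_dur_h = config$hp_infusion_min / 60,
            V = config$plasma_volume_L,
            k_on = config$k_on, k_el_free = config$k_el_free,
            mode = config$complex_clearance_mode,
            k_el_complex = config$k_el_complex,
            vmax = config$vmax, km = config$km)
  t_end <- max(config$schedule_h)
  breaks <- unique(pmin(c(0, p$hb_dur_h,
                          if (p$hp_dose_umol_sites > 0)
                            p$hb_dur_h + p$hp_dur_h),
                        t_end))
  breaks <- sort(c(breaks, t_end))
  dense <- sort(unique(c(config$schedule_h, breaks,
                         seq(0, min(2, t_end), by = 0.01),
                         seq(0, t_end, length.out = 481))))
  y <- c(hb = 0, hp = config$basal_hp_uM, complex = 0, elim = 0)
  out <- NULL
  for (i in seq_len(length(breaks) - 1)) {
    seg <- dense[dense >= breaks[i] & dense <= breaks[i + 1]]
    seg <- sort(unique(c(breaks[i], seg, breaks[i + 1])))
    # rates are constant between breakpoints; evaluate at the midpoint
    mid <- (breaks[i] + breaks[i + 1]) / 2
    p$in_hb <- infusion_rate(mid, p$hb_dose_umol, 0, p$hb_dur_h) / p$V
    p$in_hp <- if (p$hp_dose_umol_sites > 0) {
      infusion_rate(mid, p$hp_dose_umol_sites, p$hb_dur_h, p$hp_dur_h) / p$V
    } else 0
    sol <- deSolve::lsoda(y, seg, hemopk_rhs, parms = p,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failed for config: hb_dose_g=",
           config$hb_dose_g, " hp_dose_g=", config$hp_dose_g,
           " mode=", config$complex_clearance_mode)
    }
    sol <- as.data.frame(sol)
    y <- unlist(sol[nrow(sol), c("hb", "hp", "complex", "elim")])
    names(y) <- c("hb", "hp", "complex", "elim")
    out <- if (is.null(out)) sol else rbind(out, sol[-1, ])
  }
  out[!duplicated(out$time), ]
}

# Multiplicative lognormal error with unit mean and coefficient of variation
# cv; below-LOQ values (other than true zeros) become NA.
apply_measurement_error <- function(conc, cv, loq) {
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    conc <- conc * stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
  }
  conc[conc > 0 & conc < loq] <- NA_real_
  conc
}

new_profile <- function(subject_id, analyte, times_h, conc_uM) {
  structure(data.frame(subject_id = subject_id, analyte = analyte,
                       time_h = times_h, conc_uM = conc_uM,
                       stringsAsFactors = FALSE),
            class = c("hemopk_profile", "data.frame"))
}

#' Simulate one subject of a study arm
#'
#' Integrates the binding/clearance model, samples the free-Hb and Hb:Hp
#' concentrations at the schedule, applies multiplicative lognormal
#' measurement error, and censors values below the LOQ. The noise-free state
#' trajectory and the generating rate constants are returned as ground truth.
#'
#' @param config A [study_config()].
#' @param subject_seed Integer seed for this subject's measurement error.
#' @param subject_id Identifier stored in the output profiles.
#' @return A list with elements `free`, `bound`, `total` (data frames with
#'   columns `subject_id`, `analyte`, `time_h`, `conc_uM`) and `truth` (dense
#'   noise-free trajectories plus true kinetic parameters).
#' @export
simulate_subject <- function(config, subject_seed, subject_id = "S1") {
  stopifnot(inherits(config, "hemopk_config"))
  traj <- integrate_model(config)
  idx <- match(config$schedule_h, traj$time)
  stopifnot(!anyNA(idx))
  free_true <- traj$hb[idx]
  bound_true <- traj$complex[idx]
  set.seed(as.integer(subject_seed %% .Machine$integer.max))
  free_obs <- apply_measurement_error(free_true, config$noise_cv,
                                      config$loq_uM)
  bound_obs <- apply_measurement_error(bound_true, config$noise_cv,
                                       config$loq_uM)
  total_obs <- ifelse(is.na(free_obs) & is.na(bound_obs), NA_real_,
                      ifelse(is.na(free_obs), 0, free_obs) +
                        ifelse(is.na(bound_obs), 0, bound_obs))
  k_term_complex <- if (config$complex_clearance_mode == "first_order") {
    config$k_el_complex
  } else {
    config$vmax / config$km
  }
  truth <- list(
    trajectory = traj,
    schedule_free_uM = free_true,
    schedule_bound_uM = bound_true,
    cl_free_L_h = config$k_el_free * config$plasma_volume_L,
    cl_complex_L_h = k_term_complex * config$plasma_volume_L,
    v_L = config$plasma_volume_L,
    k_free = config$k_el_free,
    k_complex_terminal = k_term_complex,
    dose_umol = config$hb_dose_umol
  )
  list(free = new_profile(subject_id, "free_hb", config$schedule_h, free_obs),
       bound = new_profile(subject_id, "bound_hb", config$schedule_h,
                           bound_obs),
       total = new_profile(subject_id, "total_hb", config$schedule_h,
                           total_obs),
       truth = truth)
}

#' Simulate all subjects of a study arm
#'
#' Per-subject seeds are derived reproducibly from the study seed as
#' `seed + subject index`, so the same configuration always yields identical
#' output.
#'
#' @param config A [study_config()].
#' @return A list of [simulate_subject()] results, one per subject, named
#'   `S1 ... Sn`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "hemopk_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(config, config$seed + i, sprintf("S%d", i))
  })
  names(subjects) <- sprintf("S%d", seq_len(config$n_subjects))
  subjects
}

#' Reference seven-arm study design
#'
#' The bundled study design: seven arms of Beagle-scale Hb exposure (4 g Hb
#' over 10 min), with or without 4 g Hp (dimeric or multimeric phenotype)
#' over the following 10 min, and with or without glucocorticoid
#' pre-treatment emulated as elevated basal Hp. Exogenous-Hp arms use
#' saturable complex clearance (one admissible mechanism for the two-phase
#' decay seen at high complex concentrations); endogenous-Hp arms use
#' first-order clearance.
#'
#' @param seed Study seed; arm seeds are offset from it.
#' @param noise_cv Measurement error CV applied to every arm.
#' @return Named list of arms, each with elements `config`, `phenotype` (SEC
#'   elution behavior of the complex) and `analytes` (which profiles are
#'   analyzed, mirroring the reported tables).
#' @export
reference_study_arms <- function(seed = 20140385, noise_cv = 0.1) {
  arm <- function(offset, n, basal, hp_g, mode, phenotype, analytes) {
    list(config = study_config(hb_dose_g = 4, hp_dose_g = hp_g,
                               basal_hp_uM = basal,
                               complex_clearance_mode = mode,
                               noise_cv = noise_cv, n_subjects = n,
                               seed = seed + offset),
         phenotype = phenotype, analytes = analytes)
  }
  list(
    dog_hb = arm(0, 4, 90, 0, "first_order", "dog", "total_hb"),
    human_hb = arm(100, 4, 90, 0, "first_order", "dog", "total_hb"),
    prednisone_dog_hb = arm(200, 6, 280, 0, "first_order", "dog",
                            c("free_hb", "bound_hb")),
    prednisone_human_hb = arm(300, 6, 280, 0, "first_order", "dog",
                              c("free_hb", "bound_hb")),
    human_hb_dimeric_hp = arm(400, 6, 90, 4, "michaelis_menten",
                              "human_dimeric", c("free_hb", "bound_hb")),
    human_hb_multimeric_hp = arm(500, 6, 90, 4, "michaelis_menten",
                                 "human_multimeric",
                                 c("free_hb", "bound_hb")),
    prednisone_human_hb_multimeric_hp = arm(600, 6, 280, 4,
                                            "michaelis_menten",
                                            "human_multimeric",
                                            c("free_hb", "bound_hb"))
  )
}
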