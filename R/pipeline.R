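#' Push one free/bound concentration pair through the measurement chain
#'
#' Forward-generates the raw measurements a plasma sample would produce —
#' an absorbance spectrum of its heme content (plus a turbidity blank) and a
#' SEC chromatogram — then inverts them exactly as the analysis prescribes:
#' blank correction and multi-component speciation give total heme; peak
#' integration and the percent-free formula partition it into free and
#' bound heme.
#'
#' @param free_uM,bound_uM True heme concentrations, uM.
#' @param phenotype SEC phenotype of the complex, see
#'   [generate_chromatogram()].
#' @param species_fractions Composition of the circulating heme used for the
#'   forward spectrum (default mostly ferrous with small ferric/hemichrome
#'   fractions, as in fresh plasma samples).
#' @param table Extinction table.
#' @param spec_noise_sd,sec_noise_sd Additive measurement noise (AU) on the
#'   spectrum and chromatogram.
#' @param seed Optional seed for the noise.
#' @return List with `total_heme_uM`, `pct_free`, `free_uM`, `bound_uM` as
#'   recovered by the chain.
#' @export
measure_sample_chain <- function(free_uM, bound_uM, phenotype = "dog",
                                 species_fractions = c(ferrous = 0.92,
                                                       ferric = 0.06,
                                                       hemichrome = 0.02),
                                 table = synthetic_extinction_table(),
                                 spec_noise_sd = 0, sec_noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  total <- free_uM + bound_uM
  conc <- species_fractions / sum(species_fractions) * total
  wl <- table$wavelength_nm
  # turbidity/background common to sample and blank
  blank_abs <- 0.05 + 2e-4 * (max(wl) - wl)
  samp <- forward_spectrum(conc, table)
  samp <- spectrum(wl, samp$absorbance_AU + blank_abs +
                     stats::rnorm(length(wl), 0, spec_noise_sd))
  blank <- spectrum(wl, blank_abs)
  speciation <- fit_species(blank_correct(samp, blank), table)
  total_est <- total_heme(speciation)
  if (total_est <= 0) { # blank sample
    return(list(total_heme_uM = 0, pct_free = NA_real_,
                free_uM = 0, bound_uM = 0))
  }
  chrom <- generate_chromatogram(free_uM, bound_uM, phenotype,
                                 noise_sd = sec_noise_sd)
  pct <- percent_free(integrate_peaks(chrom))
  if (is.na(pct)) {
    list(total_heme_uM = total_est, pct_free = NA_real_,
         free_uM = NA_real_, bound_uM = NA_real_)
  } else {
    part <- speciate_concentration(total_est, pct)
    list(total_heme_uM = total_est, pct_free = pct,
         free_uM = part$free_uM, bound_uM = part$bound_uM)
  }
}

# Re-measure a simulated subject through the spectral + SEC chain. Operates
# on the noise-free truth; measurement noise enters through the instrument
# noise arguments.
chain_measure_subject <- function(subject, phenotype, loq_uM = 1, ...) {
  free_t <- subject$truth$schedule_free_uM
  bound_t <- subject$truth$schedule_bound_uM
  free <- bound <- numeric(length(free_t))
  for (i in seq_along(free_t)) {
    m <- measure_sample_chain(free_t[i], bound_t[i], phenotype, ...)
    free[i] <- m$free_uM
    bound[i] <- m$bound_uM
  }
  # post-dose readouts below the LOQ (including peak areas clipped to zero)
  # are unquantifiable; the t = 0 baseline stays a recorded zero
  censor <- function(x) {
    x[seq_along(x) > 1 & x < loq_uM] <- NA_real_
    x
  }
  out <- subject
  out$free$conc_uM <- censor(free)
  out$bound$conc_uM <- censor(bound)
  out$total$conc_uM <- censor(free + bound)
  out
}

#' Run a full multi-arm study
#'
#' Simulates every arm, optionally replaces the sampled concentrations by
#' the spectral + SEC measurement-chain readout, performs per-subject NCA on
#' each arm's analytes, and aggregates to mean +/- SEM group summaries. The
#' run is deterministic given the arm seeds.
#'
#' @param arms Arm list as produced by [reference_study_arms()] (or loaded
#'   with [load_study_arms()]); default the bundled seven-arm design.
#' @param measurement_chain If `TRUE`, concentrations are passed through the
#'   forward spectrum/chromatogram models and re-derived; if `FALSE`
#'   (default), NCA runs directly on the sampled concentrations.
#' @param out_dir Optional directory; if given, per-subject profile CSVs
#'   (`time_h,conc_uM`), per-subject PK and group-summary CSVs and a run
#'   manifest are written under it.
#' @param selection Terminal-slope selection, see [terminal_slope()].
#' @return List of class `hemopk_study`: per-arm results (`subjects`,
#'   `pk` per analyte, `summary` per analyte), the combined `group_table`
#'   (one row per arm x analyte x parameter), and `manifest`.
#' @export
run_study <- function(arms = reference_study_arms(),
                      measurement_chain = FALSE, out_dir = NULL,
                      selection = list()) {
  results <- list()
  failures <- character(0)
  for (arm_name in names(arms)) {
    arm <- arms[[arm_name]]
    res <- try({
      subjects <- simulate_study(arm$config)
      if (measurement_chain) {
        subjects <- lapply(subjects, chain_measure_subject,
                           phenotype = arm$phenotype,
                           loq_uM = arm$config$loq_uM)
      }
      dose <- arm$config$hb_dose_umol
      pk <- list()
      summaries <- list()
      missing_analytes <- character(0)
      for (analyte in arm$analytes) {
        key <- sub("_hb$", "", analyte)
        pk[[analyte]] <- lapply(subjects, function(s)
          nca_subject(s[[key]], dose, selection))
        smry <- tryCatch(aggregate_group(pk[[analyte]]),
                         error = function(e) NULL)
        if (is.null(smry)) {
          # e.g. an analyte only transiently above the LOQ in every subject
          missing_analytes <- c(missing_analytes, analyte)
        } else {
          summaries[[analyte]] <- smry
        }
      }
      list(subjects = subjects, pk = pk, summary = summaries,
           missing_analytes = missing_analytes,
           phenotype = arm$phenotype, config = arm$config)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("arm ", arm_name, " failed: ",
              conditionMessage(attr(res, "condition")))
      failures <- c(failures, arm_name)
    } else {
      results[[arm_name]] <- res
    }
  }
  parts <- unlist(lapply(names(results), function(a) {
    lapply(names(results[[a]]$summary), function(an) {
      cbind(arm = a, analyte = an, results[[a]]$summary[[an]])
    })
  }), recursive = FALSE)
  group_table <- if (length(parts)) do.call(rbind, parts) else NULL
  manifest <- list(
    arms = names(arms), failed_arms = failures,
    seeds = vapply(arms, function(a) a$config$seed, integer(1)),
    measurement_chain = measurement_chain,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- structure(list(arms = results, group_table = group_table,
                        manifest = manifest, failed_arms = failures),
                   class = "hemopk_study")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

# Flatten successful per-subject PK fits of a study into one data frame.
pk_table <- function(study) {
  rows <- list()
  for (a in names(study$arms)) {
    for (an in names(study$arms[[a]]$pk)) {
      for (p in study$arms[[a]]$pk[[an]]) {
        if (inherits(p, "hemopk_pk")) {
          rows[[length(rows) + 1]] <-
            cbind(arm = a, as.data.frame(p[lengths(p) == 1]))
        }
      }
    }
  }
  do.call(rbind, rows)
}

write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof_dir <- file.path(out_dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (a in names(study$arms)) {
    for (s in names(study$arms[[a]]$subjects)) {
      subj <- study$arms[[a]]$subjects[[s]]
      for (an in c("free", "bound", "total")) {
        utils::write.csv(
          subj[[an]][, c("time_h", "conc_uM")],
          file.path(prof_dir, sprintf("%s_%s_%s.csv", a, s, an)),
          row.names = FALSE)
      }
    }
  }
  utils::write.csv(pk_table(study),
                   file.path(out_dir, "pk_subjects.csv"), row.names = FALSE)
  utils::write.csv(study$group_table,
                   file.path(out_dir, "pk_group_summary.csv"),
                   row.names = FALSE)
  writeLines(yaml::as.yaml(study$manifest),
             file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Load a study-arm configuration from a YAML file
#'
#' The file maps arm names to [study_config()] arguments plus `phenotype`
#' and `analytes`; see `inst/extdata/reference_study.yaml` for the bundled
#' seven-arm design.
#'
#' @param path YAML file path.
#' @return Arm list suitable for [run_study()].
#' @export
load_study_arms <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(a) {
    phenotype <- a$phenotype %||% "dog"
    analytes <- unlist(a$analytes %||% "total_hb")
    a$phenotype <- NULL
    a$analytes <- NULL
    list(config = do.call(study_config, a), phenotype = phenotype,
         analytes = analytes)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Plot mean +/- SEM concentration-time profiles with terminal fits
#'
#' One panel per arm; one trace per analyte (free/bound/total) showing the
#' group mean and SEM at each sampled time, with the terminal-phase
#' single-exponential fit of the mean profile overlaid.
#'
#' @param study A `hemopk_study` from [run_study()].
#' @param file Optional file path (png/pdf); when `NULL` the ggplot object
#'   is returned without writing.
#' @param log_y Plot the concentration axis on a log scale.
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_profiles <- function(study, file = NULL, log_y = TRUE) {
  stopifnot(inherits(study, "hemopk_study"))
  if (length(study$arms) == 0) {
    warning("no arms to plot")
    return(invisible(NULL))
  }
  rows <- list()
  fits <- list()
  for (a in names(study$arms)) {
    arm <- study$arms[[a]]
    for (an in names(arm$pk)) {
      key <- sub("_hb$", "", an)
      mat <- vapply(arm$subjects, function(s) s[[key]]$conc_uM,
                    numeric(length(arm$config$schedule_h)))
      m <- rowMeans(mat, na.rm = TRUE)
      n_obs <- rowSums(!is.na(mat))
      sem <- apply(mat, 1, function(v)
        if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) /
          sqrt(sum(!is.na(v))) else NA_real_)
      t <- arm$config$schedule_h
      rows[[length(rows) + 1]] <- data.frame(
        arm = a, analyte = an, time_h = t,
        mean_uM = ifelse(n_obs > 0, m, NA), sem_uM = sem)
      ts <- try(terminal_slope(t, ifelse(n_obs > 0, m, NA)), silent = TRUE)
      if (!inherits(ts, "try-error") && !is.na(ts$k)) {
        tt <- seq(0, max(t), length.out = 200)
        c0 <- ts$c_last_uM * exp(ts$k * ts$t_last_h)
        fits[[length(fits) + 1]] <- data.frame(
          arm = a, analyte = an, time_h = tt, fit_uM = c0 * exp(-ts$k * tt))
      }
    }
  }
  df <- do.call(rbind, rows)
  if (log_y) df <- df[!is.na(df$mean_uM) & df$mean_uM > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_h, y = mean_uM,
                                        color = analyte)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_uM - sem_uM,
                                        ymax = mean_uM + sem_uM),
                           width = 0, na.rm = TRUE) +
    ggplot2::facet_wrap(~arm, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Plasma heme (µmol/L)",
                  color = NULL) +
    ggplot2::theme_bw()
  if (length(fits)) {
    fit_df <- do.call(rbind, fits)
    p <- p + ggplot2::geom_line(
      data = fit_df,
      ggplot2::aes(x = time_h, y = fit_uM,
                   color = analyte),
      linetype = 2, na.rm = TRUE)
  }
  if (log_y) {
    p <- p + ggplot2::scale_y_log10()
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 10, height = 7, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Read a concentration profile CSV
#'
#' Two-column CSV `time_h,conc_uM`; empty cells are missing observations.
#'
#' @param path CSV path.
#' @param subject_id,analyte Metadata attached to the profile.
#' @return Profile data frame as used by [nca_subject()].
#' @export
read_profile_csv <- function(path, subject_id = basename(path),
                             analyte = NA_character_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_h", "conc_uM") %in% names(d)))
  new_profile(subject_id, analyte, d$time_h, d$conc_uM)
}
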