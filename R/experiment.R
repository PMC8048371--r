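#' Configuration of a virtual test-retest experiment
#'
#' Describes a cohort of virtual subjects, each carrying subject-specific
#' compartment diffusivities (Gaussian jitter around the phantom values,
#' emulating biological inter-subject variation), scanned twice (test and
#' retest) with one or both DWI protocols.
#'
#' @param phantom A `phantom_spec` (defaults to [default_phantom()]).
#' @param protocols Character subset of `c("RAD", "EPI")`.
#' @param rad_params,epi_params `acq_params` for the two protocols.
#' @param model A `respiration_model`.
#' @param n_subjects Number of virtual subjects (the in-vivo design used 10
#'   per protocol).
#' @param subject_jitter Relative SD of the per-subject diffusivity jitter
#'   (default 0.15, giving a tumor inter-subject SD of about 0.2e-3 mm^2/s).
#' @param snr_target Target reference-compartment SNR used to calibrate the
#'   k-space noise; `NULL` keeps the `noise_sigma` already in the params
#'   (0 = noiseless).
#' @param ref_compartment Compartment used for SNR calibration.
#' @param seed Master seed; every random stage derives from it.
#' @param out_dir Optional directory for CSV outputs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = default_phantom(),
                              protocols = c("RAD", "EPI"),
                              rad_params = acq_params("RAD"),
                              epi_params = acq_params("EPI"),
                              model = respiration_model(),
                              n_subjects = 10L,
                              subject_jitter = 0.15,
                              snr_target = 20,
                              ref_compartment = "water",
                              seed = 1L,
                              out_dir = NULL) {
  structure(list(phantom = phantom, protocols = protocols,
                 rad_params = rad_params, epi_params = epi_params,
                 model = model, n_subjects = as.integer(n_subjects),
                 subject_jitter = subject_jitter, snr_target = snr_target,
                 ref_compartment = ref_compartment, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Schema and cross-field checks; returns findings instead of raising, so a
#' driver can report all problems at once. An empty character vector means the
#' configuration is valid.
#'
#' @param config An `experiment_config`.
#' @return Character vector of findings (empty when valid).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)
  if (!inherits(config$phantom, "phantom_spec")) add("phantom: not a phantom_spec")
  for (pname in c("rad_params", "epi_params")) {
    p <- config[[pname]]
    if (!inherits(p, "acq_params")) { add(paste0(pname, ": not acq_params")); next }
    if (p$delta_small >= p$delta_big)
      add(paste0(pname, ": delta_small (", p$delta_small,
                 " ms) must be < delta_big (", p$delta_big, " ms)"))
    if (any(diff(p$b_values) <= 0)) add(paste0(pname, ": b_values not strictly increasing"))
    if (p$protocol == "EPI" && p$matrix_phase %% p$n_shots != 0)
      add(paste0(pname, ": n_shots (", p$n_shots, ") does not divide matrix_phase (",
                 p$matrix_phase, ")"))
    if (p$gated) {
      sc <- try(schedule_acquisition(p, config$model), silent = TRUE)
      if (inherits(sc, "try-error"))
        add(paste0(pname, ": gating window shorter than readout (",
                   attr(sc, "condition")$message, ")"))
    }
  }
  if (config$n_subjects < 1) add("n_subjects must be >= 1")
  if (config$subject_jitter < 0) add("subject_jitter must be >= 0")
  if (is.null(config$seed) || is.na(config$seed)) add("seed must be set")
  findings
}

jittered_phantom <- function(phantom, rel_jitter) {
  comps <- lapply(phantom$compartments, function(cp) {
    cp$d_true <- max(cp$d_true * (1 + stats::rnorm(1, sd = rel_jitter)),
                     0.1 * cp$d_true)
    cp
  })
  phantom_spec(comps, fov = phantom$fov, field_strength = phantom$field_strength)
}

#' Run a simulated test-retest experiment end to end
#'
#' For each virtual subject and session (test, retest) and each requested
#' protocol: rasterize the subject's jittered phantom, simulate k-space under
#' the respiratory model, reconstruct, fit the three-parameter diffusion
#' model, and extract ROI-mean ADCs per compartment. Then compute the
#' repeatability statistics per tissue x protocol. Fully deterministic given
#' the config seed.
#'
#' @param config An `experiment_config` (validated first; any finding aborts).
#' @param verbose Print stage progress.
#' @return A list: `measurements` (subject/session/protocol/tissue ADC in
#'   1e-3 mm^2/s), `table` (tissue x protocol repeatability rows),
#'   `bland_altman` (per tissue x protocol), `config`. CSVs are written to
#'   `config$out_dir` when set.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  findings <- validate_config(config)
  if (length(findings) > 0)
    stop("stage config: invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  say <- function(...) if (verbose) message(sprintf(...))

  protos <- config$protocols
  params_list <- list(RAD = config$rad_params, EPI = config$epi_params)[protos]

  # calibrate noise once per protocol on the nominal phantom
  sigma <- list()
  base_maps <- list()
  for (pr in protos) {
    p <- params_list[[pr]]
    mt <- if (pr == "RAD") p$matrix_read else p$matrix_phase
    base_maps[[pr]] <- rasterize(config$phantom, mt)
    sigma[[pr]] <- if (is.null(config$snr_target)) p$noise_sigma else
      calibrate_noise_sigma(base_maps[[pr]], p, config$model, config$snr_target,
                            ref_compartment = config$ref_compartment)
    say("stage calibrate: %s noise_sigma = %.4g", pr, sigma[[pr]])
  }

  set.seed(config$seed)
  n <- config$n_subjects
  subject_specs <- lapply(seq_len(n), function(i)
    jittered_phantom(config$phantom, config$subject_jitter))
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                             n * 2 * length(protos)),
                  nrow = n)

  rows <- list()
  for (i in seq_len(n)) {
    col <- 0
    for (sess in c("test", "retest")) {
      for (pr in protos) {
        col <- col + 1
        p <- params_list[[pr]]
        p$noise_sigma <- sigma[[pr]]
        mt <- if (pr == "RAD") p$matrix_read else p$matrix_phase
        maps <- rasterize(subject_specs[[i]], mt)
        ks <- tryCatch({
          if (pr == "RAD") simulate_radial_kspace(maps, p, config$model, seed = seeds[i, col])
          else simulate_epi_kspace(maps, p, config$model, seed = seeds[i, col])
        }, error = function(e) stop("stage simulate: ", conditionMessage(e)))
        st <- tryCatch({
          if (pr == "RAD") fbp_reconstruct(ks) else epi_reconstruct(ks)
        }, error = function(e) stop("stage recon: ", conditionMessage(e)))
        pm <- tryCatch(fit_stack(st),
                       error = function(e) stop("stage fit: ", conditionMessage(e)))
        masks <- roi_masks(base_maps[[pr]], erode = 1L)
        tab <- tryCatch(roi_table(pm, masks),
                        error = function(e) stop("stage roi: ", conditionMessage(e)))
        say("stage roi: subject %d %s %s done (seed %d)", i, sess, pr, seeds[i, col])
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, session = sess, protocol = pr,
          tissue = tab$roi, adc = tab$mean)
      }
    }
  }
  meas <- do.call(rbind, rows)
  tab <- tryCatch(repeatability_table(meas),
                  error = function(e) stop("stage repeat: ", conditionMessage(e)))

  ba <- list()
  for (i in seq_len(nrow(tab))) {
    sub <- meas[meas$tissue == tab$tissue[i] & meas$protocol == tab$protocol[i], ]
    te <- sub[sub$session == "test", ]; re <- sub[sub$session == "retest", ]
    m <- merge(te[, c("subject", "adc")], re[, c("subject", "adc")], by = "subject")
    if (nrow(m) >= 2)
      ba[[paste(tab$tissue[i], tab$protocol[i], sep = "_")]] <-
        bland_altman(paired_measurements(m$adc.x, m$adc.y, subject = m$subject,
                                         tissue = tab$tissue[i]))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meas, file.path(config$out_dir, "cohort_measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(config$out_dir, "repeatability_table.csv"),
                     row.names = FALSE)
    bpts <- do.call(rbind, lapply(names(ba), function(nm)
      cbind(group = nm, ba[[nm]]$points,
            bias = ba[[nm]]$bias, upper = ba[[nm]]$upper, lower = ba[[nm]]$lower)))
    if (!is.null(bpts))
      utils::write.csv(bpts, file.path(config$out_dir, "bland_altman.csv"),
                       row.names = FALSE)
  }
  list(measurements = meas, table = tab, bland_altman = ba, config = config)
}
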