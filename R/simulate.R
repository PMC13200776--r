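# Synthetic-data generation: landmark recordings with planted per-region
# palsy severity, rater tables drawn from the two-way model, and
# longitudinal cohorts with known recovery trajectories and rater
# noise/bias, so every analysis step can be validated against planted
# ground truth.

#' Simulation configuration for a single recording battery
#'
#' @param severity Named or positional numeric vector of the true
#'   per-region symmetry ratios `c(forehead, eye, mouth)`, each in
#'   `[0, 1]` (1 = symmetric, 0 = complete regional paresis).
#' @param affected_side `"left"` or `"right"`.
#' @param landmark_noise_sd Isotropic Gaussian noise SD in mm added to
#'   every landmark coordinate of every movement frame; `>= 0`.
#' @param n_frames Frames per recording, `>= 2`; odd counts place a frame
#'   exactly at the activation peak.  Default 31 (5 s at 6 Hz plus the
#'   start frame).
#' @param duration Capture window in seconds; default 5.
#' @param peak_amplitude Healthy-side peak displacement in mm; default 8.
#' @param tasks `"diagnostic3"` (three grimaces, one per region) or
#'   `"training9"` (full battery).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(severity = c(forehead = 1, eye = 1, mouth = 1),
                              affected_side = "left",
                              landmark_noise_sd = 0,
                              n_frames = 31L,
                              duration = 5,
                              peak_amplitude = 8,
                              tasks = c("diagnostic3", "training9"),
                              seed = 1L) {
  severity <- as.numeric(severity)
  if (length(severity) != 3L || anyNA(severity) ||
      any(severity < 0 | severity > 1)) {
    stop("severity must be 3 values (forehead, eye, mouth) in [0, 1]",
         call. = FALSE)
  }
  names(severity) <- c("forehead", "eye", "mouth")
  affected_side <- match.arg(affected_side, c("left", "right"))
  tasks <- match.arg(tasks)
  stopifnot(landmark_noise_sd >= 0, n_frames >= 2L, duration > 0,
            peak_amplitude > 0)
  structure(list(
    severity = severity, affected_side = affected_side,
    landmark_noise_sd = landmark_noise_sd, n_frames = as.integer(n_frames),
    duration = duration, peak_amplitude = peak_amplitude,
    tasks = tasks, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Canonical mirror-symmetric neutral landmark set, millimetre scale.
# Three landmarks per region and side plus four non-collinear midline
# landmarks (the rigid-alignment reference).
canonical_face <- function() {
  lm <- landmark_set(
    id = c("browInnerL", "browMidL", "browOuterL",
           "browInnerR", "browMidR", "browOuterR",
           "eyeInnerL", "eyeOuterL", "lidUpperL",
           "eyeInnerR", "eyeOuterR", "lidUpperR",
           "mouthCornerL", "lipUpperL", "lipLowerL",
           "mouthCornerR", "lipUpperR", "lipLowerR",
           "noseTip", "noseBridge", "foreheadMid", "chin"),
    side = c(rep(c("left"), 3), rep("right", 3),
             rep("left", 3), rep("right", 3),
             rep("left", 3), rep("right", 3),
             rep("midline", 4)),
    region = c(rep("forehead", 6), rep("eye", 6), rep("mouth", 6),
               rep("other", 4))
  )
  # x: lateral (left positive), y: vertical (up positive), z: depth
  pos <- rbind(
    browInnerL  = c( 15,  45, 5), browMidL  = c( 30, 48, 3),
    browOuterL  = c( 45,  44, 0),
    browInnerR  = c(-15,  45, 5), browMidR  = c(-30, 48, 3),
    browOuterR  = c(-45,  44, 0),
    eyeInnerL   = c( 14,  30, 4), eyeOuterL = c( 42, 30, 0),
    lidUpperL   = c( 28,  36, 3),
    eyeInnerR   = c(-14,  30, 4), eyeOuterR = c(-42, 30, 0),
    lidUpperR   = c(-28,  36, 3),
    mouthCornerL = c( 25, -25, 2), lipUpperL = c( 10, -18, 6),
    lipLowerL    = c( 10, -32, 5),
    mouthCornerR = c(-25, -25, 2), lipUpperR = c(-10, -18, 6),
    lipLowerR    = c(-10, -32, 5),
    noseTip     = c(0,  0, 20), noseBridge = c(0, 25, 10),
    foreheadMid = c(0, 55,  2), chin       = c(0, -55, 4)
  )
  list(landmarks = lm, neutral = landmark_frame(0, pos))
}

# Unit displacement direction of a moving landmark: mostly vertical for
# forehead/eye tasks, lateral-vertical for mouth tasks; mirrored across
# the midline so the construction is exactly symmetric.
displacement_direction <- function(region, x_sign) {
  v <- switch(region,
    forehead = c(0, 1, 0.15),
    eye = c(0, -1, 0.1),
    mouth = c(0.8 * x_sign, 0.6, 0.2),
    c(0, 0, 0)
  )
  v / sqrt(sum(v^2))
}

#' Simulate one movement recording
#'
#' Builds the canonical mirror-symmetric neutral face and animates the
#' landmarks of the task's region with a smooth half-sine activation over
#' the capture window.  Healthy-side landmarks reach the configured peak
#' displacement; affected-side landmarks reach `peak * severity[region]`.
#' Landmarks of other regions and the midline stay at rest.  Isotropic
#' Gaussian noise of the configured SD is added to every coordinate of
#' every movement frame.  Output is deterministic for a fixed seed.
#'
#' @param config A `simulation_config`.
#' @param task One of the nine movement task names.
#' @return A `movement_recording`.
#' @export
simulate_recording <- function(config, task) {
  stopifnot(inherits(config, "simulation_config"))
  region <- task_region(task)
  face <- canonical_face()
  lm <- face$landmarks
  neutral <- face$neutral
  ids <- rownames(neutral$positions)
  healthy <- if (config$affected_side == "left") "right" else "left"

  # per-task RNG substream so batteries are reproducible task by task
  task_idx <- match(task, movement_tasks()$task)
  rng <- local_rng(config$seed + 1000L * task_idx)
  on.exit(rng(), add = TRUE)

  times <- seq(0, config$duration, length.out = config$n_frames)
  frames <- lapply(times, function(t) {
    act <- sin(pi * t / config$duration)  # half-sine activation in [0,1]
    pos <- neutral$positions
    for (i in which(lm$region == region & lm$side != "midline")) {
      id <- lm$id[i]
      peak <- config$peak_amplitude *
        if (lm$side[i] == healthy) 1 else config$severity[[region]]
      dir <- displacement_direction(region,
                                    x_sign = if (lm$side[i] == "left") 1 else -1)
      pos[id, ] <- pos[id, ] + act * peak * dir
    }
    if (config$landmark_noise_sd > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos), 0,
                                       config$landmark_noise_sd),
                          nrow = nrow(pos))
      rownames(pos) <- ids
    }
    landmark_frame(t, pos)
  })
  movement_recording(task, lm, neutral, frames, duration = config$duration)
}

#' Simulate a full recording battery
#'
#' One recording per task of the configured battery (`diagnostic3` or
#' `training9`).
#'
#' @param config A `simulation_config`.
#' @return Named list of `movement_recording`s.
#' @export
simulate_battery <- function(config) {
  task_names <- if (config$tasks == "diagnostic3") diagnostic_battery()
                else movement_tasks()$task
  stats::setNames(lapply(task_names, function(tk) {
    simulate_recording(config, tk)
  }), task_names)
}

# Run a block with a private RNG state; returns the restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulate a rater table from the two-way model
#'
#' Draws `value[i, j] = mu + subject[i] + rater[j] + error[i, j]` with
#' independent centred Gaussian components of the given SDs, the standard
#' generative model behind the two-way ICC.  The closed-form population
#' ICCs for these variance components are returned alongside the table.
#'
#' @param n Subjects. @param k Raters/measurements.
#' @param sigma_subject,sigma_rater,sigma_error Component SDs, `>= 0`.
#' @param mu Grand mean.
#' @param seed Integer seed.
#' @return List with `table` (a `rater_table`) and `population_icc`
#'   (named: `consistency_single`, `consistency_average`,
#'   `absolute_single`, `absolute_average`).
#' @export
simulate_rater_table <- function(n, k, sigma_subject, sigma_rater = 0,
                                 sigma_error = 1, mu = 50, seed = 1L) {
  stopifnot(n >= 2, k >= 2, sigma_subject >= 0, sigma_rater >= 0,
            sigma_error >= 0)
  rng <- local_rng(as.integer(seed))
  on.exit(rng(), add = TRUE)
  subj <- stats::rnorm(n, 0, sigma_subject)
  rat <- stats::rnorm(k, 0, sigma_rater)
  err <- matrix(stats::rnorm(n * k, 0, sigma_error), n, k)
  tab <- rater_table(mu + outer(subj, rat, `+`) + err)

  vs <- sigma_subject^2; vr <- sigma_rater^2; ve <- sigma_error^2
  pop <- c(
    consistency_single = vs / (vs + ve),
    consistency_average = vs / (vs + ve / k),
    absolute_single = vs / (vs + vr + ve),
    absolute_average = vs / (vs + (vr + ve) / k)
  )
  list(table = tab, population_icc = pop)
}

#' Cohort configuration for the longitudinal simulator
#'
#' Defaults emulate a small prospective cohort of acute unilateral facial
#' palsy: moderate baseline deficits, exponential recovery toward normal
#' function over a four-week follow-up, three raters scoring each visit on
#' the clinical scales, and an instrumented DFI measurement.
#'
#' @param n_patients Number of patients, `>= 1`.
#' @param baseline_mean,baseline_sd Mean/SD of the true baseline
#'   standardized score (percent intact function); draws are clamped to
#'   `[0, 95]`.
#' @param recovery_rate_mean,recovery_rate_sd Per-patient exponential
#'   recovery rate (1/day), log-normal across patients.
#' @param visit_days Strictly increasing visit times in days.
#' @param rater_bias Numeric vector, one additive bias (percent points)
#'   per rater; its length sets the number of raters.
#' @param rater_noise_sd Rater noise SD in percent points.
#' @param dfi_bias Systematic DFI offset in percent points (positive =
#'   DFI more optimistic than the truth).
#' @param dfi_noise_sd DFI measurement noise SD in percent points.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 21L,
                          baseline_mean = 40, baseline_sd = 15,
                          recovery_rate_mean = 0.1,
                          recovery_rate_sd = 0.04,
                          visit_days = c(0, 28),
                          rater_bias = c(0, 0, 0),
                          rater_noise_sd = 5,
                          dfi_bias = 0,
                          dfi_noise_sd = 5,
                          seed = 1L) {
  stopifnot(n_patients >= 1, baseline_sd >= 0, recovery_rate_mean > 0,
            recovery_rate_sd >= 0, length(visit_days) >= 1,
            !is.unsorted(visit_days, strictly = TRUE),
            length(rater_bias) >= 1, rater_noise_sd >= 0, dfi_noise_sd >= 0)
  structure(list(
    n_patients = as.integer(n_patients),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    recovery_rate_mean = recovery_rate_mean,
    recovery_rate_sd = recovery_rate_sd,
    visit_days = visit_days,
    rater_bias = rater_bias, rater_noise_sd = rater_noise_sd,
    dfi_bias = dfi_bias, dfi_noise_sd = dfi_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate a longitudinal cohort with rater scores
#'
#' Per patient, a true baseline standardized score is drawn and recovers
#' exponentially toward 100% at a patient-specific rate:
#' `truth(t) = 100 - (100 - baseline) * exp(-rate * t)`.  At each visit,
#' each rater observes `truth + bias + noise` and records it on each
#' clinical scale by inverting that scale's standardization (SI and HBS
#' discretize to their legal grades); the DFI measurement is
#' `truth + dfi_bias + noise`, clamped to `[0, 100]`.  Fixed seeds give
#' identical datasets.
#'
#' @param config A `cohort_config`.
#' @return A data frame with one row per patient x visit: `patient_id`,
#'   `visit_day`, `truth`, per-rater raw scores (`si_r1`, `hbs_r1`,
#'   `sfgs_r1`, ...), per-rater standardized percents (`rater1_pct`, ...),
#'   and `dfi`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  n <- config$n_patients
  k <- length(config$rater_bias)
  baseline <- pmin(pmax(stats::rnorm(n, config$baseline_mean,
                                     config$baseline_sd), 0), 95)
  # log-normal rates matching the requested mean/SD on the natural scale
  if (config$recovery_rate_sd > 0) {
    cv2 <- (config$recovery_rate_sd / config$recovery_rate_mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(config$recovery_rate_mean) - sdlog^2 / 2
    rate <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    rate <- rep(config$recovery_rate_mean, n)
  }

  rows <- list()
  for (i in seq_len(n)) {
    for (day in config$visit_days) {
      truth <- 100 - (100 - baseline[i]) * exp(-rate[i] * day)
      row <- list(patient_id = i, visit_day = day, truth = truth)
      for (r in seq_len(k)) {
        observed <- truth + config$rater_bias[r] +
          stats::rnorm(1, 0, config$rater_noise_sd)
        observed <- min(max(observed, 0), 100)
        si <- convert_score(clinical_score("SFGS", observed), "SI")$value
        hbs <- convert_score(clinical_score("SFGS", observed), "HBS")$value
        row[[paste0("si_r", r)]] <- si
        row[[paste0("hbs_r", r)]] <- hbs
        row[[paste0("sfgs_r", r)]] <- observed
        row[[paste0("rater", r, "_pct")]] <- observed
      }
      dfi <- truth + config$dfi_bias +
        stats::rnorm(1, 0, config$dfi_noise_sd)
      row$dfi <- min(max(dfi, 0), 100)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
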