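# Digital Facial Index: contralateral normalization of per-region movement
# amplitudes and the fixed 10/40/50 weighted composite.

#' Regional weights of the Digital Facial Index
#'
#' Fixed composite weights: forehead 10%, eye region 40%, mouth region 50%.
#' They sum to exactly 1.
#'
#' @return Named numeric vector `c(forehead, eye, mouth)`.
#' @export
dfi_weights <- function() {
  c(forehead = 0.10, eye = 0.40, mouth = 0.50)
}

#' Contralateral symmetry ratio of one region
#'
#' The affected-side amplitude is normalized by the contralateral
#' (healthy-side) amplitude and clipped to `[0, 1]`: a region moving more
#' on the affected side than on the healthy side is treated as fully
#' symmetric.  When both amplitudes fall below the dead-zone threshold the
#' region shows no evaluable motion and is scored as symmetric (ratio 1);
#' when only the affected amplitude is below threshold the region is scored
#' as complete paresis (ratio 0).
#'
#' @param affected Affected-side amplitude in mm, `>= 0`.
#' @param contralateral Healthy-side amplitude in mm, `>= 0`.
#' @param dead_zone Amplitudes below this (mm) count as no motion;
#'   default 0.5.
#' @return Ratio in `[0, 1]`.
#' @export
compute_symmetry_ratio <- function(affected, contralateral, dead_zone = 0.5) {
  stopifnot(is.numeric(affected), is.numeric(contralateral),
            is.finite(affected), is.finite(contralateral))
  if (affected < 0 || contralateral < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (contralateral < dead_zone) {
    return(1)  # no evaluable contralateral motion: not scorable as asymmetry
  }
  if (affected < dead_zone) {
    return(0)
  }
  min(affected / contralateral, 1)
}

#' Detect the affected hemiface from amplitudes
#'
#' Standalone use of the grading method must infer which side is paretic.
#' Per region the amplitudes of the two sides are compared; the side whose
#' regional amplitudes, weighted by the DFI composite weights, average
#' smaller is reported as affected.  An explicit override always wins.
#'
#' @param amplitudes Data frame with columns `region`, `side`, `amplitude`
#'   covering both sides of at least one region.
#' @param override Optional `"left"` or `"right"`; returned unchanged.
#' @return `"left"` or `"right"`.
#' @export
detect_affected_side <- function(amplitudes, override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("left", "right")))
  }
  w <- dfi_weights()
  score <- c(left = 0, right = 0)
  wsum <- c(left = 0, right = 0)
  for (i in seq_len(nrow(amplitudes))) {
    reg <- amplitudes$region[i]
    sd_ <- amplitudes$side[i]
    if (!reg %in% names(w) || !sd_ %in% c("left", "right")) next
    score[sd_] <- score[sd_] + w[[reg]] * amplitudes$amplitude[i]
    wsum[sd_] <- wsum[sd_] + w[[reg]]
  }
  if (any(wsum == 0)) {
    stop("amplitudes for both sides of at least one region are required",
         call. = FALSE)
  }
  m <- score / wsum
  if (isTRUE(all.equal(m[["left"]], m[["right"]]))) {
    stop("ambiguous side: weighted mean amplitudes are tied; ",
         "pass affected_side explicitly", call. = FALSE)
  }
  if (m[["left"]] < m[["right"]]) "left" else "right"
}

#' Compute the Digital Facial Index from a recording battery
#'
#' Each recording probes one facial region.  Per task, the affected and
#' contralateral amplitudes are extracted and turned into a symmetry ratio;
#' regions probed by several tasks use the mean of the per-task ratios.
#' The DFI is the weighted composite
#' `100 * (0.1 r_forehead + 0.4 r_eye + 0.5 r_mouth)`, expressed on a scale
#' from 0% (complete paresis) to 100% (intact facial function).
#'
#' The battery must cover all three regions; the minimal diagnostic set is
#' the three-grimace battery ([diagnostic_battery()]).
#'
#' @param recordings List of `movement_recording`s covering forehead, eye,
#'   and mouth.
#' @param affected_side Optional `"left"` or `"right"`.  When omitted, the
#'   side is inferred with [detect_affected_side()].
#' @param dead_zone Dead-zone threshold in mm for the symmetry ratio.
#' @return A list of class `dfi_result` with elements `dfi_percent`,
#'   `ratios` (named numeric), `affected_side`, `weights`, `amplitudes`
#'   (per task/region/side), and `tasks_used`.
#' @export
compute_dfi <- function(recordings, affected_side = NULL, dead_zone = 0.5) {
  if (inherits(recordings, "movement_recording")) {
    recordings <- list(recordings)
  }
  stopifnot(length(recordings) >= 1L)
  regions <- vapply(recordings, function(r) task_region(r$task), character(1))
  missing <- setdiff(c("forehead", "eye", "mouth"), unique(regions))
  if (length(missing)) {
    stop("incomplete task battery: missing region(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  amps <- do.call(rbind, lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    reg <- regions[i]
    rbind(
      cbind(task = rec$task, extract_region_amplitude(rec, reg, "left")),
      cbind(task = rec$task, extract_region_amplitude(rec, reg, "right"))
    )
  }))

  side <- detect_affected_side(amps, override = affected_side)
  contra <- if (side == "left") "right" else "left"

  per_task_ratio <- vapply(seq_along(recordings), function(i) {
    a <- amps[amps$task == recordings[[i]]$task & amps$side == side,
              "amplitude"]
    b <- amps[amps$task == recordings[[i]]$task & amps$side == contra,
              "amplitude"]
    compute_symmetry_ratio(a, b, dead_zone = dead_zone)
  }, numeric(1))

  w <- dfi_weights()
  ratios <- vapply(names(w), function(reg) {
    mean(per_task_ratio[regions == reg])
  }, numeric(1))

  dfi <- 100 * sum(w * ratios)
  structure(list(
    dfi_percent = dfi,
    ratios = ratios,
    affected_side = side,
    weights = w,
    amplitudes = amps,
    tasks_used = vapply(recordings, `[[`, character(1), "task")
  ), class = "dfi_result")
}

#' @export
print.dfi_result <- function(x, ...) {
  cat(sprintf("Digital Facial Index: %.1f%%  (affected side: %s)\n",
              x$dfi_percent, x$affected_side))
  for (reg in names(x$weights)) {
    cat(sprintf("  %-8s ratio %.3f  (weight %.0f%%)\n", reg,
                x$ratios[[reg]], 100 * x$weights[[reg]]))
  }
  invisible(x)
}

#' Exercise-execution accuracy feedback
#'
#' Percentage feedback for a training movement: the achieved affected-side
#' amplitude of the task's region relative to a reference amplitude, capped
#' at 100%.
#'
#' @param recording A `movement_recording` of the exercised task.
#' @param reference_amplitude Target amplitude in mm, `> 0`.
#' @param affected_side `"left"` or `"right"`.
#' @return Percent in `[0, 100]`.
#' @export
exercise_accuracy <- function(recording, reference_amplitude, affected_side) {
  if (!is.numeric(reference_amplitude) || reference_amplitude <= 0) {
    stop("reference_amplitude must be positive", call. = FALSE)
  }
  affected_side <- match.arg(affected_side, c("left", "right"))
  reg <- task_region(recording$task)
  achieved <- extract_region_amplitude(recording, reg,
                                       affected_side)$amplitude
  100 * min(achieved / reference_amplitude, 1)
}
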