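# Domain types for facial landmark geometry: landmark sets, time-stamped
# frames, and movement recordings.  Coordinates are millimetres in a
# right-handed, subject-centric frame ("left" is the subject's anatomical
# left).

FACE_SIDES   <- c("left", "right", "midline")
FACE_REGIONS <- c("forehead", "eye", "mouth", "other")

#' Facial movement tasks
#'
#' The standardized movement battery consists of nine training movements;
#' the diagnostic mode uses a three-grimace subset with one task per facial
#' region.  Each task probes exactly one region: eyebrow elevation probes
#' the forehead, eye closure the eye region, and the remaining six tasks
#' the mouth region.
#'
#' @format A data frame with columns `task` and `region`.
#' @export
movement_tasks <- function() {
  data.frame(
    task = c("eyebrow_elevation", "eye_closure", "cheek_inflation",
             "lip_pursing", "mouth_lateral_right", "mouth_lateral_left",
             "mouth_open_wide", "mouth_corner_elevation", "show_teeth"),
    region = c("forehead", "eye", rep("mouth", 7L)),
    stringsAsFactors = FALSE
  )
}

#' Region probed by a movement task
#'
#' @param task Task name, one of the nine standardized movements.
#' @return `"forehead"`, `"eye"`, or `"mouth"`.
#' @export
task_region <- function(task) {
  tab <- movement_tasks()
  i <- match(task, tab$task)
  if (is.na(i)) {
    stop("unknown movement task: ", task, call. = FALSE)
  }
  tab$region[i]
}

#' The three-grimace diagnostic battery
#'
#' One task per region: eyebrow elevation (forehead), eye closure (eye),
#' showing the teeth (mouth).
#'
#' @return Character vector of three task names.
#' @export
diagnostic_battery <- function() {
  c("eyebrow_elevation", "eye_closure", "show_teeth")
}

#' Construct a landmark annotation table
#'
#' Every landmark carries a side label (subject's own left/right, or
#' midline) and a region label.  Non-midline landmarks must come in mirror
#' pairs: for each left landmark a right landmark with the same region and
#' the same base identifier (side suffix stripped) must exist.
#'
#' @param id Character vector of landmark identifiers.
#' @param side Character vector, each `"left"`, `"right"`, or `"midline"`.
#' @param region Character vector, each `"forehead"`, `"eye"`, `"mouth"`,
#'   or `"other"`.
#' @param check If `TRUE` (default), enforce the mirror-pair invariant.
#' @return A data frame of class `landmark_set`.
#' @export
landmark_set <- function(id, side, region, check = TRUE) {
  id <- as.character(id)
  side <- as.character(side)
  region <- as.character(region)
  if (length(id) != length(side) || length(id) != length(region)) {
    stop("id, side and region must have equal length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate landmark ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  bad <- !side %in% FACE_SIDES
  if (any(bad)) {
    stop("invalid side label(s): ", paste(unique(side[bad]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !region %in% FACE_REGIONS
  if (any(bad)) {
    stop("invalid region label(s): ",
         paste(unique(region[bad]), collapse = ", "), call. = FALSE)
  }
  lm <- data.frame(id = id, side = side, region = region,
                   stringsAsFactors = FALSE)
  class(lm) <- c("landmark_set", "data.frame")
  if (check) mirror_pairs(lm)  # errors on an unpaired non-midline landmark
  lm
}

#' Mirror pairs of a landmark set
#'
#' Pairs each left landmark with its right partner.  Pairing is by shared
#' base identifier: the trailing side tag (`L`/`R`, `_l`/`_r`,
#' `_left`/`_right`, case-insensitive) is stripped and landmarks with equal
#' stems are matched.  Partners must share the region label.
#'
#' @param landmarks A `landmark_set`.
#' @return A data frame with columns `left`, `right`, `region`; zero rows
#'   if the set contains only midline landmarks.
#' @export
mirror_pairs <- function(landmarks) {
  lat <- landmarks[landmarks$side != "midline", , drop = FALSE]
  if (nrow(lat) == 0L) {
    return(data.frame(left = character(), right = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  stems <- mapply(strip_side_tag, lat$id, lat$side, USE.NAMES = FALSE)
  left  <- lat[lat$side == "left", , drop = FALSE]
  right <- lat[lat$side == "right", , drop = FALSE]
  lstem <- stems[lat$side == "left"]
  rstem <- stems[lat$side == "right"]
  j <- match(lstem, rstem)
  if (anyNA(j)) {
    stop("unpaired landmark: ", paste(left$id[is.na(j)], collapse = ", "),
         call. = FALSE)
  }
  unmatched_right <- setdiff(seq_len(nrow(right)), j)
  if (length(unmatched_right)) {
    stop("unpaired landmark: ",
         paste(right$id[unmatched_right], collapse = ", "), call. = FALSE)
  }
  if (any(left$region != right$region[j])) {
    bad <- left$id[left$region != right$region[j]]
    stop("mirror partners disagree on region: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(left = left$id, right = right$id[j], region = left$region,
             stringsAsFactors = FALSE)
}

# Strip a trailing side tag from a landmark id; falls back to the id itself
# when no recognizable tag is present (such ids can then only pair if the
# opposite side uses the identical id, which duplicate checking forbids).
strip_side_tag <- function(id, side) {
  patterns <- if (side == "left") {
    c("_left$", "_l$", "L$", "\\.l$")
  } else {
    c("_right$", "_r$", "R$", "\\.r$")
  }
  for (p in patterns) {
    if (grepl(p, id, ignore.case = (substr(p, 1, 1) == "_"))) {
      return(sub(p, "", id))
    }
  }
  id
}

#' Construct a landmark frame
#'
#' One time point of a recording: a timestamp and a 3-column coordinate
#' matrix (millimetres) with one named row per landmark.
#'
#' @param t Time in seconds, `>= 0`.
#' @param positions Numeric matrix, `n x 3`, rownames = landmark ids.
#' @return A list of class `landmark_frame`.
#' @export
landmark_frame <- function(t, positions) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) {
    stop("positions must have 3 columns (x, y, z)", call. = FALSE)
  }
  if (is.null(rownames(positions))) {
    stop("positions must have landmark ids as rownames", call. = FALSE)
  }
  if (!all(is.finite(positions))) {
    stop("non-finite coordinate in frame at t=", t, call. = FALSE)
  }
  structure(list(t = t, positions = positions), class = "landmark_frame")
}

#' Construct a movement recording
#'
#' A recording bundles a task label, a landmark annotation table, a neutral
#' (rest-face) frame, and a time-ordered sequence of movement frames.  All
#' frames must share the neutral frame's landmark id set.  The default
#' capture window is 5 seconds.
#'
#' @param task One of the nine movement task names.
#' @param landmarks A `landmark_set` covering every id in the frames.
#' @param neutral A `landmark_frame` holding the rest face.
#' @param frames List of `landmark_frame`s, non-empty, time-ordered.
#' @param duration Recording window in seconds, `> 0`; default 5.
#' @return A list of class `movement_recording`.
#' @export
movement_recording <- function(task, landmarks, neutral, frames,
                               duration = 5) {
  task_region(task)  # validates the task name
  stopifnot(inherits(landmarks, "landmark_set"),
            inherits(neutral, "landmark_frame"),
            is.list(frames), length(frames) >= 1L,
            is.numeric(duration), duration > 0)
  ids <- rownames(neutral$positions)
  if (!setequal(ids, landmarks$id)) {
    stop("neutral frame landmark ids do not match the landmark set",
         call. = FALSE)
  }
  times <- vapply(frames, function(f) f$t, numeric(1))
  if (is.unsorted(times)) {
    stop("frames are not time-ordered", call. = FALSE)
  }
  for (f in frames) {
    if (!setequal(rownames(f$positions), ids)) {
      stop("inconsistent landmark set: frame at t=", f$t,
           " does not match the neutral frame", call. = FALSE)
    }
  }
  structure(list(task = task, landmarks = landmarks, neutral = neutral,
                 frames = frames, duration = duration),
            class = "movement_recording")
}

#' @export
print.movement_recording <- function(x, ...) {
  cat("Movement recording:", x$task, "(", task_region(x$task), "region )\n")
  cat("  ", length(x$frames), "frames over", x$duration, "s;",
      nrow(x$landmarks), "landmarks\n")
  invisible(x)
}

# Least-squares rigid superposition (Kabsch): rotation + translation
# mapping the rows of `from` onto `to`.  Reflections are excluded by
# sign-correcting the smallest singular direction.  Needs >= 3
# non-collinear points for a unique rotation; with fewer the translation
# of centroids alone is returned.
rigid_transform <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3L, ncol(to) == 3L)
  cf <- colMeans(from)
  ct <- colMeans(to)
  if (nrow(from) < 3L) {
    return(list(R = diag(3), t = ct - cf))
  }
  A <- sweep(from, 2L, cf)
  B <- sweep(to, 2L, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = ct - as.vector(R %*% cf))
}

apply_rigid <- function(points, tf) {
  sweep(points %*% t(tf$R), 2L, tf$t, `+`)
}

# Align every frame of a recording to its neutral frame using the midline
# landmarks as the rigid reference, removing head motion before amplitude
# extraction.  With no midline landmarks the recording is returned as is.
align_recording <- function(recording) {
  mid_ids <- recording$landmarks$id[recording$landmarks$side == "midline"]
  if (length(mid_ids) == 0L) {
    return(recording)
  }
  ref <- recording$neutral$positions[mid_ids, , drop = FALSE]
  recording$frames <- lapply(recording$frames, function(f) {
    tf <- rigid_transform(f$positions[mid_ids, , drop = FALSE], ref)
    f$positions <- apply_rigid(f$positions, tf)
    f
  })
  recording
}

#' Extract a per-region, per-side movement amplitude
#'
#' For each landmark of the requested region and side, the maximum
#' Euclidean displacement (millimetres) from its neutral-frame position
#' across all movement frames is computed; the amplitude is the mean of
#' these per-landmark maxima.  Head motion is removed first by rigidly
#' aligning each frame's midline landmarks to the neutral frame
#' (least-squares superposition), so the amplitude is invariant under a
#' rigid transform applied to any frame.
#'
#' @param recording A `movement_recording`.
#' @param region `"forehead"`, `"eye"`, or `"mouth"`.
#' @param side `"left"` or `"right"`.
#' @param align Remove rigid head motion before measuring (default `TRUE`).
#' @return A one-row data frame with columns `region`, `side`, `amplitude`.
#' @export
extract_region_amplitude <- function(recording, region, side, align = TRUE) {
  stopifnot(inherits(recording, "movement_recording"))
  region <- match.arg(region, c("forehead", "eye", "mouth", "other"))
  side <- match.arg(side, c("left", "right"))
  lm <- recording$landmarks
  ids <- lm$id[lm$region == region & lm$side == side]
  if (length(ids) == 0L) {
    stop("empty region: no landmarks with region '", region,
         "' and side '", side, "'", call. = FALSE)
  }
  rec <- if (align) align_recording(recording) else recording
  ref <- rec$neutral$positions[ids, , drop = FALSE]
  max_disp <- rep(0, length(ids))
  for (f in rec$frames) {
    d <- f$positions[ids, , drop = FALSE] - ref
    disp <- sqrt(rowSums(d * d))
    max_disp <- pmax(max_disp, disp)
  }
  data.frame(region = region, side = side, amplitude = mean(max_disp),
             stringsAsFactors = FALSE)
}
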