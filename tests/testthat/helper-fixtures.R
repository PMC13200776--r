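# Shared fixture builders: hand-made landmark recordings and an
# independent ANOVA-based ICC oracle.

# A minimal face: one mirror pair per requested region plus three
# non-collinear midline landmarks (enough for exact rigid re-alignment).
make_face <- function(regions = c("forehead", "eye", "mouth"),
                      extra_pairs = 0L) {
  ids <- character(); sides <- character(); regs <- character()
  base_y <- c(forehead = 40, eye = 25, mouth = -25)
  pos <- NULL
  for (r in regions) {
    n_pairs <- 1L + extra_pairs
    for (p in seq_len(n_pairs)) {
      idL <- paste0(r, p, "L"); idR <- paste0(r, p, "R")
      ids <- c(ids, idL, idR)
      sides <- c(sides, "left", "right")
      regs <- c(regs, r, r)
      y <- base_y[[r]] + 3 * (p - 1)
      pos <- rbind(pos, c(20 + 5 * p, y, 3), c(-(20 + 5 * p), y, 3))
      rownames(pos)[nrow(pos) - 1:0] <- c(idL, idR)
    }
  }
  ids <- c(ids, "noseTip", "noseBridge", "chin")
  sides <- c(sides, "midline", "midline", "midline")
  regs <- c(regs, "other", "other", "other")
  pos <- rbind(pos, noseTip = c(0, 0, 20), noseBridge = c(0, 25, 10),
               chin = c(0, -55, 4))
  list(landmarks = landmark_set(ids, sides, regs),
       neutral = landmark_frame(0, pos))
}

# Build a recording where selected landmarks follow straight-line paths.
# displacements: named list id -> length-3 vector of the final offset; the
# path is linear from the neutral position, sampled over n_frames.
make_recording <- function(task = "eyebrow_elevation",
                           face = make_face(task_region(task)),
                           displacements = list(),
                           n_frames = 5L, duration = 5) {
  times <- seq(duration / n_frames, duration, length.out = n_frames)
  frames <- lapply(times, function(t) {
    pos <- face$neutral$positions
    frac <- t / duration
    for (id in names(displacements)) {
      pos[id, ] <- pos[id, ] + frac * displacements[[id]]
    }
    landmark_frame(t, pos)
  })
  movement_recording(task, face$landmarks, face$neutral, frames,
                     duration = duration)
}

# A noise-free diagnostic battery in which the affected-side landmark of
# each region reaches `ratio * 8` mm and the healthy side reaches 8 mm.
make_planted_battery <- function(ratios, affected = "left", peak = 8) {
  tasks <- diagnostic_battery()
  regions <- vapply(tasks, task_region, character(1))
  lapply(seq_along(tasks), function(i) {
    r <- regions[[i]]
    face <- make_face(r)
    dirs <- c(0, 1, 0)
    dl <- if (affected == "left") ratios[[r]] else 1
    dr <- if (affected == "right") ratios[[r]] else 1
    make_recording(tasks[[i]], face, displacements = stats::setNames(
      list(peak * dl * dirs, peak * dr * dirs),
      c(paste0(r, "1L"), paste0(r, "1R"))
    ))
  })
}

# Random rigid transform (uniform rotation via QR, bounded translation).
random_rigid <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = runif(3, -30, 30))
}

transform_frame <- function(frame, tf) {
  pos <- sweep(frame$positions %*% t(tf$R), 2, tf$t, `+`)
  landmark_frame(frame$t, pos)
}

transform_recording <- function(rec, tf, per_frame = FALSE) {
  rec$neutral <- transform_frame(rec$neutral, tf)
  rec$frames <- lapply(rec$frames, function(f) {
    this_tf <- if (per_frame) random_rigid() else tf
    transform_frame(f, this_tf)
  })
  rec
}

# Independent ICC oracle: mean squares from a stats::aov two-way
# decomposition (long-format fit), then the textbook ICC forms.  This
# route never touches the package's sums-of-squares code.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(value ~ subject + rater, data = long)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  MSR <- tab[rn == "subject", "Mean Sq"]
  MSC <- tab[rn == "rater", "Mean Sq"]
  MSE <- tab[rn == "Residuals", "Mean Sq"]
  c(
    consistency_single = (MSR - MSE) / (MSR + (k - 1) * MSE),
    consistency_average = (MSR - MSE) / MSR,
    absolute_single =
      (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
    absolute_average = (MSR - MSE) / (MSR + (MSC - MSE) / n)
  )
}
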