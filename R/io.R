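# File readers and writers.  Recording files are JSON (or long-format
# CSV); rater tables and questionnaire responses are CSV with a header
# row, UTF-8, comma-separated, "." decimal separator.  Percentages are
# stored as numbers on the 0-100 scale throughout.

#' Read a movement recording
#'
#' JSON schema:
#' `{"task": name, "duration_s": x, "landmarks": [{"id","side","region"}],
#'   "neutral": {"positions": {id: [x,y,z]}},
#'   "frames": [{"t": x, "positions": {id: [x,y,z]}}]}`.
#' Long-format CSV is also accepted, with columns `task, frame_index, t,
#' landmark_id, side, region, x, y, z`; `frame_index` of `-1` marks the
#' neutral frame.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return A `movement_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_recording_json(path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_recording_csv(path)
  } else {
    stop("unsupported recording format (expected .json or .csv): ", path,
         call. = FALSE)
  }
}

read_recording_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("task", "duration_s", "landmarks", "neutral", "frames")) {
    if (is.null(obj[[field]])) {
      if (field == "neutral") {
        stop("missing neutral frame in ", path, call. = FALSE)
      }
      stop("recording JSON missing field '", field, "' in ", path,
           call. = FALSE)
    }
  }
  lm <- landmark_set(
    id = vapply(obj$landmarks, function(l) l$id, character(1)),
    side = vapply(obj$landmarks, function(l) l$side, character(1)),
    region = vapply(obj$landmarks, function(l) l$region, character(1))
  )
  parse_positions <- function(plist, where) {
    if (is.null(plist)) {
      stop("missing positions in ", where, " of ", path, call. = FALSE)
    }
    m <- do.call(rbind, lapply(plist, function(p) as.numeric(unlist(p))))
    if (ncol(m) != 3L) {
      stop("positions in ", where, " must be [x, y, z] triples",
           call. = FALSE)
    }
    rownames(m) <- names(plist)
    m
  }
  neutral <- landmark_frame(0, parse_positions(obj$neutral$positions,
                                               "neutral frame"))
  frames <- lapply(obj$frames, function(f) {
    landmark_frame(as.numeric(f$t), parse_positions(f$positions,
                                                    paste0("frame t=", f$t)))
  })
  movement_recording(obj$task, lm, neutral, frames,
                     duration = as.numeric(obj$duration_s))
}

read_recording_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task", "frame_index", "t", "landmark_id", "side", "region",
            "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("recording CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!any(df$frame_index == -1)) {
    stop("missing neutral frame (no rows with frame_index -1) in ", path,
         call. = FALSE)
  }
  lm_rows <- !duplicated(df$landmark_id)
  lm <- landmark_set(df$landmark_id[lm_rows], df$side[lm_rows],
                     df$region[lm_rows])
  frame_of <- function(sub, t) {
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$landmark_id
    landmark_frame(t, m)
  }
  neutral <- frame_of(df[df$frame_index == -1, , drop = FALSE], 0)
  idx <- sort(unique(df$frame_index[df$frame_index >= 0]))
  frames <- lapply(idx, function(i) {
    sub <- df[df$frame_index == i, , drop = FALSE]
    frame_of(sub, sub$t[1])
  })
  duration <- max(df$t[df$frame_index >= 0])
  movement_recording(df$task[1], lm, neutral, frames,
                     duration = max(duration, .Machine$double.eps))
}

#' Write a movement recording as JSON
#'
#' Inverse of [read_recording()]; a write/read round trip reproduces all
#' coordinates exactly.
#'
#' @param recording A `movement_recording`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "movement_recording"))
  pos_list <- function(frame) {
    lapply(stats::setNames(seq_len(nrow(frame$positions)),
                           rownames(frame$positions)),
           function(i) unname(frame$positions[i, ]))
  }
  obj <- list(
    task = recording$task,
    duration_s = recording$duration,
    landmarks = lapply(seq_len(nrow(recording$landmarks)), function(i) {
      as.list(recording$landmarks[i, c("id", "side", "region")])
    }),
    neutral = list(positions = pos_list(recording$neutral)),
    frames = lapply(recording$frames, function(f) {
      list(t = f$t, positions = pos_list(f))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rater table from CSV
#'
#' Expected layout: a `subject_id` column (optional) followed by one
#' numeric column per rater/measurement, values pre-standardized to the
#' 0-100% scale.
#'
#' @param path CSV path.
#' @param range Legal value range, default `c(0, 100)`; out-of-range
#'   cells are a parse error.
#' @return A `rater_table`.
#' @export
read_rater_table <- function(path, range = c(0, 100)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  subjects <- NULL
  if ("subject_id" %in% names(df)) {
    subjects <- as.character(df$subject_id)
    df$subject_id <- NULL
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric measurement column(s): ",
         paste(non_num, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df)
  out <- which(m < range[1] | m > range[2], arr.ind = TRUE)
  if (nrow(out)) {
    stop("value ", m[out[1, 1], out[1, 2]], " in column '",
         colnames(m)[out[1, 2]], "' is outside [", range[1], ", ",
         range[2], "]", call. = FALSE)
  }
  rater_table(m, subjects = subjects)
}

#' Write an analysis report as JSON
#'
#' Serializes DFI results, Bland-Altman reports, ICC reports, or any named
#' list to JSON at full precision.  A write/read round trip reproduces all
#' numeric fields exactly.
#'
#' @param report The object to serialize.
#' @param path Output path.
#' @param seed Optional integer recorded in the report for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  obj <- unclass(report)
  if (inherits(report, "dfi_result")) {
    obj$ratios <- as.list(obj$ratios)
    obj$weights <- as.list(obj$weights)
  }
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  obj$tool <- paste0("dfigrade ",
                     as.character(utils::packageVersion("dfigrade")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON path.
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
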