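# Conversion between the four facial-function scales on a common
# standardized 0-100% "intact function" axis.
#
#   SI   - Stennert Index, integer 0-10, inverse (0 = normal)
#   HBS  - House-Brackmann Scale, grade I-VI, inverse (I = normal)
#   SFGS - Sunnybrook Facial Grading System, 0-100, direct
#   DFI  - Digital Facial Index, 0-100%, direct
#
# The standardization is linear and anchored at the scale endpoints; it
# reproduces the published worked example DFI 60% = SI 4 = HBS III =
# SFGS 60 exactly.

SCALES <- c("SI", "HBS", "SFGS", "DFI")

#' Construct a clinical score
#'
#' @param scale `"SI"`, `"HBS"`, `"SFGS"`, or `"DFI"`.
#' @param value SI integer 0-10; HBS integer grade 1-6 (I-VI); SFGS and
#'   DFI 0-100.
#' @return A list of class `clinical_score`.
#' @export
clinical_score <- function(scale, value) {
  scale <- match.arg(scale, SCALES)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("value must be a single finite number", call. = FALSE)
  }
  ok <- switch(scale,
    SI   = value >= 0 && value <= 10 && value == round(value),
    HBS  = value >= 1 && value <= 6 && value == round(value),
    SFGS = value >= 0 && value <= 100,
    DFI  = value >= 0 && value <= 100
  )
  if (!ok) {
    stop("value ", value, " is outside the legal range of scale ", scale,
         call. = FALSE)
  }
  structure(list(scale = scale, value = value), class = "clinical_score")
}

#' @export
print.clinical_score <- function(x, ...) {
  val <- if (x$scale == "HBS") render_hbs(x$value) else format(x$value)
  cat(sprintf("%s %s  (standardized: %.1f%% intact function)\n",
              x$scale, val, standardize_score(x)$percent))
  invisible(x)
}

#' Standardize a clinical score to percent intact function
#'
#' Maps any of the four scales onto a common 0-100% axis where 100%
#' reflects fully intact facial function: SFGS and DFI map identically,
#' the SI as `(10 - SI) * 10`, and the HBS as `(6 - grade) * 20`.  The
#' mapping is strictly monotone in facial function on every scale.
#'
#' @param score A `clinical_score`, or a scale name combined with `value`.
#' @param value Raw value when `score` is given as a scale name.
#' @return A list of class `standardized_score` with `percent` and
#'   `source_scale`.
#' @export
standardize_score <- function(score, value = NULL) {
  if (!inherits(score, "clinical_score")) {
    score <- clinical_score(score, value)
  }
  percent <- switch(score$scale,
    SI   = (10 - score$value) * 10,
    HBS  = (6 - score$value) * 20,
    SFGS = score$value,
    DFI  = score$value
  )
  structure(list(percent = percent, source_scale = score$scale),
            class = "standardized_score")
}

#' Convert a score between facial-function scales
#'
#' Standardizes the source score to percent intact function and inverts
#' the target scale's standardization.  Discrete targets (SI, HBS) round
#' to the nearest legal grade, with exact ties rounding toward worse
#' function (conservative clinical reporting).  Converting a score to its
#' own scale returns it unchanged.
#'
#' @param score A `clinical_score`, or a scale name combined with `value`.
#' @param target `"SI"`, `"HBS"`, `"SFGS"`, or `"DFI"`.
#' @param value Raw value when `score` is given as a scale name.
#' @return A `clinical_score` on the target scale.
#' @export
convert_score <- function(score, target, value = NULL) {
  if (!inherits(score, "clinical_score")) {
    score <- clinical_score(score, value)
  }
  target <- match.arg(target, SCALES)
  if (target == score$scale) {
    return(score)
  }
  p <- standardize_score(score)$percent
  raw <- switch(target,
    SI   = round_half_worse(10 - p / 10, lo = 0, hi = 10),
    HBS  = round_half_worse(6 - p / 20, lo = 1, hi = 6),
    SFGS = p,
    DFI  = p
  )
  clinical_score(target, raw)
}

# Round to the nearest integer grade on an inverse scale, ties toward the
# larger (worse-function) grade, clamped to the legal range.
round_half_worse <- function(x, lo, hi) {
  g <- floor(x + 0.5)  # .5 rounds up = toward worse function
  min(max(g, lo), hi)
}

#' Render a House-Brackmann grade as a roman numeral
#'
#' @param grade Integer 1-6.
#' @return `"I"` ... `"VI"`.
#' @export
render_hbs <- function(grade) {
  if (!is.numeric(grade) || length(grade) != 1L || !is.finite(grade) ||
      grade != round(grade) || grade < 1 || grade > 6) {
    stop("HBS grade must be an integer between 1 and 6", call. = FALSE)
  }
  as.character(utils::as.roman(grade))
}
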