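#' Define an ordinal indicator coding scheme
#'
#' An indicator spec maps a raw survey scale (an ordered set of integer scale
#' positions) onto a small set of ordinal vulnerability codes by binning the
#' raw scale at cut points. Codes follow the asset/deficit convention used by
#' deprivation-style indices: a negative code marks a social asset protective
#' against vulnerability, 0 is neutral, and positive codes mark deficits
#' (higher code = more vulnerable).
#'
#' @param name Indicator name (single string), used as the column prefix in
#'   cohort tables (`<name>_raw`, `<name>_code`).
#' @param raw_scale Integer vector of admissible raw scale positions, in
#'   increasing order of vulnerability.
#' @param cut_points Numeric vector of bin boundaries on the raw scale; a raw
#'   value `v` falls in bin `i` when `cut_points[i-1] < v <= cut_points[i]`
#'   (with open outer ends). Must have `length(codes) - 1` elements and be
#'   strictly increasing.
#' @param codes Strictly increasing integer codes, one per bin.
#' @param labels Optional character labels, one per bin.
#' @param direction Logical; `TRUE` (default) records that a higher code
#'   means more vulnerability. Kept as metadata for report labelling.
#' @return An object of class `indicator_spec`.
#' @examples
#' edu <- indicator_spec("education", raw_scale = 1:8,
#'                       cut_points = c(3.5, 5.5), codes = c(-1L, 0L, 1L),
#'                       labels = c("high", "mid", "low"))
#' recode_indicator(c(1, 4, 8), edu)
#' @export
indicator_spec <- function(name, raw_scale, cut_points, codes,
                           labels = NULL, direction = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  raw_scale <- as.integer(raw_scale)
  codes <- as.integer(codes)
  if (length(codes) < 2L) {
    stop("indicator_spec: need at least two codes for '", name, "'")
  }
  if (any(diff(codes) <= 0L)) {
    stop("indicator_spec: codes must be strictly increasing for '", name, "'")
  }
  if (length(cut_points) != length(codes) - 1L) {
    stop("indicator_spec: need length(codes) - 1 cut points for '", name, "'")
  }
  if (any(diff(cut_points) <= 0)) {
    stop("indicator_spec: cut points must be strictly increasing for '",
         name, "'")
  }
  bins <- findInterval(raw_scale, cut_points) + 1L
  if (length(unique(bins)) != length(codes)) {
    stop("indicator_spec: cut points leave an empty bin for '", name, "'")
  }
  if (!is.null(labels) && length(labels) != length(codes)) {
    stop("indicator_spec: need one label per code for '", name, "'")
  }
  structure(
    list(name = name, raw_scale = raw_scale, cut_points = cut_points,
         codes = codes, labels = labels, direction = isTRUE(direction)),
    class = "indicator_spec"
  )
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat("Indicator spec:", x$name, "\n")
  bins <- findInterval(x$raw_scale, x$cut_points) + 1L
  for (i in seq_along(x$codes)) {
    lab <- if (is.null(x$labels)) "" else paste0(" (", x$labels[i], ")")
    cat(sprintf("  code %+d%s <- raw {%s}\n", x$codes[i], lab,
                paste(x$raw_scale[bins == i], collapse = ", ")))
  }
  invisible(x)
}

#' Recode raw scale positions to vulnerability codes
#'
#' Total and deterministic on the spec's raw scale: every admissible raw
#' value maps to exactly one code. `NA` values propagate.
#'
#' @param raw_value Vector of raw scale positions.
#' @param spec An [indicator_spec()].
#' @return Integer vector of codes, same length as `raw_value`.
#' @export
recode_indicator <- function(raw_value, spec) {
  stopifnot(inherits(spec, "indicator_spec"))
  ok <- is.na(raw_value) | raw_value %in% spec$raw_scale
  if (!all(ok)) {
    bad <- which(!ok)
    stop(sprintf(
      "recode_indicator: value(s) outside the raw scale of '%s' at position(s) %s: %s",
      spec$name, paste(utils::head(bad, 5L), collapse = ", "),
      paste(utils::head(raw_value[bad], 5L), collapse = ", ")))
  }
  out <- rep(NA_integer_, length(raw_value))
  idx <- !is.na(raw_value)
  out[idx] <- spec$codes[findInterval(raw_value[idx], spec$cut_points) + 1L]
  out
}

#' Default indicator coding schemes
#'
#' The published coding of the five social indicators: education (8-point raw
#' scale, 1 = post-graduate university ... 8 = primary or less, collapsed to
#' university / secondary-technical / low with codes -1/0/+1), self-perceived
#' financial status (7-point raw scale, 1 = very comfortable ... 7 = very
#' poor, collapsed to comfortable / tight-to-moderate / poor, -1/0/+1),
#' instrumental social support (persons able to help with daily activities:
#' 0 = more than one, 1 = one, 2 = none, coded -1/0/+1), confidant social
#' support (same raw scale, coded 0/+1/+2 -- no protective category), and
#' language spoken at home (0 = majority language, 1 = other, coded 0/+1).
#'
#' The raw-to-bin mapping for the 8- and 7-point scales is configurable;
#' these defaults place university (complete or partial, raw 1-3) in the
#' asset bin and none/primary/partial-secondary (raw 6-8) in the deficit bin,
#' and financial raw 1-2 / 3-5 / 6-7 in the three bins.
#'
#' @return Named list of [indicator_spec()] objects.
#' @export
default_indicator_specs <- function() {
  list(
    education = indicator_spec(
      "education", raw_scale = 1:8, cut_points = c(3.5, 5.5),
      codes = c(-1L, 0L, 1L),
      labels = c("high (university)", "mid (secondary/technical)",
                 "low (<= partial secondary)")),
    financial = indicator_spec(
      "financial", raw_scale = 1:7, cut_points = c(2.5, 5.5),
      codes = c(-1L, 0L, 1L),
      labels = c("comfortable", "tight to moderately comfortable",
                 "very tight to poor")),
    instrumental = indicator_spec(
      "instrumental", raw_scale = 0:2, cut_points = c(0.5, 1.5),
      codes = c(-1L, 0L, 1L),
      labels = c("high support (1+ persons)", "medium (one person)",
                 "low (none)")),
    confidant = indicator_spec(
      "confidant", raw_scale = 0:2, cut_points = c(0.5, 1.5),
      codes = c(0L, 1L, 2L),
      labels = c("high support (1+ persons)", "medium (one person)",
                 "low (none)")),
    language = indicator_spec(
      "language", raw_scale = 0:1, cut_points = 0.5,
      codes = c(0L, 1L),
      labels = c("majority language at home", "other language at home"))
  )
}
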