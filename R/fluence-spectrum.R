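#' Binned electron fluence spectrum
#'
#' Wraps a binned fluence differential in energy at one geometry point.
#' Fluence is particle fluence per unit energy on an arbitrary absolute
#' scale; all downstream LET moments are invariant under rescaling.
#'
#' @param bins Data frame with columns `e_low_MeV`, `e_high_MeV` (strictly
#'   increasing, contiguous bins not required) and `fluence` (>= 0, per MeV).
#' @param delta_keV Delta-ray cutoff this spectrum is scored down to; the
#'   lowest bin edge must not be below it.
#' @param kind `"TEF"` (total electron fluence) or `"SE"`
#'   (secondary, electron-impact-generated electrons only).
#' @param track_end_fluence Fluence density at the cutoff, `Phi(Delta)`,
#'   feeding the track-end correction. If `NA`, the first bin's density is
#'   used with a warning.
#' @param geometry Optional [geometry_point()] describing where the spectrum
#'   was scored.
#' @return A tibble of class `"fluence_spectrum"` with the metadata stored in
#'   attributes.
#' @export
fluence_spectrum <- function(bins, delta_keV = 1, kind = c("TEF", "SE"),
                             track_end_fluence = 0, geometry = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("e_low_MeV", "e_high_MeV", "fluence") %in% names(bins)))
  bins <- tibble::as_tibble(bins[c("e_low_MeV", "e_high_MeV", "fluence")])
  if (nrow(bins) < 1L) stop("spectrum needs at least one bin", call. = FALSE)
  if (any(bins$e_high_MeV <= bins$e_low_MeV) ||
      is.unsorted(bins$e_low_MeV, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (any(bins$fluence < 0)) stop("fluence must be non-negative", call. = FALSE)
  if (!any(bins$fluence > 0)) stop("spectrum has no positive bin", call. = FALSE)
  if (bins$e_low_MeV[1] < delta_keV / 1000 * (1 - 1e-9)) {
    stop("spectrum extends below the delta cutoff", call. = FALSE)
  }
  if (is.na(track_end_fluence)) {
    warning("track-end fluence missing; using the first bin's density")
    track_end_fluence <- bins$fluence[1]
  }
  if (track_end_fluence < 0) stop("track-end fluence must be >= 0", call. = FALSE)
  attr(bins, "delta_keV") <- delta_keV
  attr(bins, "kind") <- kind
  attr(bins, "track_end_fluence") <- track_end_fluence
  attr(bins, "geometry") <- geometry
  class(bins) <- c("fluence_spectrum", class(bins))
  bins
}

#' Geometry point of a scored spectrum
#'
#' @param field_cm Side of the square field (cm).
#' @param depth_cm Water depth (cm).
#' @param offaxis_cm Lateral distance from the central axis (cm).
#' @return A named list of class `"geometry_point"`.
#' @export
geometry_point <- function(field_cm, depth_cm, offaxis_cm) {
  stopifnot(field_cm > 0, depth_cm >= 0, offaxis_cm >= 0)
  structure(list(field_cm = field_cm, depth_cm = depth_cm,
                 offaxis_cm = offaxis_cm),
            class = "geometry_point")
}

#' @export
print.geometry_point <- function(x, ...) {
  cat(sprintf("<geometry_point> %g x %g cm field, depth %g cm, off-axis %g cm\n",
              x$field_cm, x$field_cm, x$depth_cm, x$offaxis_cm))
  invisible(x)
}

#' @export
print.fluence_spectrum <- function(x, ...) {
  cat(sprintf("<fluence_spectrum> kind = %s, %d bins on [%g, %g] MeV, delta = %g keV\n",
              attr(x, "kind"), nrow(x), x$e_low_MeV[1], x$e_high_MeV[nrow(x)],
              attr(x, "delta_keV")))
  g <- attr(x, "geometry")
  if (!is.null(g)) print(g)
  NextMethod()
}

# geometric bin midpoints, natural for log-spaced slowing-down grids
.bin_mid <- function(spec) sqrt(spec$e_low_MeV * spec$e_high_MeV)
.bin_width <- function(spec) spec$e_high_MeV - spec$e_low_MeV

#' Read and write the spectrum TSV dialect
#'
#' Plain-text exchange format: comment headers `# kind=`, `# delta_keV=`,
#' `# field_cm=  depth_cm=  offaxis_cm=`, tab-separated columns
#' `E_low_MeV E_high_MeV fluence_density`, and an optional trailing
#' `# phi_at_delta=` comment carrying the track-end fluence.
#'
#' @param spec A [fluence_spectrum()].
#' @param path File path.
#' @return `write_spectrum_tsv()` returns `path` invisibly;
#'   `read_spectrum_tsv()` returns a [fluence_spectrum()].
#' @export
write_spectrum_tsv <- function(spec, path) {
  g <- attr(spec, "geometry")
  lines <- c(
    sprintf("# kind=%s", attr(spec, "kind")),
    sprintf("# delta_keV=%g", attr(spec, "delta_keV")),
    if (!is.null(g)) sprintf("# field_cm=%g\tdepth_cm=%g\toffaxis_cm=%g",
                             g$field_cm, g$depth_cm, g$offaxis_cm),
    "E_low_MeV\tE_high_MeV\tfluence_density",
    sprintf("%.10g\t%.10g\t%.10g", spec$e_low_MeV, spec$e_high_MeV, spec$fluence),
    sprintf("# phi_at_delta=%.10g", attr(spec, "track_end_fluence"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  grab <- function(key) {
    m <- regmatches(comments, regexec(paste0(key, "=([^\t ]+)"), comments))
    v <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    if (length(v)) v[1] else NA_character_
  }
  kind <- grab("kind")
  delta <- as.numeric(grab("delta_keV"))
  phi_d <- suppressWarnings(as.numeric(grab("phi_at_delta")))
  geom <- NULL
  fc <- suppressWarnings(as.numeric(grab("field_cm")))
  if (!is.na(fc)) {
    geom <- geometry_point(fc, as.numeric(grab("depth_cm")),
                           as.numeric(grab("offaxis_cm")))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[!grepl("^E_low", body)]
  dat <- utils::read.table(text = body,
                           col.names = c("e_low_MeV", "e_high_MeV", "fluence"))
  fluence_spectrum(dat, delta_keV = delta, kind = kind,
                   track_end_fluence = if (is.na(phi_d)) NA else phi_d,
                   geometry = geom)
}
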