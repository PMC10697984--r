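# Track- and dose-average restricted LET of a binned electron fluence
# spectrum. Both are ratios of fluence integrals of the restricted stopping
# power, each augmented by a track-end term at the cutoff:
#
#   L_D = ( int L^2 Phi dE + S(D)^2 Phi(D) D ) / ( int L Phi dE + S(D) Phi(D) D )
#   L_T = ( int L  Phi dE + S(D)   Phi(D) D ) / ( int   Phi dE +        Phi(D) D )
#
# The track-end term accounts for electrons whose energy falls below the
# cutoff and that deposit the remainder locally. Integrals are midpoint-rule
# sums over bins with the restricted stopping power interpolated log-log at
# geometric bin midpoints.

.moment_pieces <- function(spec, table,
                           weighting = c("particle", "energy")) {
  weighting <- match.arg(weighting)
  d_spec <- attr(spec, "delta_keV")
  d_tab <- attr(table, "delta_keV")
  if (!isTRUE(all.equal(d_spec, d_tab))) {
    stop(sprintf("delta cutoff mismatch: spectrum %g keV vs table %g keV",
                 d_spec, d_tab), call. = FALSE)
  }
  mid <- .bin_mid(spec)
  w <- spec$fluence * .bin_width(spec)
  if (weighting == "energy") w <- w * mid
  if (!any(w > 0)) stop("all-zero fluence: LET moments undefined", call. = FALSE)
  L <- let_lookup(table, mid, "restricted")
  delta_MeV <- d_spec / 1000
  S_delta <- let_lookup(table, max(delta_MeV, min(table$energy_MeV)), "unrestricted")
  phi_d <- attr(spec, "track_end_fluence")
  if (weighting == "energy") phi_d <- phi_d * delta_MeV
  list(L = L, w = w,
       end_n = phi_d * delta_MeV,            # Phi(D) D        (Eq. 2 denominator)
       end_L = S_delta * phi_d * delta_MeV,  # S(D) Phi(D) D
       end_L2 = S_delta^2 * phi_d * delta_MeV)
}

#' Track-end correction terms
#'
#' Returns the three track-end contributions built from the unrestricted
#' stopping power at the cutoff: `S(Delta) Phi(Delta) Delta`,
#' `S(Delta)^2 Phi(Delta) Delta` and `Phi(Delta) Delta`.
#'
#' @param spec A [fluence_spectrum()].
#' @param table A [build_stopping_table()] covering the spectrum at the same
#'   cutoff.
#' @return Tibble with columns `term` and `value`.
#' @export
track_end_terms <- function(spec, table) {
  p <- .moment_pieces(spec, table)
  tibble::tibble(
    term = c("S_phi_delta", "S2_phi_delta", "phi_delta"),
    value = c(p$end_L, p$end_L2, p$end_n)
  )
}

#' Dose-average restricted LET of a fluence spectrum
#'
#' Ratio of the \eqn{L_\Delta^2}-weighted to the \eqn{L_\Delta}-weighted
#' fluence integral, each with its track-end term. Invariant under rescaling
#' of the fluence by any positive constant.
#'
#' @inheritParams track_end_terms
#' @param weighting `"particle"` (default) weights by particle fluence;
#'   `"energy"` weights by energy fluence, provided for sensitivity checks.
#' @return Dose-average LET in keV/um.
#' @export
dose_average_let <- function(spec, table, weighting = "particle") {
  p <- .moment_pieces(spec, table, weighting)
  (sum(p$L^2 * p$w) + p$end_L2) / (sum(p$L * p$w) + p$end_L)
}

#' Track-average restricted LET of a fluence spectrum
#'
#' Fluence-weighted mean of \eqn{L_\Delta} with track-end terms; always at or
#' below the dose average.
#'
#' @inheritParams dose_average_let
#' @return Track-average LET in keV/um.
#' @export
track_average_let <- function(spec, table, weighting = "particle") {
  p <- .moment_pieces(spec, table, weighting)
  (sum(p$L * p$w) + p$end_L) / (sum(p$w) + p$end_n)
}

#' Both LET moments of a spectrum as a one-row tibble
#'
#' @inheritParams dose_average_let
#' @param rel_u Relative standard uncertainty (k = 1) to attach; the 0.006
#'   default is the combined standard uncertainty quoted for this kind of
#'   Monte-Carlo-driven LET evaluation.
#' @return One-row tibble: geometry columns (if present), `kind`,
#'   `track_let`, `dose_let` (keV/um), `delta_keV`, `rel_u`.
#' @export
let_moments <- function(spec, table, weighting = "particle", rel_u = 0.006) {
  g <- attr(spec, "geometry")
  res <- tibble::tibble(
    field_cm = if (is.null(g)) NA_real_ else g$field_cm,
    depth_cm = if (is.null(g)) NA_real_ else g$depth_cm,
    offaxis_cm = if (is.null(g)) NA_real_ else g$offaxis_cm,
    kind = attr(spec, "kind"),
    track_let = track_average_let(spec, table, weighting),
    dose_let = dose_average_let(spec, table, weighting),
    delta_keV = attr(spec, "delta_keV")
  )
  attach_uncertainty(res, rel_u)
}

#' Attach a relative standard uncertainty to LET results
#'
#' @param result Tibble of LET results (from [let_moments()] or row-bound
#'   collections of them).
#' @param rel_u Relative standard uncertainty as a fraction in `[0, 1)`.
#' @return `result` with a `rel_u` column set.
#' @export
attach_uncertainty <- function(result, rel_u = 0.006) {
  if (!is.numeric(rel_u) || length(rel_u) != 1L || rel_u < 0 || rel_u >= 1) {
    stop("rel_u must be a single fraction in [0, 1)", call. = FALSE)
  }
  result$rel_u <- rel_u
  result
}
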