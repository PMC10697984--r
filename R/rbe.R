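# Quadratic calibration of maximum low-dose RBE (RBE_M, dicentrics in human
# lymphocytes, relative to Co-60 gamma rays) against photon energy, and
# per-geometry prediction with first-order uncertainty propagation.

#' Read an RBE_M calibration table
#'
#' Expects columns `photon_energy_MeV`, `rbe_m`, `std_u`. The packaged
#' default (`extdata/rbe_dicentrics_synthetic.csv`) is a synthetic stand-in
#' emulating the published dicentric photon-energy response: RBE_M near 1 at
#' the Co-60 reference energy, rising toward soft photon energies, with the
#' large relative uncertainties typical of cytogenetic data. Replace it with
#' real calibration data for substantive use.
#'
#' @param path CSV path; `NULL` loads the packaged synthetic table.
#' @return Tibble with the three calibration columns.
#' @export
read_rbe_calibration <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rbe_dicentrics_synthetic.csv",
                                package = "penumbralet", mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  need <- c("photon_energy_MeV", "rbe_m", "std_u")
  if (!all(need %in% names(out))) {
    stop("calibration table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(out$photon_energy_MeV <= 0) || any(out$rbe_m <= 0) || any(out$std_u < 0)) {
    stop("invalid calibration rows: energies and RBE must be positive, std_u >= 0",
         call. = FALSE)
  }
  out
}

.rbe_coord <- function(E, scale) if (scale == "log10") log10(E) else E

#' Fit a quadratic RBE_M(photon energy) calibration
#'
#' Degree-2 polynomial least squares in the chosen energy coordinate,
#' inverse-variance weighted by default. The default coordinate is
#' `log10(E)` because calibration energies span orders of magnitude. The
#' parameter covariance for a weighted fit is `(X' W X)^-1` with
#' `W = diag(1/std_u^2)`, i.e. propagation of the stated measurement
#' uncertainties; the unweighted fit uses the usual residual-variance
#' estimate.
#'
#' @param points Data frame with columns `photon_energy_MeV`, `rbe_m` and
#'   (if `weighted`) `std_u`; at least 3 distinct energies.
#' @param scale Energy coordinate, `"log10"` (default) or `"linear"`.
#' @param weighted Use inverse-variance weights (default `TRUE`). Falls back
#'   to unweighted with a warning when uncertainties are missing or zero.
#' @return Object of class `"rbe_fit"`: coefficients `(c0, c1, c2)`,
#'   3x3 covariance, scale, calibration range and the data.
#' @export
fit_rbe_curve <- function(points, scale = c("log10", "linear"), weighted = TRUE) {
  scale <- match.arg(scale)
  points <- tibble::as_tibble(points)
  E <- points$photon_energy_MeV
  if (length(unique(E)) < 3L) {
    stop("need at least 3 distinct photon energies for a quadratic fit",
         call. = FALSE)
  }
  if (any(E <= 0)) stop("photon energies must be positive", call. = FALSE)
  u <- points$std_u
  if (weighted && (is.null(u) || any(!is.finite(u)) || any(u <= 0))) {
    warning("missing or zero uncertainties; falling back to an unweighted fit")
    weighted <- FALSE
  }
  x <- .rbe_coord(E, scale)
  X <- cbind(1, x, x^2)
  y <- points$rbe_m
  if (weighted) {
    W <- 1 / u^2
    XtWX <- crossprod(X * sqrt(W))
    beta <- solve(XtWX, crossprod(X, W * y))
    covariance <- solve(XtWX)
  } else {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    dof <- length(y) - 3L
    sigma2 <- if (dof > 0) sum(fit$residuals^2) / dof else 0
    covariance <- sigma2 * solve(crossprod(X))
  }
  beta <- as.numeric(beta)
  names(beta) <- c("c0", "c1", "c2")
  dimnames(covariance) <- list(names(beta), names(beta))
  structure(
    list(coefficients = beta, covariance = covariance, energy_scale = scale,
         valid_range = range(E), weighted = weighted, data = points,
         fitted = as.numeric(X %*% beta)),
    class = "rbe_fit"
  )
}

#' @export
print.rbe_fit <- function(x, ...) {
  cat(sprintf("<rbe_fit> quadratic in %s(E), %s, %d points on [%g, %g] MeV\n",
              if (x$energy_scale == "log10") "log10" else "",
              if (x$weighted) "inverse-variance weighted" else "unweighted",
              nrow(x$data), x$valid_range[1], x$valid_range[2]))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RBE calibration fit
#'
#' @param x An `"rbe_fit"`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy rbe_fit
#' @export
tidy.rbe_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients),
                 std.error = sqrt(diag(x$covariance)))
}

#' One-row summary of an RBE calibration fit
#'
#' @param x An `"rbe_fit"`.
#' @param ... Unused.
#' @return Tibble with point count, range, scale, weighting and the
#'   (weighted) residual sum of squares.
#' @method glance rbe_fit
#' @export
glance.rbe_fit <- function(x, ...) {
  r <- x$data$rbe_m - x$fitted
  w <- if (x$weighted) 1 / x$data$std_u^2 else rep(1, length(r))
  tibble::tibble(nobs = nrow(x$data),
                 energy_min_MeV = x$valid_range[1],
                 energy_max_MeV = x$valid_range[2],
                 energy_scale = x$energy_scale,
                 weighted = x$weighted,
                 wrss = sum(w * r^2))
}

#' Predict RBE_M at photon energies
#'
#' Evaluates the calibration quadratic with first-order propagation of the
#' coefficient covariance. Quadratics diverge outside their calibration
#' range, so energies outside it are clamped to the nearest boundary and
#' flagged rather than extrapolated.
#'
#' @param fit An [fit_rbe_curve()] result.
#' @param E Photon energies in MeV (vectorised).
#' @return Tibble with `photon_energy_MeV`, `rbe_m`, `std_u`,
#'   `extrapolated`.
#' @export
predict_rbem <- function(fit, E) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("photon energy must be positive and finite", call. = FALSE)
  }
  extrap <- E < fit$valid_range[1] | E > fit$valid_range[2]
  Ec <- pmin(pmax(E, fit$valid_range[1]), fit$valid_range[2])
  x <- .rbe_coord(Ec, fit$energy_scale)
  X <- cbind(1, x, x^2)
  val <- as.numeric(X %*% fit$coefficients)
  var <- rowSums((X %*% fit$covariance) * X)
  tibble::tibble(photon_energy_MeV = E, rbe_m = val,
                 std_u = sqrt(pmax(var, 0)), extrapolated = extrap)
}

#' Fluence-weighted mean photon energy
#'
#' Maps a binned photon spectrum to a single effective energy on the
#' calibration axis. The choice of the fluence-weighted mean is a documented
#' package convention for connecting a spectrum to the single-energy
#' calibration curve.
#'
#' @param photon_spec Data frame with columns `e_low_MeV`, `e_high_MeV`,
#'   `fluence` (density per MeV).
#' @return Effective photon energy in MeV.
#' @export
effective_photon_energy <- function(photon_spec) {
  w <- photon_spec$fluence * (photon_spec$e_high_MeV - photon_spec$e_low_MeV)
  if (!any(w > 0)) stop("all-zero photon spectrum", call. = FALSE)
  mid <- sqrt(photon_spec$e_low_MeV * photon_spec$e_high_MeV)
  sum(mid * w) / sum(w)
}

#' Serialise an RBE fit report to JSON
#'
#' @param fit An `"rbe_fit"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rbe_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         covariance = fit$covariance,
         energy_scale = fit$energy_scale,
         valid_range_MeV = fit$valid_range,
         weighted = fit$weighted),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
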