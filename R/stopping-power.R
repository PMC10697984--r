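# Electron collision stopping powers in the condensed ICRU-37 closed form.
# Internally everything is evaluated as mass stopping power (MeV cm^2/g) and
# converted to linear keV/um at the surface: 1 MeV/cm == 0.1 keV/um.

.kev_per_um_per_MeV_per_cm <- 0.1

# kinematic helpers on kinetic energy in MeV
.tau <- function(E) E / .mc2_MeV
.beta2 <- function(tau) tau * (tau + 2) / (tau + 1)^2

.check_energy <- function(E, floor_keV) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("kinetic energy must be positive and finite", call. = FALSE)
  }
  if (any(E < floor_keV / 1000)) {
    stop(sprintf(
      "kinetic energy below the %g keV validity floor of the Bethe formula; refusing to extrapolate",
      floor_keV), call. = FALSE)
  }
  invisible(TRUE)
}

#' Sternheimer density-effect correction
#'
#' Evaluates the density-effect correction \eqn{\delta} on
#' \eqn{x = \log_{10}(p / m_e c)}: below `x0` the conductor term
#' `delta0 * 10^(2(x - x0))` (zero for insulators), the quadratic-bridge form
#' on `[x0, x1)`, and the asymptote `2 ln(10) x - Cbar` above `x1`.
#' Non-negative and non-decreasing in energy.
#'
#' @param E Kinetic energy in MeV (vectorised).
#' @param material A [material_spec()]; default liquid water.
#' @return Dimensionless correction, same length as `E`.
#' @export
density_effect_delta <- function(E, material = water_liquid()) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("kinetic energy must be positive and finite", call. = FALSE)
  }
  tau <- .tau(E)
  x <- log10(sqrt(tau * (tau + 2)))  # log10(beta*gamma)
  bridge <- 2 * log(10) * x - material$cbar + material$a * (material$x1 - x)^material$m
  asymptote <- 2 * log(10) * x - material$cbar
  below <- material$delta0 * 10^(2 * (x - material$x0))
  out <- ifelse(x < material$x0, below,
                ifelse(x < material$x1, bridge, asymptote))
  pmax(out, 0)
}

# shared leading factor and logarithmic term of the ICRU-37 closed form
.bethe_parts <- function(E, material) {
  tau <- .tau(E)
  beta2 <- .beta2(tau)
  I_MeV <- material$I_eV * 1e-6
  list(
    tau = tau, beta2 = beta2,
    lead = .k_MeVcm2 * material$Z_over_A / beta2,
    logterm = log(tau^2 * (tau + 2) / (2 * (I_MeV / .mc2_MeV)^2)),
    delta = density_effect_delta(E, material)
  )
}

# Moller stopping-number auxiliaries: G(tau, eta) generalises the usual
# F^-(tau); eta = Delta/E is the fractional cutoff, eta = 1/2 recovers the
# unrestricted case.
.G_minus <- function(tau, beta2, eta) {
  -1 - beta2 + log(4 * (1 - eta) * eta) + 1 / (1 - eta) +
    (1 - beta2) * (tau^2 * eta^2 / 2 + (2 * tau + 1) * log(1 - eta))
}

#' Unrestricted electron collision stopping power
#'
#' Bethe collision stopping power for electrons (Moller close collisions,
#' ICRU-37 closed form) with the Sternheimer density-effect correction,
#' returned as linear stopping power in keV/um. Radiative losses are excluded
#' by definition: LET is a collisional quantity.
#'
#' @param E Kinetic energy in MeV (vectorised).
#' @param material A [material_spec()]; default liquid water.
#' @param floor_keV Validity floor in keV below which evaluation errors
#'   rather than extrapolates (default 1 keV).
#' @return Linear collision stopping power, keV/um.
#' @examples
#' collision_stopping_power(1)        # ~0.19 keV/um in water
#' @export
collision_stopping_power <- function(E, material = water_liquid(),
                                     floor_keV = 1) {
  .check_energy(E, floor_keV)
  p <- .bethe_parts(E, material)
  mass <- p$lead * (p$logterm + .G_minus(p$tau, p$beta2, 0.5) - p$delta)
  mass * material$density_g_cm3 * .kev_per_um_per_MeV_per_cm
}

#' Restricted electron collision stopping power (restricted LET)
#'
#' Collision stopping power counting only energy transfers below the
#' delta-ray cutoff `delta_keV`. For `delta_keV >= E/2` the maximum possible
#' energy transfer to an indistinguishable secondary is already below the
#' cutoff and the unrestricted value is returned exactly.
#'
#' @inheritParams collision_stopping_power
#' @param delta_keV Delta-ray cutoff in keV (default 1 keV).
#' @return Linear restricted stopping power \eqn{L_\Delta}, keV/um.
#' @examples
#' restricted_let(1, delta_keV = 1)   # < collision_stopping_power(1)
#' @export
restricted_let <- function(E, delta_keV = 1, material = water_liquid(),
                           floor_keV = 1) {
  if (any(delta_keV <= 0)) stop("delta cutoff must be positive", call. = FALSE)
  .check_energy(E, floor_keV)
  p <- .bethe_parts(E, material)
  eta <- pmin(delta_keV / 1000 / E, 0.5)
  mass <- p$lead * (p$logterm + .G_minus(p$tau, p$beta2, eta) - p$delta)
  mass * material$density_g_cm3 * .kev_per_um_per_MeV_per_cm
}

#' Tabulate stopping powers on an energy grid
#'
#' Evaluates unrestricted and restricted stopping powers on a strictly
#' increasing kinetic-energy grid and returns a tibble of class
#' `"stopping_power_table"`. Consumers interpolate log-log linearly between
#' grid rows via [let_lookup()].
#'
#' @param grid_MeV Strictly increasing kinetic energies (MeV); must start at
#'   or above the cutoff. Default: 200 log-spaced points from 1 keV to
#'   6.5 MeV via [default_energy_grid()].
#' @param delta_keV Delta-ray cutoff in keV.
#' @param material A [material_spec()].
#' @return Tibble with columns `energy_MeV`, `S_keV_um` (unrestricted) and
#'   `L_keV_um` (restricted), and attributes `delta_keV`, `material`.
#' @export
build_stopping_table <- function(grid_MeV = default_energy_grid(),
                                 delta_keV = 1,
                                 material = water_liquid()) {
  if (is.unsorted(grid_MeV, strictly = TRUE)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (min(grid_MeV) < delta_keV / 1000 * (1 - 1e-12)) {
    stop("energy grid must not extend below the delta cutoff", call. = FALSE)
  }
  out <- tibble::tibble(
    energy_MeV = grid_MeV,
    S_keV_um = collision_stopping_power(grid_MeV, material),
    L_keV_um = restricted_let(grid_MeV, delta_keV, material)
  )
  attr(out, "delta_keV") <- delta_keV
  attr(out, "material") <- material
  class(out) <- c("stopping_power_table", class(out))
  out
}

#' Default kinetic-energy grid
#'
#' 200 log-spaced points spanning the delta cutoff up to 6.5 MeV, slightly
#' above the highest electron energies a 6 MV beam sets in motion.
#'
#' @param from_keV,to_MeV Grid limits.
#' @param n Number of points.
#' @return Numeric vector of kinetic energies in MeV.
#' @export
default_energy_grid <- function(from_keV = 1, to_MeV = 6.5, n = 200) {
  exp(seq(log(from_keV / 1000), log(to_MeV), length.out = n))
}

#' Interpolate a stopping-power table
#'
#' Log-log linear interpolation of either column at arbitrary energies
#' inside the tabulated range.
#'
#' @param table A [build_stopping_table()] result.
#' @param E Kinetic energies (MeV) inside the tabulated range.
#' @param what `"restricted"` (default) or `"unrestricted"`.
#' @return Interpolated stopping power, keV/um.
#' @export
let_lookup <- function(table, E, what = c("restricted", "unrestricted")) {
  what <- match.arg(what)
  rng <- range(table$energy_MeV)
  if (any(E < rng[1] * (1 - 1e-9)) || any(E > rng[2] * (1 + 1e-9))) {
    stop("energy outside the tabulated range [", rng[1], ", ", rng[2], "] MeV",
         call. = FALSE)
  }
  col <- if (what == "restricted") table$L_keV_um else table$S_keV_um
  exp(stats::approx(log(table$energy_MeV), log(col), xout = log(pmin(pmax(E, rng[1]), rng[2])),
                    rule = 2)$y)
}

#' Write / read a stopping-power table as TSV
#'
#' The on-disk dialect is a commented header naming the columns and cutoff,
#' followed by three tab-separated numeric columns.
#'
#' @param table A `"stopping_power_table"`.
#' @param path File path.
#' @return `write_stopping_table()` returns `path` invisibly;
#'   `read_stopping_table()` returns a tibble with the `delta_keV` attribute
#'   restored (the material attribute is not serialised).
#' @export
write_stopping_table <- function(table, path) {
  header <- sprintf("# energy_MeV\tS_keV_per_um\tL_delta_keV_per_um\tdelta_keV=%g",
                    attr(table, "delta_keV"))
  lines <- c(header, sprintf("%.10g\t%.10g\t%.10g",
                             table$energy_MeV, table$S_keV_um, table$L_keV_um))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stopping_table
#' @export
read_stopping_table <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines[1], regexec("delta_keV=([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(m) != 2) stop("missing delta_keV header in ", path, call. = FALSE)
  dat <- utils::read.table(text = lines[-1], col.names = c("energy_MeV", "S_keV_um", "L_keV_um"))
  out <- tibble::as_tibble(dat)
  attr(out, "delta_keV") <- as.numeric(m[2])
  class(out) <- c("stopping_power_table", class(out))
  out
}
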