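# Physical constants used throughout (CODATA-era values).
.mc2_MeV <- 0.51099895      # electron rest energy
.k_MeVcm2 <- 0.1535374      # 2*pi*r_e^2*mc^2*N_A, MeV cm^2 / mol
.re_cm <- 2.8179403e-13     # classical electron radius
.NA_mol <- 6.02214076e23

#' Material specification for stopping-power calculations
#'
#' Builds the set of constants needed by the Bethe/Moller collision
#' stopping-power formulas: mean excitation energy, density, Z/A and the
#' Sternheimer density-effect parameterisation. The bridge coefficient `a` is
#' derived from `(cbar, x0, x1, m)` so that the density-effect correction is
#' exactly continuous at `x0`; for liquid water the derived value agrees with
#' the published fitted coefficient to better than 0.1%.
#'
#' @param name Material name (must match a row of the packaged material table
#'   when `...` constants are not supplied).
#' @param density_g_cm3,I_eV,Z_over_A Overrides for the tabulated constants.
#' @param x0,x1,cbar,m,delta0 Sternheimer density-effect coefficients.
#' @return A list of class `"material_spec"`.
#' @examples
#' water_liquid()
#' @export
material_spec <- function(name, density_g_cm3, I_eV, Z_over_A,
                          x0, x1, cbar, m, delta0 = 0) {
  stopifnot(density_g_cm3 > 0, I_eV > 0, Z_over_A > 0, x0 < x1, m > 0)
  a <- (cbar - 2 * log(10) * x0) / (x1 - x0)^m
  stopifnot(a > 0)
  structure(
    list(name = name, density_g_cm3 = density_g_cm3, I_eV = I_eV,
         Z_over_A = Z_over_A, x0 = x0, x1 = x1, cbar = cbar, m = m,
         a = a, delta0 = delta0),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: rho = %g g/cm^3, I = %g eV, Z/A = %g\n",
              x$name, x$density_g_cm3, x$I_eV, x$Z_over_A))
  cat(sprintf("  Sternheimer: x0 = %g, x1 = %g, Cbar = %g, m = %g, a = %.5f\n",
              x$x0, x$x1, x$cbar, x$m, x$a))
  invisible(x)
}

#' Load a material from the packaged constants table
#'
#' Material constants ship as a plain CSV under `extdata/materials.csv` so
#' they can be inspected and replaced; they are data, not code.
#'
#' @param name Material name, e.g. `"water_liquid"`.
#' @param path Optional path to an alternative constants CSV with the same
#'   columns.
#' @return A [material_spec()].
#' @export
load_material <- function(name, path = NULL) {
  path <- path %||% system.file("extdata", "materials.csv",
                                package = "penumbralet", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("material '", name, "' not found in ", path, call. = FALSE)
  }
  material_spec(name = row$name, density_g_cm3 = row$density_g_cm3,
                I_eV = row$I_eV, Z_over_A = row$Z_over_A, x0 = row$x0,
                x1 = row$x1, cbar = row$cbar, m = row$m, delta0 = row$delta0)
}

#' Liquid water with the I = 75 eV convention
#'
#' The default medium. The 75 eV mean excitation energy is the ICRU-37-era
#' value used by the EGSnrc toolchain; newer recommendations (ICRU 90) give
#' 78 eV. Override via [material_spec()] if another convention is wanted.
#'
#' @return A [material_spec()] for liquid water.
#' @export
water_liquid <- function() load_material("water_liquid")
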