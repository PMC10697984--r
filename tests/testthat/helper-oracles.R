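# Independent oracles and fixture builders shared across tests.

# Hard-collision (delta-ray) part of the electron stopping power by direct
# numerical integration of the energy-weighted Moller cross section over
# fractional transfers [delta/E, 1/2]. Independent of the closed forms in
# the package: only the shared physical constants appear.
oracle_moller_hard_term <- function(E_MeV, delta_keV, Z_over_A = 0.55508,
                                    density = 1.0) {
  mc2 <- 0.51099895
  tau <- E_MeV / mc2
  beta2 <- tau * (tau + 2) / (tau + 1)^2
  integrand <- function(eps) {
    eps * (1 / eps^2 + 1 / (1 - eps)^2 + (tau / (tau + 1))^2 -
             (2 * tau + 1) / (tau + 1)^2 / (eps * (1 - eps)))
  }
  val <- stats::integrate(integrand, delta_keV / 1000 / E_MeV, 0.5,
                          rel.tol = 1e-12)$value
  0.1535374 * Z_over_A / beta2 * val * density * 0.1  # keV/um
}

# Klein-Nishina total cross section (cm^2) for a photon of energy k (MeV),
# closed form, used to validate the recoil-electron quadrature.
oracle_kn_total <- function(k) {
  mc2 <- 0.51099895
  re <- 2.8179403e-13
  a <- k / mc2
  2 * pi * re^2 * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
      log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  )
}

# Weighted quadratic fit through lm()'s QR path: an independent route to the
# normal-equations solution used by the package.
oracle_quadratic_fit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  unname(coef(stats::lm(y ~ x + I(x^2), weights = w)))
}

# A stopping-power table with prescribed restricted values at chosen node
# energies (log-log interpolation is exact at nodes). For moment tests where
# the L values, not the physics, are under control.
synthetic_let_table <- function(energy_MeV, L_values, S_values = L_values,
                                delta_keV = 1) {
  tab <- tibble::tibble(energy_MeV = energy_MeV, S_keV_um = S_values,
                        L_keV_um = L_values)
  attr(tab, "delta_keV") <- delta_keV
  class(tab) <- c("stopping_power_table", class(tab))
  tab
}

# Single-bin spectrum centred (geometrically) on E0.
mono_spectrum <- function(E0_MeV, rel_halfwidth = 0.01, delta_keV = 1,
                          track_end = 0) {
  fluence_spectrum(
    tibble::tibble(e_low_MeV = E0_MeV * (1 - rel_halfwidth),
                   e_high_MeV = E0_MeV * (1 + rel_halfwidth),
                   fluence = 1),
    delta_keV = delta_keV, track_end_fluence = track_end)
}

# Shared default water table for tests that exercise the real physics.
test_water_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_stopping_table()
    tab
  }
})
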