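test_that("photon spectra are deterministic and normalised to unit fluence", {
  g <- geometry_point(2.7, 1.35, 0)
  a <- generate_photon_spectrum(g)
  b <- generate_photon_spectrum(g)
  expect_identical(a, b)
  expect_equal(sum(a$fluence * (a$e_high_MeV - a$e_low_MeV)), 1, tolerance = 1e-12)
})

test_that("photon spectra harden with depth and soften beyond the edge", {
  beam <- photon_beam_model()
  shallow <- generate_photon_spectrum(geometry_point(2.7, 0.15, 0), beam)
  deep <- generate_photon_spectrum(geometry_point(2.7, 9.85, 0), beam)
  expect_gt(effective_photon_energy(deep), effective_photon_energy(shallow))
  centre <- generate_photon_spectrum(geometry_point(2.7, 9.85, 0), beam)
  out <- generate_photon_spectrum(geometry_point(2.7, 9.85, 1.35 + 2), beam)
  expect_lt(effective_photon_energy(out), effective_photon_energy(centre))
})

test_that("scatter fraction is zero inside the field and saturating beyond", {
  beam <- photon_beam_model()
  expect_equal(scatter_fraction(c(-1, 0), beam), c(0, 0))
  f <- scatter_fraction(c(0.5, 1, 2, 5), beam)
  expect_true(all(diff(f) > 0))
  expect_true(all(f <= beam$scatter_max))
})

test_that("Compton recoil source respects the kinematic edge and is linear", {
  # monoenergetic photons at 1.25 MeV: T_max = 2k^2/(mc^2 + 2k) ~ 1.038 MeV
  mono <- tibble::tibble(e_low_MeV = 1.2499, e_high_MeV = 1.2501, fluence = 1e4)
  src <- compton_electron_source(mono)
  tmax <- 2 * 1.25^2 / (0.51099895 + 2 * 1.25)
  mid <- sqrt(src$e_low_MeV * src$e_high_MeV)
  expect_true(all(src$source[mid > tmax] == 0))
  expect_true(any(src$source[mid < tmax] > 0))
  expect_true(all(src$source >= 0))
  mono2 <- mono; mono2$fluence <- 2 * mono2$fluence
  expect_equal(compton_electron_source(mono2)$source, 2 * src$source,
               tolerance = 1e-12)
})

test_that("integrated recoil spectrum reproduces the Klein-Nishina total cross-section", {
  # quadrature of dsigma/dT over [0, T_max] vs the closed-form total
  for (k in c(0.3, 1.25, 5)) {
    tmax <- 2 * k^2 / (0.51099895 + 2 * k)
    grid <- seq(1e-6, tmax * (1 - 1e-9), length.out = 20001)
    dsdT <- penumbralet:::.kn_recoil(k, grid)
    total <- sum((dsdT[-1] + dsdT[-length(dsdT)]) / 2 * diff(grid))
    expect_equal(total, oracle_kn_total(k), tolerance = 2e-3)
  }
})

test_that("primaries-only slowing-down fluence matches the CSDA closed form", {
  tab <- test_water_table()
  grid <- default_energy_grid()
  n <- length(grid) - 1
  src <- tibble::tibble(e_low_MeV = grid[-(n + 1)], e_high_MeV = grid[-1],
                        source = 0)
  i0 <- 150  # a high-energy source bin
  src$source[i0] <- 1
  spec <- slowing_down_spectrum(src, tab, include_secondaries = FALSE)
  N <- src$source[i0] * (src$e_high_MeV[i0] - src$e_low_MeV[i0])
  mid <- sqrt(src$e_low_MeV * src$e_high_MeV)
  S <- let_lookup(tab, mid, "unrestricted") / 0.1  # MeV/cm
  below <- seq_len(i0 - 1)
  expect_equal(spec$fluence[below], N / S[below], tolerance = 1e-10)
  expect_true(all(spec$fluence[(i0 + 1):n] == 0))
})

test_that("Moller secondaries only add fluence, concentrated at low energies", {
  tab <- test_water_table()
  g <- geometry_point(2.7, 1.35, 0)
  src <- compton_electron_source(generate_photon_spectrum(g))
  prim <- slowing_down_spectrum(src, tab, include_secondaries = FALSE)
  tef <- slowing_down_spectrum(src, tab, include_secondaries = TRUE)
  se <- secondary_only_spectrum(src, tab)
  expect_true(all(tef$fluence >= prim$fluence * (1 - 1e-12)))
  mean_of <- function(s) {
    w <- s$fluence * (s$e_high_MeV - s$e_low_MeV)
    sum(sqrt(s$e_low_MeV * s$e_high_MeV) * w) / sum(w)
  }
  expect_lt(mean_of(se), mean_of(tef))
  expect_gt(dose_average_let(se, tab), dose_average_let(tef, tab))
})

test_that("a zero electron source is rejected by the spectrum constructor", {
  tab <- test_water_table()
  grid <- default_energy_grid()
  n <- length(grid) - 1
  src <- tibble::tibble(e_low_MeV = grid[-(n + 1)], e_high_MeV = grid[-1],
                        source = 0)
  expect_error(slowing_down_spectrum(src, tab), "no positive bin")
})

test_that("slowing-down closure: deposition equals source energy input", {
  tab <- test_water_table()
  g <- geometry_point(4.5, 1.35, 0)
  src <- compton_electron_source(generate_photon_spectrum(g))
  spec <- slowing_down_spectrum(src, tab, include_secondaries = FALSE)
  mid <- sqrt(src$e_low_MeV * src$e_high_MeV)
  dE <- src$e_high_MeV - src$e_low_MeV
  S <- let_lookup(tab, mid, "unrestricted") / 0.1
  S_delta <- let_lookup(tab, 0.001, "unrestricted") / 0.1
  deposit <- sum(spec$fluence * S * dE) +
    attr(spec, "track_end_fluence") * S_delta * 1e-3
  source_energy <- sum(src$source * mid * dE)
  expect_lt(abs(deposit / source_energy - 1), 0.02)
  # with knock-on feedback the closure holds against primary + secondary input
  tef <- slowing_down_spectrum(src, tab, include_secondaries = TRUE)
  K <- penumbralet:::.moller_kernel(mid, dE, 1e-3)
  q_sec <- as.numeric(K %*% tef$fluence)
  deposit2 <- sum(tef$fluence * S * dE) +
    attr(tef, "track_end_fluence") * S_delta * 1e-3
  input2 <- sum((src$source + q_sec) * mid * dE)
  expect_lt(abs(deposit2 / input2 - 1), 0.02)
})

test_that("non-convergence of the knock-on iteration errors with the residual", {
  tab <- test_water_table()
  g <- geometry_point(2.7, 1.35, 0)
  src <- compton_electron_source(generate_photon_spectrum(g))
  expect_error(slowing_down_spectrum(src, tab, tol = 1e-12, max_sweeps = 2),
               "did not converge")
})

test_that("generated cases are reproducible bitwise through the TSV writer", {
  tab <- test_water_table()
  g <- geometry_point(0.9, 1.35, 2.45)
  a <- generate_case(g, table = tab)
  b <- generate_case(g, table = tab)
  pa <- tempfile(); pb <- tempfile()
  on.exit(unlink(c(pa, pb)))
  write_spectrum_tsv(a$tef, pa)
  write_spectrum_tsv(b$tef, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_identical(a$se$fluence, b$se$fluence)
})

test_that("noise injection is seed-reproducible and leaves the RNG state alone", {
  tab <- test_water_table()
  g <- geometry_point(0.9, 1.35, 0)
  beam <- photon_beam_model(seed = 99L)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- generate_case(g, beam, tab, noise_sd = 0.05)
  after <- runif(1)
  b <- generate_case(g, beam, tab, noise_sd = 0.05)
  expect_identical(a$tef$fluence, b$tef$fluence)
  expect_identical(before, after)  # RNG stream undisturbed
  clean <- generate_case(g, beam, tab)
  expect_false(identical(a$tef$fluence, clean$tef$fluence))
})

test_that("increasing the scatter fraction softens photons and raises TEF LET", {
  tab <- test_water_table()
  g <- geometry_point(2.7, 9.85, 2.7 / 2 + 2)
  means <- c(); lets <- c()
  for (sm in c(0.2, 0.5, 0.8)) {
    beam <- photon_beam_model(scatter_max = sm)
    case <- generate_case(g, beam, tab)
    means <- c(means, effective_photon_energy(case$photon))
    lets <- c(lets, dose_average_let(case$tef, tab))
  }
  expect_true(all(diff(means) < 0))
  expect_true(all(diff(lets) > 0))
})

test_that("out-of-field cases have higher TEF dose-average LET than on-axis", {
  tab <- test_water_table()
  for (d in c(1.35, 9.85)) {
    on_axis <- generate_case(geometry_point(2.2, d, 0), table = tab)
    off <- generate_case(geometry_point(2.2, d, 1.1 + 2), table = tab)
    expect_gte(dose_average_let(off$tef, tab), dose_average_let(on_axis$tef, tab))
    expect_gt(dose_average_let(off$se, tab), dose_average_let(off$tef, tab))
  }
})
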