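test_that("a monoenergetic spectrum returns L_delta(E0) for both averages", {
  tab <- test_water_table()
  for (E0 in c(0.01, 0.3, 2)) {
    spec <- mono_spectrum(E0)
    L0 <- let_lookup(tab, sqrt(spec$e_low_MeV * spec$e_high_MeV))
    expect_equal(track_average_let(spec, tab), L0, tolerance = 1e-14)
    expect_equal(dose_average_let(spec, tab), L0, tolerance = 1e-14)
  }
})

test_that("two equal-fluence bins with L = 1 and 3 keV/um give 2.0 and 2.5", {
  tab <- synthetic_let_table(c(0.001, 0.2, 0.8, 2.0), c(12, 1, 3, 4))
  # bins [0.1, 0.4] and [0.4, 1.6]: geometric midpoints 0.2 and 0.8 MeV sit
  # exactly on table nodes; fluences chosen so each bin carries equal fluence
  spec <- fluence_spectrum(
    tibble::tibble(e_low_MeV = c(0.1, 0.4), e_high_MeV = c(0.4, 1.6),
                   fluence = c(1 / 0.3, 1 / 1.2)),
    delta_keV = 1, track_end_fluence = 0)
  expect_equal(track_average_let(spec, tab), 2.0, tolerance = 1e-12)
  expect_equal(dose_average_let(spec, tab), 2.5, tolerance = 1e-12)
})

test_that("moments agree with a hand-expanded sum on few-bin spectra", {
  tab <- test_water_table()
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    edges <- sort(exp(runif(n + 1, log(0.0012), log(6))))
    while (any(diff(edges) <= 0)) edges <- sort(exp(runif(n + 1, log(0.0012), log(6))))
    phi <- runif(n, 0, 5)
    phi[sample(n, 1)] <- phi[sample(n, 1)] + 0.5  # ensure a positive bin
    phid <- runif(1, 0, 2)
    spec <- fluence_spectrum(
      tibble::tibble(e_low_MeV = edges[-(n + 1)], e_high_MeV = edges[-1],
                     fluence = phi),
      delta_keV = 1, track_end_fluence = phid)
    mid <- sqrt(edges[-(n + 1)] * edges[-1])
    L <- let_lookup(tab, mid)
    w <- phi * diff(edges)
    Sd <- let_lookup(tab, 0.001, "unrestricted")
    dMeV <- 1e-3
    LD <- (sum(L^2 * w) + Sd^2 * phid * dMeV) / (sum(L * w) + Sd * phid * dMeV)
    LT <- (sum(L * w) + Sd * phid * dMeV) / (sum(w) + phid * dMeV)
    expect_equal(dose_average_let(spec, tab), LD, tolerance = 1e-12)
    expect_equal(track_average_let(spec, tab), LT, tolerance = 1e-12)
  }
})

test_that("dose average dominates track average across random spectra", {
  tab <- test_water_table()
  set.seed(123)
  for (rep in 1:300) {
    n <- sample(2:40, 1)
    edges <- sort(exp(runif(n + 1, log(0.001), log(6.5))))
    if (any(diff(edges) == 0)) next
    phi <- rexp(n)
    spec <- fluence_spectrum(
      tibble::tibble(e_low_MeV = edges[-(n + 1)], e_high_MeV = edges[-1],
                     fluence = phi),
      delta_keV = 1, track_end_fluence = rexp(1))
    expect_gte(dose_average_let(spec, tab) * (1 + 1e-12),
               track_average_let(spec, tab))
  }
})

test_that("both averages are invariant under rescaling of the fluence", {
  tab <- test_water_table()
  set.seed(5)
  edges <- exp(seq(log(0.001), log(5), length.out = 31))
  phi <- rexp(30)
  build <- function(c) fluence_spectrum(
    tibble::tibble(e_low_MeV = edges[-31], e_high_MeV = edges[-1],
                   fluence = c * phi),
    delta_keV = 1, track_end_fluence = c * 0.7)
  base_d <- dose_average_let(build(1), tab)
  base_t <- track_average_let(build(1), tab)
  for (c in c(1e-8, 3.7, 1e9)) {
    expect_equal(dose_average_let(build(c), tab), base_d, tolerance = 1e-13)
    expect_equal(track_average_let(build(c), tab), base_t, tolerance = 1e-13)
  }
})

test_that("halving bin widths of a smooth spectrum moves moments by < 0.2%", {
  tab <- test_water_table()
  make <- function(n) {
    edges <- exp(seq(log(0.001), log(6), length.out = n + 1))
    mid <- sqrt(edges[-(n + 1)] * edges[-1])
    fluence_spectrum(
      tibble::tibble(e_low_MeV = edges[-(n + 1)], e_high_MeV = edges[-1],
                     fluence = mid^0.4 * exp(-mid / 0.8)),
      delta_keV = 1, track_end_fluence = 0.01)
  }
  coarse <- make(100); fine <- make(200)
  expect_lt(abs(dose_average_let(fine, tab) / dose_average_let(coarse, tab) - 1), 0.002)
  expect_lt(abs(track_average_let(fine, tab) / track_average_let(coarse, tab) - 1), 0.002)
})

test_that("track-end terms follow their defining products and scale linearly", {
  tab <- test_water_table()
  spec0 <- mono_spectrum(0.5, track_end = 0)
  expect_true(all(track_end_terms(spec0, tab)$value == 0))
  spec1 <- mono_spectrum(0.5, track_end = 1)
  te <- track_end_terms(spec1, tab)
  Sd <- let_lookup(tab, 0.001, "unrestricted")
  expect_equal(te$value[te$term == "S_phi_delta"], Sd * 1 * 1e-3)
  expect_equal(te$value[te$term == "S2_phi_delta"], Sd^2 * 1 * 1e-3)
  expect_equal(te$value[te$term == "phi_delta"], 1e-3)
  spec2 <- mono_spectrum(0.5, track_end = 2)
  expect_equal(track_end_terms(spec2, tab)$value, 2 * te$value)
})

test_that("cutoff mismatches and invalid spectra are rejected", {
  tab <- test_water_table()                    # delta = 1 keV
  spec <- mono_spectrum(0.5, delta_keV = 10)   # delta = 10 keV
  expect_error(dose_average_let(spec, tab), "mismatch")
  expect_error(
    fluence_spectrum(tibble::tibble(e_low_MeV = 0.1, e_high_MeV = 0.2, fluence = 0)),
    "no positive bin")
  expect_error(
    fluence_spectrum(tibble::tibble(e_low_MeV = 1e-5, e_high_MeV = 0.2, fluence = 1)),
    "below the delta cutoff")
  expect_warning(
    fluence_spectrum(tibble::tibble(e_low_MeV = 0.1, e_high_MeV = 0.2, fluence = 1),
                     track_end_fluence = NA),
    "first bin")
})

test_that("uncertainty attachment validates and scales as stated", {
  tab <- test_water_table()
  spec <- mono_spectrum(0.5)
  res <- let_moments(spec, tab)
  expect_equal(res$rel_u, 0.006)
  expect_equal(res$dose_let * res$rel_u, res$dose_let * 0.006)
  res0 <- attach_uncertainty(res, 0)
  expect_equal(res0$rel_u, 0)
  expect_error(attach_uncertainty(res, 1.2), "fraction")
  expect_error(attach_uncertainty(res, -0.1), "fraction")
})

test_that("energy-fluence weighting is available and shifts the averages", {
  tab <- test_water_table()
  edges <- exp(seq(log(0.001), log(5), length.out = 41))
  spec <- fluence_spectrum(
    tibble::tibble(e_low_MeV = edges[-41], e_high_MeV = edges[-1],
                   fluence = rep(1, 40)),
    delta_keV = 1, track_end_fluence = 0.1)
  p <- track_average_let(spec, tab, weighting = "particle")
  e <- track_average_let(spec, tab, weighting = "energy")
  # energy weighting emphasises fast (low-LET) electrons
  expect_lt(e, p)
})

test_that("spectra round-trip through the TSV dialect with metadata", {
  spec <- fluence_spectrum(
    tibble::tibble(e_low_MeV = c(0.001, 0.01), e_high_MeV = c(0.01, 0.1),
                   fluence = c(2, 1)),
    delta_keV = 1, kind = "SE", track_end_fluence = 0.25,
    geometry = geometry_point(2.7, 1.35, 3.35))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_spectrum_tsv(spec, path)
  back <- read_spectrum_tsv(path)
  expect_equal(back$fluence, spec$fluence)
  expect_equal(attr(back, "kind"), "SE")
  expect_equal(attr(back, "track_end_fluence"), 0.25)
  expect_equal(attr(back, "geometry")$offaxis_cm, 3.35)
})
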