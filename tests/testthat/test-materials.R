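test_that("daily relaxation force follows the empirical branch model", {
  # peak on day 0 per unit increment: 3.57 + 6.79 + 6.89 + 1.22
  expect_equal(relaxation_force(0, 1, 0), 18.47, tolerance = 1e-12)
  # linear in the applied increment
  t <- c(0, 10, 1e3, 4e4)
  expect_equal(relaxation_force(3, 2, t), 2 * relaxation_force(3, 1, t))
  # long-time plateau fraction on day 0: 1.22 / 18.47
  expect_equal(relaxation_force(0, 1, 1e9) / relaxation_force(0, 1, 0),
               1.22 / 18.47, tolerance = 1e-10)
  # monotone non-increasing in t for all days 0..15
  tg <- c(0, 10^seq(-1, log10(43200), length.out = 80))
  for (j in seq(0, 15, by = 3)) {
    f <- relaxation_force(j, 1, tg)
    expect_true(all(diff(f) <= 0), info = paste("day", j))
  }
  expect_error(relaxation_force(0, 1, -1), "negative")
  expect_error(relaxation_force(0, -1, 1), "negative")
})

test_that("residual force is the fixed fraction of the peak", {
  expect_equal(residual_force(0, 100), 6.23)
  expect_equal(residual_force(5, 0), 0)
  expect_equal(residual_force(0, 18.47), 0.0623 * 18.47)
  expect_error(residual_force(0, -2), "negative")
})

test_that("fit_prony recovers an exact single-exponential model", {
  t <- c(0, 10^seq(-1, 3.5, length.out = 60))
  y <- 1 - 0.5 * (1 - exp(-t / 100))
  crv <- relaxation_curve(t, 20 * y)  # arbitrary peak scaling
  fit <- fit_prony(crv, n_terms = 1)
  expect_equal(fit$g, 0.5, tolerance = 1e-6)
  expect_equal(fit$tau, 100, tolerance = 1e-6)
})

test_that("fit_prony round-trips two-term models", {
  cases <- list(c(g1 = 0.3, g2 = 0.4, t1 = 5, t2 = 500),
                c(g1 = 0.396, g2 = 0.542, t1 = 10.775, t2 = 977.88),
                c(g1 = 0.1, g2 = 0.7, t1 = 50, t2 = 2000))
  for (p in cases) {
    t <- c(0, 10^seq(-1, log10(43200), length.out = 120))
    y <- 1 - p["g1"] * (1 - exp(-t / p["t1"])) -
      p["g2"] * (1 - exp(-t / p["t2"]))
    fit <- fit_prony(relaxation_curve(t, y), n_terms = 2)
    expect_equal(fit$g, unname(p[c("g1", "g2")]), tolerance = 1e-4)
    expect_equal(fit$tau, unname(p[c("t1", "t2")]), tolerance = 1e-4)
    expect_true(all(diff(fit$tau) > 0))  # sorted ascending
  }
})

test_that("two-term fit of the day-0 relaxation curve matches the published coefficients", {
  crv <- sample_relaxation_curve(j = 0)
  fit <- fit_prony(crv, n_terms = 2)
  expect_equal(fit$g[1], 0.396, tolerance = 0.1)
  expect_equal(fit$tau[1], 10.775, tolerance = 0.1)
  expect_equal(fit$g[2], 0.542, tolerance = 0.1)
  expect_equal(fit$tau[2], 977.88, tolerance = 0.1)
  # long-time fraction consistent with the residual-force fraction
  expect_equal(1 - sum(fit$g), 0.0623, tolerance = 0.15)
})

test_that("relaxation curves round-trip through CSV", {
  crv <- sample_relaxation_curve(j = 2, n = 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_relaxation_curve(crv, path)
  back <- read_relaxation_curve(path, day = 2)
  expect_equal(back$t, crv$t)
  expect_equal(back$force, crv$force, tolerance = 1e-12)
})

test_that("mixture rule is exact for pure phases and the cube-root blend", {
  lib <- material_library()
  pure_conn <- mixture_properties(tissue_state(), lib)
  expect_equal(pure_conn$E, unname(lib$connective["E"]))
  expect_equal(pure_conn$nu, unname(lib$connective["nu"]))
  expect_equal(pure_conn$prony$g, lib$callus_prony$g)

  pure_woven <- mixture_properties(tissue_state(conn = 0, bone = 100), lib)
  expect_equal(pure_woven$E, unname(lib$woven["E"]))
  expect_length(pure_woven$prony$g, 0)  # fully mineralised: elastic

  half <- mixture_properties(tissue_state(conn = 50, bone = 50),
                             material_library(connective = c(E = 3, nu = 0.3),
                                              woven = c(E = 4000, nu = 0.36)))
  expect_equal(half$E, (0.5 * 3^(1/3) + 0.5 * 4000^(1/3))^3, tolerance = 1e-12)
  expect_equal(half$E, 649.1, tolerance = 0.01)
})

test_that("mixture stiffness is monotone in mineralisation", {
  lib <- material_library()
  bones <- seq(0, 100, by = 5)
  E <- vapply(bones, function(b)
    mixture_properties(tissue_state(conn = 100 - b, bone = b), lib)$E, 0)
  expect_true(all(diff(E) > 0))
})

test_that("tissue state and library invariants are enforced", {
  expect_error(tissue_state(conn = 60, bone = 60), "sum to 100")
  expect_error(tissue_state(conn = 110, bone = -10), "non-negative")
  expect_error(material_library(cartilage = c(E = 5000, nu = 0.45)),
               "ordering")
  expect_error(prony_model(g = c(0.6, 0.5), tau = c(1, 10)), "sum")
  expect_error(prony_model(g = 0.5, tau = -1), "positive")
})

test_that("instantaneous-modulus calibration matches the day-0 peak stiffness", {
  geom <- do_geometry()  # 1 mm gap, annulus 12/16 mm
  E <- calibrate_instantaneous_modulus(geom)
  A <- pi / 4 * (16^2 - 12^2)
  expect_equal(E * A / 1, 18.47, tolerance = 1e-12)
})
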