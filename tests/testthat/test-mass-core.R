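# Mass functionals: thresholds, normalized current, outputs, closures.

test_that("threshold and maxima evaluation equals an independent Horner oracle", {
  fx <- make_fixture_mass("I", seed = 7)
  horner <- function(cf, x) {   # independent evaluation, increasing powers
    acc <- 0
    for (k in rev(seq_along(cf))) acc <- acc * x + cf[k]
    acc
  }
  for (d in c(3.25, 16.75)) {
    th <- thresholds_and_maxima(fx, d)
    x <- fx$nu_K_hat + d
    expect_equal(th$i_th1, horner(fx$coefficients$th1, x), tolerance = 1e-12)
    expect_equal(th$M1, horner(fx$coefficients$M1, x), tolerance = 1e-12)
  }
})

test_that("fixture parametrizations are deterministic and structurally valid", {
  a <- make_fixture_mass("E", seed = 3)
  b <- make_fixture_mass("E", seed = 3)
  expect_identical(a$coefficients, b$coefficients)
  th <- thresholds_and_maxima(a, seq(0, 20, by = 2))
  expect_true(all(th$i_th1 < th$i_th2))
  expect_equal(unname(a$exponents), c(0.5, 0.62, 0.28))
  expect_equal(a$C1, -65); expect_equal(a$C2, 0.1)
  i <- make_fixture_mass("I", seed = 3)
  expect_equal(unname(i$exponents), c(0.5, 0.5, 0.5))
  expect_equal(i$C1, -60); expect_equal(i$C2, 0)
})

test_that("mass outputs hit the edge values of the firing window", {
  fx <- make_fixture_mass("I")
  th <- thresholds_and_maxima(fx, 0)
  ev <- evaluate_mass(fx, c(th$i_th1, th$i_th2,
                            (th$i_th1 + 3 * th$i_th2) / 4), 0,
                      closure = "none")
  expect_equal(ev$Q, c(0, 1, 0.75), tolerance = 1e-12)
  expect_equal(ev$FR, c(0, th$M1, th$M1 * sqrt(0.75)), tolerance = 1e-12)
  expect_equal(ev$Vm[1], fx$C1)               # onset potential is C1
  expect_equal(ev$Vm[2], th$M2)               # boundary potential is M2
  expect_equal(ev$Kflux[2], th$M3)
  expect_equal(ev$regime, c("F", "F", "F"))
})

test_that("firing rate is continuous at onset, monotone in the window, zero outside", {
  fx <- make_fixture_mass("E")
  th <- thresholds_and_maxima(fx, 5)
  X <- seq(th$i_th1 - 2, th$i_th2 + 2, length.out = 101)
  ev <- evaluate_mass(fx, X, 5, closure = "none")
  expect_true(all(diff(ev$FR[ev$regime == "F"]) >= 0))
  expect_true(all(ev$FR[ev$regime != "F"] == 0))
  eps <- evaluate_mass(fx, th$i_th1 + 1e-9 * (th$i_th2 - th$i_th1), 5,
                       closure = "none")
  expect_lt(eps$FR, 1e-3 * th$M1)   # FR -> 0 continuously at i_th1
  expect_equal(ev$regime[1], "NF")
  expect_equal(ev$regime[101], "DB")
})

test_that("total current composes injected and signed synaptic terms", {
  fx <- make_fixture_mass("I")
  expect_equal(total_current(fx, 2), 2)
  syn <- list(list(g = 0.04, h = 50, sign = -1))
  expect_equal(total_current(fx, 2, 0, syn), 0)
  both <- list(list(g = 0.2, h = 10, sign = 1),
               list(g = 0.04, h = 25, sign = -1))
  expect_equal(total_current(fx, 0, 0, both), 2 - 1)
  expect_error(total_current(fx, 0, 0, list(list(g = 1, h = 1, sign = 2))),
               "sign")
  # the literal injected-plus-pump form is available on request
  expect_equal(total_current(fx, 0, 0, pump = TRUE), 1.25 / 4)
})

test_that("fixed-point closures give resting and depolarized branch values", {
  wbm <- get_wbm()
  th <- thresholds_and_maxima(wbm, 0)
  nf <- evaluate_mass(wbm, th$i_th1 - 0.3, 0)
  expect_equal(nf$regime, "NF")
  expect_lt(abs(nf$Vm + 64), 6)      # near rest
  expect_lt(nf$Kflux, 0)
  db <- evaluate_mass(wbm, th$i_th2 + 3, 0)
  expect_equal(db$regime, "DB")
  expect_gt(db$Vm, -35)
  expect_gt(db$Kflux, 0)
})

test_that("degenerate firing windows fall back to the sign of X - i_th1", {
  fx <- make_fixture_mass("I")
  fx$coefficients$th2 <- fx$coefficients$th1   # force i_th2 == i_th1
  expect_warning(lo <- evaluate_mass(fx, -5, 0, closure = "none"),
                 "degenerate")
  expect_equal(lo$regime, "NF")
  expect_warning(hi <- evaluate_mass(fx, 50, 0, closure = "none"),
                 "degenerate")
  expect_equal(hi$regime, "DB")
})

test_that("extrapolation beyond the fitted potassium window warns", {
  fx <- make_fixture_mass("I")
  expect_warning(thresholds_and_maxima(fx, 30), "outside the fitted range")
  expect_silent(thresholds_and_maxima(fx, 10))
})
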