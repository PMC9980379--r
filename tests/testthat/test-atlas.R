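# Analytic regime boundaries of the coupled network.

test_that("zero inhibitory coupling collapses the bistable band", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  rae <- rae_boundary(fE, fI, g_EI = 0.2, g_IE = 0, dnuK = 0)
  bs <- bistability_boundary(fE, fI, g_EI = 0.2, g_IE = 0, dnuK = 0)
  expect_equal(bs, rae)
  # any positive coupling opens a band of width g_IE * M1_I
  thI <- thresholds_and_maxima(fI, 0)
  bs2 <- bistability_boundary(fE, fI, g_EI = 0.2, g_IE = 0.04, dnuK = 0)
  rae2 <- rae_boundary(fE, fI, g_EI = 0.2, g_IE = 0.04, dnuK = 0)
  expect_equal(rae2 - bs2, 0.04 * thI$M1, tolerance = 1e-12)
  expect_lt(bs2, rae2)
})

test_that("an overwhelming excitatory coupling pushes the RAE boundary to onset", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  thE <- thresholds_and_maxima(fE, 0)
  rae <- rae_boundary(fE, fI, g_EI = 1e6, g_IE = 0, dnuK = 0)
  expect_equal(rae, thE$i_th1, tolerance = 1e-4)
})

test_that("the RAE boundary is absent when the E mass cannot silence the I mass", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  # tiny E-to-I coupling: required presynaptic rate far exceeds M1_E
  rae <- rae_boundary(fE, fI, g_EI = 1e-4, g_IE = 0.04, dnuK = 0)
  expect_true(is.na(rae))
  # the effective DB boundary then falls back to the bare line
  db <- db_boundary(fE, 0, rae)
  expect_equal(db$db_eff, db$db_bare)
})

test_that("effective DB onset never exceeds the bare line and equals RAE below it", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  rae <- rae_boundary(fE, fI, 0.2, 0.04, dnuK = 5)
  db <- db_boundary(fE, 5, rae)
  expect_lte(db$db_eff, db$db_bare)
  if (!is.na(rae) && rae < db$db_bare) expect_equal(db$db_eff, rae)
})

test_that("all boundaries shift to lower currents as potassium rises", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  at <- regime_atlas(fE, fI, dnuK = seq(0, 20, by = 2.5))
  expect_true(all(diff(at$rae) < 0))
  expect_true(all(diff(at$bs) < 0))
  expect_true(all(diff(at$db_bare) < 0))
  expect_true(all(diff(at$db_eff) < 0))
  # ordering invariant where the boundaries exist
  expect_true(all(at$bs <= at$rae))
  expect_true(all(at$fo <= at$bs))
  expect_true(all(at$db_eff <= at$db_bare))
})

test_that("the coupling-ratio atlas is consistent with the fixed-coupling atlas", {
  fE <- make_fixture_mass("E"); fI <- make_fixture_mass("I")
  ra <- regime_atlas(fE, fI, dnuK = 15, ratio = c(0.5, 1, 2), g_IE_hat = 0.04)
  fixed <- regime_atlas(fE, fI, g_IE = 0.04, dnuK = 15)
  for (col in c("fo", "bs", "rae", "db_bare", "db_eff"))
    expect_equal(ra[ra$ratio == 1, col], fixed[[col]], tolerance = 1e-12)
  # boundaries monotone in the coupling ratio
  expect_true(all(diff(ra$rae) > 0))
  expect_true(!is.unsorted(ra$db_eff))
})

test_that("analytic boundaries agree with slow-ramp transitions", {
  wbm <- get_wbm(); sem <- get_sem()
  for (cfg in list(list(d = 0, r = 1), list(d = 15, r = 1),
                   list(d = 0, r = 0.5))) {
    g_ie <- cfg$r * 0.04
    net <- mnm_network(sem, wbm, g_EI = 0.2, g_IE = g_ie, dnuK = cfg$d)
    rae <- rae_boundary(sem, wbm, 0.2, g_ie, cfg$d)
    bs <- bistability_boundary(sem, wbm, 0.2, g_ie, cfg$d)
    peak <- max(rae * 1.6, 40)
    h <- hysteresis_scan(net, peak = peak, duration = 30000)
    entry <- h$rising[["I_db_entry"]]
    if (cfg$d == 0) {
      # non-oscillatory approach: quasi-static theory applies tightly
      expect_lt(abs(entry - rae) / rae, 0.02)
    } else {
      # at elevated potassium the balanced branch loses stability through
      # the delayed-inhibition oscillation before the quasi-static boundary;
      # entry then happens inside the bistable band
      expect_gte(entry, bs)
      expect_lte(entry, rae * 1.02)
    }
    # the falling-phase recovery tracks the bistability boundary
    expect_lt(abs(h$falling[["I_db_exit"]] - bs), pmax(0.02 * bs, 0.1))
  }
})

test_that("regions contract with elevated potassium in the fitted masses", {
  wbm <- get_wbm(); sem <- get_sem()
  at <- regime_atlas(sem, wbm, dnuK = c(0, 15))
  # widths of the firing, bistable and RAE bands all shrink
  f_width <- at$bs - at$fo
  bs_width <- at$rae - at$bs
  rae_width <- at$db_bare - at$rae
  expect_lt(f_width[2], f_width[1])
  expect_lte(bs_width[2], bs_width[1] + 1e-9)
  expect_lt(rae_width[2], rae_width[1])
})
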