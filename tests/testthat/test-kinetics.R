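codata <- constants_profile("codata")

test_that("rate ratios follow the Arrhenius form and its symmetries", {
  expect_equal(rate_ratio(0, 298.15, codata), 1.0)
  # high-precision evaluation of exp(2.4 / (1.987204e-3 * 273.15))
  expect_equal(rate_ratio(2.4, 273.15, codata), 83.21929, tolerance = 1e-6)
  for (de in c(0.5, 1.3, 2.4, 8)) for (T in c(273.15, 303.15)) {
    expect_equal(rate_ratio(de, T, codata) * rate_ratio(-de, T, codata), 1,
                 tolerance = 1e-12)
  }
})

test_that("effective-constant calibration recovers planted constants exactly", {
  kb0 <- 1.75e-3
  cells <- expand.grid(delta_eps = c(1, 3, 6), T = c(273.15, 293.15))
  cells$ratio <- exp(cells$delta_eps / (kb0 * cells$T))
  fit <- fit_effective_kB(cells)
  expect_equal(fit$kB, kb0, tolerance = 1e-14)
  # single cell: exact inversion
  one <- data.frame(delta_eps = 2.4, T = 273.15, ratio = 106)
  expect_equal(fit_effective_kB(one)$kB, 2.4 / (273.15 * log(106)),
               tolerance = 1e-14)
  expect_error(fit_effective_kB(data.frame(delta_eps = 0, T = 273, ratio = 2)),
               "degenerate")
})

test_that("the calibrated constant matches per-cell inversion of the 8 kcal/mol row", {
  ref <- reference_rate_table()
  row8 <- ref[ref$delta_eps == 8, ]
  # independent oracle: invert each cell, then average
  kb_cells <- 8 / (celsius_to_kelvin(row8$temp_c) * log(row8$ratio))
  pe <- constants_profile("paper_effective")
  expect_equal(pe$kB, mean(kb_cells), tolerance = 1e-4)
  expect_equal(pe$kB, 1.886e-3, tolerance = 1e-3)
})

test_that("high-energy fraction equals the quadrature oracle", {
  expect_equal(high_energy_fraction(0, 300, codata), 1.0)
  # Ea = kB*T: erfc(1) + (2/sqrt(pi)) e^-1, cross-checked by quadrature
  expect_equal(high_energy_fraction(codata$kB * 300, 300, codata),
               0.5724067, tolerance = 1e-6)
  expect_equal(high_energy_fraction(codata$kB * 300, 300, codata),
               mb_fraction_quad(codata$kB * 300, 300), tolerance = 1e-10)
  # closed form vs adaptive quadrature over the whole working domain
  for (x in c(0.01, 0.5, 1, 2, 5, 10, 13.3, 20, 30, 40)) {
    Ea <- x * codata$kB * 283.15
    expect_equal(high_energy_fraction(Ea, 283.15, codata),
                 mb_fraction_quad(Ea, 283.15), tolerance = 1e-10)
  }
})

test_that("high-energy fraction is monotone in barrier and temperature", {
  Ea <- seq(0, 20, by = 0.5)
  f <- high_energy_fraction(Ea, 283.15, codata)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  Ts <- seq(260, 320, by = 5)
  fT <- high_energy_fraction(7.2, Ts, codata)
  expect_true(all(diff(fT) > 0))
})

test_that("enhancement factors reproduce the derived landmark values", {
  expect_equal(enhancement_factor(7.2, 283.15, 283.15, codata), 1.0)
  # quadrature-oracle value for the 0 -> 10 C warm-up at Ea = 7.2
  expect_equal(enhancement_factor(7.2, 273.15, 283.15, codata),
               mb_fraction_quad(7.2, 283.15) / mb_fraction_quad(7.2, 273.15),
               tolerance = 1e-10)
  expect_equal(enhancement_factor(7.2, 273.15, 283.15, codata), 1.571019,
               tolerance = 1e-6)
  # the 0 -> 30 C warm-up at the same barrier
  expect_equal(enhancement_factor(7.2, 273.15, 303.15, codata), 3.540518,
               tolerance = 1e-6)
  # strictly increasing in Ea for T2 > T1
  ef <- enhancement_factor(seq(1, 20, by = 1), 273.15, 283.15, codata)
  expect_true(all(diff(ef) > 0))
})

test_that("desorption partitioning splits and conserves counts", {
  p <- partition_desorbed(1000, 1)
  expect_equal(p$n_cis, 500); expect_equal(p$n_trans, 500)
  p991 <- partition_desorbed(1000, 106, "nearest")
  expect_identical(c(p991$n_cis, p991$n_trans), c(991, 9))
  p20k <- partition_desorbed(20000, 67.0, "nearest")
  expect_identical(c(p20k$n_cis, p20k$n_trans), c(19706, 294))
  # conservation: exact without rounding, within 1 with rounding
  set.seed(3)
  for (k in 1:25) {
    tot <- sample(10:100000, 1); r <- exp(runif(1, -3, 6))
    pe <- partition_desorbed(tot, r, "none")
    expect_equal(pe$n_cis + pe$n_trans, tot, tolerance = 1e-9)
    pn <- partition_desorbed(tot, r, "nearest")
    expect_lte(abs(pn$n_cis + pn$n_trans - tot), 1)
  }
})

test_that("isomer-specific enhancement factors follow the count ratios", {
  p1 <- partition_desorbed(1000, 106, "nearest")
  expect_equal(unclass(isomer_specific_EF(p1, p1))[c("EF_cis", "EF_trans")],
               list(EF_cis = 1, EF_trans = 1))
  p10 <- partition_desorbed(3000, 90.2, "nearest")
  ef10 <- isomer_specific_EF(p1, p10)
  expect_equal(round(ef10$EF_cis, 2), 2.99)
  p30 <- partition_desorbed(20000, 67.0, "nearest")
  ef30 <- isomer_specific_EF(p1, p30)
  expect_equal(round(ef30$EF_cis, 1), 19.9)
  expect_equal(round(ef30$EF_trans, 1), 32.7)
  expect_error(isomer_specific_EF(p1, partition_desorbed(3000, 90.2, "none")),
               "rounding")
})

test_that("the rate-table replica matches the reference under calibration", {
  pe <- constants_profile("paper_effective")
  tab <- table2_replica(pe)
  expect_true(all(tab$ratio > 1))
  for (de in unique(tab$delta_eps)) {
    sub <- tab[tab$delta_eps == de, ]
    expect_true(all(diff(sub$ratio[order(sub$temp_c)]) < 0))
  }
  m <- merge(tab, reference_rate_table(), by = c("delta_eps", "temp_c"),
             suffixes = c("_got", "_ref"))
  expect_lt(max(abs(m$ratio_got / m$ratio_ref - 1)), 0.05)
  # the standard constant underestimates every reference cell
  mc <- merge(table2_replica(codata), reference_rate_table(),
              by = c("delta_eps", "temp_c"), suffixes = c("_got", "_ref"))
  expect_true(all(mc$ratio_got < mc$ratio_ref))
})

test_that("enhancement curves are ordered EF_trans >= EF_total >= EF_cis", {
  cur <- ef_curve(2.4, Ea_grid = seq(2, 18, by = 2), profile = codata)
  expect_true(all(cur$EF_trans >= cur$EF_total))
  expect_true(all(cur$EF_total >= cur$EF_cis))
  # degenerate temperature change: everything is 1
  flat <- ef_curve(2.4, Ea_grid = c(5, 10), T2_list = 273.15, profile = codata)
  expect_equal(flat$EF_total, c(1, 1))
  expect_equal(flat$EF_cis, c(1, 1))
  # strictly increasing in Ea for a genuine warm-up
  warm <- ef_curve(2.4, Ea_grid = seq(1, 20), T2_list = 283.15,
                   profile = codata)
  expect_true(all(diff(warm$EF_total) > 0))
})
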