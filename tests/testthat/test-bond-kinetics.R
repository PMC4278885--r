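# Bell kinetics, first-rupture competition, and the KMC oracle.

test_that("bell_rate matches the Bell law and validates its domain", {
  expect_equal(bell_rate(bell_bond(1e-4, 1.0), force = 0), 1e-4)
  expect_equal(bell_rate(bell_bond(1e-4, 0), force = 100), 1e-4)
  # hand evaluation: 1e-4 * e^10 at F = 41.1, dx = 1, kT = 4.11
  expect_equal(bell_rate(bell_bond(1e-4, 1.0), force = 41.1, kT = 4.11),
               1e-4 * exp(10), tolerance = 1e-12)
  # monotone non-decreasing in force
  f <- seq(0, 80, by = 5)
  expect_true(all(diff(bell_rate(bell_bond(1e-3, 0.8), f)) >= 0))
  expect_error(bell_rate(bell_bond(1e-4, 1), force = -1), "force")
  expect_error(bell_rate(bell_bond(1e-4, 1), force = 1, kT = 0), "kT")
  expect_error(bell_bond(-1, 1), "k0")
  expect_error(bell_bond(1, -1), "dx")
  expect_error(bell_bond(1, 1, label = ""), "label")
})

test_that("force_ramp validates inputs and multiplies speed by stiffness", {
  r <- force_ramp(retraction_speed = 2, effective_stiffness = 50)
  expect_equal(r$loading_rate, 2 * 1000 * 50)
  expect_equal(force_ramp(loading_rate = 3e4)$loading_rate, 3e4)
  expect_error(force_ramp(loading_rate = 0), "loading_rate")
  expect_error(force_ramp(kT = -1), "kT")
})

test_that("identical bonds split rupture probability 50:50", {
  b <- bell_bond(1e-3, 1.0)
  expect_equal(first_rupture_prob(serial_probe(b, b), default_ramp()), 0.5,
               tolerance = 1e-9)
  # also at unequal dx and different loading rates
  b2 <- bell_bond(7e-2, 0.4)
  expect_equal(first_rupture_prob(serial_probe(b2, b2), force_ramp(loading_rate = 1e3)),
               0.5, tolerance = 1e-9)
})

test_that("equal-dx probes follow the closed form k0_ref/(k0_ref + k0_prot)", {
  # hazards stay proportional at every force, so the split is ramp-independent
  expect_equal(first_rupture_prob(
    serial_probe(bell_bond(1e-3, 1), bell_bond(2e-3, 1)), default_ramp()),
    2 / 3, tolerance = 1e-9)
  set.seed(101)
  for (i in 1:10) {
    k_prot <- 10^runif(1, -5, -1); k_ref <- 10^runif(1, -5, -1)
    dx <- runif(1, 0.2, 2)
    ramp <- force_ramp(loading_rate = 10^runif(1, 3, 6))
    p <- first_rupture_prob(
      serial_probe(bell_bond(k_prot, dx), bell_bond(k_ref, dx)), ramp)
    expect_equal(p, k_ref / (k_ref + k_prot), tolerance = 1e-9)
  }
})

test_that("first_rupture_prob is a probability with label-exchange symmetry", {
  set.seed(42)
  for (i in 1:8) {
    prot <- bell_bond(10^runif(1, -5, -1), runif(1, 0.2, 1.8))
    ref <- bell_bond(10^runif(1, -5, -1), runif(1, 0.2, 1.8))
    ramp <- default_ramp()
    p <- first_rupture_prob(serial_probe(prot, ref), ramp)
    p_swapped <- first_rupture_prob(serial_probe(ref, prot), ramp)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_lt(abs(p_swapped - (1 - p)), 1e-8)  # absolute: p may sit at 0/1
  }
})

test_that("degenerate probes are handled: unbreakable bonds", {
  dead <- bell_bond(0, 1)
  live <- bell_bond(1e-3, 1)
  expect_error(first_rupture_prob(serial_probe(dead, dead), default_ramp()),
               "no rupture possible")
  expect_equal(first_rupture_prob(serial_probe(dead, live), default_ramp()), 1)
  expect_equal(first_rupture_prob(serial_probe(live, dead), default_ramp()), 0)
})

test_that("KMC oracle: trivial limits, determinism, and bookkeeping", {
  ramp <- default_ramp()
  live <- bell_bond(1e-3, 1)
  dead <- bell_bond(0, 1)
  # unbreakable reference -> protein always breaks
  st <- simulate_ruptures_kmc(serial_probe(live, dead), ramp, n = 500, seed = 3)
  expect_equal(st$n_protein_broken, 500L)
  expect_equal(st$n_reference_broken + st$n_protein_broken, st$n_trials)
  expect_error(simulate_ruptures_kmc(serial_probe(live, live), ramp, n = 0, seed = 1),
               "n must be")
  expect_error(simulate_ruptures_kmc(serial_probe(dead, dead), ramp, n = 10, seed = 1),
               "no rupture possible")
  # identical bonds: fraction within 3 binomial SE of 0.5
  st2 <- simulate_ruptures_kmc(serial_probe(live, live), ramp, n = 1e5, seed = 11)
  expect_lt(abs(st2$n_reference_broken / 1e5 - 0.5), 3 * sqrt(0.25 / 1e5))
  # same seed -> identical result; different seed -> (almost surely) not
  st3 <- simulate_ruptures_kmc(serial_probe(live, live), ramp, n = 1e5, seed = 11)
  expect_identical(st2$n_reference_broken, st3$n_reference_broken)
  expect_identical(st2$mean_rupture_force, st3$mean_rupture_force)
})

test_that("KMC agrees with quadrature within 3 binomial SE (unequal dx)", {
  ramp <- default_ramp()
  set.seed(7)
  for (i in 1:4) {
    probe <- serial_probe(bell_bond(10^runif(1, -4, -1), runif(1, 0.4, 1.6)),
                          bell_bond(10^runif(1, -4, -1), runif(1, 0.4, 1.6)))
    p <- first_rupture_prob(probe, ramp)
    n <- 1e5
    st <- simulate_ruptures_kmc(probe, ramp, n = n, seed = 100 + i)
    se <- sqrt(max(p * (1 - p), 1 / n) / n)
    expect_lt(abs(st$n_reference_broken / n - p), 3 * se)
  }
})

test_that("most_probable_rupture_force: closed form, monotonicity, round trip", {
  ramp <- default_ramp()
  # hand evaluation of (kT/dx) ln(r dx / (k0 kT)) at the default ramp
  expect_equal(most_probable_rupture_force(bell_bond(1e-4, 1.0), ramp),
               4.11 * log(1e5 * 1 / (1e-4 * 4.11)), tolerance = 1e-12)
  expect_equal(round(most_probable_rupture_force(bell_bond(1e-4, 1.0), ramp), 1),
               79.4)
  # doubling the loading rate increases the most probable force
  expect_gt(most_probable_rupture_force(bell_bond(1e-4, 1), force_ramp(loading_rate = 2e5)),
            most_probable_rupture_force(bell_bond(1e-4, 1), ramp))
  expect_error(most_probable_rupture_force(bell_bond(0, 1), ramp), "k0 > 0")
  expect_error(most_probable_rupture_force(bell_bond(1e-3, 0), ramp), "dx > 0")
  # inverse round trip F -> bond -> F
  for (f in c(15, 32.5, 65, 90)) {
    b <- bond_from_characteristic_force(f, ramp, dx = 0.8)
    expect_equal(most_probable_rupture_force(b, ramp), f, tolerance = 1e-9)
  }
})

test_that("bond_from_characteristic_force: hand value and monotonicity", {
  ramp <- default_ramp()
  b <- bond_from_characteristic_force(65, ramp, dx = 1)
  expect_equal(b$k0, 1e5 * 1 / 4.11 * exp(-65 / 4.11), tolerance = 1e-12)
  expect_equal(b$k0, 3.3e-3, tolerance = 0.02)  # approximate hand evaluation
  # larger force at fixed dx -> smaller k0
  k0s <- vapply(c(30, 50, 70, 90),
                function(f) bond_from_characteristic_force(f, ramp)$k0, numeric(1))
  expect_true(all(diff(k0s) < 0))
  expect_error(bond_from_characteristic_force(0, ramp), "force")
  expect_error(bond_from_characteristic_force(10, ramp, dx = 0), "dx")
})

test_that("sensitivity_curve: NF monotone, balanced point steepest", {
  ramp <- default_ramp()
  ref <- bond_from_characteristic_force(65, ramp, label = "ref")
  grid <- seq(45, 85, by = 1)
  sc <- sensitivity_curve(ref, grid, ramp)
  expect_equal(nrow(sc), length(grid))
  expect_true(all(diff(sc$nf) >= 0))           # stronger protein, higher NF
  # NF ~ 0.5 exactly when protein matches the reference characteristic force
  expect_equal(sc$nf[sc$protein_force == 65], 0.5, tolerance = 1e-6)
  # far stronger protein: NF -> 1
  expect_gt(sc$nf[length(grid)], 0.99)
  # |slope| maximal at the grid point whose NF is nearest 0.5,
  # and clearly steeper than where NF ~ 0.9
  i_max <- which.max(abs(sc$slope))
  i_bal <- which.min(abs(sc$nf - 0.5))
  expect_lte(abs(i_max - i_bal), 1)            # within grid resolution
  i_09 <- which.min(abs(sc$nf - 0.9))
  expect_gt(abs(sc$slope[i_bal]), abs(sc$slope[i_09]))
  expect_error(sensitivity_curve(ref, numeric(0), ramp), "non-empty")
  expect_error(sensitivity_curve(ref, c(2, 1), ramp), "sorted")
})
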