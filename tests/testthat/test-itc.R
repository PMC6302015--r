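ca_seq <- sequential_params(c(4.3e6, 2.0e5, 3.5e6), c(-10.1, 1.4, -17.8))
zn_two <- two_sets_params(0.7, 2.3e5, -11.8, 2.0, 9.2e6, -7.3)
mg_one <- one_set_params(2.7, 5.2e5, -2.1)

test_that("free-ligand mass balance matches an independent bisection", {
  p <- one_set_params(1, 1e6, -10)
  expect_equal(free_ligand(0, 25e-6, p), 0)
  # vanishing affinity: everything stays free
  weak <- one_set_params(1, 1e-9, -10)
  expect_equal(free_ligand(10e-6, 25e-6, weak), 10e-6, tolerance = 1e-9)
  for (pars in list(p, zn_two, ca_seq)) {
    for (lt in c(1e-6, 10e-6, 60e-6, 200e-6)) {
      got <- free_ligand(lt, 25e-6, pars)
      want <- bisect_free_ligand(lt, 25e-6,
                                 function(x) bound_per_protein(pars, x))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("overflow-cell dilution bookkeeping conserves mass", {
  prot <- titration_protocol(cell_volume = 200e-6,
                             injection_volumes = rep(2e-6, 25))
  c1 <- cell_composition(prot, 1)
  expect_equal(c1$total_protein, 25e-6 * (1 - 0.01))
  expect_equal(c1$total_ligand, 500e-6 * 0.01)
  # closed-form mass accounting: cell content = delivered - overflowed
  comp <- cell_composition(prot)
  xprev <- c(0, head(comp$total_ligand, -1))
  delivered <- prot$syringe_ligand_conc * sum(prot$injection_volumes)
  overflow <- sum(prot$injection_volumes * xprev)
  expect_equal(prot$cell_volume * tail(comp$total_ligand, 1),
               delivered - overflow, tolerance = 1e-12)
  expect_error(cell_composition(prot, 26), "out of range")
})

test_that("simulated heats vanish without enthalpy and at saturation", {
  prot <- titration_protocol()
  zero <- simulate_isotherm(prot, one_set_params(1, 1e7, 0))
  expect_equal(zero$heat, rep(0, nrow(zero)))
  iso <- simulate_isotherm(prot, one_set_params(1, 1e7, -10))
  expect_gt(abs(iso$heat[1]), 9)
  expect_lt(abs(tail(iso$heat, 1)), 0.05)
  expect_true(all(diff(iso$molar_ratio) > 0))
  expect_error(simulate_isotherm(prot, mg_one, noise_sd = -1), "non-negative")
})

test_that("one-set cumulative heat matches the closed-form isotherm", {
  prot <- titration_protocol(syringe_ligand_conc = 500e-6)
  p <- one_set_params(1.3, 1e7, -10)
  iso <- simulate_isotherm(prot, p)
  comp <- cell_composition(prot)
  q_sim <- attr(iso, "Q_kcal_per_L") * prot$cell_volume
  q_ref <- wiseman_cumulative_heat(p$n, p$k_a, p$dh, comp$total_protein,
                                   comp$total_ligand, prot$cell_volume)
  expect_equal(q_sim, q_ref, tolerance = 1e-8)
})

test_that("mass is conserved at every simulated injection", {
  prot <- titration_protocol()
  for (pars in list(mg_one, zn_two, ca_seq)) {
    iso <- simulate_isotherm(prot, pars)
    comp <- cell_composition(prot)
    bound <- comp$total_protein * bound_per_protein(pars, iso$free_ligand)
    expect_equal(iso$free_ligand + bound, comp$total_ligand,
                 tolerance = 1e-10)
  }
})

test_that("model reductions reproduce the one-set isotherm pointwise", {
  prot <- titration_protocol()
  one <- simulate_isotherm(prot, one_set_params(1, 2e6, -8))
  seq0 <- simulate_isotherm(prot, sequential_params(c(2e6, 0, 0),
                                                    c(-8, 0, 0)))
  expect_equal(seq0$heat, one$heat, tolerance = 1e-9)
  both <- simulate_isotherm(prot, two_sets_params(0.4, 2e6, -8, 0.6, 2e6, -8))
  expect_equal(both$heat, one$heat, tolerance = 1e-9)
})

test_that("sequential calcium parameters give a multiphasic isotherm", {
  p <- titration_protocol(syringe_ligand_conc = 500e-6)
  iso <- simulate_isotherm(p, ca_seq)
  # three overlapping binding steps leave a plateau/shoulder: |heat| is not
  # monotone before saturation
  early <- abs(iso$heat[iso$molar_ratio < 3])
  expect_true(any(diff(early) > 1e-3))
  expect_true(any(diff(early) < -1e-3))
  # heats die out once all three sites fill
  expect_lt(max(abs(tail(iso$heat, 5))), 0.05)
})

test_that("single-site exothermic heats decay after the stoichiometry point", {
  prot <- titration_protocol(syringe_ligand_conc = 750e-6)
  iso <- simulate_isotherm(prot, one_set_params(2, 1e6, -12))
  past <- which(iso$molar_ratio > 2)
  expect_true(all(diff(abs(iso$heat[past])) <= 1e-12))
})

test_that("noiseless fits recover the generating parameters exactly", {
  prot <- titration_protocol(syringe_ligand_conc = 750e-6)
  iso <- simulate_isotherm(prot, mg_one)
  fit <- fit_isotherm(iso, prot, "one_set", n_starts = 4)
  expect_true(fit$converged)
  expect_equal(fit$params$n, mg_one$n, tolerance = 1e-6)
  expect_equal(fit$params$k_a, mg_one$k_a, tolerance = 1e-6)
  expect_equal(fit$params$dh, mg_one$dh, tolerance = 1e-6)
  expect_true(all(is.finite(fit$param_errors)))
  # flat isotherm: flagged, not thrown
  flat <- iso
  flat$heat <- rep(1, nrow(flat))
  expect_false(fit_isotherm(flat, prot, "one_set")$converged)
})

test_that("fitted log10 K is nearly unbiased at moderate c-values", {
  prot <- titration_protocol(syringe_ligand_conc = 750e-6,
                             injection_volumes = rep(2e-6, 30))
  for (k_true in c(4e5, 4e6)) {   # c = n K Mt of ~20 and ~200
    p <- one_set_params(2, k_true, -8)
    lk <- vapply(1:10, function(s) {
      d <- gen_itc_dataset(prot, p, noise_frac = 0.01, seed = s)
      log10(fit_isotherm(d$isotherm, prot, "one_set", n_starts = 4,
                         seed = s)$params$k_a)
    }, numeric(1))
    expect_lt(abs(mean(lk) - log10(k_true)), 0.1)
  }
})

test_that("derived thermodynamics reproduce the reference binding table", {
  t1 <- derive_thermo(3.320e4, -3.0, 298.15)
  expect_equal(t1$k_d, 30.12e-6, tolerance = 1e-3)
  expect_equal(round(t1$dg, 1), -6.2)
  expect_equal(round(t1$ds, 1), 10.6)
  t2 <- derive_thermo(11.800e4, -3.2, 298.15)
  expect_equal(round(t2$dg, 1), -6.9)
  # the table's 12.4 follows from the rounded dG (-6.9); the unrounded
  # computation gives 12.47
  expect_equal(t2$ds, 1000 * (-3.2 + 6.9) / 298.15, tolerance = 0.01)
  # identity checks
  expect_equal(derive_thermo(1, -5, 300)$dg, 0)
  expect_equal(t1$dg, t1$dh - 298.15 * t1$ds / 1000, tolerance = 1e-9)
  expect_error(derive_thermo(-1, 0), "positive")
})
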