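test_that("coupling coefficient arithmetic, symmetry and unit invariance", {
  # additive construction: kd_ab = kd_a * kd_b / kd_wt
  add <- coupling_coefficient(1e-4, 3e-4, 5e-4, 3e-4 * 5e-4 / 1e-4)
  expect_equal(add$omega, 1.0)
  expect_equal(add$verdict, "additive")
  # (100, 300, 500, 3000) uM: omega = (3 * 5) / 30 = 0.5
  half <- coupling_coefficient(100e-6, 300e-6, 500e-6, 3000e-6)
  expect_equal(half$omega, 0.5)
  # swapping A and B leaves omega unchanged
  swap <- coupling_coefficient(100e-6, 500e-6, 300e-6, 3000e-6)
  expect_equal(swap$omega, half$omega)
  # unit invariance
  mm <- coupling_coefficient(0.1, 0.3, 0.5, 3)
  expect_equal(mm$omega, half$omega)
  expect_error(coupling_coefficient(1, -1, 1, 1), "positive")
})

test_that("cycle scan over preset genotypes reproduces the designed couplings", {
  p <- kir_presets()
  cond <- solution_condition(100, 100, c(Mg = 0))
  gens <- c("WT", "E224G", "G177N", "M183N", "D172N", "A184Q",
            "E224G/G177N", "E224G/M183N", "E224G/D172N", "E224G/A184Q")
  kds <- sapply(gens, function(g)
    apparent_kd(state_model(apply_genotype(p$blockers$Mg, p$genotypes[[g]])),
                40, cond))
  pairs <- list(c("E224G", "G177N"), c("E224G", "M183N"),
                c("E224G", "D172N"), c("E224G", "A184Q"),
                c("E224G", "A178C"))
  scan <- cycle_scan(kds, pairs, v = 40)
  get <- function(bname) scan$omega[scan$mut_b == bname]
  # boundary-residue doubles are built additively: omega exactly 1
  expect_equal(get("D172N"), 1, tolerance = 1e-9)
  expect_equal(get("A184Q"), 1, tolerance = 1e-9)
  # bundle-crossing doubles carry a negative-cooperative interaction
  expect_lt(get("G177N"), 0.5)
  expect_lt(get("M183N"), 0.5)
  expect_equal(scan$verdict[scan$mut_b == "G177N"], "negative-cooperative")
  # pair with a missing double is skipped, not fatal
  expect_true("E224G/A178C" %in% names(attr(scan, "skipped")))
})

test_that("no-interaction two-blocker model factorizes: f_both = f_a * f_b", {
  # both blockers without punch-through: the doubly-occupied state is in
  # detailed balance and open probability factorizes exactly
  a <- simple_blocker("A", kon0 = 5e6, koff0 = 4300)
  b <- simple_blocker("B", kon0 = 1e7, koff0 = 8000, z = 4,
                      delta_on = 0.06, zdelta_off = 1.0)
  conc <- c(A = 1e-3, B = 1e-3)
  cond <- solution_condition(100, 100, conc)
  m4 <- state_model(list(a, b))
  for (v in c(-30, 30, 100)) {
    f_both <- steady_state(m4, v, cond)[["O"]]
    f_a <- steady_state(state_model(a), v,
                        solution_condition(100, 100, conc["A"]))[["O"]]
    f_b <- steady_state(state_model(b), v,
                        solution_condition(100, 100, conc["B"]))[["O"]]
    expect_equal(f_both, f_a * f_b, tolerance = 1e-9)
  }
})

test_that("steady-state synergy flag separates occlusion from independence", {
  # full preset model (punch-through + occlusion): synergy at +100 mV
  des <- design_synergy(conc_a = 1e-3, conc_b = 1e-5, test_mv = 100)
  ex <- generate_experiment(des, seed = 21, noise_sd = 0)
  res <- synergy_steady_state(ex, v = 100)
  expect_lt(res$f_both, res$f_pred_independent)
  expect_lt(res$f_both, res$f_pred_competition)
  expect_true(res$flags$steady_state_synergy)
  # no-interaction model: flag must stay off (false-positive control)
  a <- simple_blocker("A", kon0 = 5e6, koff0 = 4300)
  b <- simple_blocker("B", kon0 = 1e7, koff0 = 8000, z = 4,
                      delta_on = 0.06, zdelta_off = 1.0)
  pre <- custom_presets(list(a, b))
  kd_a <- apparent_kd(state_model(a), 100, solution_condition(100, 100, c(A = 0)))
  kd_b <- apparent_kd(state_model(b), 100, solution_condition(100, 100, c(B = 0)))
  des0 <- design_synergy(conc_a = kd_a, conc_b = kd_b, blocker_a = "A",
                         blocker_b = "B", test_mv = 100)
  ex0 <- generate_experiment(des0, seed = 22, presets = pre, noise_sd = 0)
  res0 <- synergy_steady_state(ex0, v = 100)
  expect_equal(res0$f_both, res0$f_pred_independent, tolerance = 1e-4)
  expect_false(res0$flags$steady_state_synergy)
  # absent blocker A reduces the prediction to f_b
  desA0 <- design_synergy(conc_a = 0, conc_b = kd_b, blocker_a = "A",
                          blocker_b = "B", test_mv = 100)
  exA0 <- generate_experiment(desA0, seed = 23, presets = pre, noise_sd = 0)
  rA0 <- synergy_steady_state(exA0, v = 100)
  expect_equal(rA0$f_a, 1, tolerance = 1e-9)
  expect_equal(rA0$f_pred_independent, rA0$f_b, tolerance = 1e-9)
  # missing design group is a design error
  broken <- filter_experiment(ex, ex$design$group != "B")
  expect_error(synergy_steady_state(broken, v = 100), "missing group")
})

test_that("onset rates add when unbinding is negligible", {
  # parallel entry: decay of P_O at rate konA[A] + konB[B]. The blockers
  # unbind readily at and below 0 mV (so the holding/pre-pulse equilibria
  # leave the pore mostly open) but have negligible off rates at +100 mV
  # where the onset is measured.
  a <- blocker_spec("A", z = 2, kon0 = 5e6, delta_on = 0, koff0 = 500,
                    zdelta_off = 1.5, theta = 2, vs = 4)
  b <- blocker_spec("B", z = 4, kon0 = 1e7, delta_on = 0, koff0 = 500,
                    zdelta_off = 1.5, theta = 2, vs = 4)
  pre <- custom_presets(list(a, b))
  des <- design_synergy(conc_a = 1e-6, conc_b = 8e-7, blocker_a = "A",
                        blocker_b = "B", test_mv = 100)
  des$test_ms <- 600
  ex <- generate_experiment(des, seed = 31, noise_sd = 0, presets = pre)
  res <- synergy_kinetics(ex, v = 100, tolerance = 0.02)
  cond <- solution_condition(100, 100, c(A = 1e-6, B = 8e-7))
  expect_equal(res$rate_a, rate_on(a, 100, cond) + rate_off(a, 100, cond),
               tolerance = 0.02)
  expect_equal(res$rate_b, rate_on(b, 100, cond) + rate_off(b, 100, cond),
               tolerance = 0.02)
  expect_equal(res$rate_both, res$rate_a + res$rate_b, tolerance = 0.02)
  expect_true(res$flags$kinetic_additivity)
  # blocker A absent: its group shows no decay and rate_both reduces to B's
  des0 <- design_synergy(conc_a = 0, conc_b = 8e-7, blocker_a = "A",
                         blocker_b = "B", test_mv = 100)
  des0$test_ms <- 600
  ex0 <- generate_experiment(des0, seed = 32, noise_sd = 0, presets = pre)
  res0 <- synergy_kinetics(ex0, v = 100)
  expect_equal(res0$rate_a, 0)
  expect_equal(res0$rate_both, res0$rate_b, tolerance = 0.02)
})

test_that("initial decay slope of the open state is exactly additive", {
  p <- kir_presets()
  cond_ab <- solution_condition(100, 100, c(Mg = 1e-3, SPM = 1e-5))
  m4 <- state_model(list(p$blockers$Mg, p$blockers$SPM))
  q <- build_generator(m4, 100, cond_ab)
  slope_both <- -q["O", "O"]
  m_a <- state_model(p$blockers$Mg)
  m_b <- state_model(p$blockers$SPM)
  qa <- build_generator(m_a, 100, solution_condition(100, 100, c(Mg = 1e-3)))
  qb <- build_generator(m_b, 100, solution_condition(100, 100, c(SPM = 1e-5)))
  expect_equal(slope_both, -qa["O", "O"] - qb["O", "O"], tolerance = 1e-12)
})

test_that("relative currents move oppositely for Mg and SPM with depolarization in asymmetric K+", {
  # 20 mM out / 100 mM in: Mg block deepens (+20 to +100 mV) while SPM
  # block is relieved by punch-through
  p <- kir_presets()
  cond <- solution_condition(k_in = 100, k_out = 20, c(Mg = 0, SPM = 0))
  v <- seq(20, 100, 20)
  f_mg <- hill_relative_current(1e-3, apparent_kd(state_model(p$blockers$Mg), v, cond))
  f_spm <- hill_relative_current(1e-5, apparent_kd(state_model(p$blockers$SPM), v, cond))
  expect_true(all(diff(f_mg) < 0))
  expect_true(all(diff(f_spm[-1]) > 0))
  expect_gt(f_spm[length(f_spm)], f_spm[1])
})
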