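test_that("Nernst potential matches the standard cases", {
  expect_equal(nernst_potential(solution_condition(100, 100)), 0)
  expect_equal(nernst_potential(solution_condition(300, 300)), 0)
  ek <- nernst_potential(solution_condition(k_in = 100, k_out = 20))
  expect_equal(ek, 25 * log(20 / 100))
  expect_equal(round(ek), -40)
  expect_error(solution_condition(k_in = -1), "positive")
})

test_that("GHK open-channel current has the right zeros, sign and value", {
  sym <- solution_condition(100, 100)
  expect_equal(open_channel_current(0, sym), 0)
  asym <- solution_condition(k_in = 100, k_out = 20)
  expect_equal(open_channel_current(nernst_potential(asym), asym), 0,
               tolerance = 1e-12)
  # direct one-line evaluation of the GHK expression as oracle
  perm <- 0.07
  u <- 50 / 25
  expect_equal(open_channel_current(50, sym, perm),
               perm * u * (100 - 100 * exp(-u)) / (1 - exp(-u)))
  expect_lt(open_channel_current(-100, sym), 0)  # inward negative
  expect_gt(open_channel_current(100, sym), 0)
})

test_that("rate laws evaluate to their closed forms", {
  b <- blocker_spec("X", z = 2, kon0 = 1.2e6, delta_on = 0.075,
                    koff0 = 280, zdelta_off = 0.67, theta = 0)
  cond0 <- solution_condition(100, 100, blockers = c(X = 0))
  expect_equal(rate_on(b, 100, cond0), 0)
  cond1 <- solution_condition(100, 100, blockers = c(X = 1e-6))
  expect_equal(rate_on(b, 0, cond1), 1.2)
  cond2 <- solution_condition(100, 100, blockers = c(X = 1e-4))
  # z * delta_on = 0.15 per 25 mV at +100 mV
  expect_equal(rate_on(b, 100, cond2), 1.2e6 * 1e-4 * exp(0.6))
  expect_equal(rate_off(b, 0, cond1), 280)
  expect_equal(rate_off(b, -100, cond1), 280 * exp(0.67 * 4))
  expect_error(rate_on(b, 0, solution_condition(100, 100, c(Mg = 0))),
               "no concentration")
})

test_that("flux-coupling factor saturates to unity under inward flux", {
  b <- blocker_spec("X", z = 2, kon0 = 1e6, delta_on = 0.08, koff0 = 1000,
                    zdelta_off = 0.5, theta = 1.5, vs = 4)
  b0 <- b; b0$theta <- 0
  cond <- solution_condition(100, 100, blockers = c(X = 1e-4))
  # far below E_K the coupled and uncoupled off rates coincide
  expect_equal(rate_off(b, -100, cond), rate_off(b0, -100, cond),
               tolerance = 1e-3)
  # far above E_K the off rate is suppressed by exp(-2 theta)
  expect_equal(rate_off(b, 100, cond) / rate_off(b0, 100, cond),
               exp(-2 * 1.5), tolerance = 1e-3)
  # suppression is monotone in V around E_K
  v <- seq(-20, 20, 2)
  supp <- rate_off(b, v, cond) / rate_off(b0, v, cond)
  expect_true(all(diff(supp) < 0))
})

test_that("generator rows sum to zero and have the 2-state eigenstructure", {
  p <- kir_presets()
  cond <- solution_condition(100, 100, c(Mg = 1e-4, SPM = 1e-6))
  m2 <- state_model(p$blockers$Mg)
  m4 <- state_model(list(p$blockers$Mg, p$blockers$SPM))
  for (v in c(-100, -30, 0, 30, 100)) {
    q2 <- build_generator(m2, v, cond)
    q4 <- build_generator(m4, v, cond)
    expect_true(all(abs(rowSums(q2)) < 1e-10 * max(abs(q2)) + 1e-12))
    expect_true(all(abs(rowSums(q4)) < 1e-10 * max(abs(q4)) + 1e-12))
    expect_true(all(q4[upper.tri(q4) | lower.tri(q4)] >= 0))
    b <- p$blockers$Mg
    ev <- sort(Re(eigen(q2, only.values = TRUE)$values))
    expect_equal(ev, sort(c(0, -(rate_on(b, v, cond) + rate_off(b, v, cond)))),
                 tolerance = 1e-10)
  }
  # zero concentration leaves O absorbing
  cond0 <- solution_condition(100, 100, c(Mg = 0))
  q <- build_generator(m2, 50, cond0)
  expect_equal(q["O", "Mg"], 0)
  expect_gt(q["Mg", "O"], 0)
  expect_error(build_generator(m2, 0, solution_condition(100, 100, c(SPM = 0))),
               "lacks concentrations")
})

test_that("stationary occupancy matches hand-solved balance equations", {
  # 2-state: P_O = koff / (kon + koff); at [B] = Kd exactly one half
  b <- simple_blocker()
  m <- state_model(b)
  cond <- solution_condition(100, 100, c(Mg = 1e-4))
  for (v in c(-50, 0, 60)) {
    ss <- steady_state(m, v, cond)
    expect_equal(sum(ss), 1)
    expect_equal(ss[["O"]],
                 rate_off(b, v, cond) / (rate_on(b, v, cond) + rate_off(b, v, cond)),
                 tolerance = 1e-12)
  }
  kd <- apparent_kd(m, 40, cond)
  ss <- steady_state(m, 40, solution_condition(100, 100, c(Mg = kd)))
  expect_equal(ss[["O"]], 0.5, tolerance = 1e-12)
  ss0 <- steady_state(m, 40, solution_condition(100, 100, c(Mg = 0)))
  expect_equal(ss0[["O"]], 1)
  # punch-through: P_O = (koff + kexit) / (kon + koff + kexit), hand-solved
  s <- blocker_spec("SPM", z = 4, kon0 = 1e7, delta_on = 0.06, koff0 = 50,
                    zdelta_off = 2.32, kexit0 = 0.5, zdelta_exit = 1)
  ms <- state_model(s)
  cs <- solution_condition(100, 100, c(SPM = 2e-7))
  for (v in c(0, 60)) {
    tot <- rate_off(s, v, cs) + rate_exit(s, v, cs)
    expect_equal(steady_state(ms, v, cs)[["O"]],
                 tot / (rate_on(s, v, cs) + tot), tolerance = 1e-12)
  }
})

test_that("apparent Kd agrees with a bisection search for P_O = 0.5", {
  p <- kir_presets()
  for (id in c("Mg", "SPM")) {
    b <- p$blockers[[id]]
    m <- state_model(b)
    cond <- solution_condition(100, 100, stats::setNames(0, id))
    for (v in c(-30, 10, 50)) {
      kd <- apparent_kd(m, v, cond)
      f <- function(conc) {
        cc <- solution_condition(100, 100, stats::setNames(conc, id))
        steady_state(m, v, cc)[["O"]] - 0.5
      }
      root <- uniroot(f, c(kd * 1e-4, kd * 1e4), tol = kd * 1e-12)$root
      expect_equal(kd, root, tolerance = 1e-9)
    }
  }
  # punch-through strictly increases Kd above koff/kon
  s <- p$blockers$SPM
  s0 <- s; s0$kexit0 <- 0
  cond <- solution_condition(100, 100, c(SPM = 0))
  expect_gt(apparent_kd(state_model(s), 60, cond),
            apparent_kd(state_model(s0), 60, cond))
  # defined per blocker only
  m2 <- state_model(list(p$blockers$Mg, p$blockers$SPM))
  expect_error(apparent_kd(m2, 0, cond), "single-blocker")
})

test_that("relaxation solves the master equation (closed form and oracles)", {
  b <- simple_blocker()
  m <- state_model(b)
  cond <- solution_condition(100, 100, c(Mg = 1e-4))
  v <- 80
  ron <- rate_on(b, v, cond); roff <- rate_off(b, v, cond)
  p0 <- c(1, 0)
  t_ms <- c(0, 0.5, 1, 2, 5, 20, 1000)
  occ <- relax_occupancy(m, v, cond, p0, t_ms)
  expect_equal(unname(occ[1, ]), p0)            # t = 0 exact
  pinf <- roff / (ron + roff)
  closed <- pinf + (1 - pinf) * exp(-(ron + roff) * t_ms / 1000)
  expect_equal(unname(occ[, "O"]), closed, tolerance = 1e-9)
  expect_equal(unname(occ[nrow(occ), "O"]),
               steady_state(m, v, cond)[["O"]], tolerance = 1e-9)
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_error(relax_occupancy(m, v, cond, c(0.7, 0.7), 1), "sum to 1")
})

test_that("relaxation matches micro-step integration and Gillespie ensembles", {
  p <- kir_presets()
  m4 <- state_model(list(p$blockers$Mg, p$blockers$SPM))
  cond <- solution_condition(100, 100, c(Mg = 1e-3, SPM = 1e-5))
  v <- 100
  q <- build_generator(m4, v, cond)
  p0 <- c(1, 0, 0, 0)
  for (t_ms in c(0.5, 2)) {
    ours <- relax_occupancy(m4, v, cond, p0, t_ms)[1, ]
    brute <- euler_relax(q, p0, t_ms / 1000, dt = 1e-6)
    expect_equal(unname(ours), brute, tolerance = 1e-6)
  }
  n <- 1e5
  t_ms <- 1
  ours <- relax_occupancy(m4, v, cond, p0, t_ms)[1, ]
  gil <- gillespie_occupancy(q, start = 1, t_end_s = t_ms / 1000, n = n,
                             seed = 42)
  se <- sqrt(pmax(ours * (1 - ours), 1e-12) / n)
  expect_true(all(abs(gil - ours) <= 3 * se + 1e-12))
})

test_that("Mg apparent Kd falls monotonically with V above E_K under flux coupling", {
  p <- kir_presets()
  m <- state_model(p$blockers$Mg)
  cond <- solution_condition(100, 100, c(Mg = 0))
  v <- seq(0, 100, 5)
  kd <- apparent_kd(m, v, cond)
  expect_true(all(diff(kd) < 0))
})

test_that("genotype multipliers scale blocker parameters", {
  p <- kir_presets()
  b <- apply_genotype(p$blockers$Mg, p$genotypes$E224G)
  expect_equal(b$koff0, p$blockers$Mg$koff0 * 0.086047)
  expect_equal(b$kon0, p$blockers$Mg$kon0 * 0.24)
  wt <- apply_genotype(p$blockers$Mg, p$genotypes$WT)
  expect_identical(wt, p$blockers$Mg)
  expect_error(genotype_spec("bad", c(kon0 = -1)), "positive")
  expect_error(blocker_spec("Mg", 2, 1e6, 0.08, 100, 0.5, kexit0 = 1),
               "punch")
})
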