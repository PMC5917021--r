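test_that("grid initialization places patrolling monocytes at the set density", {
  cfg <- ab_config(rows = 10, cols = 10)
  st <- ab_init(cfg, seed = 1)
  expect_equal(sum(st$pop$Mun), 4) # floor(100 / 25)
  expect_true(all(vapply(st$pop[c("M1", "M2", "N", "F")], sum, numeric(1)) == 0))
  expect_identical(damaged_fraction(st), 0)
  expect_true(all(st$life == 1) && all(st$cel == 1) && all(st$ccl == 1))
  expect_true(all(vapply(st$conc, function(m) all(m == 0), logical(1))))
  # seeded reproducibility of placement
  st2 <- ab_init(cfg, seed = 1)
  expect_identical(st$pop$Mun, st2$pop$Mun)
  ag <- ab_agents(st)
  expect_identical(nrow(ag), 4L)
  expect_true(all(ag$kind == "MONO_UN"))
})

test_that("particle deposition follows the smoking square wave", {
  cfg <- ab_config(rows = 5, cols = 5)
  st <- ab_init(cfg, seed = 1)
  # e_s = 0: never deposits
  sig0 <- smoking_signal(e_s = 0, T_s = 100)
  for (s in 0:20) st <- ab_deposit(st, sig0, s, config = cfg)
  expect_identical(sum(st$particles), 0)

  # on-phase step adds exactly e_s particles
  sig <- smoking_signal(e_s = 5, T_s = 50, period = 10, duty = 0.5)
  set.seed(2)
  st1 <- ab_deposit(st, sig, step = 0, config = cfg)
  expect_identical(sum(st1$particles), 5)
  # off-phase step within T_s adds nothing
  st2 <- ab_deposit(st, sig, step = 7, config = cfg)
  expect_identical(sum(st2$particles), 0)
  # past the total smoking time nothing deposits, any phase
  st3 <- ab_deposit(st, sig, step = 50, config = cfg)
  expect_identical(sum(st3$particles), 0)
})

test_that("zero exposure leaves tissue fully healthy over any horizon", {
  cfg <- ab_config(rows = 8, cols = 8)
  p <- immune_params()
  for (seed in 1:3) {
    res <- ab_run(ab_init(cfg, seed = seed), smoking_signal(0, 90), p, cfg,
                  n_steps = 120, seed = seed)
    expect_true(all(res$series$mean_life == 1))
    expect_true(all(res$series$damaged_frac == 0))
  }
})

test_that("a healthy empty state is absorbing up to monocyte patrolling", {
  cfg <- ab_config(rows = 4, cols = 4)
  p <- immune_params()
  st <- ab_init(cfg, seed = 3)
  res <- ab_run(st, smoking_signal(0, 0), p, cfg, 50, seed = 3)
  fin <- res$state
  expect_true(all(fin$life == 1))
  expect_true(all(fin$cel == 1) && all(fin$ccl == 1))
  # no activated phenotypes ever appear without cytokines
  expect_identical(sum(fin$pop$M1) + sum(fin$pop$M2) + sum(fin$pop$N), 0)
  expect_true(all(vapply(fin$conc, function(m) all(m == 0), logical(1))))
})

test_that("dead cells never revive and damage is monotone", {
  cfg <- ab_config(rows = 6, cols = 6)
  p <- immune_params()
  st <- ab_init(cfg, seed = 4)
  sig <- smoking_signal(e_s = 8, T_s = 40)
  set.seed(4)
  prev_dead <- !st$alive
  df <- 0
  for (i in 1:60) {
    st <- ab_deposit(st, sig, st$step, config = cfg)
    st <- ab_step(st, p, cfg)
    dead <- !st$alive
    expect_true(all(dead[prev_dead])) # irreversibility
    expect_gte(damaged_fraction(st), df)
    prev_dead <- dead
    df <- damaged_fraction(st)
    expect_true(all(st$life >= 0 & st$life <= 1))
    expect_true(all(st$cel >= 0 & st$cel <= 1))
    expect_true(all(st$ccl >= 0 & st$ccl <= 1))
    expect_true(all(vapply(st$conc, function(m) all(m >= 0), logical(1))))
  }
  expect_gt(df, 0) # this exposure does destroy tissue
})

test_that("diffusion conserves cytokine mass when decay is off", {
  # all decay rates zero, no agents, no particles: grid sums must be constant
  p <- immune_params(dIL10 = 0, dTa = 0, dIL1 = 0, dTb = 0, dIL8 = 0,
                     dM = 0, dE = 0, dFC = 0)
  cfg <- ab_config(rows = 7, cols = 5, D = 0.2, mono_density = 0, k_damps = 0)
  st <- ab_init(cfg, seed = 1)
  st$conc$Ta[3, 2] <- 100
  st$conc$IL1[1, 1] <- 50 # corner: zero-flux boundary
  tot0 <- vapply(st$conc, sum, numeric(1))
  for (i in 1:40) st <- ab_step(st, p, cfg)
  tot <- vapply(st$conc, sum, numeric(1))
  expect_equal(tot, tot0, tolerance = 1e-10)
  expect_true(all(st$conc$Ta >= 0))
})

test_that("seeded runs are bit-identical", {
  cfg <- ab_config(rows = 6, cols = 6)
  p <- immune_params()
  sig <- smoking_signal(e_s = 10, T_s = 30)
  r1 <- ab_run(ab_init(cfg, seed = 7), sig, p, cfg, 50, seed = 7)
  r2 <- ab_run(ab_init(cfg, seed = 7), sig, p, cfg, 50, seed = 7)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$state$life, r2$state$life)
})

test_that("a 1x1 deterministic grid reproduces the well-mixed Euler trajectory", {
  p <- immune_params()
  dt <- 0.01
  cfg <- ab_config(rows = 1, cols = 1, dt = dt, D = 0, k_damps = 0, s_p = 0,
                   fib_recruit_threshold = Inf, influx_scale = 1,
                   ta_influx_cap = Inf, mono_density = 0,
                   deterministic = TRUE, decay = "euler")
  st <- ab_init(cfg)
  st$pop$Mun[1, 1] <- 50; st$pop$M1[1, 1] <- 30; st$pop$M2[1, 1] <- 20
  st$pop$N[1, 1] <- 5; st$pop$F[1, 1] <- 1
  s0 <- immune_state(Mun = 50, M1 = 30, M2 = 20, N = 5, F = 1, C = 100)
  tr <- wm_integrate(s0, p, duration = 100 * dt, dt = dt, method = "euler")
  res <- ab_run(st, smoking_signal(0, 0), p, cfg, 100)
  fin <- res$state
  ab_vals <- c(Mun = fin$pop$Mun[1, 1], M1 = fin$pop$M1[1, 1],
               M2 = fin$pop$M2[1, 1], IL10 = fin$conc$IL10[1, 1],
               Ta = fin$conc$Ta[1, 1], IL1 = fin$conc$IL1[1, 1],
               Tb = fin$conc$Tb[1, 1], F = fin$pop$F[1, 1], C = fin$C[1, 1],
               MMP = fin$conc$MMP[1, 1], IL8 = fin$conc$IL8[1, 1],
               N = fin$pop$N[1, 1], El = fin$conc$El[1, 1])
  wm_vals <- unlist(tr[nrow(tr), names(ab_vals)])
  expect_equal(ab_vals, wm_vals, tolerance = 1e-8)
})

test_that("phagocytosis clears a particle shared with a macrophage", {
  # 2x1 grid, certain clearance: the patrolling monocyte reaches the particle
  # and removes it within a few steps
  p <- immune_params()
  cfg <- ab_config(rows = 2, cols = 1, p_clear = 1, s_p = 0, k_damps = 0,
                   influx_scale = 0, mono_density = 0)
  st <- ab_init(cfg, seed = 1)
  st$pop$Mun[1, 1] <- 1
  st$particles[2, 1] <- 1
  set.seed(1)
  steps <- 0
  while (sum(st$particles) > 0 && steps < 50) {
    st <- ab_step(st, p, cfg)
    steps <- steps + 1
  }
  expect_identical(sum(st$particles), 0)
})

test_that("mean residual tissue life decreases with exposure", {
  cfg <- ab_config(rows = 8, cols = 8)
  p <- immune_params()
  finals <- vapply(c(0L, 5L, 10L), function(es) {
    mean(vapply(1:10, function(s) {
      res <- ab_run(ab_init(cfg, seed = s), smoking_signal(es, 20), p, cfg,
                    40, seed = s * 100 + es)
      tail(res$series$mean_life, 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(finals) <= 0))
  expect_identical(finals[1], 1)
})
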