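test_that("recruitment and growth polynomials match their printed coefficients", {
  expect_identical(monocyte_recruitment(0), 57.302)
  # hand arithmetic on the printed coefficients
  expect_equal(monocyte_recruitment(2), 0.335 * 8 - 6.309 * 4 + 32.281 * 2 + 57.302)
  expect_equal(monocyte_recruitment(1), 83.609)
  expect_identical(fibroblast_growth_factor(0), 7.11)
  expect_equal(fibroblast_growth_factor(1), 12.72)
  expect_equal(fibroblast_growth_factor(10), 0.05 * 1000 - 0.98 * 100 + 65.4 + 7.11)
  expect_error(monocyte_recruitment(-1), "Ta")
  expect_error(fibroblast_growth_factor(-0.5), "Tb")
})

test_that("Hill activation saturates correctly and rejects bad constants", {
  expect_identical(hill(0, 5), 0)
  expect_identical(hill(10, 10), 0.5)
  expect_equal(hill(90, 10), 0.9)
  expect_equal(1 - hill(25, 25), 0.5) # inhibition form
  expect_error(hill(1, 0), "c")
  expect_error(hill(-1, 10), "x")
})

test_that("derivatives reproduce hand-substituted special cases", {
  p <- immune_params()
  # resting tissue with no macrophages: only the recruitment influx is active
  d0 <- immune_derivatives(immune_state(Mun = 0), p)
  expect_equal(unname(d0["Mun"]), 57.302)
  expect_true(all(d0[setdiff(names(d0), "Mun")] == 0))

  # only M2 = 100 present: IL10, TGFb, IL8 secretion and M2 losses
  d2 <- immune_derivatives(immune_state(Mun = 0, M2 = 100), p)
  expect_equal(unname(d2["IL10"]), p$k5 * 100)   # 0.05, inhibition factor 1
  expect_equal(unname(d2["Tb"]), p$k8 * 100)     # 7
  expect_equal(unname(d2["IL8"]), p$k13 * 100)   # 0.05
  expect_equal(unname(d2["M2"]), -(p$km21 + p$mu) * 100) # -25
  expect_equal(unname(d2["M1"]), p$km21 * 100)

  # pure function: identical input, identical output
  s <- immune_state(M1 = 10, IL10 = 3, Ta = 1)
  expect_identical(immune_derivatives(s, p), immune_derivatives(s, p))
  expect_error(immune_derivatives(immune_state(Mun = 0) - 1, p), "negative|finite")
})

test_that("IL10 inhibition on IL1/TNFa uses its own constant", {
  # with IL10 at the c1 level (100), IL10 self-secretion halves but the
  # IL1/TNFa secretion factor is c/(IL10+c) = 25/125
  p <- immune_params()
  d <- immune_derivatives(immune_state(Mun = 0, M1 = 100, M2 = 100, IL10 = 100), p)
  expect_equal(unname(d["IL10"]), p$k5 * 100 * 0.5 - p$dIL10 * 100)
  expect_equal(unname(d["Ta"]), p$k6 * 100 * 25 / 125)
  # setting c = c1 recovers the single-constant variant
  p2 <- immune_params(c = 100)
  d2 <- immune_derivatives(immune_state(Mun = 0, M1 = 100, IL10 = 100), p2)
  expect_equal(unname(d2["Ta"]), p2$k6 * 100 * 0.5)
})

test_that("integration matches the closed-form macrophage relaxation", {
  p <- immune_params()
  tr <- wm_integrate(immune_state(Mun = 0), p, duration = 50, dt = 0.01)
  mstar <- 57.302 / p$mu
  # analytic: Mun(t) = Mun* + (Mun0 - Mun*) exp(-mu t)
  expect_equal(tail(tr$Mun, 1), mstar + (0 - mstar) * exp(-p$mu * 50),
               tolerance = 0.01)
  expect_true(all(tr[, c("IL10", "Ta", "IL1", "Tb", "IL8")] == 0))
  # euler at the same dt agrees within its order too
  tre <- wm_integrate(immune_state(Mun = 0), p, duration = 50, dt = 0.01,
                      method = "euler")
  expect_equal(tail(tre$Mun, 1), mstar, tolerance = 0.01)
})

test_that("zero-duration integration returns exactly the initial state", {
  s0 <- immune_state(M1 = 5, IL1 = 2)
  tr <- wm_integrate(s0, immune_params(), duration = 0)
  expect_identical(nrow(tr), 1L)
  expect_equal(as.numeric(tr[1, names(s0)]), as.numeric(s0))
})

test_that("one explicit-Euler step equals state + dt * derivatives", {
  p <- immune_params()
  s0 <- immune_state(M1 = 20, M2 = 10, IL10 = 1, Ta = 0.5, IL1 = 3, C = 50,
                     MMP = 2, N = 4, El = 1, F = 2, Tb = 0.2, IL8 = 0.1)
  dt <- 1e-4
  tr <- wm_integrate(s0, p, duration = dt, dt = dt, method = "euler")
  expected <- as.numeric(s0) + dt * immune_derivatives(s0, p)
  got <- as.numeric(tr[2, names(s0)])
  expect_equal(got, unname(expected), tolerance = 1e-12)
})

test_that("halving the step changes the Euler solution consistently", {
  p <- immune_params()
  s0 <- immune_state(M1 = 10, IL1 = 5)
  f1 <- tail(wm_integrate(s0, p, 2, dt = 0.02, method = "euler"), 1)
  f2 <- tail(wm_integrate(s0, p, 2, dt = 0.01, method = "euler"), 1)
  f4 <- tail(wm_integrate(s0, p, 2, dt = 0.005, method = "euler"), 1)
  # first-order scheme: error shrinks by about half with the step
  e1 <- abs(f1$Mun - f4$Mun)
  e2 <- abs(f2$Mun - f4$Mun)
  expect_lt(e2, e1)
})

test_that("non-negativity holds along stochastic-free integrations", {
  p <- immune_params()
  tr <- wm_integrate(immune_state(M1 = 50, M2 = 30, IL1 = 5, Ta = 2, IL10 = 1),
                     p, duration = 20, dt = 0.05)
  expect_true(all(as.matrix(tr[, -1]) >= 0))
})

test_that("peak TNF-alpha response is monotone in its secretion rate", {
  s0 <- immune_state(M1 = 100)
  peaks <- vapply(c(7e-4, 7e-3, 7e-2), function(k6) {
    max(wm_integrate(s0, immune_params(k6 = k6), 10, dt = 0.05)$Ta)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("steady-state solver finds the resting macrophage pool", {
  p <- immune_params()
  st <- wm_steady_state(p, immune_state(Mun = 0), tol = 1e-4)
  expect_equal(unname(st["Mun"]), 57.302 / p$mu, tolerance = 0.01)
  # definition: the returned state has derivative norm below tol
  expect_lt(sqrt(sum(immune_derivatives(st, p)^2)), 1e-4)
})

test_that("IL10 equilibrium under a pinned M2 pool matches the quadratic root", {
  p <- immune_params()
  M2 <- 100
  # independent closed form: positive root of d*x^2 + d*c1*x - k5*M2*c1 = 0
  root <- (-p$dIL10 * p$c1 + sqrt((p$dIL10 * p$c1)^2 +
           4 * p$dIL10 * p$k5 * M2 * p$c1)) / (2 * p$dIL10)
  expect_equal(root, 0.02, tolerance = 1e-3)
  f <- function(x) {
    unname(immune_derivatives(immune_state(Mun = 0, M2 = M2, IL10 = x), p)["IL10"])
  }
  got <- stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
  expect_equal(got, root, tolerance = 1e-6)
})

test_that("integration guards against divergence with a named error", {
  # forced blow-up: huge fibroblast pool with no apoptosis grows without bound
  p <- immune_params(dF = 0, k10 = 50)
  expect_error(
    wm_integrate(immune_state(F = 1e6, Tb = 10), p, duration = 50, dt = 0.5,
                 method = "euler"),
    "diverged.*F")
})

test_that("trajectories tidy, glance and round-trip through parameters I/O", {
  skip_if_not_installed("yaml")
  tr <- wm_integrate(immune_state(), immune_params(), 1, dt = 0.5)
  long <- tidy(tr)
  expect_setequal(unique(long$variable),
                  c("Mun", "M1", "M2", "IL10", "Ta", "IL1", "Tb", "F", "C",
                    "MMP", "IL8", "N", "El"))
  g <- glance(tr)
  expect_identical(nrow(g), 1L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_immune_params(immune_params(k6 = 0.123), f)
  expect_equal(read_immune_params(f)$k6, 0.123)
})
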