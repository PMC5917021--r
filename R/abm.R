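#' Smoking exposure signal
#'
#' Periodic square-wave exposure: during the "on" phase of each period,
#' `e_s` smoke particles are deposited per step, for a total smoking time of
#' `T_s` steps; afterwards the simulation runs `post_steps` further steps to
#' re-equilibrate. The wave frequency is `1/period` (per step).
#'
#' @param e_s particles deposited per on-step (integer >= 0); the exposure.
#' @param T_s total smoking time, steps (>= 0).
#' @param period square-wave period, steps.
#' @param duty fraction of each period that is "on" (0 < duty <= 1).
#' @param post_steps equilibration steps simulated after cessation.
#' @return An object of class `smoking_signal`.
#' @examples
#' sig <- smoking_signal(e_s = 10, T_s = 50)
#' sum(vapply(0:49, function(s) smoking_active(sig, s), logical(1))) # on-steps
#' @export
smoking_signal <- function(e_s, T_s, period = 10, duty = 0.5, post_steps = 20) {
  stopifnot(e_s >= 0, e_s == round(e_s), T_s >= 0, period >= 1,
            duty > 0, duty <= 1, post_steps >= 0)
  structure(list(e_s = as.integer(e_s), T_s = as.integer(T_s),
                 period = period, duty = duty,
                 post_steps = as.integer(post_steps)),
            class = "smoking_signal")
}

#' @describeIn smoking_signal is the signal "on" (depositing) at 0-based step
#'   `step`?
#' @param signal a `smoking_signal`.
#' @param step 0-based step index.
#' @export
smoking_active <- function(signal, step) {
  step < signal$T_s && (step %% signal$period) < signal$duty * signal$period
}

#' Configuration of the agent-based tissue model
#'
#' Grid geometry, step size and the spatial constants that the grid model adds
#' on top of the well-mixed rate equations. Each grid cell represents a small
#' portion of an alveolar unit, treated as a unit well-mixed volume, so a
#' secretion rate in pg/cell/day contributes pg/ml/day per resident agent.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param dt step length, days.
#' @param D cytokine diffusion coefficient, cell^2/step (explicit 4-neighbour
#'   scheme, mass-conserving, zero-flux borders; stability requires `D <= 0.25`;
#'   `D = 0` gives strictly local dynamics).
#' @param k_damps tissue-life loss rate per unit pro-inflammatory activation,
#'   1/day. The inflammation index is the mean of the IL1 and TNFa Hill
#'   activations. Calibrated so that every nonzero exposure in the design grid
#'   destroys at least half of the tissue (see the methods vignette).
#' @param s_p TNFa (pg/ml) emitted into its cell by one deposited particle per
#'   step. Effective source strength chosen so a particle-laden site and its
#'   immediate neighbours sit in the saturated region of the TNFa Hill response
#'   despite the fast TNFa turnover.
#' @param p_clear per-step probability that a macrophage sharing a cell with
#'   particles phagocytoses one.
#' @param fib_recruit_threshold local TGFb (pg/ml) above which one fibroblast
#'   is seeded per step.
#' @param k_eldeg elastase-driven elastin degradation coefficient, ml/pg/day.
#' @param C0 initial per-cell collagen, ug; normalizes the collagen fraction.
#' @param influx_scale fraction of the aggregate monocyte-recruitment influx
#'   that enters this grid per step.
#' @param ta_influx_cap TNFa (pg/ml) at which the recruitment cubic is clamped
#'   when evaluating influx (the polynomial is a fit over a bounded
#'   physiological range).
#' @param mono_density initial patrolling-monocyte density, agents per cell.
#' @param deterministic replace all random draws by expected-value updates.
#' @param decay `"exact"` (default) uses the exact per-step decay factor
#'   `exp(-d*dt)`; `"euler"` uses the linear first-order increment evaluated on
#'   the step-start state, which makes a 1x1 deterministic grid reproduce the
#'   explicit-Euler trajectory of the well-mixed model exactly.
#' @return An object of class `ab_config`.
#' @export
ab_config <- function(rows = 13, cols = 10, dt = 0.1, D = 0.1,
                      k_damps = 5, s_p = 2e5, p_clear = 0.1,
                      fib_recruit_threshold = 5, k_eldeg = 0.05, C0 = 100,
                      influx_scale = 0.01, ta_influx_cap = 10,
                      mono_density = 1 / 25,
                      deterministic = FALSE, decay = c("exact", "euler")) {
  decay <- match.arg(decay)
  stopifnot(rows >= 1, cols >= 1, dt > 0, D >= 0, D <= 0.25,
            k_damps >= 0, s_p >= 0, p_clear >= 0, p_clear <= 1,
            k_eldeg >= 0, C0 > 0, influx_scale >= 0, mono_density >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols), dt = dt,
                 D = D, k_damps = k_damps, s_p = s_p, p_clear = p_clear,
                 fib_recruit_threshold = fib_recruit_threshold,
                 k_eldeg = k_eldeg, C0 = C0, influx_scale = influx_scale,
                 ta_influx_cap = ta_influx_cap, mono_density = mono_density,
                 deterministic = deterministic, decay = decay),
            class = "ab_config")
}

.conc_fields <- c("IL10", "Ta", "IL1", "Tb", "IL8", "MMP", "El")
.pop_fields  <- c("Mun", "M1", "M2", "N", "F")
.mobile_kinds <- c("Mun", "M1", "M2", "N")

#' Initialize the agent-based grid
#'
#' All alveolar-unit cells start alive with full tissue life and full
#' elastin/collagen content, zero local concentrations and no particles.
#' Patrolling undifferentiated monocytes are placed uniformly at the
#' configured baseline density.
#'
#' @param config an [ab_config].
#' @param seed optional integer; seeds the session RNG for reproducible
#'   placement.
#' @return An object of class `ab_state`: matrices `life`, `cel`, `ccl`, `C`,
#'   `particles`, logical `alive`, a list `conc` of seven local-concentration
#'   matrices and a list `pop` of five per-cell agent-count matrices.
#' @examples
#' st <- ab_init(ab_config(rows = 10, cols = 10), seed = 1)
#' sum(st$pop$Mun) # floor(100 / 25) patrolling monocytes
#' @export
ab_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- config$rows; c <- config$cols; nc <- r * c
  zero <- matrix(0, r, c)
  st <- list(
    rows = r, cols = c,
    life = matrix(1, r, c),
    alive = matrix(TRUE, r, c),
    cel = matrix(1, r, c),
    ccl = matrix(1, r, c),
    C = matrix(config$C0, r, c),
    particles = zero,
    conc = stats::setNames(rep(list(zero), length(.conc_fields)), .conc_fields),
    pop = stats::setNames(rep(list(zero), length(.pop_fields)), .pop_fields),
    step = 0L, deposited = 0L,
    nbrs = grid_neighbours(r, c)
  )
  n_agents <- floor(nc * config$mono_density)
  if (n_agents > 0) {
    if (config$deterministic) {
      st$pop$Mun <- matrix(n_agents / nc, r, c)
    } else {
      at <- sample.int(nc, n_agents, replace = n_agents > nc)
      st$pop$Mun <- matrix(tabulate(at, nbins = nc), r, c)
    }
  }
  class(st) <- "ab_state"
  st
}

# 4-neighbour linear indices for every cell of an r x c grid (column-major)
grid_neighbours <- function(r, c) {
  lapply(seq_len(r * c), function(i) {
    ri <- (i - 1L) %% r + 1L
    ci <- (i - 1L) %/% r + 1L
    nb <- integer(0)
    if (ri > 1L) nb <- c(nb, i - 1L)
    if (ri < r)  nb <- c(nb, i + 1L)
    if (ci > 1L) nb <- c(nb, i - r)
    if (ci < c)  nb <- c(nb, i + r)
    nb
  })
}

#' Fraction of destroyed tissue
#'
#' @param state an [ab_state].
#' @return Share of dead alveolar-unit cells, in \[0, 1\].
#' @export
damaged_fraction <- function(state) {
  mean(!state$alive)
}

#' Agent table of an AB state
#'
#' Materializes the per-cell agent counts as one row per individual agent.
#'
#' @param state an [ab_state].
#' @return A tibble with columns `kind`, `row`, `col` (0-based positions).
#' @export
ab_agents <- function(state) {
  purrr::map_dfr(.pop_fields, function(k) {
    n <- round(state$pop[[k]])
    idx <- which(n > 0)
    if (!length(idx)) return(tibble::tibble(kind = character(),
                                            row = integer(), col = integer()))
    idx <- rep(idx, n[idx])
    tibble::tibble(
      kind = c(Mun = "MONO_UN", M1 = "M1", M2 = "M2",
               N = "NEUTROPHIL", F = "FIBROBLAST")[[k]],
      row = (idx - 1L) %% state$rows,
      col = (idx - 1L) %/% state$rows
    )
  })
}

#' Deposit smoke particles
#'
#' If the 0-based `step` lies within the total smoking time and in the "on"
#' phase of the exposure wave, `e_s` particles are added to randomly chosen
#' target cells; otherwise the state is returned unchanged.
#'
#' @param state an [ab_state].
#' @param signal a [smoking_signal].
#' @param step 0-based step index (defaults to the state's own counter).
#' @param targets integer vector of candidate cell indices (column-major);
#'   default all cells.
#' @param config an [ab_config] (deterministic mode spreads the expected
#'   deposition uniformly over the targets).
#' @return The updated `ab_state`.
#' @export
ab_deposit <- function(state, signal, step = state$step,
                       targets = seq_len(state$rows * state$cols),
                       config = ab_config(rows = state$rows, cols = state$cols)) {
  if (signal$e_s == 0 || !smoking_active(signal, step)) return(state)
  if (!length(targets)) stop("no deposition targets", call. = FALSE)
  if (config$deterministic) {
    state$particles[targets] <- state$particles[targets] + signal$e_s / length(targets)
  } else {
    at <- targets[sample.int(length(targets), signal$e_s, replace = TRUE)]
    add <- tabulate(at, nbins = state$rows * state$cols)
    state$particles <- state$particles + matrix(add, state$rows, state$cols)
  }
  state$deposited <- state$deposited + signal$e_s
  state
}

# exact multinomial thinning of counts n (vector) into the columns of prob
# matrix p (rows = cells); returns matrix of draws, one column per outcome,
# remaining counts implicitly stay
multinom_split <- function(n, p, deterministic) {
  k <- ncol(p)
  tot <- rowSums(p)
  over <- tot > 1
  if (any(over)) p[over, ] <- p[over, ] / tot[over]
  out <- matrix(0, length(n), k)
  if (deterministic) {
    for (j in seq_len(k)) out[, j] <- n * p[, j]
    return(out)
  }
  rem <- n
  pleft <- rep(1, length(n))
  for (j in seq_len(k)) {
    pj <- p[, j] / pleft
    pj[!is.finite(pj) | pj < 0] <- 0
    pj[pj > 1] <- 1
    out[, j] <- rbinom(length(n), rem, pj)
    rem <- rem - out[, j]
    pleft <- pleft - p[, j]
  }
  out
}

# explicit mass-conserving 4-neighbour diffusion with zero-flux borders
diffuse <- function(X, D) {
  if (D == 0) return(X)
  r <- nrow(X); c <- ncol(X)
  up    <- rbind(X[-1, , drop = FALSE], 0)
  down  <- rbind(0, X[-r, , drop = FALSE])
  left  <- cbind(X[, -1, drop = FALSE], 0)
  right <- cbind(0, X[, -c, drop = FALSE])
  deg <- matrix(4, r, c)
  deg[1, ] <- deg[1, ] - 1; deg[r, ] <- deg[r, ] - 1
  deg[, 1] <- deg[, 1] - 1; deg[, c] <- deg[, c] - 1
  if (r == 1) deg <- deg + 1  # corrections for degenerate dims
  if (c == 1) deg <- deg + 1
  X + D * (up + down + left + right - deg * X)
}

#' Advance the agent-based model one step
#'
#' One time step of length `config$dt`, applying in fixed order: particle TNFa
#' emission; per-agent cytokine secretion (with the same IL10 inhibition
#' factors as the well-mixed model); cytokine diffusion; decay; monocyte
#' influx; agent movement (random walk, biased one step up the TNFa gradient
#' where TNFa exceeds its Hill constant); macrophage differentiation and
#' emigration; neutrophil recruitment and fibroblast seeding/turnover;
#' phagocytosis; collagen/elastin update; DAMPS tissue damage; TGFb secretion
#' by damaged tissue. All rate expressions are evaluated on the step-start
#' state, so in deterministic mode the composite update is one explicit-Euler
#' step of the underlying rate equations.
#'
#' @param state an [ab_state].
#' @param params an [immune_params].
#' @param config an [ab_config].
#' @return The updated `ab_state`.
#' @export
ab_step <- function(state, params, config) {
  p <- params; cf <- config; dt <- cf$dt
  det <- cf$deterministic
  r <- state$rows; c <- state$cols; ncell <- r * c

  # --- snapshot (all rates evaluate on the step-start state) ---
  s0 <- state$conc
  pop0 <- state$pop
  life0 <- state$life
  alive0 <- state$alive
  C0m <- state$C
  cel0 <- state$cel
  particles0 <- state$particles

  hIL1 <- hill(s0$IL1, p$cIL1)
  hTa  <- hill(s0$Ta,  p$cTa)
  hIL10 <- hill(s0$IL10, p$cIL10)
  inh1 <- p$c1 / (s0$IL10 + p$c1)
  inhc <- p$c  / (s0$IL10 + p$c)
  inh2 <- p$c2 / (s0$IL8 + p$c2)

  conc <- state$conc

  # (1) particle TNFa emission
  if (any(particles0 > 0)) conc$Ta <- conc$Ta + cf$s_p * particles0

  # (2) agent secretion
  conc$IL10 <- conc$IL10 + p$k5 * pop0$M2 * inh1 * dt
  conc$Ta   <- conc$Ta   + p$k6 * pop0$M1 * inhc * dt
  conc$IL1  <- conc$IL1  + p$k7 * pop0$M1 * inhc * dt
  conc$Tb   <- conc$Tb   + (p$k8 * pop0$M2 + p$k9 * pop0$F) * dt
  conc$IL8  <- conc$IL8  + p$k13 * pop0$M2 * inh2 * dt
  conc$MMP  <- conc$MMP  + p$k12 * pop0$M1 * dt
  conc$El   <- conc$El   + p$k15 * pop0$N * dt

  # (3) diffusion (on the current field; mass conserving, zero-flux borders)
  if (cf$D > 0) conc <- lapply(conc, diffuse, D = cf$D)

  # (4) decay; "euler" evaluates the linear increment on the snapshot so the
  # composite step is exactly explicit Euler, "exact" is unconditionally stable
  drate <- c(IL10 = p$dIL10, Ta = p$dTa, IL1 = p$dIL1, Tb = p$dTb,
             IL8 = p$dIL8, MMP = p$dM, El = p$dE)
  for (f in .conc_fields) {
    if (cf$decay == "exact") {
      conc[[f]] <- conc[[f]] * exp(-drate[[f]] * dt)
    } else {
      conc[[f]] <- conc[[f]] - drate[[f]] * dt * s0[[f]]
    }
  }
  # MMP-collagen cleavage consumes MMP alongside its first-order decay
  conc$MMP <- conc$MMP - p$dFC * s0$MMP * C0m * dt
  conc <- lapply(conc, pmax, 0)

  pop <- state$pop

  # (5) monocyte influx at random alive cells
  mean_ta <- mean(s0$Ta)
  lam_in <- monocyte_recruitment(min(mean_ta, cf$ta_influx_cap)) * dt * cf$influx_scale
  n_alive <- sum(alive0)
  if (lam_in > 0 && n_alive > 0) {
    if (det) {
      pop$Mun[alive0] <- pop$Mun[alive0] + lam_in / n_alive
    } else {
      n_new <- rpois(1, lam_in)
      if (n_new > 0) {
        cells <- which(alive0)
        at <- cells[sample.int(length(cells), n_new, replace = TRUE)]
        pop$Mun <- pop$Mun + matrix(tabulate(at, nbins = ncell), r, c)
      }
    }
  }

  # (6) movement: random walk, biased one step up the TNFa gradient where
  # local TNFa exceeds its Hill constant; vectorized as four directional splits
  if (ncell > 1) {
    ta0 <- s0$Ta
    nb_ta <- cbind(  # neighbour TNFa per direction, -Inf outside the grid
      up    = as.vector(rbind(-Inf, ta0[-r, , drop = FALSE])),
      down  = as.vector(rbind(ta0[-1, , drop = FALSE], -Inf)),
      left  = as.vector(cbind(-Inf, ta0[, -c, drop = FALSE])),
      right = as.vector(cbind(ta0[, -1, drop = FALSE], -Inf))
    )
    valid <- is.finite(nb_ta)
    P <- valid / rowSums(valid)
    biased <- as.vector(ta0 > p$cTa)
    if (any(biased)) {
      best <- max.col(nb_ta[biased, , drop = FALSE], ties.method = "first")
      Pb <- matrix(0, sum(biased), 4)
      Pb[cbind(seq_len(sum(biased)), best)] <- 1
      P[biased, ] <- Pb
    }
    for (k in .mobile_kinds) {
      n <- pop[[k]]
      if (!any(n > 0)) next
      mv <- multinom_split(as.vector(n), P, det)
      up <- matrix(mv[, 1], r, c); dn <- matrix(mv[, 2], r, c)
      lf <- matrix(mv[, 3], r, c); rt <- matrix(mv[, 4], r, c)
      pop[[k]] <- rbind(up[-1, , drop = FALSE], 0) +  # arriving from below
        rbind(0, dn[-r, , drop = FALSE]) +            # from above
        cbind(lf[, -1, drop = FALSE], 0) +            # from the right
        cbind(0, rt[, -c, drop = FALSE])              # from the left
    }
  }

  # (7) differentiation, phenotype exchange, emigration (rates from snapshot;
  # deterministic mode also draws the counts from the snapshot so the step is
  # one Euler update of the rate equations)
  nvec <- function(m) as.vector(m)
  base <- if (det) pop0 else pop
  pm <- cbind(as.vector((p$k2 * hIL1 + p$k3 * hTa) * dt),  # Mun -> M1
              as.vector(p$k4 * hIL10 * dt),                # Mun -> M2
              rep(p$mu * dt, ncell))                       # emigrate
  mun_mv <- multinom_split(nvec(base$Mun), pm, det)
  m1_mv <- multinom_split(nvec(base$M1),
                          cbind(rep(p$km12 * dt, ncell), rep(p$mu * dt, ncell)), det)
  m2_mv <- multinom_split(nvec(base$M2),
                          cbind(rep(p$km21 * dt, ncell), rep(p$mu * dt, ncell)), det)
  n_out <- multinom_split(nvec(base$N), cbind(rep(p$muN * dt, ncell)), det)

  pop$Mun <- pop$Mun - matrix(rowSums(mun_mv), r, c)
  pop$M1 <- pop$M1 + matrix(mun_mv[, 1] + m2_mv[, 1] - rowSums(m1_mv), r, c)
  pop$M2 <- pop$M2 + matrix(mun_mv[, 2] + m1_mv[, 1] - rowSums(m2_mv), r, c)
  pop$N <- pop$N - matrix(n_out[, 1], r, c)

  # (8) neutrophil recruitment (vs local IL8) and fibroblast dynamics
  lamN <- pmax(p$k14rate * (1 - sum(pop0$N) / p$Nmax), 0) *
    hill(s0$IL8, p$cIL8) * dt
  if (any(lamN > 0)) {
    addN <- if (det) lamN else matrix(rpois(ncell, lamN), r, c)
    pop$N <- pop$N + addN
  }
  seedF <- (s0$Tb > cf$fib_recruit_threshold) & alive0
  if (any(seedF)) pop$F[seedF] <- pop$F[seedF] + 1
  fg <- p$k10 * fibroblast_growth_factor(s0$Tb) * dt
  births <- if (det) fg * pop0$F else matrix(rpois(ncell, fg * nvec(pop0$F)), r, c)
  deaths <- matrix(multinom_split(nvec(pop0$F),
                                  cbind(rep(p$dF * dt, ncell)), det)[, 1], r, c)
  pop$F <- pmax(pop$F + births - deaths, 0)

  # (9) phagocytosis
  macs <- pop0$Mun + pop0$M1 + pop0$M2
  can <- particles0 > 0 & macs > 0
  if (any(can)) {
    removed <- if (det) {
      pmin(particles0, macs * cf$p_clear)
    } else {
      pmin(particles0,
           matrix(rbinom(ncell, nvec(round(macs)), cf$p_clear), r, c))
    }
    state$particles <- state$particles - removed * can
  }

  # (10) matrix update: collagen balance and elastase-driven elastin loss
  state$C <- pmax(C0m + (p$k11 * pop0$F - p$dFC * s0$MMP * C0m) * dt, 0)
  state$ccl <- pmin(state$C / cf$C0, 1)
  state$cel <- pmin(pmax(cel0 - cf$k_eldeg * s0$El * cel0 * dt, 0), 1)

  # (11) DAMPS: tissue life falls with the mean pro-inflammatory activation
  if (cf$k_damps > 0) {
    idx <- 0.5 * (hIL1 + hTa)
    life <- state$life - cf$k_damps * dt * idx
    life[!alive0] <- 0
    died <- alive0 & life <= 0
    life[life <= 0] <- 0
    state$life <- life
    if (any(died)) state$alive[died] <- FALSE
  }

  # (12) damaged tissue secretes TGFb to recruit fibroblasts
  dmg <- life0 < 1
  if (any(dmg)) {
    conc$Tb[dmg] <- conc$Tb[dmg] + p$lam * (1 - life0[dmg]) * dt
  }

  state$conc <- conc
  state$pop <- lapply(pop, pmax, 0)
  state$step <- state$step + 1L
  state
}

#' Run the agent-based model
#'
#' Applies deposition and one model step `n_steps` times, recording aggregate
#' statistics at every step.
#'
#' @param state an [ab_state] (fresh from [ab_init] or mid-run).
#' @param signal a [smoking_signal].
#' @param params an [immune_params].
#' @param config an [ab_config].
#' @param n_steps number of steps (>= 0).
#' @param seed optional integer seed for the whole run.
#' @return A list with `state` (final [ab_state]) and `series`, a tibble with
#'   one row per step: `step`, `mean_life`, `damaged_frac`, mean local
#'   concentration of each cytokine, and total particle count.
#' @examples
#' res <- ab_run(ab_init(ab_config(rows = 5, cols = 5), seed = 1),
#'               smoking_signal(e_s = 0, T_s = 10),
#'               immune_params(), ab_config(rows = 5, cols = 5), n_steps = 5)
#' res$series$mean_life # stays 1: zero exposure never damages tissue
#' @export
ab_run <- function(state, signal, params, config, n_steps, seed = NULL) {
  stopifnot(n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  rec <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    state <- ab_deposit(state, signal, state$step, config = config)
    state <- ab_step(state, params, config)
    rec[[i]] <- c(step = state$step, mean_life = mean(state$life),
                  damaged_frac = damaged_fraction(state),
                  vapply(state$conc, mean, numeric(1)),
                  particles = sum(state$particles))
  }
  series <- if (n_steps > 0) {
    tibble::as_tibble(do.call(rbind, rec))
  } else {
    tibble::tibble(step = numeric(), mean_life = numeric(),
                   damaged_frac = numeric())
  }
  list(state = state, series = series)
}

#' @export
print.ab_state <- function(x, ...) {
  cat(sprintf("<ab_state> %dx%d grid, step %d\n", x$rows, x$cols, x$step))
  cat(sprintf("  mean tissue life %.3f, damaged fraction %.3f, %d particles\n",
              mean(x$life), damaged_fraction(x), round(sum(x$particles))))
  agents <- vapply(x$pop, sum, numeric(1))
  cat("  agents:", paste(sprintf("%s=%.6g", names(agents), agents), collapse = " "), "\n")
  invisible(x)
}

#' @export
autoplot.ab_state <- function(object, field = c("life", "cel", "ccl", "particles"),
                              ...) {
  field <- match.arg(field)
  m <- object[[field]]
  df <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)), value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = field)
}
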