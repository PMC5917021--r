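#' Monocyte recruitment rate driven by TNF-alpha
#'
#' Cubic recruitment response of circulating monocytes to the local TNF-alpha
#' concentration, fitted from wound-fluid chemotaxis data. This is the influx
#' term of the undifferentiated-macrophage balance.
#'
#' @param Ta TNF-alpha concentration, pg/ml (scalar or vector, >= 0).
#' @return Recruitment rate in cells/day.
#' @examples
#' monocyte_recruitment(0) # resting influx, 57.302 cells/day
#' @export
monocyte_recruitment <- function(Ta) {
  if (any(!is.finite(Ta)) || any(Ta < 0)) {
    stop("Ta must be finite and >= 0", call. = FALSE)
  }
  0.335 * Ta^3 - 6.309 * Ta^2 + 32.281 * Ta + 57.302
}

#' Fibroblast growth factor driven by TGF-beta
#'
#' Cubic proliferative response of fibroblasts to TGF-beta; multiplies the
#' fibroblast growth rate constant in the fibroblast balance.
#'
#' @param Tb TGF-beta concentration, pg/ml (scalar or vector, >= 0).
#' @return Dimensionless growth factor.
#' @examples
#' fibroblast_growth_factor(0) # 7.11
#' @export
fibroblast_growth_factor <- function(Tb) {
  if (any(!is.finite(Tb)) || any(Tb < 0)) {
    stop("Tb must be finite and >= 0", call. = FALSE)
  }
  0.05 * Tb^3 - 0.98 * Tb^2 + 6.54 * Tb + 7.11
}

#' Hill activation
#'
#' Saturating cooperative-binding activation `x / (x + c)`. The complementary
#' inhibition form `c / (x + c)` is `1 - hill(x, c)`.
#'
#' @param x concentration, >= 0 (vectorized).
#' @param c half-saturation constant, > 0.
#' @return Fraction in \[0, 1\].
#' @examples
#' hill(10, 10) # 0.5
#' @export
hill <- function(x, c) {
  if (any(!is.finite(c)) || any(c <= 0)) stop("c must be > 0", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("x must be >= 0", call. = FALSE)
  x / (x + c)
}

#' Time derivatives of the immune/remodeling model
#'
#' Right-hand side of the thirteen coupled ODEs: macrophage recruitment,
#' Hill-mediated polarization into M1/M2 with reversible transitions, cytokine
#' secretion under IL10 inhibition, TGF-beta-driven fibroblast growth, collagen
#' deposition and MMP cleavage, IL8-driven neutrophil recruitment and elastase
#' release.
#'
#' @param state an [immune_state] (or named numeric with the same 13 fields).
#' @param params an [immune_params].
#' @return Named numeric vector of d/dt for every field, same order as `state`.
#' @examples
#' immune_derivatives(immune_state(M2 = 100), immune_params())["Tb"] # k8 * 100
#' @export
immune_derivatives <- function(state, params = immune_params()) {
  s <- unclass(state)[.state_fields]
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("state must be finite and >= 0", call. = FALSE)
  }
  p <- params
  hIL1  <- hill(s[["IL1"]],  p$cIL1)
  hTa   <- hill(s[["Ta"]],   p$cTa)
  hIL10 <- hill(s[["IL10"]], p$cIL10)
  inh1  <- p$c1 / (s[["IL10"]] + p$c1)  # IL10 self-inhibition
  inhc  <- p$c  / (s[["IL10"]] + p$c)   # IL10 inhibition on IL1/TNFa secretion
  inh2  <- p$c2 / (s[["IL8"]] + p$c2)   # IL8 self-inhibition

  act1 <- (p$k2 * hIL1 + p$k3 * hTa) * s[["Mun"]]
  act2 <- p$k4 * hIL10 * s[["Mun"]]

  d <- c(
    Mun = monocyte_recruitment(s[["Ta"]]) - act1 - act2 - p$mu * s[["Mun"]],
    M1  = act1 + p$km21 * s[["M2"]] - (p$km12 + p$mu) * s[["M1"]],
    M2  = act2 + p$km12 * s[["M1"]] - (p$km21 + p$mu) * s[["M2"]],
    IL10 = p$k5 * s[["M2"]] * inh1 - p$dIL10 * s[["IL10"]],
    Ta  = p$k6 * s[["M1"]] * inhc - p$dTa * s[["Ta"]],
    IL1 = p$k7 * s[["M1"]] * inhc - p$dIL1 * s[["IL1"]],
    Tb  = p$k8 * s[["M2"]] + p$k9 * s[["F"]] - p$dTb * s[["Tb"]],
    F   = p$k10 * fibroblast_growth_factor(s[["Tb"]]) * s[["F"]] - p$dF * s[["F"]],
    C   = p$k11 * s[["F"]] - p$dFC * s[["MMP"]] * s[["C"]],
    MMP = p$k12 * s[["M1"]] - p$dFC * s[["MMP"]] * s[["C"]] - p$dM * s[["MMP"]],
    IL8 = p$k13 * s[["M2"]] * inh2 - p$dIL8 * s[["IL8"]],
    N   = p$k14rate * (1 - s[["N"]] / p$Nmax) * hill(s[["IL8"]], p$cIL8) -
          p$muN * s[["N"]],
    El  = p$k15 * s[["N"]] - p$dE * s[["El"]]
  )
  d
}

.overflow_guard <- 1e12

#' Integrate the immune/remodeling ODE model
#'
#' Integrates the thirteen-variable model from `state0` over `duration` days.
#' The default integrator is `deSolve::lsoda` (adaptive, stiffness-switching;
#' the fibroblast growth term is stiff relative to the cytokine decay rates).
#' A fixed-step explicit Euler scheme (`method = "euler"`) is provided as the
#' discretization against which the agent-based model is checked.
#'
#' Components driven below zero by the discretization are clamped to zero; the
#' number of clamping events is recorded in the `clamped` attribute. Any
#' component exceeding 1e12 in magnitude aborts with an error naming it.
#'
#' @param state0 initial [immune_state].
#' @param params [immune_params].
#' @param duration length of the run, days (>= 0).
#' @param dt output (and, for `"euler"`, step) interval, days.
#' @param method `"lsoda"` (default) or `"euler"`.
#' @return A `wm_trajectory`: a tibble with column `t` (days) and one column
#'   per state variable, one row per output time starting at `t = 0`.
#' @examples
#' tr <- wm_integrate(immune_state(), duration = 5, dt = 0.5)
#' tail(tr, 1)
#' @export
wm_integrate <- function(state0, params = immune_params(), duration, dt = 0.01,
                         method = c("lsoda", "euler")) {
  method <- match.arg(method)
  stopifnot(duration >= 0, dt > 0)
  s0 <- stats::setNames(as.numeric(unclass(state0)[.state_fields]), .state_fields)
  validate_immune_state(s0)
  if (duration == 0) {
    out <- tibble::as_tibble(as.list(s0))
    out <- dplyr::bind_cols(tibble::tibble(t = 0), out)
    return(new_wm_trajectory(out, clamped = 0L))
  }
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  clamped <- 0L

  if (method == "lsoda") {
    rhs <- function(t, y, parms) {
      y <- pmax(y, 0)
      list(immune_derivatives(y, parms))
    }
    sol <- deSolve::lsoda(y = s0, times = times, func = rhs, parms = params)
    m <- as.matrix(sol)[, -1, drop = FALSE]
    neg <- m < 0
    clamped <- sum(neg)
    m[neg] <- 0
  } else {
    m <- matrix(NA_real_, nrow = length(times), ncol = 13,
                dimnames = list(NULL, .state_fields))
    y <- s0
    m[1, ] <- y
    for (i in seq_along(times)[-1]) {
      h <- times[i] - times[i - 1]
      y <- y + h * immune_derivatives(y, params)
      neg <- y < 0
      if (any(neg)) {
        clamped <- clamped + sum(neg)
        y[neg] <- 0
      }
      over <- abs(y) > .overflow_guard
      if (any(over)) {
        stop("integration diverged in component(s): ",
             paste(.state_fields[over], collapse = ", "), call. = FALSE)
      }
      m[i, ] <- y
    }
  }
  over <- !is.finite(m) | abs(m) > .overflow_guard
  if (any(over)) {
    comp <- unique(colnames(m)[col(m)[over]])
    stop("integration diverged in component(s): ",
         paste(comp, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(t = times), tibble::as_tibble(m))
  new_wm_trajectory(out, clamped = clamped)
}

new_wm_trajectory <- function(tbl, clamped = 0L) {
  attr(tbl, "clamped") <- as.integer(clamped)
  class(tbl) <- c("wm_trajectory", class(tbl))
  tbl
}

#' Steady state of the immune/remodeling model
#'
#' Integrates from `state0` in growing chunks until the derivative norm drops
#' below `tol`, or errors after `horizon` days.
#'
#' @param params [immune_params].
#' @param state0 starting [immune_state]; default all-zero fields except the
#'   resting macrophage pool.
#' @param tol maximum L2 norm of the derivative vector at the returned state.
#' @param horizon give up after this many simulated days.
#' @return An [immune_state] with `attr(,"norm")` the achieved derivative norm.
#' @examples
#' st <- wm_steady_state(immune_params(), immune_state(Mun = 0))
#' st["Mun"] # ~ 57.302 / 0.2
#' @export
wm_steady_state <- function(params = immune_params(), state0 = immune_state(),
                            tol = 1e-6, horizon = 2000) {
  stopifnot(tol > 0)
  y <- do.call(immune_state, as.list(unclass(state0)[.state_fields]))
  elapsed <- 0
  chunk <- 25
  repeat {
    nrm <- sqrt(sum(immune_derivatives(y, params)^2))
    if (nrm < tol) break
    if (elapsed >= horizon) {
      stop(sprintf("no steady state within %g days (last derivative norm %.3g)",
                   horizon, nrm), call. = FALSE)
    }
    tr <- wm_integrate(y, params, duration = chunk, dt = chunk / 50)
    y <- trajectory_state(tr, nrow(tr))
    elapsed <- elapsed + chunk
    chunk <- min(chunk * 2, horizon - elapsed + chunk)
  }
  out <- do.call(immune_state, as.list(unclass(y)[.state_fields]))
  attr(out, "norm") <- sqrt(sum(immune_derivatives(out, params)^2))
  out
}

# row i of a trajectory as an immune_state-like named vector
trajectory_state <- function(tr, i) {
  v <- as.numeric(tr[i, .state_fields])
  names(v) <- .state_fields
  class(v) <- "immune_state"
  v
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.wm_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"t",
                      names_to = "variable", values_to = "value")
}

#' @export
glance.wm_trajectory <- function(x, ...) {
  final <- x[nrow(x), ]
  tibble::tibble(
    duration = final$t,
    n_steps = nrow(x) - 1L,
    clamped = attr(x, "clamped") %||% 0L,
    Mun_final = final$Mun,
    Ta_peak = max(x$Ta),
    C_final = final$C
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.wm_trajectory <- function(object, variables = NULL, ...) {
  long <- tidy(object)
  if (!is.null(variables)) long <- dplyr::filter(long, .data$variable %in% variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL)
}

#' @importFrom rlang %||% .data :=
NULL
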