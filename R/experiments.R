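#' Smoking-exposure experiment design
#'
#' The Cartesian product of five exposure levels (particles per smoking step,
#' 0 to 20) and five total smoking times (10 to 90 steps): 25 design points.
#'
#' @return A tibble with columns `e_s` and `T_s`, 25 rows in lexicographic
#'   order.
#' @export
exposure_design <- function() {
  tidyr::expand_grid(e_s = c(0L, 5L, 10L, 15L, 20L),
                     T_s = c(10L, 30L, 50L, 70L, 90L))
}

#' Fractional-factorial parameter design
#'
#' The 16-run two-level fractional factorial over six rate constants used for
#' parameter-sensitivity screening: TGFb secretion by M2 (`k8`), IL10 decay
#' (`dIL10`), MMP secretion (`k12`), IL8 secretion (`k13`), fibroblast
#' apoptosis (`dF`) and MMP decay (`dM`). Rows are the literal published
#' design, in order.
#'
#' @return A tibble with columns `experiment`, `k8`, `dIL10`, `k12`, `k13`,
#'   `dF`, `dM`; 16 rows.
#' @export
factorial_design <- function() {
  tibble::tribble(
    ~experiment, ~k8,  ~dIL10, ~k12, ~k13,   ~dF,  ~dM,
    1L,  0.70, 2.5, 3, 0.5e-3, 0.12, 0.875,
    2L,  0.14, 2.5, 3, 0.5e-3, 0.24, 0.875,
    3L,  0.70, 5.0, 3, 0.5e-3, 0.24, 1.750,
    4L,  0.14, 5.0, 3, 0.5e-3, 0.12, 1.750,
    5L,  0.70, 2.5, 6, 0.5e-3, 0.24, 1.750,
    6L,  0.14, 2.5, 6, 0.5e-3, 0.12, 1.750,
    7L,  0.70, 5.0, 6, 0.5e-3, 0.12, 0.875,
    8L,  0.14, 5.0, 6, 0.5e-3, 0.24, 0.875,
    9L,  0.70, 2.5, 3, 1.0e-3, 0.12, 1.750,
    10L, 0.14, 2.5, 3, 1.0e-3, 0.24, 1.750,
    11L, 0.70, 5.0, 3, 1.0e-3, 0.24, 0.875,
    12L, 0.14, 5.0, 3, 1.0e-3, 0.12, 0.875,
    13L, 0.70, 2.5, 6, 1.0e-3, 0.24, 0.875,
    14L, 0.14, 2.5, 6, 1.0e-3, 0.12, 0.875,
    15L, 0.70, 5.0, 6, 1.0e-3, 0.12, 1.750,
    16L, 0.14, 5.0, 6, 1.0e-3, 0.24, 1.750
  )
}

#' Run the smoking-exposure grid experiment
#'
#' Runs the coupled agent/FE model at every design point of
#' [exposure_design()], for `T_s` smoking steps plus the signal's
#' post-cessation equilibration, over `n_seeds` random seeds, and records the
#' residual mean tissue life as percent of initial.
#'
#' @param params an [immune_params].
#' @param ab_cfg an [ab_config] (grid size = one CT voxel by default).
#' @param coupling a [coupling_config].
#' @param load a [breathing_load].
#' @param n_seeds replicate seeds per design point.
#' @param post_steps equilibration steps after cessation.
#' @param base_seed integer; replicate `i` of every design point runs under
#'   seed `base_seed + i` (common random numbers across design points).
#' @return An `exposure_result`: tibble of per-run rows (`e_s`, `T_s`, `seed`,
#'   `residual_life_pct`, `damaged_frac`, `n_cycles`), with the 5x5
#'   residual-percent table (seed-averaged) in attribute `grid` and per-run
#'   step series in attribute `series`.
#' @export
run_exposure_experiment <- function(params = immune_params(),
                                    ab_cfg = ab_config(),
                                    coupling = coupling_config(),
                                    load = breathing_load(),
                                    n_seeds = 3, post_steps = 20,
                                    base_seed = 1) {
  design <- exposure_design()
  runs <- list()
  series <- list()
  k <- 0L
  for (i in seq_len(nrow(design))) {
    for (s in seq_len(n_seeds)) {
      k <- k + 1L
      sig <- smoking_signal(e_s = design$e_s[i], T_s = design$T_s[i],
                            post_steps = post_steps)
      ab0 <- ab_init(ab_cfg, seed = base_seed + s)
      h <- run_coupled(ab0, sig, params, ab_cfg, coupling, load,
                       seed = base_seed + s)
      st <- attr(h, "state")
      runs[[k]] <- tibble::tibble(
        e_s = design$e_s[i], T_s = design$T_s[i], seed = base_seed + s,
        residual_life_pct = 100 * mean(st$life),
        damaged_frac = damaged_fraction(st),
        n_cycles = nrow(h))
      series[[k]] <- dplyr::mutate(tibble::as_tibble(h),
                                   e_s = design$e_s[i], T_s = design$T_s[i],
                                   seed = base_seed + s)
    }
  }
  out <- dplyr::bind_rows(runs)
  grid <- out |>
    dplyr::group_by(.data$e_s, .data$T_s) |>
    dplyr::summarise(residual_life_pct = mean(.data$residual_life_pct),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "T_s", values_from = "residual_life_pct",
                       names_prefix = "T_s=")
  attr(out, "grid") <- grid
  attr(out, "series") <- dplyr::bind_rows(series)
  class(out) <- c("exposure_result", class(out))
  out
}

#' @export
autoplot.exposure_result <- function(object, ...) {
  avg <- object |>
    dplyr::group_by(.data$e_s, .data$T_s) |>
    dplyr::summarise(residual = mean(.data$residual_life_pct), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = factor(.data$T_s), y = factor(.data$e_s),
                                    fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$residual))) +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "white",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "smoking time (steps)", y = "exposure (particles/step)",
                  fill = "residual\nlife (%)")
}

#' Run the fractional-factorial parameter experiment
#'
#' Runs the coupled model once per row of [factorial_design()] at a fixed
#' medium-damage exposure (10 particles, 50 smoking steps), `n_seeds`
#' replicates per row under common random numbers, and summarizes the
#' between-row variability of the mean-tissue-life trajectory: the standard
#' deviation across the 16 rows at each step, averaged over steps.
#'
#' @inheritParams run_exposure_experiment
#' @param e_s,T_s fixed exposure conditions for all 16 runs.
#' @return A `factorial_result`: per-run tibble (`experiment`, `seed`,
#'   `residual_life_pct`), with attributes `avg_sd` (the variability
#'   statistic, tissue-life units in \[0, 1\]) and `series` (per-step mean
#'   life per run).
#' @export
run_parameter_experiment <- function(e_s = 10, T_s = 50,
                                     params = immune_params(),
                                     ab_cfg = ab_config(),
                                     coupling = coupling_config(),
                                     load = breathing_load(),
                                     n_seeds = 3, post_steps = 20,
                                     base_seed = 1) {
  design <- factorial_design()
  sig <- smoking_signal(e_s = e_s, T_s = T_s, post_steps = post_steps)
  n_steps <- T_s + post_steps
  runs <- list()
  life <- list()  # life[[run]] = per-step mean life, fixed length
  k <- 0L
  for (i in seq_len(nrow(design))) {
    p_i <- immune_params(k8 = design$k8[i], dIL10 = design$dIL10[i],
                         k12 = design$k12[i], k13 = design$k13[i],
                         dF = design$dF[i], dM = design$dM[i])
    for (s in seq_len(n_seeds)) {
      k <- k + 1L
      ab0 <- ab_init(ab_cfg, seed = base_seed + s)
      set.seed(base_seed + s)  # common random numbers across rows
      res <- ab_run(ab0, sig, p_i, ab_cfg, n_steps)
      st <- res$state
      runs[[k]] <- tibble::tibble(
        experiment = design$experiment[i], seed = base_seed + s,
        residual_life_pct = 100 * mean(st$life))
      life[[k]] <- tibble::tibble(
        experiment = design$experiment[i], seed = base_seed + s,
        step = res$series$step, mean_life = res$series$mean_life)
    }
  }
  out <- dplyr::bind_rows(runs)
  series <- dplyr::bind_rows(life)
  avg_sd <- series |>
    dplyr::group_by(.data$experiment, .data$step) |>
    dplyr::summarise(mean_life = mean(.data$mean_life), .groups = "drop") |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(sd = stats::sd(.data$mean_life), .groups = "drop") |>
    dplyr::summarise(avg_sd = mean(.data$sd)) |>
    dplyr::pull(.data$avg_sd)
  attr(out, "avg_sd") <- avg_sd
  attr(out, "series") <- series
  class(out) <- c("factorial_result", class(out))
  out
}

#' Run the mean-lung-density progression experiment
#'
#' Generates `n_patches` synthetic patches of a given severity, runs the full
#' imaging pipeline on each ([simulate_patch_progression]), and compares the
#' baseline and progression MLD lists with a Welch t-test.
#'
#' @param n_patches number of synthetic patches (>= 2).
#' @param severity generator severity for the baseline patches.
#' @param n_seeds seed pixels per patch.
#' @param signal a [smoking_signal] driving every per-pixel job.
#' @param params an [immune_params].
#' @param ab_cfg an [ab_config] template for the per-voxel jobs.
#' @param coupling a [coupling_config].
#' @param load a [breathing_load].
#' @param base_seed integer seed; patch `i` uses `base_seed + i`.
#' @return A list with `per_patch` (tibble: `patch`, `mld_before`,
#'   `mld_after`), and `comparison` (the [group_compare] tibble of baseline
#'   vs. progression).
#' @export
run_mld_experiment <- function(n_patches = 20, severity = "healthy",
                               n_seeds = 15,
                               signal = smoking_signal(e_s = 10, T_s = 50),
                               params = immune_params(),
                               ab_cfg = ab_config(),
                               coupling = coupling_config(),
                               load = breathing_load(),
                               base_seed = 1) {
  stopifnot(n_patches >= 2)
  rows <- purrr::map_dfr(seq_len(n_patches), function(i) {
    patch <- synth_patch(severity, seed = base_seed + i)
    sim <- simulate_patch_progression(patch, n_seeds = n_seeds, signal = signal,
                                      params = params, ab_cfg = ab_cfg,
                                      coupling = coupling, load = load,
                                      seed = base_seed + i)
    tibble::tibble(patch = i, mld_before = sim$mld_before,
                   mld_after = sim$mld_after)
  })
  list(per_patch = rows,
       comparison = group_compare(rows$mld_before, rows$mld_after))
}
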