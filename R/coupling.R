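#' Configuration of the AB-FE coupling cycle
#'
#' @param ab_steps_per_cycle agent-model steps between mechanical solves
#'   (default 10 steps = 1 simulated day at dt = 0.1).
#' @param damage_stop_fraction stop (and skip further mechanical solves) once
#'   this fraction of the tissue area is destroyed.
#' @param max_cycles hard cap on coupling cycles.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(ab_steps_per_cycle = 10, damage_stop_fraction = 0.80,
                            max_cycles = 100) {
  stopifnot(ab_steps_per_cycle >= 1, damage_stop_fraction > 0,
            damage_stop_fraction <= 1, max_cycles >= 1)
  structure(list(ab_steps_per_cycle = as.integer(ab_steps_per_cycle),
                 damage_stop_fraction = damage_stop_fraction,
                 max_cycles = as.integer(max_cycles)),
            class = "coupling_config")
}

#' Freeze the agent state into a mechanical problem
#'
#' Gates on remaining healthy tissue: if the damaged fraction has reached the
#' stop threshold no mechanical solve is attempted (`NULL` is returned).
#' Otherwise builds the grid-equivalent quad mesh and the per-element modulus
#' field from the local elastin/collagen content ([mixture_modulus]; dead
#' cells at 1 Pa).
#'
#' @param ab an [ab_state].
#' @param coupling a [coupling_config].
#' @param cell_size element edge length, mm.
#' @return `list(mesh, E)` or `NULL` when the damage gate trips.
#' @export
export_ab_to_fe <- function(ab, coupling = coupling_config(), cell_size = 1) {
  if (damaged_fraction(ab) >= coupling$damage_stop_fraction) return(NULL)
  mesh <- build_mesh(ab$rows, ab$cols, cell_size)
  E <- mixture_modulus(as.vector(ab$cel), as.vector(ab$ccl),
                       alive = as.vector(ab$alive))
  list(mesh = mesh, E = E)
}

#' Read the strain field back into the agent state
#'
#' Cells whose maximum principal strain exceeds their composition-weighted
#' limit ([rupture]) are marked destroyed (tissue life 0); everything else is
#' preserved.
#'
#' @param ab an [ab_state].
#' @param strains a `strain_field` from [solve_elasticity] on the matching
#'   grid-equivalent mesh.
#' @return The updated `ab_state`, with attribute `n_ruptured`.
#' @export
apply_fe_to_ab <- function(ab, strains) {
  if (nrow(strains) != ab$rows * ab$cols) {
    stop("strain field does not match the agent grid", call. = FALSE)
  }
  dead <- rupture(strains, ab$cel, ab$ccl, ab$alive)
  if (length(dead)) {
    ab$alive[dead] <- FALSE
    ab$life[dead] <- 0
  }
  attr(ab, "n_ruptured") <- length(dead)
  ab
}

#' Run the coupled agent/finite-element simulation
#'
#' Alternates agent-model bursts with mechanical solves: run the AB model for
#' `ab_steps_per_cycle` steps, freeze it, solve the plane-stress problem under
#' the breathing load, rupture over-strained cells, and repeat — until the
#' destroyed area exceeds the stop fraction, `n_steps` total agent steps have
#' been simulated, or `max_cycles` is hit.
#'
#' @param ab0 initial [ab_state].
#' @param signal a [smoking_signal].
#' @param params an [immune_params].
#' @param ab_config an [ab_config].
#' @param coupling a [coupling_config].
#' @param load a [breathing_load].
#' @param n_steps total agent steps to simulate (default: smoking time plus
#'   post-cessation equilibration from `signal`).
#' @param seed optional integer seed covering the whole run.
#' @return A `coupled_history`: a tibble with one row per cycle (`cycle`,
#'   `step`, `damaged_frac`, `mean_life`, `max_principal_strain`,
#'   `n_ruptured`), with the final `ab_state` in attribute `state`.
#' @examples
#' cfg <- ab_config(rows = 5, cols = 5)
#' h <- run_coupled(ab_init(cfg, seed = 1), smoking_signal(e_s = 0, T_s = 10),
#'                  immune_params(), cfg, seed = 1)
#' tail(h, 1)$mean_life # zero exposure: tissue stays fully healthy
#' @export
run_coupled <- function(ab0, signal, params = immune_params(),
                        ab_config = emphysim::ab_config(),
                        coupling = coupling_config(),
                        load = breathing_load(),
                        n_steps = signal$T_s + signal$post_steps,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ab <- ab0
  rows <- list()
  cycle <- 0L
  done <- 0L
  while (cycle < coupling$max_cycles && done < n_steps) {
    cycle <- cycle + 1L
    burst <- min(coupling$ab_steps_per_cycle, n_steps - done)
    res <- ab_run(ab, signal, params, ab_config, burst)
    ab <- res$state
    done <- done + burst
    maxp <- NA_real_
    n_rupt <- 0L
    fe <- export_ab_to_fe(ab, coupling)
    if (is.null(fe)) {
      rows[[cycle]] <- tibble::tibble(
        cycle = cycle, step = done, damaged_frac = damaged_fraction(ab),
        mean_life = mean(ab$life), max_principal_strain = maxp,
        n_ruptured = n_rupt)
      break
    }
    sf <- solve_elasticity(fe$mesh, fe$E, load)
    maxp <- max(sf$max_principal)
    ab <- apply_fe_to_ab(ab, sf)
    n_rupt <- attr(ab, "n_ruptured")
    rows[[cycle]] <- tibble::tibble(
      cycle = cycle, step = done, damaged_frac = damaged_fraction(ab),
      mean_life = mean(ab$life), max_principal_strain = maxp,
      n_ruptured = n_rupt)
    if (damaged_fraction(ab) >= coupling$damage_stop_fraction) break
  }
  hist <- dplyr::bind_rows(rows)
  attr(hist, "state") <- ab
  class(hist) <- c("coupled_history", class(hist))
  hist
}

#' @export
glance.coupled_history <- function(x, ...) {
  st <- attr(x, "state")
  tibble::tibble(
    n_cycles = nrow(x),
    steps = if (nrow(x)) max(x$step) else 0L,
    damaged_frac = damaged_fraction(st),
    mean_life = mean(st$life),
    total_ruptured = sum(x$n_ruptured, na.rm = TRUE)
  )
}

#' @export
autoplot.coupled_history <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("damaged_frac", "mean_life"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "agent step", y = NULL, colour = NULL)
}

#' Connected regions of destroyed tissue
#'
#' Labels the 4-connected components of the dead-cell mask after one pass of
#' morphological closing (3x3 cross dilation followed by erosion), for
#' reporting and visualization of emphysematous lesions. The mechanical model
#' itself works on per-element materials and does not consume these contours.
#'
#' @param ab an [ab_state].
#' @return A tibble with one row per region: `region`, `area` (cells, before
#'   closing), and a list-column `boundary` of (row, col) matrices of the
#'   region's boundary cells. The closed label matrix is in attribute
#'   `labels`.
#' @export
extract_damage_contours <- function(ab) {
  dead <- !ab$alive
  closed <- erode_cross(dilate_cross(dead))
  closed <- closed | dead  # closing never removes original dead cells
  lab <- label_components(closed)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  regions <- purrr::map_dfr(ids, function(id) {
    cells <- which(lab == id)
    orig <- sum(dead[cells])
    # boundary: region cells with at least one 4-neighbour outside the region
    bnd <- cells[vapply(cells, function(i) {
      any(lab[ab$nbrs[[i]]] != id)
    }, logical(1))]
    if (!length(bnd)) bnd <- cells
    tibble::tibble(
      region = id, area = orig,
      boundary = list(cbind(row = (bnd - 1L) %% ab$rows + 1L,
                            col = (bnd - 1L) %/% ab$rows + 1L))
    )
  })
  if (!nrow(regions)) {
    regions <- tibble::tibble(region = integer(), area = integer(),
                              boundary = list())
  }
  attr(regions, "labels") <- lab
  regions
}

dilate_cross <- function(m) {
  r <- nrow(m); c <- ncol(m)
  up    <- rbind(m[-1, , drop = FALSE], FALSE)
  down  <- rbind(FALSE, m[-r, , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -c, drop = FALSE])
  m | up | down | left | right
}

erode_cross <- function(m) {
  r <- nrow(m); c <- ncol(m)
  up    <- rbind(m[-1, , drop = FALSE], TRUE)
  down  <- rbind(TRUE, m[-r, , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], TRUE)
  right <- cbind(TRUE, m[, -c, drop = FALSE])
  m & up & down & left & right
}

# 4-connected component labelling by flood fill
label_components <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  lab <- matrix(0L, r, c)
  nbrs <- grid_neighbours(r, c)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nb in nbrs[[cur]]) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}
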