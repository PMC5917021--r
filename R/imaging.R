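#' CT patch container
#'
#' A square 2D patch of CT attenuation values in Hounsfield units with its
#' physical spacing.
#'
#' @param hu numeric matrix of HU values in \[-1024, 3071\], square.
#' @param spacing in-plane pixel spacing, mm.
#' @param thickness slice thickness, mm.
#' @param severity annotation: `"healthy"`, `"moderate"`, `"severe"` or
#'   `"none"`.
#' @return An object of class `ct_patch`.
#' @export
ct_patch <- function(hu, spacing = 0.78, thickness = 1.25,
                     severity = c("none", "healthy", "moderate", "severe")) {
  severity <- match.arg(severity)
  hu <- as.matrix(hu)
  stopifnot(nrow(hu) == ncol(hu), all(is.finite(hu)),
            all(hu >= -1024), all(hu <= 3071), spacing > 0, thickness > 0)
  structure(list(hu = hu, spacing = spacing, thickness = thickness,
                 severity = severity),
            class = "ct_patch")
}

#' @export
print.ct_patch <- function(x, ...) {
  cat(sprintf("<ct_patch> %dx%d px, %.2f mm spacing, severity '%s', MLD %.1f HU\n",
              nrow(x$hu), ncol(x$hu), x$spacing, x$severity, mean(x$hu)))
  invisible(x)
}

#' @export
autoplot.ct_patch <- function(object, ...) {
  m <- object$hu
  df <- tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                       hu = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1024, 0), oob = scales_squish) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "HU")
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Segment lung parenchyma by fixed threshold
#'
#' Air-rich parenchyma attenuates weakly; the mask selects pixels at or below
#' the threshold, excluding vessels and airway walls.
#'
#' @param patch a [ct_patch].
#' @param threshold HU cutoff (default -750).
#' @return Logical matrix congruent with the patch (TRUE = parenchyma).
#' @export
segment_parenchyma <- function(patch, threshold = -750) {
  patch$hu <= threshold
}

#' Alveoli contained in one CT voxel
#'
#' Stereological density of alveoli times the voxel volume, rounded to the
#' nearest ten.
#'
#' @param spacing in-plane pixel spacing, mm.
#' @param thickness slice thickness, mm.
#' @param density alveoli per cubic millimetre (default 170).
#' @return Alveolus count per voxel (multiple of ten).
#' @examples
#' alveoli_per_voxel() # 130 for the 0.78 x 0.78 x 1.25 mm voxel
#' @export
alveoli_per_voxel <- function(spacing = 0.78, thickness = 1.25, density = 170) {
  stopifnot(spacing > 0, thickness > 0, density >= 0)
  round(density * spacing^2 * thickness / 10) * 10
}

#' Most-square grid for a voxel's alveoli
#'
#' Factors the per-voxel alveolus count into the integer `rows x cols` pair
#' with the smallest aspect difference (`rows >= cols`), used as the
#' computational grid of one simulation job.
#'
#' @param n_alveoli alveoli per voxel (>= 1).
#' @return Integer vector `c(rows, cols)`.
#' @examples
#' grid_for_voxel(130) # 13 x 10
#' @export
grid_for_voxel <- function(n_alveoli = 130) {
  stopifnot(n_alveoli >= 1, n_alveoli == round(n_alveoli))
  n <- as.integer(n_alveoli)
  divs <- which(n %% seq_len(floor(sqrt(n))) == 0)
  cols <- max(divs)
  c(rows = n %/% cols, cols = cols)
}

#' Select seed pixels for particle deposition
#'
#' Uniformly samples `n` parenchyma pixels and expands each by its in-mask
#' 4-neighbours; the deduplicated union is the set of "affected" pixels, each
#' of which hosts one coupled simulation job.
#'
#' @param mask parenchyma mask (logical matrix).
#' @param n number of seeds (default 200; reduced with a warning when the mask
#'   is smaller).
#' @param seed optional integer RNG seed.
#' @return Integer matrix with columns `row`, `col` (1-based pixel indices),
#'   deduplicated; seed pixels are flagged in column `is_seed`.
#' @export
select_seeds <- function(mask, n = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(mask)
  if (!length(idx)) stop("empty parenchyma mask", call. = FALSE)
  if (length(idx) < n) {
    warning("mask has fewer pixels than requested seeds; using all")
    n <- length(idx)
  }
  seeds <- sample(idx, n)
  r <- nrow(mask); c <- ncol(mask)
  nb <- c(seeds - 1L, seeds + 1L, seeds - r, seeds + r)
  ri <- (seeds - 1L) %% r + 1L
  ci <- (seeds - 1L) %/% r + 1L
  ok <- c(ri > 1L, ri < r, ci > 1L, ci < c)
  nb <- nb[ok]
  nb <- nb[mask[nb]]
  all_idx <- unique(c(seeds, nb))
  out <- cbind(row = (all_idx - 1L) %% r + 1L,
               col = (all_idx - 1L) %/% r + 1L,
               is_seed = as.integer(all_idx %in% seeds))
  out
}

#' Map a simulated mean modulus back to Hounsfield units
#'
#' The coupled model's final mean element modulus is translated linearly into
#' attenuation: full stiffness keeps the original HU, a fully destroyed voxel
#' approaches air (-1000 HU).
#'
#' @param E_mean mean element Young's modulus after simulation, Pa.
#' @param hu_orig the pixel's original HU value.
#' @param E0 healthy reference modulus, Pa (default the full-content mixture,
#'   6070 Pa).
#' @return Remapped HU, clipped to \[-1000, `hu_orig`\].
#' @examples
#' modulus_to_hu(6070, -800) # unchanged
#' modulus_to_hu(3035, -800) # -900, halfway to air
#' @export
modulus_to_hu <- function(E_mean, hu_orig, E0 = mixture_modulus(1, 1)) {
  stopifnot(E_mean > 0, E0 > 0)
  if (any(E_mean > E0)) {
    warning("E_mean above the healthy reference; clipping to the original HU")
  }
  hu <- -1000 + (hu_orig + 1000) * (E_mean / E0)
  pmin(pmax(hu, -1000), hu_orig)
}

#' Mean lung density
#'
#' The standard CT biomarker of emphysema progression: the mean attenuation
#' over the parenchyma mask. Parenchyma destruction lowers it toward air.
#'
#' @param patch a [ct_patch].
#' @param mask parenchyma mask (default: threshold segmentation of the patch).
#' @return Mean HU over the mask.
#' @export
mld <- function(patch, mask = segment_parenchyma(patch)) {
  if (!any(mask)) stop("empty parenchyma mask", call. = FALSE)
  mean(patch$hu[mask])
}

#' Synthetic CT patch generator
#'
#' Stands in for a clinical emphysema patch database (explicitly synthetic;
#' parameters are generator choices, not measured values). Healthy patches are
#' Gaussian-textured parenchyma with a few bright vessel streaks; moderate and
#' severe patches additionally contain disk-shaped low-attenuation clusters
#' pushed toward -980 HU, mimicking the growing low-attenuation areas of
#' progressing emphysema.
#'
#' @param severity `"healthy"`, `"moderate"` or `"severe"`.
#' @param size patch edge length, pixels.
#' @param seed optional integer RNG seed (same seed, same patch).
#' @param base_mean,base_sd parenchyma texture, HU.
#' @param n_vessels number of bright vessel streaks.
#' @param spacing,thickness voxel geometry, mm.
#' @return A [ct_patch].
#' @examples
#' p <- synth_patch("severe", seed = 1)
#' mld(p) < mld(synth_patch("healthy", seed = 1))
#' @export
synth_patch <- function(severity = c("healthy", "moderate", "severe"),
                        size = 61, seed = NULL,
                        base_mean = -820, base_sd = 40, n_vessels = 6,
                        spacing = 0.78, thickness = 1.25) {
  severity <- match.arg(severity)
  if (!is.null(seed)) set.seed(seed)
  hu <- matrix(stats::rnorm(size^2, base_mean, base_sd), size, size)

  # bright vessel streaks (> -500 HU): short thick line segments
  for (v in seq_len(n_vessels)) {
    r0 <- sample.int(size, 1); c0 <- sample.int(size, 1)
    ang <- stats::runif(1, 0, pi)
    len <- 18
    t <- seq(-len / 2, len / 2, by = 0.5)
    rr <- round(r0 + t * sin(ang)); cc <- round(c0 + t * cos(ang))
    for (w in -1:1) {
      rw <- rr + w
      ok <- rw >= 1 & rw <= size & cc >= 1 & cc <= size
      hu[cbind(rw[ok], cc[ok])] <- stats::rnorm(sum(ok), -300, 80)
    }
  }

  # low-attenuation clusters for diseased severities
  n_clusters <- switch(severity, healthy = 0, moderate = 5, severe = 15)
  radii <- switch(severity, healthy = c(0, 0), moderate = c(2, 4), severe = c(3, 8))
  rows <- row(hu); cols <- col(hu)
  for (k in seq_len(n_clusters)) {
    r0 <- stats::runif(1, 1, size); c0 <- stats::runif(1, 1, size)
    rad <- stats::runif(1, radii[1], radii[2])
    d2 <- (rows - r0)^2 + (cols - c0)^2
    w <- exp(-d2 / (2 * (rad / 1.5)^2))
    inside <- d2 <= rad^2
    hu[inside] <- hu[inside] * (1 - w[inside]) + (-980 + stats::rnorm(sum(inside), 0, 8)) * w[inside]
  }
  hu <- pmin(pmax(hu, -1024), 3071)
  ct_patch(hu, spacing = spacing, thickness = thickness,
           severity = if (severity == "healthy") "healthy" else severity)
}

#' Read a CT patch from file
#'
#' Accepts a plain CSV of HU values, or PNG/TIFF images of gray levels
#' rescaled into `hu_range`. DICOM is out of scope.
#'
#' @param path file path (`.csv`, `.png`, `.tif`/`.tiff`).
#' @param hu_range HU values mapped to gray 0 and 1 for image formats.
#' @param ... passed to [ct_patch].
#' @return A [ct_patch].
#' @export
read_patch <- function(path, hu_range = c(-1024, 0), ...) {
  ext <- tolower(tools::file_ext(path))
  hu <- switch(ext,
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    png = {
      rlang::check_installed("png")
      g <- png::readPNG(path)
      if (length(dim(g)) == 3) g <- g[, , 1]
      hu_range[1] + g * diff(hu_range)
    },
    tif = , tiff = {
      rlang::check_installed("tiff")
      g <- tiff::readTIFF(path)
      if (length(dim(g)) == 3) g <- g[, , 1]
      hu_range[1] + g * diff(hu_range)
    },
    stop("unsupported patch format: ", ext, call. = FALSE)
  )
  dimnames(hu) <- NULL
  ct_patch(hu, ...)
}

#' Compare two groups of MLD values
#'
#' Welch two-sample t-test on mean-lung-density lists (group A minus group B).
#' Degenerate variance (both groups essentially constant) is reported with a
#' p-value of 1 when the means agree and 0 otherwise.
#'
#' @param mlds_a,mlds_b numeric vectors of MLD values, each of length >= 2.
#' @return A tibble with `mean_difference` (HU), `p_value`, `statistic`, `df`
#'   and `degenerate` flag.
#' @export
group_compare <- function(mlds_a, mlds_b) {
  stopifnot(length(mlds_a) >= 2, length(mlds_b) >= 2)
  diff <- mean(mlds_a) - mean(mlds_b)
  eps <- .Machine$double.eps * max(1, abs(mean(c(mlds_a, mlds_b))))
  if (stats::sd(mlds_a) <= eps && stats::sd(mlds_b) <= eps) {
    return(tibble::tibble(mean_difference = diff,
                          p_value = if (abs(diff) <= eps) 1 else 0,
                          statistic = NA_real_, df = NA_real_,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(mlds_a, mlds_b, var.equal = FALSE)
  tibble::tibble(mean_difference = diff, p_value = tt$p.value,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 degenerate = FALSE)
}

#' Simulate emphysema progression on a CT patch
#'
#' The full imaging pipeline: segment the parenchyma, select seed pixels and
#' mark them and their neighbours affected, run one coupled agent/FE job (a
#' grid of the alveoli contained in one voxel) per affected pixel, and remap
#' each job's final mean element modulus back into the pixel's attenuation.
#' Unaffected pixels are unchanged. MLD is quantified before and after over
#' the baseline mask.
#'
#' @param patch a [ct_patch].
#' @param n_seeds seed pixels per patch.
#' @param signal a [smoking_signal] driving every job.
#' @param params an [immune_params].
#' @param ab_cfg an [ab_config] template; its grid is replaced by the voxel
#'   grid.
#' @param coupling a [coupling_config].
#' @param load a [breathing_load].
#' @param seed integer seed covering seed selection and all jobs.
#' @return A list with `before`/`after` ([ct_patch]es), `mld_before`,
#'   `mld_after`, the baseline `mask` and the affected-pixel table.
#' @export
simulate_patch_progression <- function(patch, n_seeds = 15,
                                       signal = smoking_signal(e_s = 10, T_s = 50),
                                       params = immune_params(),
                                       ab_cfg = ab_config(),
                                       coupling = coupling_config(),
                                       load = breathing_load(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- segment_parenchyma(patch)
  affected <- suppressWarnings(select_seeds(mask, n = n_seeds))
  gdim <- grid_for_voxel(alveoli_per_voxel(patch$spacing, patch$thickness))
  job_cfg <- ab_cfg
  job_cfg$rows <- gdim[["rows"]]
  job_cfg$cols <- gdim[["cols"]]
  E0 <- mixture_modulus(1, 1)

  hu_new <- patch$hu
  e_means <- numeric(nrow(affected))
  for (i in seq_len(nrow(affected))) {
    ab0 <- ab_init(job_cfg)
    h <- run_coupled(ab0, signal, params, job_cfg, coupling, load)
    st <- attr(h, "state")
    E <- mixture_modulus(as.vector(st$cel), as.vector(st$ccl),
                         alive = as.vector(st$alive))
    e_means[i] <- mean(E)
    px <- affected[i, , drop = FALSE]
    hu_new[px[, "row"], px[, "col"]] <-
      suppressWarnings(modulus_to_hu(min(e_means[i], E0),
                                     patch$hu[px[, "row"], px[, "col"]], E0))
  }
  after <- patch
  after$hu <- hu_new
  list(before = patch, after = after,
       mld_before = mld(patch, mask), mld_after = mld(after, mask),
       mask = mask,
       affected = tibble::as_tibble(affected) |>
         dplyr::mutate(E_mean = e_means))
}
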