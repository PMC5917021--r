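#' Rate constants of the immune/remodeling model
#'
#' Builds the full parameter set of the well-mixed inflammation and tissue
#' remodeling model. Defaults are the literature-derived values used throughout
#' the package; a handful of constants have no published value and carry
#' documented estimates (flagged in the `estimated` attribute).
#'
#' Units follow the model's mixed convention: cell counts in cells, cytokine
#' concentrations in pg/ml, collagen in ug, rates per day.
#'
#' @param ... named overrides of any constant, e.g. `immune_params(k6 = 1e-3)`.
#'
#' @return An object of class `immune_params`: a named list with elements
#'   \describe{
#'     \item{k2, k3, k4}{activation rates of IL1/TNFa (to M1) and IL10 (to M2),
#'       ml/pg/day}
#'     \item{k5, k6, k7, k13}{cytokine secretion rates (IL10, TNFa, IL1 by M1;
#'       IL8 by M2), pg/cell/day}
#'     \item{k8, k9}{TGFb secretion by M2 and by fibroblasts, pg/cell/day}
#'     \item{k10}{fibroblast growth rate, 1/day (scaled by the TGFb growth
#'       polynomial)}
#'     \item{k11}{collagen deposition rate, ug/cell/day}
#'     \item{k12}{MMP secretion by M1, pg/cell/day}
#'     \item{k15}{elastase secretion by neutrophils, pg/cell/day}
#'     \item{km12, km21}{M1->M2 and M2->M1 transition rates, 1/day}
#'     \item{mu, muN}{macrophage and neutrophil emigration rates, 1/day}
#'     \item{cIL1, cTa, cIL10}{Hill promotion constants, pg/ml}
#'     \item{c1}{IL10 self-inhibition constant, pg/ml}
#'     \item{c}{IL10 inhibition constant acting on IL1/TNFa secretion, pg/ml}
#'     \item{c2}{IL8 self-inhibition constant, pg/ml}
#'     \item{cIL8}{neutrophil-recruitment Hill constant, pg/ml}
#'     \item{k14rate}{maximum neutrophil recruitment, cells/day}
#'     \item{Nmax}{neutrophil carrying capacity, cells}
#'     \item{dIL10, dTa, dIL1, dTb, dIL8, dM, dE}{decay rates, 1/day}
#'     \item{dF}{fibroblast apoptosis rate, 1/day}
#'     \item{dFC}{MMP-collagen cleavage coefficient, ml/pg/day}
#'     \item{lam}{TGFb secretion rate of damaged tissue, pg/cell/day}
#'   }
#'
#' Note two deliberate disambiguations of the published constants: the
#' IL10-inhibition factor on IL1/TNFa secretion uses `c` (25 pg/ml) while the
#' IL10 self-inhibition uses `c1` (100 pg/ml); and the fibroblast apoptosis
#' rate is `dF` (0.12/day) while `dFC` is the separate MMP-collagen cleavage
#' coefficient. Setting `c = c1` recovers the variant where one constant plays
#' both inhibition roles.
#'
#' @examples
#' p <- immune_params()
#' p$k6
#' attr(p, "estimated") # constants without a published value
#' @export
immune_params <- function(...) {
  p <- list(
    k2 = 0.1, k3 = 1, k4 = 0.3,
    k5 = 5e-4, k6 = 7e-4, k7 = 5e-4, k13 = 5e-4,
    k8 = 0.07, k9 = 0.04,
    k10 = 0.924, k11 = 20, k12 = 3, k15 = 3,
    km12 = 0.075, km21 = 0.05,
    mu = 0.2, muN = 0.2,
    cIL1 = 10, cTa = 10, cIL10 = 5,
    c1 = 100, c = 25, c2 = 100,
    cIL8 = 8, k14rate = 10, Nmax = 1000,
    dIL10 = 2.5, dTa = 55, dIL1 = 0.2, dTb = 15, dIL8 = 2.5,
    dM = 0.875, dE = 1,
    dF = 0.12, dFC = 1e-3,
    lam = 5e-6
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all immune parameters must be finite and >= 0", call. = FALSE)
  }
  # estimated: no published value; defaults are package choices
  attr(p, "estimated") <- c("muN", "dIL8", "c2", "Nmax", "dE", "dFC", "k14rate",
                            "km12", "k12", "k13", "k15", "cIL8")
  class(p) <- "immune_params"
  p
}

#' @export
print.immune_params <- function(x, ...) {
  cat("<immune_params> ", length(unclass(x)), " rate constants\n", sep = "")
  est <- attr(x, "estimated")
  df <- tibble::tibble(
    parameter = names(unclass(x)),
    value = unlist(unclass(x)),
    estimated = names(unclass(x)) %in% est
  )
  print(df, n = Inf)
  invisible(x)
}

#' @describeIn immune_params flat named-list round trip to YAML. Requires the
#'   `yaml` package.
#' @param path file path for reading/writing.
#' @export
write_immune_params <- function(x, path) {
  stopifnot(inherits(x, "immune_params"))
  rlang::check_installed("yaml")
  yaml::write_yaml(unclass(x)[order(names(unclass(x)))], path)
  invisible(path)
}

#' @describeIn immune_params read parameters back from YAML.
#' @export
read_immune_params <- function(path) {
  rlang::check_installed("yaml")
  do.call(immune_params, yaml::read_yaml(path))
}

# field order of the 13 state variables used everywhere in the package
.state_fields <- c("Mun", "M1", "M2", "IL10", "Ta", "IL1", "Tb", "F",
                   "C", "MMP", "IL8", "N", "El")

#' State vector of the immune/remodeling model
#'
#' The thirteen state variables: undifferentiated (`Mun`), pro-inflammatory
#' (`M1`) and repair (`M2`) macrophages (cells); cytokines `IL10`, `Ta`
#' (TNF-alpha), `IL1`, `Tb` (TGF-beta), `IL8` (pg/ml); fibroblasts `F` (cells);
#' collagen `C` (ug); `MMP` (pg/ml); neutrophils `N` (cells); elastase `El`
#' (pg/ml).
#'
#' The default initial condition is the cytokine-free resting tissue with the
#' baseline patrolling-macrophage steady state `Mun = 286.51` (the closed form
#' recruitment-at-zero over emigration, 57.302/0.2) and everything else zero.
#'
#' @param ... named overrides of any field.
#' @return A named numeric vector of class `immune_state`.
#' @examples
#' immune_state(M2 = 100)
#' @export
immune_state <- function(...) {
  s <- stats::setNames(numeric(13), .state_fields)
  s[["Mun"]] <- 57.302 / 0.2
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .state_fields)
    if (length(bad) || is.null(names(dots))) {
      stop("unknown state field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    s[names(dots)] <- dots
  }
  validate_immune_state(s)
  class(s) <- "immune_state"
  s
}

validate_immune_state <- function(s) {
  if (any(!is.finite(s))) stop("immune state contains non-finite values", call. = FALSE)
  if (any(s < 0)) stop("immune state contains negative values", call. = FALSE)
  invisible(s)
}
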