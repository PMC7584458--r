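#' Linearized (pulled) front-speed catalogue
#'
#' Travelling-wave fronts connecting pairs of stationary states are pulled
#' fronts: their asymptotic speed is the minimum speed of the linearization
#' about the invaded state. Linearizing about the healthy state gives
#' \deqn{c_\beta^{(12)} = 2\sqrt{\tilde\rho_1 (a_2 a_0/a_1 - \tilde a_1)},\qquad
#'       c_\tau^{(13)} = 2\sqrt{\tilde\rho_2 (b_2 b_0/b_1 - \tilde b_1)},}
#' with \eqn{c_\tau^{(12)} = c_\beta^{(13)} = 0} (each family is inert in
#' the other's transition) and \eqn{c_\beta^{(14)} = c_\beta^{(12)}},
#' \eqn{c_\tau^{(14)} = c_\tau^{(13)}}. Linearizing about the toxic-A-beta
#' state gives the speed of the tau front invading territory already taken
#' by A-beta,
#' \deqn{c_\tau^{(24)} = 2\sqrt{\frac{\tilde\rho_2}{a_2 b_1 \tilde a_1}
#'   \left[\tilde a_1\big(a_2 (b_0 b_2 - b_1 \tilde b_1) - a_1 b_0 b_3\big)
#'         + a_0 a_2 b_0 b_3\right]},}
#' with \eqn{c_\beta^{(24)} = 0}, and the state-3-to-4 front is slaved to
#' the A-beta field: \eqn{c_\beta^{(34)} = c_\tau^{(34)} = c_\beta^{(12)}}.
#' Here \eqn{\tilde\rho_1, \tilde\rho_2} are the toxic-species diffusivities
#' (`rho_ut`, `rho_vt`). A negative radicand means the corresponding pair of
#' states does not exist and no front can develop; such speeds are reported
#' as `NA` with `exists = FALSE`.
#'
#' @param p A [kinetic_params()] object; must validate.
#' @return An object of class `front_speed_table`: list with numeric
#'   entries `c_beta_12, c_tau_12, c_beta_13, c_tau_13, c_beta_14,
#'   c_tau_14, c_beta_24, c_tau_24, c_beta_34, c_tau_34` and a logical
#'   vector `exists` over the same names.
#' @export
#' @examples
#' linear_front_speeds(preset_params("fig22_primary"))$c_tau_24  # ~0.129
linear_front_speeds <- function(p) {
  viol <- validate_params(p)
  if (length(viol) > 0L) stop("invalid parameters: ", paste(viol, collapse = "; "))
  speed <- function(rho, radicand) {
    if (radicand < 0) NA_real_ else 2 * sqrt(rho * radicand)
  }
  c12 <- speed(p$rho_ut, p$a2 * p$a0 / p$a1 - p$a1t)
  c13 <- speed(p$rho_vt, p$b2 * p$b0 / p$b1 - p$b1t)
  rad24 <- (p$a1t * (p$a2 * (p$b0 * p$b2 - p$b1 * p$b1t) - p$a1 * p$b0 * p$b3) +
              p$a0 * p$a2 * p$b0 * p$b3) / (p$a2 * p$b1 * p$a1t)
  c24 <- speed(p$rho_vt, rad24)
  tab <- list(c_beta_12 = c12, c_tau_12 = 0,
              c_beta_13 = 0, c_tau_13 = c13,
              c_beta_14 = c12, c_tau_14 = c13,
              c_beta_24 = 0, c_tau_24 = c24,
              c_beta_34 = c12, c_tau_34 = c12)
  tab$exists <- !vapply(tab, function(x) length(x) == 1L && is.na(x), logical(1))
  structure(tab, class = "front_speed_table")
}

#' @export
print.front_speed_table <- function(x, ...) {
  nm <- setdiff(names(x), "exists")
  v <- vapply(nm, function(f) x[[f]], numeric(1))
  cat("Linearized front speeds (NA: states do not exist, no front):\n")
  print(signif(v, 6))
  invisible(x)
}

#' One-dimensional continuum front simulation
#'
#' Method-of-lines solution of the four-species reaction-diffusion system
#' on a uniform 1D grid with zero-flux (Neumann) boundaries, using the same
#' stiff integrator as the network model. The second-order central
#' difference of the diffusion operator is realized as the graph Laplacian
#' of a path lattice with spacing `dx` (whose `n/l^2` weights are exactly
#' `1/dx^2`, and whose boundary rows are the standard Neumann closure).
#' Damage in 1D is supported only with `k4 = 0`: the non-local transneuronal
#' term has no continuum representation.
#'
#' @param p A [kinetic_params()] object (per-species diffusivities are taken
#'   from it).
#' @param length Domain length (the grid spans `[0, length]`).
#' @param dx Grid spacing (> 0).
#' @param init Function of the grid coordinate vector `x` returning a list
#'   with numeric vectors `u, ut, v, vt` (healthy species default to the
#'   healthy state when omitted); values must be non-negative.
#' @param times Output time grid.
#' @param damage Optional [damage_params()] with `k4 = 0`.
#' @param ... Passed to [simulate_network()].
#' @return An object of class `field1d`: list with `x`, `times`, matrices
#'   `u, ut, v, vt` (time x grid) plus `q` when damage is given, and the
#'   underlying `trajectory`.
#' @export
simulate_front_1d <- function(p, length = 60, dx = 0.1, init, times,
                              damage = NULL, ...) {
  stopifnot(dx > 0, length > dx)
  if (!is.null(damage) && damage$k4 != 0) {
    stop("the non-local damage term (k4 > 0) is undefined in 1D; set k4 = 0")
  }
  nx <- as.integer(round(length / dx)) + 1L
  g <- cubic_lattice(nx, 1, 1, spacing = dx)
  x <- g$nodes$x
  ic <- init(x)
  stopifnot(is.list(ic))
  s0 <- list(u = if (is.null(ic$u)) rep(p$a0 / p$a1, nx) else ic$u,
             ut = if (is.null(ic$ut)) rep(0, nx) else ic$ut,
             v = if (is.null(ic$v)) rep(p$b0 / p$b1, nx) else ic$v,
             vt = if (is.null(ic$vt)) rep(0, nx) else ic$vt,
             q = rep(0, nx))
  for (f in c("u", "ut", "v", "vt")) {
    stopifnot(base::length(s0[[f]]) == nx)
    if (any(s0[[f]] < 0)) stop("initial condition must be non-negative (", f, ")")
  }
  class(s0) <- "state_vector"
  tr <- simulate_network(g, p, s0, times, damage = damage, ...)
  structure(list(x = x, times = tr$times, u = tr$u, ut = tr$ut,
                 v = tr$v, vt = tr$vt, q = tr$q, trajectory = tr),
            class = "field1d")
}

#' @export
print.field1d <- function(x, ...) {
  cat(sprintf("1D field: %d grid points on [0, %g], %d output times\n",
              length(x$x), max(x$x), length(x$times)))
  invisible(x)
}

#' Preset 1D front experiments
#'
#' Two bundled scenarios reproducing the published 1D experiments:
#'
#' * `"primary_collision"`: primary-tauopathy parameters (unit rates,
#'   `a1t = b1t = 3/4`, `b3 = 1/2`, toxic diffusivities 0.01); a toxic
#'   A-beta step seeded at the left end propagating right meets a toxic tau
#'   step seeded at the right end propagating left. After the collision the
#'   interior tau level rises from the `vt3` plateau to the fully toxic
#'   `vt4` plateau, filled by a backward front slaved to the A-beta speed.
#' * `"secondary_chase"`: secondary-tauopathy parameters (unit rates,
#'   `a1t = 3/4`, `b1t = 4/3`, `b3 = 3`); an A-beta step at the left end
#'   invades a domain carrying a negligible uniform toxic-tau inoculum
#'   (1e-11 beyond the seed margin). A tau front emerges behind the A-beta
#'   front, travels faster (`c_tau_24 > c_beta_12`), catches up, and locks
#'   to the A-beta front speed.
#'
#' @param name `"primary_collision"` or `"secondary_chase"`.
#' @param length,dx Domain length and grid spacing.
#' @param t_end Final time; output on `nt` equally spaced times from 0.
#' @param nt Number of output times.
#' @param seed_width Width of the seeded margin(s), in length units.
#' @param seed_amount Step amplitude of the toxic seeds.
#' @param ... Passed to [simulate_front_1d()].
#' @return A `field1d` with attribute `"params"`.
#' @export
front_scenario <- function(name = c("primary_collision", "secondary_chase"),
                           length = 60, dx = 0.1, t_end = 220, nt = 111,
                           seed_width = 5, seed_amount = 0.05, ...) {
  name <- match.arg(name)
  times <- seq(0, t_end, length.out = nt)
  if (name == "primary_collision") {
    p <- preset_params("fig22_primary")
    init <- function(x) list(
      ut = ifelse(x <= seed_width, seed_amount, 0),
      vt = ifelse(x >= max(x) - seed_width, seed_amount, 0))
  } else {
    p <- preset_params("fig23_secondary")
    init <- function(x) list(
      ut = ifelse(x <= seed_width, seed_amount, 0),
      vt = ifelse(x > seed_width, 1e-11, 0))
  }
  f <- simulate_front_1d(p, length = length, dx = dx, init = init,
                         times = times, ...)
  attr(f, "params") <- p
  f
}

#' Empirical front speed from a 1D field
#'
#' Tracks the position where the field crosses a fixed fraction of its
#' plateau value (linearly interpolated between grid points, outermost
#' crossing in the direction of propagation) and fits position versus time
#' by least squares. For pulled fronts the measured asymptotic slope is
#' insensitive to the tracking level. The fit window drops the first 20%
#' and the last 10% of the traversed span to avoid the initial transient
#' and boundary interaction.
#'
#' @param f A `field1d` from [simulate_front_1d()].
#' @param species One of `"u"`, `"ut"`, `"v"`, `"vt"`.
#' @param level Tracking level as a fraction of the plateau.
#' @param plateau Plateau value; defaults to the overall maximum of the
#'   tracked field.
#' @param direction `"right"` or `"left"` (direction of propagation).
#' @param window Fractions of the traversed span kept for the fit,
#'   default `c(0.2, 0.9)`.
#' @return List with `speed`, `stderr`, `r_squared`, `n_times`, and the
#'   tracked `positions`/`times`.
#' @export
measure_front_speed <- function(f, species = "ut", level = 0.5,
                                plateau = NULL, direction = c("right", "left"),
                                window = c(0.2, 0.9)) {
  direction <- match.arg(direction)
  field <- f[[species]]
  stopifnot(is.matrix(field))
  if (is.null(plateau)) plateau <- max(field)
  thr <- level * plateau
  x <- f$x
  pos <- vapply(seq_along(f$times), function(i) {
    y <- field[i, ]
    above <- y >= thr
    if (!any(above) || all(above)) return(NA_real_)
    if (direction == "right") {
      j <- max(which(above))           # outermost toward +x
      if (j == length(x)) return(x[j])
      # interpolate crossing between j (above) and j+1 (below)
      x[j] + (thr - y[j]) * (x[j + 1] - x[j]) / (y[j + 1] - y[j])
    } else {
      j <- min(which(above))
      if (j == 1L) return(x[1])
      x[j] + (thr - y[j]) * (x[j - 1] - x[j]) / (y[j - 1] - y[j])
    }
  }, numeric(1))
  ok <- is.finite(pos)
  if (sum(ok) < 3L) stop("no crossing: the tracked level ", signif(thr, 4),
                         " is not crossed over the output times")
  span <- range(pos[ok])
  lo <- span[1] + window[1] * diff(span)
  hi <- span[1] + window[2] * diff(span)
  keep <- ok & pos >= lo & pos <= hi
  if (sum(keep) < 3L) keep <- ok
  fit <- stats::lm(pos[keep] ~ f$times[keep])
  # summary.lm warns on an exactly linear track (manufactured waves); benign
  sm <- suppressWarnings(summary(fit))
  list(speed = abs(unname(stats::coef(fit)[2])),
       stderr = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n_times = sum(keep),
       positions = pos[keep], times = f$times[keep])
}
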