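#' Brain-wide toxic load series
#'
#' Node-averaged concentration (and damage) per output time - the
#' brain-wide burden curves used to summarize disease progression.
#'
#' @param traj A `trajectory` from [simulate_network()].
#' @return A data.frame with columns `time`, `mean_u`, `mean_ut`, `mean_v`,
#'   `mean_vt`, `mean_q`.
#' @export
toxic_load <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), length(traj$times) > 0L)
  data.frame(time = traj$times,
             mean_u = rowMeans(traj$u), mean_ut = rowMeans(traj$ut),
             mean_v = rowMeans(traj$v), mean_vt = rowMeans(traj$vt),
             mean_q = rowMeans(traj$q))
}

# analytic asymptotic toxic-tau level for the active regime: the vt
# component of the stable invaded state (state 4 when admissible, else
# state 3; zero for a stable healthy regime).
asymptotic_vt <- function(p) {
  eq <- stationary_states(p)
  if (eq$admissible[["s4"]]) {
    eq$states["s4", "vt"]
  } else if (eq$admissible[["s3"]]) {
    eq$states["s3", "vt"]
  } else {
    0
  }
}

# first time the series crosses `threshold` upward, by linear interpolation
.first_crossing <- function(times, series, threshold) {
  above <- series >= threshold
  if (above[1]) return(times[1])
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- series[i - 1]; y1 <- series[i]
  t0 + (threshold - y0) * (t1 - t0) / (y1 - y0)
}

#' Toxic-tau invasion window
#'
#' The invasion window is the timespan from the appearance of a global
#' (node-averaged) 1% toxic-tau concentration to the time the asymptotic
#' steady-state level is (nearly) achieved. "Achieved" needs a tolerance:
#' saturation is declared at `saturation_fraction` of the analytic
#' asymptotic level from the active regime's stationary state (default
#' 0.99; report sensitivity at 0.95/0.999 when it matters). Both crossing
#' times are located by linear interpolation on the output grid.
#'
#' @param traj A `trajectory`.
#' @param p The [kinetic_params()] used for the run (for the analytic
#'   asymptote).
#' @param onset Absolute onset threshold on `mean_vt` (default 0.01, the 1%
#'   concentration on the model's unit scale).
#' @param saturation_fraction Fraction of the asymptotic toxic-tau level
#'   declaring saturation.
#' @return List with `t_onset`, `t_saturation`, `duration`, `vinf` (the
#'   analytic asymptote used), `censored` (TRUE when the trajectory never
#'   reaches the saturation threshold) and `last_fraction` attained.
#' @export
invasion_window <- function(traj, p, onset = 0.01, saturation_fraction = 0.99) {
  load <- toxic_load(traj)
  vinf <- asymptotic_vt(p)
  if (vinf <= 0) stop("no toxic-tau asymptote in this regime (vinf = 0)")
  t_on <- .first_crossing(load$time, load$mean_vt, onset)
  t_sat <- .first_crossing(load$time, load$mean_vt, saturation_fraction * vinf)
  censored <- is.na(t_sat)
  if (is.na(t_on) && !censored) t_on <- t_sat
  list(t_onset = t_on, t_saturation = t_sat,
       duration = if (censored) NA_real_ else t_sat - t_on,
       vinf = vinf, censored = censored,
       last_fraction = load$mean_vt[nrow(load)] / vinf)
}

#' Saturation curve
#'
#' Node-averaged toxic-tau concentration expressed as a fraction of the
#' analytic asymptotic level. With `normalize = "max"` the curve is instead
#' normalized by its own maximum (the per-coupling normalization used for
#' onset comparisons across coupling strengths).
#'
#' @param traj A `trajectory`.
#' @param p The [kinetic_params()] of the run.
#' @param normalize `"asymptote"` (default) or `"max"`.
#' @return Data.frame with `time` and `fraction`. Fractions above 1 are
#'   reported as-is with a warning (overshoot of the analytic level beyond
#'   rounding indicates a non-converged asymptote).
#' @export
saturation_curve <- function(traj, p, normalize = c("asymptote", "max")) {
  normalize <- match.arg(normalize)
  load <- toxic_load(traj)
  denom <- if (normalize == "asymptote") asymptotic_vt(p) else max(load$mean_vt)
  if (denom <= 0) stop("saturation curve undefined: zero asymptotic toxic-tau level")
  frac <- load$mean_vt / denom
  if (any(frac > 1 + 1e-6)) {
    warning("saturation fraction exceeds 1 (max ", signif(max(frac), 4), ")")
  }
  data.frame(time = load$time, fraction = frac)
}

#' Constrained exponential least-squares fit
#'
#' Fits `y = A exp(-k x) + c` with decay rate `k > 0` constrained, via
#' Levenberg-Marquardt least squares with a log-parameterized rate (and a
#' Nelder-Mead fallback). Used for the invasion-window-versus-coupling and
#' onset/saturation-time-versus-coupling decay fits.
#'
#' @param xs,ys Numeric vectors (>= 4 points).
#' @param offset Include the additive offset `c` (default TRUE); with
#'   `offset = FALSE` the pure two-parameter decay is fitted.
#' @return List with `amplitude`, `rate`, `offset`, `residual` (residual
#'   norm), `fitted`, and `degenerate` (TRUE when ys is constant, where the
#'   rate is indeterminate).
#' @export
#' @examples
#' x <- 0:5
#' fit_exponential(x, 2 * exp(-0.7 * x) + 1)$rate  # ~0.7
fit_exponential <- function(xs, ys, offset = TRUE) {
  stopifnot(length(xs) == length(ys), length(xs) >= 4L, all(is.finite(xs)),
            all(is.finite(ys)))
  if (stats::sd(ys) == 0) {
    return(list(amplitude = 0, rate = NA_real_, offset = ys[1],
                residual = 0, fitted = ys, degenerate = TRUE))
  }
  xr <- diff(range(xs))
  k0 <- 1 / max(xr, .Machine$double.eps)
  c0 <- if (offset) min(ys) - 0.05 * abs(min(ys)) else 0
  A0 <- max(ys[which.min(xs)] - c0, .Machine$double.eps)
  model <- function(par, x) {
    A <- par[1]; k <- exp(par[2]); cc <- if (offset) par[3] else 0
    A * exp(-k * x) + cc
  }
  resid_fn <- function(par) ys - model(par, xs)
  par0 <- if (offset) c(A0, log(k0), c0) else c(A0, log(k0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  par <- if (!is.null(fit)) fit$par else NULL
  if (is.null(par) || !all(is.finite(par))) {
    opt <- stats::optim(par0, function(p) sum(resid_fn(p)^2),
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    par <- opt$par
  }
  fitted <- model(par, xs)
  list(amplitude = par[1], rate = exp(par[2]),
       offset = if (offset) par[3] else 0,
       residual = sqrt(sum((ys - fitted)^2)),
       fitted = fitted, degenerate = FALSE)
}
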