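#' Integration configuration
#'
#' Bundles the initial state, horizon, solver tolerances and the output
#' sampling grid used by [integrate_dwm()] and [integrate_dfm()].
#'
#' @param initial numeric `c(N, S)` initial state (nonnegative).
#' @param t_end time horizon, > 0.
#' @param rel_tol,abs_tol relative and absolute integration tolerances,
#'   each in `(0, 1e-3]`. Defaults `1e-8` / `1e-10`: trajectories feed peak
#'   detection, so they are resolved well beyond plotting accuracy.
#' @param sample_dt spacing of the output grid; default `t_end/5000`.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(initial, t_end, rel_tol = 1e-8, abs_tol = 1e-10,
                       sample_dt = t_end / 5000) {
  initial <- state_vec(initial[[1L]], initial[[2L]])
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a single positive number", call. = FALSE)
  for (tl in c(rel_tol = rel_tol, abs_tol = abs_tol))
    if (tl <= 0 || tl > 1e-3)
      stop("tolerances must lie in (0, 1e-3]", call. = FALSE)
  if (sample_dt <= 0 || sample_dt > t_end)
    stop("sample_dt must lie in (0, t_end]", call. = FALSE)
  structure(list(initial = initial, t_end = t_end, rel_tol = rel_tol,
                 abs_tol = abs_tol, sample_dt = sample_dt),
            class = "sim_config")
}

new_trajectory <- function(times, N, S, events, abs_tol) {
  # clip round-off excursions below zero (bounded by solver tolerance)
  worst <- min(N, S)
  if (worst < -1e3 * abs_tol)
    stop(sprintf("trajectory left the positive quadrant (min = %g)", worst),
         call. = FALSE)
  tr <- data.frame(t = times, N = pmax(N, 0), S = pmax(S, 0))
  attr(tr, "events") <- events
  class(tr) <- c("clio_trajectory", "data.frame")
  tr
}

#' Events recorded during integration
#'
#' @param tr a `clio_trajectory`.
#' @return A data frame with columns `time` and `label` (for the DFM,
#'   `"state_collapse"` at the collapse time and `"state_revival"` if the
#'   raw wealth drift later turns positive again); empty for the DWM.
#' @export
trajectory_events <- function(tr) {
  stopifnot(inherits(tr, "clio_trajectory"))
  attr(tr, "events")
}

no_events <- function() data.frame(time = numeric(0), label = character(0),
                                   stringsAsFactors = FALSE)

sample_grid <- function(cfg) {
  grid <- seq(0, cfg$t_end, by = cfg$sample_dt)
  if (grid[length(grid)] < cfg$t_end) grid <- c(grid, cfg$t_end)
  grid
}

#' Integrate the Demographic-Wealth Model
#'
#' Adaptive-step integration (lsoda, via \pkg{deSolve}) of the DWM vector
#' field on the output grid of `cfg`. The closed positive quadrant is
#' invariant for the smooth DWM field, so no event handling is needed;
#' round-off excursions below zero are clipped within solver tolerance.
#'
#' @param p a [dwm_params()] record.
#' @param cfg a [sim_config()].
#' @return A `clio_trajectory`: a data frame with columns `t`, `N`, `S` and
#'   an `events` attribute (empty for the DWM).
#' @examples
#' p <- preset("fig3")
#' tr <- integrate_dwm(p$params, sim_config(p$initial, 4000))
#' tail(tr, 1)   # damped oscillations onto the coexistence point
#' @export
integrate_dwm <- function(p, cfg) {
  stopifnot(inherits(p, "dwm_params"), inherits(cfg, "sim_config"))
  out <- deSolve::ode(
    y = cfg$initial, times = sample_grid(cfg),
    func = function(t, y, parms) list(dwm_rhs_unsafe(y, parms)),
    parms = p, method = "lsoda",
    rtol = cfg$rel_tol, atol = cfg$abs_tol, maxsteps = 100000)
  check_ode_complete(out, cfg$t_end)
  new_trajectory(out[, 1L], out[, 2L], out[, 3L], no_events(), cfg$abs_tol)
}

# rhs without domain checks, tolerant of tiny negative excursions taken by
# the solver's trial steps
dwm_rhs_unsafe <- function(y, p) {
  N <- y[[1L]]; S <- y[[2L]]
  K <- p$k0 + p$c * S
  c(p$r * N * (1 - N / K) - p$alpha * S * N / (p$d + N),
    p$g * S * N - p$beta * S)
}

dfm_rhs_unsafe <- function(y, p) {
  N <- y[[1L]]; S <- y[[2L]]
  K <- p$k0 + p$c * S / (p$s0 + S)
  surplus <- N * (1 - N / K)
  c(p$r * surplus, p$rho0 * surplus - p$beta * N)
}

# raw wealth drift on the collapsed manifold S = 0
dfm_drift0 <- function(N, p) p$rho0 * N * (1 - N / p$k0) - p$beta * N

check_ode_complete <- function(out, t_end) {
  tmax <- out[nrow(out), 1L]
  if (tmax < t_end * (1 - 1e-8) && is.null(attr(out, "troot")))
    stop(sprintf("integration failed (step-size collapse); last valid time %g",
                 tmax), call. = FALSE)
  invisible(out)
}

#' Integrate the Demographic-Fiscal Model with state-collapse events
#'
#' The DFM constrains state resources to `S >= 0`: once `S` reaches zero
#' with negative raw drift the state has collapsed and `S` is held at zero
#' for as long as the raw drift stays negative. Integration alternates
#' between two exact phases. In the free phase the raw vector field is
#' integrated with a root function on `S`, locating the first collapse time
#' `t*` to solver precision; the event `("state_collapse", t*)` is recorded.
#' In the collapsed phase `S` is pinned at zero and the population follows
#' pure logistic growth towards `k0`, with a root function on the raw wealth
#' drift so that the state is released again (`"state_revival"`) should the
#' drift turn positive. The drift-conditional clamp (rather than a permanent
#' one) is what lets a state rise from the `S = 0` initial condition in the
#' first place.
#'
#' @param p a [dfm_params()] record.
#' @param cfg a [sim_config()].
#' @return A `clio_trajectory` with events accessible via
#'   [trajectory_events()]. Wealth never drops below `-abs_tol`.
#' @examples
#' p <- dfm_params(r = 0.02, rho0 = 1, beta = 0.25, k0 = 1, c = 3, s0 = 10)
#' tr <- integrate_dfm(p, sim_config(c(0.5, 0), 600))
#' trajectory_events(tr)   # one state_collapse
#' @export
integrate_dfm <- function(p, cfg) {
  stopifnot(inherits(p, "dfm_params"), inherits(cfg, "sim_config"))
  grid <- sample_grid(cfg)
  events <- no_events()
  times <- numeric(0); Ns <- numeric(0); Ss <- numeric(0)
  y <- cfg$initial
  t_cur <- 0
  # start collapsed if already on the boundary with inward drift
  collapsed <- y[[2L]] <= 0 && dfm_drift0(y[[1L]], p) < 0
  for (phase in seq_len(200L)) {
    ptimes <- c(t_cur, grid[grid > t_cur + 1e-12 * cfg$t_end])
    if (length(ptimes) < 2L) break
    if (!collapsed) {
      out <- deSolve::ode(
        y = y, times = ptimes,
        func = function(t, yy, parms) list(dfm_rhs_unsafe(yy, parms)),
        parms = p, method = "lsodar",
        # offset the root marginally below zero so an S = 0 start with
        # positive drift does not fire immediately
        rootfunc = function(t, yy, parms) yy[[2L]] + 1e-13,
        rtol = cfg$rel_tol, atol = cfg$abs_tol, maxsteps = 100000)
    } else {
      out <- deSolve::ode(
        y = c(y[[1L]], 0), times = ptimes,
        func = function(t, yy, parms)
          list(c(parms$r * yy[[1L]] * (1 - yy[[1L]] / parms$k0), 0)),
        parms = p, method = "lsodar",
        rootfunc = function(t, yy, parms) dfm_drift0(yy[[1L]], parms),
        rtol = cfg$rel_tol, atol = cfg$abs_tol, maxsteps = 100000)
    }
    check_ode_complete(out, cfg$t_end)
    keep <- if (length(times)) out[, 1L] > times[length(times)] else
      rep(TRUE, nrow(out))
    times <- c(times, out[keep, 1L])
    Ns <- c(Ns, out[keep, 2L]); Ss <- c(Ss, out[keep, 3L])
    troot <- attr(out, "troot")
    if (is.null(troot) || out[nrow(out), 1L] >= cfg$t_end * (1 - 1e-12)) break
    t_cur <- troot[1L]
    y <- c(out[nrow(out), 2L], 0)
    if (!collapsed) {
      events <- rbind(events, data.frame(time = t_cur,
                                         label = "state_collapse",
                                         stringsAsFactors = FALSE))
      collapsed <- TRUE
    } else {
      events <- rbind(events, data.frame(time = t_cur,
                                         label = "state_revival",
                                         stringsAsFactors = FALSE))
      collapsed <- FALSE
    }
  }
  new_trajectory(times, Ns, Ss, events, cfg$abs_tol)
}

#' Attractor type, period and amplitude of a trajectory
#'
#' Decides whether a trajectory has settled on a fixed point or a limit
#' cycle, and measures the cycle. The leading `transient_fraction` of the
#' horizon is discarded (extended automatically to 70% and 85% if the first
#' window is inconclusive, since convergence slows dramatically near a Hopf
#' point). Local maxima of `N(t)` are found by three-point comparison and
#' refined by quadratic interpolation, giving period estimates beyond the
#' sampling resolution. The verdict is
#' \itemize{
#'   \item `fixed-point` if the late oscillation amplitude has decayed below
#'     `1e-6` of the mean level,
#'   \item `limit-cycle` if at least 5 post-transient peaks exist and the
#'     last successive peak heights agree within 0.5% relative,
#'   \item `undecided` otherwise (e.g. a transient not yet resolved).
#' }
#'
#' @param tr a `clio_trajectory`.
#' @param transient_fraction fraction of the horizon discarded before
#'   analysis (default 0.5).
#' @return An object of class `"cycle_summary"`: list with `attractor`,
#'   `period` (`NA` unless a limit cycle), `n_peaks`, and the extrema
#'   `N_min`, `N_max`, `S_min`, `S_max` over the final window.
#' @export
cycle_summary <- function(tr, transient_fraction = 0.5) {
  stopifnot(inherits(tr, "clio_trajectory"))
  if (nrow(tr) < 10L) stop("trajectory too short to analyse", call. = FALSE)
  fractions <- unique(pmin(c(transient_fraction, 0.7, 0.85), 0.95))
  verdict <- NULL
  for (frac in fractions) {
    verdict <- cycle_window_verdict(tr, frac)
    if (verdict$attractor != "undecided") break
  }
  verdict
}

cycle_window_verdict <- function(tr, frac) {
  t0 <- tr$t[1L] + frac * (tr$t[nrow(tr)] - tr$t[1L])
  w <- tr[tr$t >= t0, , drop = FALSE]
  out <- function(attractor, period, n_peaks, ww) {
    structure(list(attractor = attractor, period = period, n_peaks = n_peaks,
                   N_min = min(ww$N), N_max = max(ww$N),
                   S_min = min(ww$S), S_max = max(ww$S)),
              class = "cycle_summary")
  }
  # settled: late-window amplitude negligible against the mean level
  late <- w[w$t >= w$t[1L] + 0.8 * (w$t[nrow(w)] - w$t[1L]), , drop = FALSE]
  scale_N <- max(mean(late$N), 1e-12)
  if (diff(range(late$N)) < 1e-6 * scale_N &&
      diff(range(late$S)) < 1e-6 * max(mean(late$S), 1e-12))
    return(out("fixed-point", NA_real_, 0L, late))
  pk <- refined_peaks(w$t, w$N)
  if (nrow(pk) < 5L) return(out("undecided", NA_real_, nrow(pk), w))
  last <- utils::tail(pk, 5L)
  drift <- abs(diff(last$height)) / pmax(last$height[-1L], 1e-12)
  if (all(drift < 0.005)) {
    use <- utils::tail(pk, min(nrow(pk), 10L))
    period <- mean(diff(use$time))
    cyc <- w[w$t >= use$time[1L] & w$t <= use$time[nrow(use)], , drop = FALSE]
    return(out("limit-cycle", period, nrow(pk), cyc))
  }
  out("undecided", NA_real_, nrow(pk), w)
}

# interior local maxima by three-point comparison, height and location
# refined by the vertex of the parabola through the three samples
refined_peaks <- function(t, x) {
  n <- length(x)
  if (n < 3L) return(data.frame(time = numeric(0), height = numeric(0)))
  i <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  i <- i[i > 1L & i < n]
  if (!length(i)) return(data.frame(time = numeric(0), height = numeric(0)))
  tt <- t[i]; hh <- x[i]
  dl <- x[i] - x[i - 1L]; dr <- x[i] - x[i + 1L]
  hl <- t[i] - t[i - 1L]; hr <- t[i + 1L] - t[i]
  denom <- dl * hr + dr * hl
  ok <- denom > 0
  delta <- ifelse(ok, 0.5 * (dl * hr^2 - dr * hl^2) / denom, 0)
  tt <- tt + delta
  # parabola height correction at the refined abscissa
  a <- ifelse(ok, -(dl / hl + dr / hr) / (hl + hr), 0)
  b <- ifelse(ok, (dl * hr / hl - dr * hl / hr) / (hl + hr), 0)
  hh <- hh + b * delta + a * delta^2
  data.frame(time = tt, height = hh)
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat("attractor:", x$attractor)
  if (x$attractor == "limit-cycle")
    cat(sprintf(" (period %.6g, %d peaks)", x$period, x$n_peaks))
  cat(sprintf("\n  N in [%.6g, %.6g], S in [%.6g, %.6g]\n",
              x$N_min, x$N_max, x$S_min, x$S_max))
  invisible(x)
}

#' @export
print.clio_trajectory <- function(x, ...) {
  ev <- trajectory_events(x)
  cat(sprintf("trajectory: %d samples on t in [%g, %g]\n",
              nrow(x), x$t[1L], x$t[nrow(x)]))
  if (nrow(ev))
    for (i in seq_len(nrow(ev)))
      cat(sprintf("  event %s at t = %g\n", ev$label[i], ev$time[i]))
  NextMethod()
}
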