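#' One-parameter continuation of the DWM coexistence equilibrium
#'
#' Every equilibrium of the DWM is available in closed form, so
#' "continuation" is branch evaluation on a parameter grid followed by
#' sign-change detection and bisection refinement -- no predictor-corrector
#' machinery is needed. The function tracks the coexistence branch
#' `(N*(v), S*(v))` over the grid, records trace, determinant and stability
#' at every point, and detects
#' \itemize{
#'   \item transcritical (branch) points, where the signed wealth branch
#'     `S*` crosses zero (the coexistence point passes through the stateless
#'     equilibrium `(k0, 0)` and they exchange stability; equivalently
#'     `beta/g = k0`), and
#'   \item Hopf points, where the coexistence trace crosses zero with
#'     positive determinant. Each Hopf point carries its first Lyapunov
#'     coefficient (see [first_lyapunov()]).
#' }
#'
#' @param p a [dwm_params()] baseline record.
#' @param name swept parameter, one of `r, alpha, g, beta, c, k0, d`.
#' @param lo,hi sweep range, `lo < hi`.
#' @param n_grid number of grid points (default 2001, enough to bracket
#'   every bifurcation of interest at the scales the model produces).
#' @return An object of class `"bifurcation_diagram"`: list with
#'   `swept_param`, `grid`, `branch` (data frame: `param`, `N_star`,
#'   `S_star`, `trace`, `det`, `stable`; `NA` rows where the interior
#'   equilibrium is absent) and `detected` (data frame of refined points:
#'   `param_value`, `kind`, `l1`, `supercritical`).
#' @examples
#' p <- preset("fig3")$params
#' d <- sweep_equilibria(p, "g", 0.01, 2)
#' d$detected    # transcritical at 0.1, Hopf near 0.992
#' @export
sweep_equilibria <- function(p, name, lo, hi, n_grid = 2001L) {
  stopifnot(inherits(p, "dwm_params"))
  name <- match.arg(name, c("r", "alpha", "g", "beta", "c", "k0", "d"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  branch <- vapply(grid, function(v) branch_point(set_param(p, name, v)),
                   numeric(5L))
  branch <- as.data.frame(t(branch))
  names(branch) <- c("N_star", "S_star", "trace", "det", "S_signed")
  branch$stable <- as.integer(branch$trace < 0 & branch$det > 0)
  branch$stable[is.na(branch$trace)] <- NA_integer_
  detected <- detect_points(p, name, grid, branch)
  structure(list(swept_param = name, grid = grid,
                 branch = cbind(param = grid,
                                branch[c("N_star", "S_star", "trace",
                                         "det", "stable")]),
                 detected = detected),
            class = "bifurcation_diagram")
}

# (N*, S*, trace, det, signed S branch) at one parameter point; NAs where
# the interior equilibrium is absent
branch_point <- function(p) {
  s_signed <- coexistence_root(p)
  eq <- coexistence(p)
  if (is.null(eq))
    return(c(NA_real_, NA_real_, NA_real_, NA_real_, s_signed))
  c(eq$N, eq$S, eq$trace, eq$det, s_signed)
}

detect_points <- function(p, name, grid, branch) {
  det0 <- data.frame(param_value = numeric(0), kind = character(0),
                     l1 = numeric(0), supercritical = logical(0),
                     stringsAsFactors = FALSE)
  out <- det0
  s <- branch$S_signed
  for (i in seq_len(length(grid) - 1L)) {
    if (is.finite(s[i]) && is.finite(s[i + 1L]) &&
        sign(s[i]) != sign(s[i + 1L]) && s[i] != 0) {
      v <- find_transcritical(p, name, c(grid[i], grid[i + 1L]))
      out <- rbind(out, data.frame(param_value = v, kind = "transcritical",
                                   l1 = NA_real_, supercritical = NA,
                                   stringsAsFactors = FALSE))
    }
    tr <- branch$trace
    if (!anyNA(tr[i:(i + 1L)]) &&
        sign(tr[i]) != sign(tr[i + 1L]) && tr[i] != 0 &&
        branch$det[i] > 0 && branch$det[i + 1L] > 0) {
      bp <- find_hopf(p, name, c(grid[i], grid[i + 1L]))
      out <- rbind(out, data.frame(param_value = bp$param_value,
                                   kind = "hopf", l1 = bp$l1,
                                   supercritical = bp$supercritical,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$param_value), , drop = FALSE]
}

#' Locate a transcritical (branch) point
#'
#' The coexistence branch crosses the stateless equilibrium where
#' `S* = 0`, i.e. `N* = beta/g = k0`; across this point the two equilibria
#' exchange stability. For the three parameters entering that relation the
#' root is returned in closed form (`g = beta/k0`, `beta = g*k0`,
#' `k0 = beta/g`); for any other parameter the signed wealth branch is
#' bisected over the bracket.
#'
#' @param p a [dwm_params()] record.
#' @param name swept parameter name.
#' @param bracket optional `c(lo, hi)` interval. Required for parameters
#'   without a closed form; when supplied with a closed form it is checked
#'   for containment.
#' @return The parameter value at the branch point.
#' @export
find_transcritical <- function(p, name, bracket = NULL) {
  stopifnot(inherits(p, "dwm_params"))
  closed <- switch(name,
                   g = p$beta / p$k0,
                   beta = p$g * p$k0,
                   k0 = p$beta / p$g,
                   NULL)
  if (!is.null(closed)) {
    if (!is.null(bracket) && (closed < min(bracket) || closed > max(bracket)))
      stop(sprintf("branch point %g lies outside the bracket", closed),
           call. = FALSE)
    return(closed)
  }
  if (is.null(bracket))
    stop("a bracket is required for parameters without a closed form",
         call. = FALSE)
  f <- function(v) coexistence_root(set_param(p, name, v))
  if (!is.finite(f(bracket[1L])) || !is.finite(f(bracket[2L])) ||
      sign(f(bracket[1L])) == sign(f(bracket[2L])))
    stop("signed wealth branch does not change sign across the bracket",
         call. = FALSE)
  stats::uniroot(f, bracket, tol = 1e-12)$root
}

#' Locate a Hopf bifurcation of the coexistence equilibrium
#'
#' Bisects the coexistence Jacobian trace (the `mu` functional of
#' [mu_value()]) to its zero over the bracket and certifies the candidate:
#' the determinant must be positive there, so that the eigenvalues are a
#' purely imaginary pair. The first Lyapunov coefficient is attached;
#' a negative value means the Hopf is supercritical (a stable small cycle
#' emerges on the unstable side).
#'
#' @param p a [dwm_params()] record.
#' @param name swept parameter name.
#' @param bracket `c(lo, hi)`; the trace must change sign across it and the
#'   coexistence point must exist at both ends.
#' @return An object of class `"bif_point"`: list with `param_value`,
#'   `kind = "hopf"`, `l1`, `supercritical`, `omega` (imaginary part of the
#'   eigenvalue pair) and the coexistence `equilibrium` at the point.
#' @examples
#' p <- preset("fig3")$params
#' find_hopf(p, "g", c(0.5, 1.5))$param_value   # 0.992 to 3 decimals
#' @export
find_hopf <- function(p, name, bracket) {
  stopifnot(inherits(p, "dwm_params"))
  f <- function(v) {
    q <- set_param(p, name, v)
    eq <- coexistence(q)
    if (is.null(eq)) return(NA_real_)
    eq$trace
  }
  flo <- f(bracket[1L]); fhi <- f(bracket[2L])
  if (!is.finite(flo) || !is.finite(fhi))
    stop("coexistence equilibrium must exist at both bracket ends",
         call. = FALSE)
  if (sign(flo) == sign(fhi))
    stop("trace does not change sign across the bracket", call. = FALSE)
  v <- stats::uniroot(f, bracket, tol = 1e-12)$root
  q <- set_param(p, name, v)
  eq <- coexistence(q)
  if (is.null(eq) || eq$det <= 0)
    stop("candidate root rejected: determinant not positive (not a Hopf)",
         call. = FALSE)
  l1 <- first_lyapunov(q, eq)
  structure(list(param_value = v, kind = "hopf", l1 = l1,
                 supercritical = l1 < 0, omega = sqrt(eq$det),
                 equilibrium = eq),
            class = "bif_point")
}

#' @export
print.bif_point <- function(x, ...) {
  cat(sprintf("%s point at parameter value %.10g\n", x$kind, x$param_value))
  if (x$kind == "hopf")
    cat(sprintf("  l1 = %.6g (%s), omega = %.6g\n", x$l1,
                if (x$supercritical) "supercritical" else "subcritical",
                x$omega))
  invisible(x)
}

#' First Lyapunov coefficient at a Hopf point of the DWM
#'
#' Computes the planar first Lyapunov coefficient by normal-form reduction:
#' the system is shifted to the coexistence equilibrium, transformed by the
#' eigenbasis `T = [Re q, -Im q]` of the eigenvector `q` for the eigenvalue
#' `i*omega` (bringing the linear part to rotation form `u' = -omega v + f`,
#' `v' = omega u + g`), and the classical coefficient
#' \deqn{l_1 = \tfrac{1}{16}(f_{uuu} + f_{uvv} + g_{uuv} + g_{vvv}) +
#'   \tfrac{1}{16\omega}\big(f_{uv}(f_{uu}+f_{vv}) - g_{uv}(g_{uu}+g_{vv})
#'   - f_{uu}g_{uu} + f_{vv}g_{vv}\big)}
#' is evaluated from the analytic second- and third-order partial
#' derivatives of the vector field (no finite differencing). Only the sign
#' is contract-bearing -- normalisation conventions for the magnitude differ
#' between textbooks -- and a negative sign certifies a supercritical Hopf.
#'
#' @param p a [dwm_params()] record at (numerically at) a Hopf point.
#' @param eq the coexistence equilibrium of `p`; computed if omitted.
#' @param trace_tol largest |trace| accepted as "at the Hopf point"
#'   (default `1e-6`).
#' @return The scalar coefficient `l1`.
#' @export
first_lyapunov <- function(p, eq = NULL, trace_tol = 1e-6) {
  stopifnot(inherits(p, "dwm_params"))
  if (is.null(eq)) eq <- coexistence(p)
  if (is.null(eq))
    stop("no coexistence equilibrium", call. = FALSE)
  if (eq$det <= 0 || abs(eq$trace) > trace_tol)
    stop("not a Hopf point: need det > 0 and trace ~ 0", call. = FALSE)
  A <- eq$jacobian
  w <- sqrt(eq$det)
  # eigenvector for i*w: q = (a12, i*w - a11); T = [Re q, -Im q]
  if (abs(A[1L, 2L]) > 1e-14 * max(abs(A))) {
    T <- matrix(c(A[1L, 2L], 0, -A[1L, 1L], -w), 2L, 2L, byrow = TRUE)
  } else {
    # fall back to q = (i*w - a22, a21)
    T <- matrix(c(-A[2L, 2L], -w, A[2L, 1L], 0), 2L, 2L, byrow = TRUE)
  }
  Tinv <- solve(T)
  dv <- dwm_higher_derivs(eq$N, eq$S, p)
  # transform the derivative tensors to normal coordinates u = Tinv (x - x*)
  d2 <- function(m, a, b) {
    Ta <- T[, a]; Tb <- T[, b]
    Tinv[m, 1L] * drop(Ta %*% dv$H1 %*% Tb) +
      Tinv[m, 2L] * drop(Ta %*% dv$H2 %*% Tb)
  }
  d3 <- function(m, a, b, c) {
    acc <- 0
    for (j in 1:2) for (k in 1:2) for (l in 1:2)
      acc <- acc + dv$C1[j, k, l] * T[j, a] * T[k, b] * T[l, c]
    Tinv[m, 1L] * acc  # third derivatives of the wealth equation vanish
  }
  fuu <- d2(1L, 1L, 1L); fvv <- d2(1L, 2L, 2L); fuv <- d2(1L, 1L, 2L)
  guu <- d2(2L, 1L, 1L); gvv <- d2(2L, 2L, 2L); guv <- d2(2L, 1L, 2L)
  (d3(1L, 1L, 1L, 1L) + d3(1L, 1L, 2L, 2L) +
     d3(2L, 1L, 1L, 2L) + d3(2L, 2L, 2L, 2L)) / 16 +
    (fuv * (fuu + fvv) - guv * (guu + gvv) - fuu * guu + fvv * gvv) / (16 * w)
}

# analytic second- and third-order partials of the DWM field at (N, S);
# the wealth equation g*S*N - beta*S is bilinear so only its mixed second
# derivative survives
dwm_higher_derivs <- function(N, S, p) {
  K <- p$k0 + p$c * S
  D <- p$d + N
  H1 <- matrix(c(-2 * p$r / K + 2 * p$alpha * S * p$d / D^3,
                 2 * p$r * p$c * N / K^2 - p$alpha * p$d / D^2,
                 2 * p$r * p$c * N / K^2 - p$alpha * p$d / D^2,
                 -2 * p$r * p$c^2 * N^2 / K^3), 2L, 2L)
  H2 <- matrix(c(0, p$g, p$g, 0), 2L, 2L)
  C1 <- array(0, c(2L, 2L, 2L))
  fNNN <- -6 * p$alpha * S * p$d / D^4
  fNNS <- 2 * p$r * p$c / K^2 + 2 * p$alpha * p$d / D^3
  fNSS <- -4 * p$r * p$c^2 * N / K^3
  fSSS <- 6 * p$r * p$c^3 * N^2 / K^4
  C1[1, 1, 1] <- fNNN
  C1[1, 1, 2] <- C1[1, 2, 1] <- C1[2, 1, 1] <- fNNS
  C1[1, 2, 2] <- C1[2, 1, 2] <- C1[2, 2, 1] <- fNSS
  C1[2, 2, 2] <- fSSS
  list(H1 = H1, H2 = H2, C1 = C1)
}

#' Simulated limit-cycle branch beyond a Hopf point
#'
#' For each grid value of the swept parameter past the Hopf point, the model
#' is integrated well past its transient and the emerging cycle is measured
#' with [cycle_summary()]. Along a supercritical branch the amplitude is
#' zero at the Hopf end and grows like the square root of the distance to
#' it. The integration horizon is chosen adaptively as `14/mu` (capped):
#' the relaxation rate onto the cycle is proportional to the trace `mu`,
#' which vanishes at the Hopf point, so nearby cycles need far longer to
#' establish.
#'
#' @param p a [dwm_params()] baseline record.
#' @param name swept parameter name.
#' @param from_hopf parameter value of the Hopf point.
#' @param to far end of the branch.
#' @param n number of grid points beyond the Hopf point (default 10).
#' @param t_end optional fixed horizon overriding the adaptive choice.
#' @param max_t_end cap on the adaptive horizon (default `2e6`).
#' @return A data frame (class `"cycle_branch"`): `param`, `attractor`,
#'   `period`, `N_min`, `N_max`, `S_min`, `S_max`, `amplitude`
#'   (peak-to-trough range of `N`).
#' @export
cycle_branch <- function(p, name, from_hopf, to, n = 10L, t_end = NULL,
                         max_t_end = 2e6) {
  stopifnot(inherits(p, "dwm_params"))
  grid <- seq(from_hopf, to, length.out = n + 1L)[-1L]
  rows <- lapply(grid, function(v) {
    q <- set_param(p, name, v)
    eq <- coexistence(q)
    if (is.null(eq))
      return(data.frame(param = v, attractor = "undecided",
                        period = NA_real_, N_min = NA_real_, N_max = NA_real_,
                        S_min = NA_real_, S_max = NA_real_,
                        amplitude = NA_real_, stringsAsFactors = FALSE))
    te <- if (!is.null(t_end)) t_end else
      min(max_t_end, max(6e4, 14 / max(eq$trace, 1e-12)))
    # dense sampling: relaxation-type cycles have narrow peaks, and the
    # 0.5% peak-height agreement test needs them resolved
    cfg <- sim_config(c(eq$N * 1.02, eq$S), te, sample_dt = te / 20000)
    cs <- cycle_summary(integrate_dwm(q, cfg))
    data.frame(param = v, attractor = cs$attractor, period = cs$period,
               N_min = cs$N_min, N_max = cs$N_max,
               S_min = cs$S_min, S_max = cs$S_max,
               amplitude = cs$N_max - cs$N_min, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cycle_branch", "data.frame")
  out
}

#' Paradox-of-enrichment scan over the stateless carrying capacity
#'
#' Sweeps `k0` and summarises the regime at each value, reproducing the
#' enrichment story of consumer-resource theory in the state-population
#' setting: below the transcritical value `beta/g` the state cannot survive
#' and `(k0, 0)` is the attractor ("stateless"); between the transcritical
#' and the Hopf value the coexistence point is stable; beyond the Hopf
#' value the equilibrium sheds a limit cycle whose amplitude grows with
#' `k0` while its wealth and population minima sink towards zero --
#' enriching the capacity destabilises the society.
#'
#' @param p a [dwm_params()] baseline record.
#' @param k0_lo,k0_hi scan range.
#' @param n number of scan points (default 21).
#' @param ... passed to [cycle_branch()]-style simulation (`t_end`,
#'   `max_t_end`).
#' @return A data frame: `k0`, `regime` (`stateless`,
#'   `stable-coexistence`, `limit-cycle` or `undecided`), `N_min`, `S_min`,
#'   `amplitude`, `period`.
#' @export
enrichment_scan <- function(p, k0_lo, k0_hi, n = 21L, ...) {
  stopifnot(inherits(p, "dwm_params"))
  grid <- seq(k0_lo, k0_hi, length.out = n)
  rows <- lapply(grid, function(k0) {
    q <- set_param(p, "k0", k0)
    eq <- coexistence(q)
    if (is.null(eq))
      return(data.frame(k0 = k0, regime = "stateless", N_min = k0,
                        S_min = 0, amplitude = 0, period = NA_real_,
                        stringsAsFactors = FALSE))
    if (eq$trace < 0 && eq$det > 0)
      return(data.frame(k0 = k0, regime = "stable-coexistence", N_min = eq$N,
                        S_min = eq$S, amplitude = 0, period = NA_real_,
                        stringsAsFactors = FALSE))
    cb <- cycle_branch(q, "k0", k0 - 1e-12, k0, n = 1L, ...)
    data.frame(k0 = k0,
               regime = if (cb$attractor == "limit-cycle") "limit-cycle"
                        else "undecided",
               N_min = cb$N_min, S_min = cb$S_min,
               amplitude = cb$amplitude, period = cb$period,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation diagram: parameter '%s' over [%g, %g] (%d points)\n",
              x$swept_param, min(x$grid), max(x$grid), length(x$grid)))
  if (nrow(x$detected)) {
    cat("detected points:\n")
    for (i in seq_len(nrow(x$detected))) {
      d <- x$detected[i, ]
      if (d$kind == "hopf")
        cat(sprintf("  hopf at %s = %.10g (l1 = %.4g, %s)\n", x$swept_param,
                    d$param_value, d$l1,
                    if (isTRUE(d$supercritical)) "supercritical"
                    else "subcritical"))
      else
        cat(sprintf("  transcritical at %s = %.10g\n", x$swept_param,
                    d$param_value))
    }
  } else cat("no bifurcation points detected in range\n")
  invisible(x)
}
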