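#' @title Equilibria of the Demographic-Wealth Model
#' @description
#' The DWM always has the origin `(0, 0)` and the stateless equilibrium
#' `(k0, 0)`. When the state can sustain itself (`beta/g < k0`) an interior
#' coexistence point appears at `N* = beta/g`, with `S*` on the population
#' nullcline. These functions locate the equilibria in closed form, attach
#' the exact Jacobian, its eigenvalues, and a standard planar classification.
#' @name dwm_equilibria
NULL

new_equilibrium <- function(kind, N, S, p, tol = 1e-9) {
  J <- dwm_jacobian(c(N, S), p)
  tr <- J[1L, 1L] + J[2L, 2L]
  dt <- J[1L, 1L] * J[2L, 2L] - J[1L, 2L] * J[2L, 1L]
  ev <- eigen(J, only.values = TRUE)$values
  if (is.double(ev)) ev <- as.complex(ev)
  structure(
    list(kind = kind, N = N, S = S, jacobian = J,
         trace = tr, det = dt, eigenvalues = ev,
         classification = classify_equilibrium(tr, dt, tol = tol)),
    class = "clio_equilibrium")
}

#' Classify a planar equilibrium from trace and determinant
#'
#' Standard linearised classification of a fixed point of a planar system:
#' negative determinant gives a saddle; positive determinant gives a node or
#' focus depending on the sign of the discriminant `trace^2 - 4 det`, stable
#' when the trace is negative. Borderline cases (trace or determinant
#' numerically zero) are flagged `nonhyperbolic`; the trace threshold is
#' scale-aware, `|trace| < tol * max(1, |det|)`.
#'
#' @param trace Jacobian trace at the equilibrium.
#' @param det Jacobian determinant at the equilibrium.
#' @param tol nonhyperbolicity tolerance (default `1e-9`).
#' @return One of `"saddle"`, `"stable-node"`, `"unstable-node"`,
#'   `"stable-focus"`, `"unstable-focus"`, `"nonhyperbolic"`.
#' @export
classify_equilibrium <- function(trace, det, tol = 1e-9) {
  if (abs(det) < tol^2) return("nonhyperbolic")
  if (det < 0) return("saddle")
  if (abs(trace) < tol * max(1, abs(det))) return("nonhyperbolic")
  disc <- trace^2 - 4 * det
  if (disc >= 0) {
    if (trace < 0) "stable-node" else "unstable-node"
  } else {
    if (trace < 0) "stable-focus" else "unstable-focus"
  }
}

#' Boundary equilibria of the DWM
#'
#' Returns the two equilibria that exist for every parameter set: the origin
#' `(0, 0)`, which is always a saddle (its Jacobian is diagonal with entries
#' `r` and `-beta`, so the determinant `-r*beta` is negative), and the
#' stateless population `(k0, 0)`, whose Jacobian is triangular with
#' eigenvalues `-r` and `g*k0 - beta`. The stateless state is therefore a
#' sink exactly when `beta/g > k0` (the state spends faster than it can grow
#' and cannot establish itself) and a saddle-type unstable equilibrium when
#' `beta/g < k0`.
#'
#' @param p a [dwm_params()] record.
#' @return A list of two `clio_equilibrium` objects, kinds `"origin"` and
#'   `"stateless"`.
#' @seealso [coexistence()], [classify_equilibrium()]
#' @export
boundary_equilibria <- function(p) {
  stopifnot(inherits(p, "dwm_params"))
  list(new_equilibrium("origin", 0, 0, p),
       new_equilibrium("stateless", p$k0, 0, p))
}

# Signed continuation of the coexistence wealth branch: the root of the
# cleared nullcline quadratic
#   c*alpha*S^2 + (alpha*k0 - r*c*(d+N*))*S - r*(d+N*)*(k0-N*) = 0
# that passes through S = 0 at the transcritical point N* = k0. For c = 0
# the relation is linear. May be negative (branch continued outside the
# quadrant) or NA (no real root).
coexistence_root <- function(p) {
  N <- p$beta / p$g
  if (p$c == 0) {
    return(p$r * (p$d + N) * (p$k0 - N) / (p$alpha * p$k0))
  }
  A <- p$c * p$alpha
  B <- p$alpha * p$k0 - p$r * p$c * (p$d + N)
  C <- -p$r * (p$d + N) * (p$k0 - N)
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NA_real_)
  roots <- sort(c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A)))
  pos <- roots[roots > 0]
  if (length(pos) == 2L) {
    # Clearing denominators can in principle introduce a spurious root; keep
    # the one(s) satisfying the original nullcline relation, preferring the
    # smaller wealth value.
    res <- vapply(pos, function(S) {
      abs(p$alpha * S / (p$d + N) - p$r * (1 - N / (p$k0 + p$c * S)))
    }, numeric(1))
    ok <- pos[res < 1e-8 * max(1, p$r)]
    if (length(ok) == 2L)
      warning("two admissible coexistence roots; taking the smaller one")
    return(if (length(ok)) ok[1L] else pos[1L])
  }
  if (length(pos) == 1L) return(pos)
  # no positive root: return the larger (least negative) root so that sweeps
  # see a continuous signed branch crossing zero at the transcritical point
  roots[2L]
}

#' Coexistence equilibrium of the DWM
#'
#' Locates the interior equilibrium `(N*, S*)` in closed form. The wealth
#' nullcline fixes `N* = beta/g`; `S*` is the unique positive root of the
#' quadratic obtained by clearing denominators of the population nullcline
#' relation `alpha*S/(d + N*) = r(1 - N*/(k0 + c*S))` (linear when `c = 0`,
#' giving `S* = r(d + N*)(k0 - N*)/(alpha*k0)`). When no positive root
#' exists -- the state cannot coexist with the population, `N* >= k0 + c*S*`
#' -- the function returns `NULL`: absence is a value, not an error.
#'
#' @param p a [dwm_params()] record.
#' @return A `clio_equilibrium` of kind `"coexistence"`, or `NULL` when the
#'   interior equilibrium does not exist in the positive quadrant.
#' @examples
#' p <- dwm_params(r = 0.02, alpha = 0.05, g = 0.15, beta = 0.1,
#'                 c = 0.5, k0 = 1, d = 1)
#' eq <- coexistence(p)
#' c(eq$N, eq$S)   # (2/3, 0.27614)
#' @export
coexistence <- function(p) {
  stopifnot(inherits(p, "dwm_params"))
  S <- coexistence_root(p)
  if (!is.finite(S) || S <= 0) return(NULL)
  N <- p$beta / p$g
  if (N >= p$k0 + p$c * S) return(NULL)
  new_equilibrium("coexistence", N, S, p)
}

#' Stability functional of the coexistence point
#'
#' Evaluates the criterion that governs the stability of the interior
#' equilibrium: with the factor functions of [growth_g()] and
#' [saturation_p()],
#' \deqn{\mu(N^*, S^*) = p(N) \frac{\partial}{\partial N}
#'   \left( \frac{N\, g(N, S^*)}{p(N)} \right)\Big|_{N = N^*},}
#' the partial taken in `N` with `S*` held fixed as a parameter of the
#' expression. Because `N/p(N) = (d + N)/alpha`, this reduces to the closed
#' form
#' \deqn{\mu = \frac{r N^*}{d + N^*}
#'   \left( 1 - \frac{2 N^* + d}{k_0 + c S^*} \right),}
#' which equals the Jacobian trace at the coexistence point exactly (the
#' lower-right Jacobian entry vanishes there). Negative values mean the
#' coexistence point is stable; a zero crossing with positive determinant is
#' a Hopf bifurcation.
#'
#' @param p a [dwm_params()] record whose coexistence point exists.
#' @return The scalar `mu` value (equal to the coexistence Jacobian trace).
#' @seealso [coexistence()], [find_hopf()], [hopf_critical_c0()]
#' @export
mu_value <- function(p) {
  stopifnot(inherits(p, "dwm_params"))
  eq <- coexistence(p)
  if (is.null(eq))
    stop("coexistence equilibrium does not exist for these parameters",
         call. = FALSE)
  mu_at(eq$N, eq$S, p)
}

mu_at <- function(N, S, p) {
  p$r * N / (p$d + N) * (1 - (2 * N + p$d) / (p$k0 + p$c * S))
}

#' Closed-form Hopf bifurcation values for the capacity-decoupled DWM
#'
#' When `c = 0` the state's wealth no longer influences the carrying
#' capacity and the Hopf condition `mu = 0` becomes explicit: a Hopf
#' bifurcation occurs at
#' \deqn{k_0 = 2\beta/g + d, \quad d = k_0 - 2\beta/g, \quad
#'       \beta = (k_0 - d)\,g/2, \quad g = 2\beta/(k_0 - d),}
#' four algebraic rearrangements of the single relation `k0 = 2N* + d`.
#' Existence restrictions: for the parameter `d` a Hopf point requires
#' `k0 > 2*beta/g` (otherwise the critical `d` would not be positive), and
#' for `g` and `beta` it requires `d < k0`. When the requested parameter
#' admits no Hopf bifurcation the function returns `NA` with an explanatory
#' `"reason"` attribute rather than an error.
#'
#' @param p a [dwm_params()] record with `c = 0` (anything else is an error).
#' @param which which parameter to solve for: `"k0"`, `"d"`, `"beta"` or
#'   `"g"`.
#' @return The critical parameter value, or `NA_real_` (with attribute
#'   `reason`) when no Hopf bifurcation exists for that parameter.
#' @examples
#' p <- dwm_params(r = 0.02, alpha = 0.05, g = 0.15, beta = 0.1,
#'                 c = 0, k0 = 1, d = 1)
#' hopf_critical_c0(p, "k0")   # 2*0.1/0.15 + 1 = 7/3
#' @export
hopf_critical_c0 <- function(p, which = c("k0", "d", "beta", "g")) {
  stopifnot(inherits(p, "dwm_params"))
  which <- match.arg(which)
  if (p$c != 0)
    stop("closed-form Hopf values require c = 0", call. = FALSE)
  no_hopf <- function(reason) structure(NA_real_, reason = reason)
  switch(which,
    k0 = 2 * p$beta / p$g + p$d,
    d = {
      v <- p$k0 - 2 * p$beta / p$g
      if (v <= 0)
        no_hopf("no Hopf in d: requires k0 > 2*beta/g") else v
    },
    beta = {
      if (p$d >= p$k0)
        no_hopf("no Hopf in beta: requires d < k0")
      else (p$k0 - p$d) * p$g / 2
    },
    g = {
      if (p$d >= p$k0)
        no_hopf("no Hopf in g: requires d < k0")
      else 2 * p$beta / (p$k0 - p$d)
    })
}

#' All equilibria of a DWM parameter set
#'
#' @param p a [dwm_params()] record.
#' @return A list of two or three `clio_equilibrium` objects (origin,
#'   stateless, and the coexistence point when it exists).
#' @export
dwm_equilibria <- function(p) {
  eqs <- boundary_equilibria(p)
  co <- coexistence(p)
  if (!is.null(co)) eqs <- c(eqs, list(co))
  eqs
}

#' Tabulate equilibria for CSV export
#'
#' @param eqs a `clio_equilibrium` or list of them.
#' @return A data frame with one row per equilibrium: kind, coordinates,
#'   trace, determinant, eigenvalue components and classification.
#' @export
equilibria_table <- function(eqs) {
  if (inherits(eqs, "clio_equilibrium")) eqs <- list(eqs)
  do.call(rbind, lapply(eqs, function(e) {
    data.frame(kind = e$kind, N = e$N, S = e$S,
               trace = e$trace, det = e$det,
               eig_re1 = Re(e$eigenvalues[1L]), eig_im1 = Im(e$eigenvalues[1L]),
               eig_re2 = Re(e$eigenvalues[2L]), eig_im2 = Im(e$eigenvalues[2L]),
               classification = e$classification,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.clio_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (N = %.6g, S = %.6g): %s\n",
              x$kind, x$N, x$S, x$classification))
  cat(sprintf("  trace = %.6g, det = %.6g, eigenvalues = %s\n",
              x$trace, x$det,
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  invisible(x)
}
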