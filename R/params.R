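#' Parameter record for the Demographic-Wealth Model
#'
#' Constructs and validates the parameter set of the Demographic-Wealth Model
#' (DWM), a planar ODE for population density `N` and accumulated state
#' wealth `S`:
#' \deqn{\dot N = r N (1 - N/(k_0 + cS)) - \alpha S N / (d + N), \quad
#'       \dot S = g S N - \beta S.}
#'
#' The carrying capacity of the population is `k0 + c*S`: a wealthy state
#' provides land and infrastructure, raising the capacity linearly in its
#' wealth. The state extracts from the population through a Holling type-II
#' response `alpha*S*N/(d + N)`, and its wealth grows through taxation and
#' reinvestment (`g*S*N`) while upkeep consumes a fixed fraction (`beta*S`).
#'
#' @param r intrinsic population growth rate (per unit time), > 0.
#' @param alpha strength of the negative state-to-population feedback, > 0.
#' @param g effective state growth coefficient, the product of the tax rate
#'   and the reinvested surplus fraction, > 0. Only the product enters the
#'   model, so the two factors are never stored separately.
#' @param beta fraction of state wealth spent on upkeep per unit time, > 0.
#' @param c sensitivity of the carrying capacity to state wealth, >= 0.
#'   `c = 0` is the analysed special case in which wealth no longer
#'   influences the capacity (for example an island with no room left).
#' @param k0 carrying capacity of the stateless population, > 0.
#' @param d half-saturation constant of the Holling type-II response, > 0.
#'
#' @return An object of class `c("dwm_params", "clio_params")`: a validated
#'   named list of the seven parameters.
#' @seealso [dfm_params()], [dwm_rhs()], [coexistence()], [preset()]
#' @examples
#' p <- dwm_params(r = 0.02, alpha = 0.05, g = 0.15, beta = 0.1,
#'                 c = 0.5, k0 = 1, d = 1)
#' coexistence(p)
#' @export
dwm_params <- function(r, alpha, g, beta, c, k0, d) {
  p <- list(r = r, alpha = alpha, g = g, beta = beta, c = c, k0 = k0, d = d)
  check_scalar_num(p)
  check_positive(p[c("r", "alpha", "g", "beta", "k0", "d")])
  if (p$c < 0) stop("'c' must be nonnegative", call. = FALSE)
  structure(p, class = c("dwm_params", "clio_params"))
}

#' Parameter record for the Demographic-Fiscal Model
#'
#' Constructs and validates the parameter set of Turchin's Demographic-Fiscal
#' Model (DFM):
#' \deqn{\dot N = r N (1 - N/k(S)), \quad
#'       \dot S = \rho_0 N (1 - N/k(S)) - \beta N,}
#' with saturating capacity `k(S) = k0 + c*S/(s0 + S)`. State resources `S`
#' are constrained nonnegative: once `S` hits zero with negative drift the
#' state has collapsed and `S` is held at zero (see [integrate_dfm()]).
#'
#' @param r intrinsic population growth rate, > 0.
#' @param rho0 per-capita taxation (surplus) coefficient, > 0.
#' @param beta per-capita state expenditure rate, >= 0. Zero is the extreme
#'   case of a state with no expenditures, which never collapses.
#' @param k0 carrying capacity of the stateless population, > 0.
#' @param c maximum possible capacity gain, `k_max - k0`, >= 0.
#' @param s0 wealth scale at which half the capacity gain is realised, > 0.
#'
#' @return An object of class `c("dfm_params", "clio_params")`.
#' @seealso [dwm_params()], [dfm_rhs()], [integrate_dfm()]
#' @examples
#' dfm_params(r = 0.02, rho0 = 1, beta = 0.25, k0 = 1, c = 3, s0 = 10)
#' @export
dfm_params <- function(r, rho0, beta, k0, c, s0) {
  p <- list(r = r, rho0 = rho0, beta = beta, k0 = k0, c = c, s0 = s0)
  check_scalar_num(p)
  check_positive(p[c("r", "rho0", "k0", "s0")])
  if (p$beta < 0) stop("'beta' must be nonnegative", call. = FALSE)
  if (p$c < 0) stop("'c' must be nonnegative", call. = FALSE)
  structure(p, class = c("dfm_params", "clio_params"))
}

check_scalar_num <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  invisible(p)
}

check_positive <- function(p) {
  for (nm in names(p)) {
    if (p[[nm]] <= 0)
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
  }
  invisible(p)
}

#' Replace one parameter, revalidating the record
#'
#' Convenience used heavily by parameter sweeps: returns a copy of `p` with
#' field `name` set to `value`, passed back through the constructor so that
#' all invariants are re-checked.
#'
#' @param p a `dwm_params` or `dfm_params` record.
#' @param name parameter name to replace.
#' @param value new value.
#' @return A record of the same class as `p`.
#' @export
set_param <- function(p, name, value) {
  stopifnot(inherits(p, "clio_params"))
  if (!name %in% names(p))
    stop(sprintf("unknown parameter '%s'; valid: %s", name,
                 paste(names(p), collapse = ", ")), call. = FALSE)
  q <- unclass(p)
  q[[name]] <- value
  do.call(if (inherits(p, "dwm_params")) dwm_params else dfm_params, q)
}

#' @export
print.clio_params <- function(x, ...) {
  model <- if (inherits(x, "dwm_params")) "Demographic-Wealth Model (DWM)"
           else "Demographic-Fiscal Model (DFM)"
  cat(model, "parameters\n")
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' A point of the (N, S) phase plane
#'
#' Validates one state of either model: population density `N` and state
#' wealth `S`, both nonnegative (the closed positive quadrant is invariant
#' for both models: the axes are themselves orbits).
#'
#' @param N population density, >= 0 (dimensionless, grain-capacity units).
#' @param S accumulated state wealth, >= 0 (dimensionless).
#' @return A named numeric vector `c(N =, S =)`.
#' @export
state_vec <- function(N, S) {
  if (!is.numeric(N) || !is.numeric(S) || length(N) != 1L || length(S) != 1L ||
      !is.finite(N) || !is.finite(S))
    stop("N and S must be single finite numbers", call. = FALSE)
  if (N < 0 || S < 0)
    stop("state must lie in the closed positive quadrant (N >= 0, S >= 0)",
         call. = FALSE)
  c(N = N, S = S)
}
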