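#' Wealth-dependent carrying capacity of the DWM
#'
#' In the Demographic-Wealth Model the carrying capacity grows linearly with
#' state wealth: `k(S) = k0 + c*S`. More wealth means more land and
#' infrastructure, hence more room for the population.
#'
#' @param S state wealth, >= 0 (vectorised).
#' @param p a [dwm_params()] record.
#' @return `k0 + c*S`, strictly increasing in `S` whenever `c > 0`.
#' @export
dwm_capacity <- function(S, p) {
  stopifnot(inherits(p, "dwm_params"))
  if (any(S < 0)) stop("S must be nonnegative", call. = FALSE)
  p$k0 + p$c * S
}

#' Saturating carrying capacity of the DFM
#'
#' `k(S) = k0 + c*S/(s0 + S)`: capacity gains saturate because at some point
#' all available land is in use and maximum productivity is reached, so the
#' capacity is bounded above by `k_max = k0 + c`.
#'
#' @param S state resources, >= 0 (vectorised).
#' @param p a [dfm_params()] record.
#' @return `k0 + c*S/(s0 + S)`, monotone increasing, bounded by `k0 + c`.
#' @export
dfm_capacity <- function(S, p) {
  stopifnot(inherits(p, "dfm_params"))
  if (any(S < 0)) stop("S must be nonnegative", call. = FALSE)
  p$k0 + p$c * S / (p$s0 + S)
}

#' Right-hand side of the Demographic-Wealth Model
#'
#' Evaluates the DWM vector field
#' \deqn{\dot N = r N (1 - N/(k_0 + cS)) - \alpha S N/(d + N), \quad
#'       \dot S = g S N - \beta S}
#' at one state.
#'
#' @param x state, a numeric `c(N, S)` (see [state_vec()]).
#' @param p a [dwm_params()] record.
#' @return Numeric `c(dN, dS)`.
#' @seealso [dwm_jacobian()], [integrate_dwm()]
#' @export
dwm_rhs <- function(x, p) {
  stopifnot(inherits(p, "dwm_params"))
  x <- as_state(x)
  N <- x[[1L]]; S <- x[[2L]]
  K <- p$k0 + p$c * S
  c(dN = p$r * N * (1 - N / K) - p$alpha * S * N / (p$d + N),
    dS = p$g * S * N - p$beta * S)
}

#' Right-hand side of the Demographic-Fiscal Model
#'
#' Evaluates the raw DFM vector field
#' \deqn{\dot N = r N (1 - N/k(S)), \quad
#'       \dot S = \rho_0 N (1 - N/k(S)) - \beta N}
#' with `k(S)` from [dfm_capacity()]. This is the unconstrained field: the
#' nonnegativity clamp on `S` (state collapse) is an event handled by
#' [integrate_dfm()], not part of the algebraic right-hand side.
#'
#' @inheritParams dwm_rhs
#' @param p a [dfm_params()] record.
#' @return Numeric `c(dN, dS)`.
#' @export
dfm_rhs <- function(x, p) {
  stopifnot(inherits(p, "dfm_params"))
  x <- as_state(x)
  N <- x[[1L]]; S <- x[[2L]]
  K <- dfm_capacity(S, p)
  surplus <- N * (1 - N / K)
  c(dN = p$r * surplus, dS = p$rho0 * surplus - p$beta * N)
}

as_state <- function(x) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop("state must be a finite numeric vector of length 2 (N, S)",
         call. = FALSE)
  if (any(x < 0))
    stop("state must lie in the closed positive quadrant", call. = FALSE)
  x
}

#' Exact Jacobian of the DWM vector field
#'
#' Analytic partial derivatives of [dwm_rhs()] with respect to `(N, S)`,
#' used for equilibrium classification and bifurcation detection. With
#' `K = k0 + c*S` and `D = d + N`:
#' \deqn{J = \begin{pmatrix}
#'   r(1 - 2N/K) - \alpha S d/D^2 & r c N^2/K^2 - \alpha N/D \\
#'   gS & gN - \beta \end{pmatrix}.}
#'
#' @inheritParams dwm_rhs
#' @return A 2x2 numeric matrix.
#' @export
dwm_jacobian <- function(x, p) {
  stopifnot(inherits(p, "dwm_params"))
  x <- as_state(x)
  N <- x[[1L]]; S <- x[[2L]]
  K <- p$k0 + p$c * S
  D <- p$d + N
  matrix(c(p$r * (1 - 2 * N / K) - p$alpha * S * p$d / D^2,
           p$r * p$c * N^2 / K^2 - p$alpha * N / D,
           p$g * S,
           p$g * N - p$beta),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("dN", "dS"), c("N", "S")))
}

#' Factor functions of the DWM phase-plane analysis
#'
#' The DWM can be written in consumer-resource factored form
#' \deqn{\dot N = N\,[g(N,S) - S\,p(N)/N\cdot N] \ldots}
#' using the per-capita growth factor `g(N,S) = r(1 - N/(k0 + c*S))`, the
#' saturating extraction response `p(N) = alpha*N/(d + N)` and the state
#' revenue function `q(N) = g*N`. These three functions drive the stability
#' criterion for the coexistence point (see [mu_value()]): `p(0) = 0`,
#' `p` saturates at `alpha`, and `q` is strictly increasing with `q(0) = 0`.
#'
#' @param N population density, >= 0 (vectorised).
#' @param S state wealth, >= 0 (vectorised, `growth_g` only).
#' @param p a [dwm_params()] record.
#' @return Numeric vector of function values.
#' @name factor_functions
NULL

#' @rdname factor_functions
#' @export
growth_g <- function(N, S, p) {
  stopifnot(inherits(p, "dwm_params"))
  if (any(N < 0) || any(S < 0)) stop("N, S must be nonnegative", call. = FALSE)
  p$r * (1 - N / (p$k0 + p$c * S))
}

#' @rdname factor_functions
#' @export
saturation_p <- function(N, p) {
  stopifnot(inherits(p, "dwm_params"))
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  p$alpha * N / (p$d + N)
}

#' @rdname factor_functions
#' @export
extraction_q <- function(N, p) {
  stopifnot(inherits(p, "dwm_params"))
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  p$g * N
}
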