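#' Registry of figure presets
#'
#' Named parameter sets and initial conditions for the standard scenarios
#' of both models (plot labels sometimes abbreviate `alpha` and `beta` as
#' `a` and `b`; the registry always uses the full model symbols). Each
#' preset carries a
#' suggested integration horizon long enough for the qualitative behaviour
#' to be unambiguous: the damped-oscillation scenarios need several
#' e-folding times of their (slow) focus, the limit-cycle scenario needs
#' tens of cycle periods.
#'
#' Available presets:
#' \describe{
#'   \item{fig1, dfm-beta-0, dfm-beta-0.1, dfm-beta-0.25, dfm-beta-0.4}{DFM
#'     rise-and-collapse runs, \code{k0 = 1, r = 0.02, rho0 = 1, c = 3, s0 = 10},
#'     initial `(0.5, 0)`; `fig1` uses the reference expenditure rate
#'     `beta = 0.25` and lists all four `beta` variants in `$variants`.}
#'   \item{fig2, dfm-rho-1, dfm-rho-2, dfm-rho-4}{same DFM baseline with
#'     `beta = 0.25` and taxation coefficient `rho0` in 1, 2, 4.}
#'   \item{fig3}{DWM baseline with stable coexistence: \code{r = 0.02, g = 0.15,
#'     alpha = 0.05, beta = 0.1, c = 0.5, k0 = 1, d = 1}, initial
#'     `(0.5, 0.01)`.}
#'   \item{fig8}{fig3 with `k0 = 2`: still stable but weakly damped,
#'     just below the Hopf value 2.095.}
#'   \item{fig9}{fig3 with \code{r = 0.1}.}
#'   \item{fig10}{fig3 with `alpha = 0.01`.}
#'   \item{fig11}{sustained limit cycle (secular cycles): \code{r = 0.04,
#'     g = 0.16, alpha = 0.006, beta = 0.1, c = 0.5, k0 = 1, d = 1},
#'     initial `(0.33, 0.01)`.}
#' }
#'
#' @param name preset name (see above).
#' @return A list of class `"clio_preset"`: `name`, `model` (`"dwm"` or
#'   `"dfm"`), `params` (a [dwm_params()] or [dfm_params()] record),
#'   `initial` (named numeric), `t_end` (suggested horizon) and optionally
#'   `variants` (named list of variant parameter values).
#' @examples
#' preset("fig3")$params$g     # 0.15
#' preset("fig11")$initial     # N = 0.33, S = 0.01
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

preset_registry <- function() {
  dfm_base <- function(beta, rho0 = 1)
    dfm_params(r = 0.02, rho0 = rho0, beta = beta, k0 = 1, c = 3, s0 = 10)
  dwm_fig3 <- function(r = 0.02, g = 0.15, alpha = 0.05, beta = 0.1,
                       c = 0.5, k0 = 1, d = 1)
    dwm_params(r = r, alpha = alpha, g = g, beta = beta, c = c, k0 = k0, d = d)
  mk <- function(name, model, params, initial, t_end, variants = NULL)
    structure(list(name = name, model = model, params = params,
                   initial = c(N = initial[[1L]], S = initial[[2L]]),
                   t_end = t_end, variants = variants),
              class = "clio_preset")
  reg <- list(
    mk("fig1", "dfm", dfm_base(0.25), c(0.5, 0), 2000,
       variants = list(beta = c(0.4, 0.25, 0.1, 0))),
    mk("dfm-beta-0", "dfm", dfm_base(0), c(0.5, 0), 2000),
    mk("dfm-beta-0.1", "dfm", dfm_base(0.1), c(0.5, 0), 2000),
    mk("dfm-beta-0.25", "dfm", dfm_base(0.25), c(0.5, 0), 2000),
    mk("dfm-beta-0.4", "dfm", dfm_base(0.4), c(0.5, 0), 2000),
    mk("fig2", "dfm", dfm_base(0.25, rho0 = 1), c(0.5, 0), 2000,
       variants = list(rho0 = c(1, 2, 4))),
    mk("dfm-rho-1", "dfm", dfm_base(0.25, rho0 = 1), c(0.5, 0), 2000),
    mk("dfm-rho-2", "dfm", dfm_base(0.25, rho0 = 2), c(0.5, 0), 2000),
    mk("dfm-rho-4", "dfm", dfm_base(0.25, rho0 = 4), c(0.5, 0), 2000),
    mk("fig3", "dwm", dwm_fig3(), c(0.5, 0.01), 8000),
    mk("fig8", "dwm", dwm_fig3(k0 = 2), c(0.5, 0.01), 40000),
    mk("fig9", "dwm", dwm_fig3(r = 0.1), c(0.5, 0.01), 4000),
    mk("fig10", "dwm", dwm_fig3(alpha = 0.01), c(0.5, 0.01), 30000),
    mk("fig11", "dwm", dwm_fig3(r = 0.04, g = 0.16, alpha = 0.006),
       c(0.33, 0.01), 20000))
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  reg
}

#' @export
print.clio_preset <- function(x, ...) {
  cat(sprintf("preset '%s' (%s), initial (N = %g, S = %g), horizon %g\n",
              x$name, toupper(x$model), x$initial[[1L]], x$initial[[2L]],
              x$t_end))
  print(x$params)
  if (!is.null(x$variants))
    for (nm in names(x$variants))
      cat(sprintf("  variants of %s: %s\n", nm,
                  paste(x$variants[[nm]], collapse = ", ")))
  invisible(x)
}
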