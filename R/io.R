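config_keys <- c("model", "r", "alpha", "g", "beta", "c", "k0", "d",
                 "rho0", "s0", "N0", "S0", "t_end")

dwm_keys <- c("r", "alpha", "g", "beta", "c", "k0", "d")
dfm_keys <- c("r", "rho0", "beta", "k0", "c", "s0")

#' Read a model configuration file
#'
#' Configurations are flat key-value text in Debian-control style
#' (`key: value`, one per line). Valid keys are `model` (`dwm` or `dfm`),
#' the model parameters (`r, alpha, g, beta, c, k0, d` for the DWM;
#' `r, rho0, beta, k0, c, s0` for the DFM) and the optional `N0`, `S0`,
#' `t_end`. Unknown keys are rejected with a message listing the valid
#' ones; a missing required parameter is reported by name.
#'
#' @param path file to read.
#' @return A list with `params` (a validated parameter record), `initial`
#'   (named numeric or `NULL`) and `t_end` (or `NULL`).
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  rec <- read.dcf(path)
  if (nrow(rec) != 1L) stop("config must contain exactly one record",
                            call. = FALSE)
  kv <- stats::setNames(as.list(rec[1L, ]), colnames(rec))
  bad <- setdiff(names(kv), config_keys)
  if (length(bad))
    stop(sprintf("unknown config key(s) %s; valid keys: %s",
                 paste(bad, collapse = ", "),
                 paste(config_keys, collapse = ", ")), call. = FALSE)
  model <- kv$model
  if (is.null(model) || !model %in% c("dwm", "dfm"))
    stop("config must set model: dwm or model: dfm", call. = FALSE)
  need <- if (model == "dwm") dwm_keys else dfm_keys
  missing_keys <- setdiff(need, names(kv))
  if (length(missing_keys))
    stop(sprintf("missing required key(s) for model %s: %s", model,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop(sprintf("key '%s' is not a number: %s", key,
                               kv[[key]]), call. = FALSE)
    v
  }
  vals <- stats::setNames(lapply(need, num), need)
  params <- do.call(if (model == "dwm") dwm_params else dfm_params, vals)
  initial <- NULL
  if (all(c("N0", "S0") %in% names(kv)))
    initial <- state_vec(num("N0"), num("S0"))
  t_end <- if ("t_end" %in% names(kv)) num("t_end") else NULL
  list(params = params, initial = initial, t_end = t_end)
}

#' Write a model configuration file
#'
#' Inverse of [load_config()]: serialises a parameter record (plus optional
#' initial state and horizon) to the flat key-value format, at full double
#' precision so that a round trip is the identity.
#'
#' @param params a [dwm_params()] or [dfm_params()] record.
#' @param path file to write.
#' @param initial optional `c(N, S)` initial state.
#' @param t_end optional horizon.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, initial = NULL, t_end = NULL) {
  stopifnot(inherits(params, "clio_params"))
  model <- if (inherits(params, "dwm_params")) "dwm" else "dfm"
  kv <- c(list(model = model),
          lapply(unclass(params), num_repr))
  if (!is.null(initial)) {
    kv$N0 <- num_repr(initial[[1L]])
    kv$S0 <- num_repr(initial[[2L]])
  }
  if (!is.null(t_end)) kv$t_end <- num_repr(t_end)
  writeLines(paste0(names(kv), ": ", unlist(kv)), path)
  invisible(path)
}

# shortest decimal representation that round-trips a double
num_repr <- function(x) formatC(x, digits = 17, format = "g")

#' Write a trajectory to CSV
#'
#' Columns `t`, `N`, `S` at full float precision, decimal point `.`, no
#' thousands separators. Metadata -- the model and any integration events
#' such as a state collapse -- is carried in `#`-commented header lines so
#' the file remains machine-comparable.
#'
#' @param tr a `clio_trajectory`.
#' @param path output file.
#' @param model optional model tag recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(tr, path, model = NULL) {
  stopifnot(inherits(tr, "clio_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model)) writeLines(sprintf("# model: %s", model), con)
  ev <- trajectory_events(tr)
  if (nrow(ev))
    writeLines(sprintf("# event: %s at t = %s", ev$label,
                       vapply(ev$time, num_repr, character(1))), con)
  writeLines("t,N,S", con)
  writeLines(paste(vapply(tr$t, num_repr, character(1)),
                   vapply(tr$N, num_repr, character(1)),
                   vapply(tr$S, num_repr, character(1)), sep = ","), con)
  invisible(path)
}

#' Write a bifurcation diagram to CSV
#'
#' The equilibrium branch goes to `path` (columns `param`, `N_star`,
#' `S_star`, `trace`, `det`, `stable`); the refined bifurcation points go
#' to a companion file (columns `param`, `kind`, `l1`), by default
#' `<path stem>_points.csv`.
#'
#' @param diag a `bifurcation_diagram` from [sweep_equilibria()].
#' @param path branch output file.
#' @param points_path companion file for the detected points.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diag, path,
                              points_path = sub("(\\.[^.]*)?$", "_points\\1",
                                                path)) {
  stopifnot(inherits(diag, "bifurcation_diagram"))
  con <- file(path, "w")
  writeLines(sprintf("# swept parameter: %s", diag$swept_param), con)
  writeLines("param,N_star,S_star,trace,det,stable", con)
  b <- diag$branch
  writeLines(paste(vapply(b$param, num_repr, character(1)),
                   vapply(b$N_star, num_repr, character(1)),
                   vapply(b$S_star, num_repr, character(1)),
                   vapply(b$trace, num_repr, character(1)),
                   vapply(b$det, num_repr, character(1)),
                   b$stable, sep = ","), con)
  close(con)
  con2 <- file(points_path, "w")
  writeLines("param,kind,l1", con2)
  d <- diag$detected
  if (nrow(d))
    writeLines(paste(vapply(d$param_value, num_repr, character(1)), d$kind,
                     vapply(d$l1, num_repr, character(1)), sep = ","), con2)
  close(con2)
  invisible(path)
}
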