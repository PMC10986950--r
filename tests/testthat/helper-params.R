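# shared fixtures: the damped-oscillation DWM baseline and random generators

fig3_params <- function(...) {
  args <- utils::modifyList(
    list(r = 0.02, alpha = 0.05, g = 0.15, beta = 0.1, c = 0.5, k0 = 1, d = 1),
    list(...))
  do.call(dwm_params, args)
}

# random DWM parameter set guaranteed to possess a coexistence point
random_dwm <- function() {
  g <- runif(1, 0.05, 0.5)
  k0 <- runif(1, 0.8, 2.5)
  beta <- g * k0 * runif(1, 0.1, 0.8)   # beta/g < k0
  dwm_params(r = runif(1, 0.01, 0.1), alpha = runif(1, 0.01, 0.2),
             g = g, beta = beta, c = runif(1, 0, 1), k0 = k0,
             d = runif(1, 0.3, 2))
}

# random c = 0 set admissible for every closed-form Hopf parameter:
# d < k0 and k0 > 2*beta/g + d
random_dwm_c0 <- function() {
  d <- runif(1, 0.2, 1)
  k0 <- d + runif(1, 0.5, 2)
  g <- runif(1, 0.05, 0.5)
  beta <- g * (k0 - d) / 2 * runif(1, 0.2, 0.9)
  dwm_params(r = runif(1, 0.01, 0.1), alpha = runif(1, 0.01, 0.2),
             g = g, beta = beta, c = 0, k0 = k0, d = d)
}

random_dfm <- function() {
  dfm_params(r = runif(1, 0.01, 0.05), rho0 = runif(1, 0.5, 2),
             beta = runif(1, 0.05, 0.4), k0 = runif(1, 0.5, 2),
             c = runif(1, 1, 4), s0 = runif(1, 5, 20))
}
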