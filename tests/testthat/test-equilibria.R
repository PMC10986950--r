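test_that("every returned equilibrium zeroes the vector field", {
  set.seed(501)
  for (i in 1:20) {
    p <- random_dwm()
    for (eq in dwm_equilibria(p))
      expect_lt(max(abs(dwm_rhs(c(eq$N, eq$S), p))), 1e-10)
  }
})

test_that("the origin is always a saddle and the stateless state flips at
           beta/g = k0", {
  set.seed(502)
  for (i in 1:10) {
    p <- random_dwm()
    eqs <- boundary_equilibria(p)
    expect_equal(eqs[[1]]$kind, "origin")
    expect_equal(eqs[[1]]$classification, "saddle")
  }
  # state spends faster than it grows: stateless population is a sink
  p_weak <- fig3_params(g = 0.05, beta = 0.1, k0 = 1)   # beta/g = 2 > k0
  expect_equal(boundary_equilibria(p_weak)[[2]]$classification, "stable-node")
  # baseline: beta/g = 2/3 < k0, stateless state is unstable (a saddle:
  # its triangular Jacobian has eigenvalues -r < 0 and g*k0 - beta > 0)
  st <- boundary_equilibria(fig3_params())[[2]]
  expect_equal(st$classification, "saddle")
  expect_lt(st$det, 0)
})

test_that("coexistence point matches an independent nullcline root-finder", {
  p <- fig3_params()
  eq <- coexistence(p)
  expect_equal(eq$N, 2 / 3)
  # oracle: solve the uncleared nullcline relation numerically
  Nst <- p$beta / p$g
  f <- function(S) p$alpha * S / (p$d + Nst) -
    p$r * (1 - Nst / (p$k0 + p$c * S))
  S_oracle <- uniroot(f, c(1e-8, 10), tol = 1e-14)$root
  expect_equal(eq$S, S_oracle, tolerance = 1e-10)
  expect_equal(eq$S, 0.2761423749, tolerance = 1e-8)
})

test_that("c = 0 coexistence reduces to the linear closed form", {
  p <- fig3_params(c = 0)
  eq <- coexistence(p)
  Nst <- p$beta / p$g
  expect_equal(eq$N, Nst)
  expect_equal(eq$S, p$r * (p$d + Nst) * (p$k0 - Nst) / (p$alpha * p$k0))
  expect_equal(eq$S, 0.2222222222, tolerance = 1e-8)
  # substitution back into the nullcline relation
  expect_equal(p$alpha * eq$S / (p$d + eq$N),
               p$r * (1 - eq$N / p$k0), tolerance = 1e-12)
})

test_that("coexistence is absent when the state cannot sustain itself", {
  expect_null(coexistence(fig3_params(g = 0.05, beta = 0.1, c = 0)))  # N* = 2 > k0
  expect_null(coexistence(fig3_params(g = 0.05, beta = 0.1)))
})

test_that("classification follows the trace/det/discriminant pattern", {
  expect_equal(coexistence(fig3_params())$classification, "stable-focus")
  p11 <- preset("fig11")$params
  eq11 <- coexistence(p11)
  expect_true(eq11$classification %in% c("unstable-focus", "unstable-node"))
  expect_gt(eq11$trace, 0)
  expect_equal(classify_equilibrium(0, 0.5), "nonhyperbolic")
  expect_equal(classify_equilibrium(-1, -0.5), "saddle")
  expect_equal(classify_equilibrium(-3, 0.5), "stable-node")
  expect_equal(classify_equilibrium(0.1, 0.5), "unstable-focus")
})

test_that("mu equals the coexistence Jacobian trace", {
  # baseline is stable, so mu < 0
  expect_lt(mu_value(fig3_params()), 0)
  # identity with the independent Jacobian route, randomized
  set.seed(503)
  for (i in 1:25) {
    p <- random_dwm()
    eq <- coexistence(p)
    if (is.null(eq)) next
    expect_equal(mu_value(p), sum(diag(dwm_jacobian(c(eq$N, eq$S), p))),
                 tolerance = 1e-10)
  }
  expect_error(mu_value(fig3_params(g = 0.05)), "does not exist")
})

test_that("closed-form Hopf values for c = 0 zero the mu functional", {
  p <- fig3_params(c = 0)
  k0c <- hopf_critical_c0(p, "k0")
  expect_equal(k0c, 7 / 3)
  # independent oracle: bisection of mu over k0
  f <- function(k0) mu_value(set_param(p, "k0", k0))
  expect_equal(k0c, uniroot(f, c(1.1, 5), tol = 1e-14)$root,
               tolerance = 1e-10)
  expect_equal(abs(f(k0c)), 0, tolerance = 1e-10)
  # the four formulas are rearrangements of one relation: self-consistency
  p2 <- set_param(p, "k0", k0c)
  expect_equal(hopf_critical_c0(p2, "beta"), p$beta)
  expect_equal(hopf_critical_c0(p2, "g"), p$g)
  expect_equal(hopf_critical_c0(p2, "d"), p$d)
})

test_that("inadmissible closed-form Hopf requests yield an explicit
           no-Hopf result", {
  # d >= k0 rules out Hopf bifurcations in g and beta
  p <- fig3_params(c = 0, d = 1.5, k0 = 1)
  expect_true(is.na(hopf_critical_c0(p, "g")))
  expect_match(attr(hopf_critical_c0(p, "g"), "reason"), "no Hopf")
  expect_true(is.na(hopf_critical_c0(p, "beta")))
  # k0 <= 2 beta/g rules out a Hopf in d
  q <- fig3_params(c = 0, g = 0.15, beta = 0.1, k0 = 1.2)  # 2b/g = 4/3 > k0
  expect_true(is.na(hopf_critical_c0(q, "d")))
  expect_error(hopf_critical_c0(fig3_params(), "k0"), "c = 0")
})

test_that("stateless and coexistence equilibria exchange stability at the
           transcritical point", {
  p <- fig3_params()
  gt <- p$beta / p$k0   # transcritical value of g
  below <- set_param(p, "g", gt * 0.98)
  above <- set_param(p, "g", gt * 1.02)
  expect_equal(boundary_equilibria(below)[[2]]$classification, "stable-node")
  expect_null(coexistence(below))
  expect_equal(boundary_equilibria(above)[[2]]$classification, "saddle")
  co <- coexistence(above)
  expect_false(is.null(co))
  expect_lt(co$trace, 0)   # newly born coexistence point is stable
})

test_that("equilibria serialize to the tabular report", {
  tab <- equilibria_table(dwm_equilibria(fig3_params()))
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$kind, c("origin", "stateless", "coexistence"))
  expect_named(tab, c("kind", "N", "S", "trace", "det", "eig_re1", "eig_im1",
                      "eig_re2", "eig_im2", "classification"))
  co <- tab[tab$kind == "coexistence", ]
  expect_equal(co$eig_im1, -co$eig_im2)
  expect_equal(co$classification, "stable-focus")
})
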