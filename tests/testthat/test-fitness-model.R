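test_that("binding steady state handles the no-zeocin and no-protein limits", {
  p <- fitness_params()
  s0 <- bound_zeocin_steady_state(c(0, 50, 1000), 0, p)
  expect_equal(s0$B, c(0, 0, 0))
  expect_equal(s0$Z_int, c(0, 0, 0))
  expect_equal(s0$R, c(0, 50, 1000))

  sF0 <- bound_zeocin_steady_state(0, 2, p)
  expect_equal(sF0$Z_int, p$k_in * 2 / p$k_out)
  expect_equal(sF0$B, 0)
  expect_equal(sF0$R, 0)
})

test_that("binding steady state solves the uptake/binding ODE", {
  p <- fitness_params()
  ss <- bound_zeocin_steady_state(100, 2, p)
  ## residuals of both ODE right-hand sides at the returned state
  dZ <- p$k_in * 2 - p$k_out * ss$Z_int - p$k_on * ss$Z_int * ss$R +
    p$k_off * ss$B
  dB <- p$k_on * ss$Z_int * ss$R - p$k_off * ss$B - p$k_deg * ss$B
  expect_lt(abs(dZ) / (p$k_in * 2), 1e-10)
  expect_lt(abs(dB) / (p$k_in * 2), 1e-10)
  expect_equal(ss$B + ss$R, ss$F)

  ## long-time ODE integration oracle on random parameter/input draws
  set.seed(101)
  for (i in 1:25) {
    pr <- fitness_params(k_in = runif(1, 0.3, 3), k_out = runif(1, 0.3, 3),
                         k_on = runif(1, 0.3, 3), k_off = runif(1, 0.03, 0.5),
                         k_deg = runif(1, 0.005, 0.1))
    F <- runif(1, 0, 2000); Z <- runif(1, 0.01, 3)
    orc <- integrate_binding_ode(F, Z, pr)
    got <- bound_zeocin_steady_state(F, Z, pr)
    expect_lt(abs(got$Z_int - orc$Z_int) / (abs(orc$Z_int) + 1e-12), 1e-8)
    expect_lt(abs(got$B - orc$B) / (abs(orc$B) + 1e-12), 1e-8)
  }
})

test_that("gamma factors have the required limits and monotonicity", {
  p <- fitness_params()
  expect_equal(gamma_zeocin(c(1, 100, 1e4), 0, p), c(1, 1, 1))
  expect_gt(gamma_zeocin(1e7, 2, p), 0.999)  # huge expression binds it all
  expect_equal(gamma_dox(c(0, 10, 1e4), 0, p), c(1, 1, 1))
  expect_equal(gamma_dox(0, 2, p), 1)

  ## brute-force monotonicity scan over a dense grid
  Fg <- 10^seq(0, 4, length.out = 60)
  Zg <- seq(0, 3, length.out = 25)
  for (Z in Zg) {
    g1 <- gamma_zeocin(Fg, Z, p)
    expect_true(all(diff(g1) >= -1e-12))  # non-decreasing in F
  }
  for (F in Fg) {
    g1 <- gamma_zeocin(F, Zg, p)
    expect_true(all(diff(g1) <= 1e-12))   # non-increasing in Z
  }
  Cg <- seq(0, 3, length.out = 25)
  for (C in Cg) expect_true(all(diff(gamma_dox(Fg, C, p)) <= 1e-12))
  for (F in Fg) expect_true(all(diff(gamma_dox(F, Cg, p)) <= 1e-12))

  expect_error(gamma_zeocin(-1, 2), "non-negative")
  expect_error(gamma_dox(10, NaN), "finite")
})

test_that("cellular fitness is bounded, multiplicative, and flat in D0Z0", {
  p <- fitness_params()
  Fg <- 10^seq(0, 4, length.out = 101)
  expect_equal(cellular_fitness(Fg, "D0Z0", p), rep(p$gamma0, 101))
  for (cond in c("D2Z0", "D0Z2", "DiZ2", "D2Z2")) {
    f <- cellular_fitness(Fg, cond, p)
    expect_true(all(f >= 0 & f <= p$gamma0 + 1e-12))
    g1 <- gamma_zeocin(Fg, parse_condition(cond)$zeo, p)
    g2 <- gamma_dox(Fg, parse_condition(cond)$dox, p)
    expect_equal(f, p$gamma0 * g1 * g2)  # multiplicativity
  }
})

test_that("landscape shapes match the six study conditions", {
  ## monotone decreasing for inducer-only, increasing for zeocin-only,
  ## interior peak when both drugs are present
  for (cond in c("D2Z0", "DiZ0")) {
    ls <- cellular_landscape(cond)
    expect_true(all(diff(ls$fitness_per_h) <= 1e-12), label = cond)
  }
  ls <- cellular_landscape("D0Z2")
  expect_true(all(diff(ls$fitness_per_h) >= -1e-12))
  for (cond in c("DiZ2", "D2Z2")) {
    ls <- cellular_landscape(cond)
    am <- which.max(ls$fitness_per_h)
    expect_gt(am, 1)
    expect_lt(am, nrow(ls))
  }
})

test_that("population fitness is the sample mean of cellular fitness", {
  p <- fitness_params()
  expect_equal(population_fitness(2.5, "D2Z2", p),
               cellular_fitness(10^2.5, "D2Z2", p))
  f1 <- cellular_fitness(10^1.2, "DiZ2", p)
  f2 <- cellular_fitness(10^3.1, "DiZ2", p)
  expect_equal(population_fitness(c(1.2, 3.1), "DiZ2", p), (f1 + f2) / 2)

  ## concatenation = size-weighted mean (exact)
  a <- runif(40, 0, 4); b <- runif(10, 0, 4)
  pa <- population_fitness(a, "D2Z2", p)
  pb <- population_fitness(b, "D2Z2", p)
  expect_equal(population_fitness(c(a, b), "D2Z2", p),
               (40 * pa + 10 * pb) / 50)
  expect_error(population_fitness(numeric(0), "D2Z2", p), "non-empty")
})

test_that("Monte-Carlo population fitness matches mixture quadrature", {
  p <- fitness_params()
  set.seed(7)
  w <- 0.4; m <- c(1, 3); sd <- 0.25
  n <- 1e5
  on <- runif(n) < w
  x <- rnorm(n, mean = ifelse(on, m[2], m[1]), sd = sd)
  mc <- population_fitness(x, "D2Z2", p)
  ## quadrature oracle over the mixture density
  quad <- function(mu) {
    g <- seq(mu - 6 * sd, mu + 6 * sd, length.out = 2001)
    sum(cellular_fitness(10^g, "D2Z2", p) * dnorm(g, mu, sd)) * diff(g)[1]
  }
  truth <- (1 - w) * quad(m[1]) + w * quad(m[2])
  se <- sd(cellular_fitness(10^x, "D2Z2", p)) / sqrt(n)
  expect_lt(abs(mc - truth), 3 * se + 1e-6)
})

test_that("landscape parameters are recovered from noiseless synthetic data", {
  true_fp <- fitness_params(gamma0 = 0.5, K_z = 0.35, h_z = 2.2,
                            K_d = 1000, h_d = 2.4)
  sc <- synth_config(seed = 11, growth_noise_sd = 0, n_cells = 3000)
  expr <- gen_expression_samples(true_fp, config = sc)
  curves <- gen_growth_curves(true_fp, config = sc, expr = expr)
  fit <- fit_fitness_params(curves, expr, params_init = fitness_params())
  for (p in c("gamma0", "K_z", "h_z", "K_d", "h_d"))
    expect_lt(abs(fit$params[[p]] - true_fp[[p]]) / true_fp[[p]], 0.01)
  expect_true(fit$diagnostics$converged)
})

test_that("landscape recovery from noisy curves stays inside the envelope", {
  ## 2 percent multiplicative noise, 3 replicate curves; envelopes from a
  ## pre-run 10-seed simulation study at these settings. gamma0 and K_d
  ## recover tightly; K_z trades off against the Hill exponent on noisy
  ## rate tables, so the functional check is on the fitted rates instead.
  true_fp <- fitness_params()
  sc <- synth_config(seed = 21, growth_noise_sd = 0.02, n_cells = 3000)
  expr <- gen_expression_samples(true_fp, config = sc)
  curves <- gen_growth_curves(true_fp, config = sc, expr = expr,
                              n_replicates = 3)
  fit <- fit_fitness_params(curves, expr, params_init = fitness_params())
  expect_lt(abs(fit$params$gamma0 - true_fp$gamma0) / true_fp$gamma0, 0.01)
  expect_lt(abs(fit$params$K_d - true_fp$K_d) / true_fp$K_d, 0.05)
  ## fitted population rates track the noiseless model rates
  truth <- vapply(seq_len(nrow(fit$rates)), function(i) {
    s <- expr$log10_fluorescence[expr$condition_label ==
                                   fit$rates$condition[i]]
    population_fitness(s, pf_environment(fit$rates$dox[i],
                                         fit$rates$zeo[i]), true_fp)
  }, numeric(1))
  expect_lt(max(abs(fit$rates$fitted - truth) / pmax(truth, 0.05)), 0.05)
})

test_that("degenerate designs are rejected", {
  sc <- synth_config(seed = 5, growth_noise_sd = 0)
  envs <- list(pf_environment(0, 0), pf_environment(2, 0))  # one zeo level
  expr <- gen_expression_samples(config = sc, envs = envs)
  curves <- gen_growth_curves(config = sc, envs = envs, expr = expr)
  expect_error(fit_fitness_params(curves, expr), "degenerate design")
})
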