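test_that("drug uptake relaxes exponentially and composes exactly", {
  cfg <- sim_config()
  st <- new_population_state(cfg, "D2Z2")
  expect_equal(unname(st$drug), c(0, 0))  # cells start drug-free

  ## no external drug: internal stays zero
  st0 <- new_population_state(cfg, "D0Z0")
  st0 <- update_drug_uptake(st0, "D0Z0", 5, cfg)
  expect_equal(unname(st0$drug), c(0, 0))

  ## long times converge to the external concentrations
  stL <- update_drug_uptake(st, "D2Z2", 200, cfg)
  expect_equal(unname(stL$drug), c(2, 2), tolerance = 1e-10)

  ## two half-steps equal one full step to machine accuracy
  a <- update_drug_uptake(st, "D2Z2", 0.8, cfg)
  b <- update_drug_uptake(update_drug_uptake(st, "D2Z2", 0.4, cfg),
                          "D2Z2", 0.4, cfg)
  expect_equal(a$drug, b$drug, tolerance = 1e-12)
  expect_error(update_drug_uptake(st, "D2Z2", -1, cfg), ">= 0")
})

test_that("bulk growth without drugs is exactly exponential", {
  cfg <- sim_config()
  st <- new_population_state(cfg, "D0Z0")
  st <- step_growth(st, cfg, 12)
  expect_equal(sum(st$counts), 1e6 * exp(cfg$fp$gamma0 * 12),
               tolerance = 1e-9)
  ## divisions equal the population increase (no death without zeocin)
  expect_equal(st$divisions, 1e6 * (exp(cfg$fp$gamma0 * 12) - 1),
               tolerance = 1e-6)
})

test_that("knockout lineages never enter the On state", {
  cfg <- sim_config(init_drug = "equilibrated")
  st <- new_population_state(cfg, "D2Z0")
  st$counts <- rbind(st$counts, c(5000, 0))
  st$id <- c(0L, 1L); st$type <- c(0L, 1L); st$r_mult <- c(1, 0)
  st$u_res <- c(0, 0); st$on_log10 <- c(3, 3); st$t_origin <- c(0, 0)
  st$preexisting <- c(FALSE, FALSE)
  for (h in 1:48) st <- step_growth(st, cfg, 1)
  expect_equal(unname(st$counts[2, 2]), 0)  # K row, On column
  expect_gt(st$counts[1, 2], 0)             # ancestral does switch On
})

test_that("small-lineage extinction matches the birth-death oracle", {
  ## single Off-state ancestral cell in zeocin with switching off: a linear
  ## birth-death process with the simulator's division and death rates
  cfg <- sim_config(init_drug = "equilibrated", k_death = 0.1)
  env <- parse_condition("D0Z2")
  g1 <- gamma_zeocin(10^cfg$off_log10, 2, cfg$fp)
  d <- cfg$k_death * (1 - g1)
  b <- cfg$fp$gamma0 * g1 + d
  T_end <- 24
  set.seed(77)
  n_rep <- 400
  extinct <- logical(n_rep)
  proto <- new_population_state(cfg, env, n0 = 1)
  for (i in seq_len(n_rep)) {
    st <- proto
    for (h in seq_len(T_end)) {
      st <- step_growth(st, cfg, 1)
      if (sum(st$counts) == 0) break
    }
    extinct[i] <- sum(st$counts) == 0
  }
  p_oracle <- bd_extinction_prob(b, d, T_end)
  se <- sqrt(p_oracle * (1 - p_oracle) / n_rep)
  expect_lt(abs(mean(extinct) - p_oracle), 3 * se + 0.01)
})

test_that("mutation injection has the right mean, types and effect laws", {
  cfg <- sim_config(init_drug = "equilibrated")
  env <- parse_condition("D2Z0")
  base <- new_population_state(cfg, env)
  base <- step_growth(base, cfg, 1)

  ## mu = 0 never injects
  cfg0 <- sim_config(mu_noZ = 0, mu_withZ = 0)
  expect_equal(nrow(inject_mutations(base, cfg0, env)$counts), 1L)

  ## Poisson mean over repeated draws (fixed division count)
  set.seed(55)
  lam_expect <- cfg$mu_noZ * base$anc_div_last
  counts <- replicate(2000, nrow(inject_mutations(base, cfg, env)$counts) - 1L)
  se <- sqrt(lam_expect / 2000)
  expect_lt(abs(mean(counts) - lam_expect), 3 * se)

  ## type fractions over many injected mutants
  set.seed(56)
  big <- base; big$anc_div_last <- big$anc_div_last * 50
  st2 <- inject_mutations(big, cfg, env)
  for (i in 1:200) st2 <- inject_mutations(st2, cfg, env)
  tp <- st2$type[st2$type != 0L]
  n <- length(tp)
  for (k in 1:3) {
    p <- c(cfg$p_K, cfg$p_T, cfg$p_G)[k]
    expect_lt(abs(mean(tp == k) - p), 3 * sqrt(p * (1 - p) / n))
  }
  ## allele invariants: K cannot switch; T reduces switching and expression;
  ## G scales resistance only
  expect_true(all(st2$r_mult[st2$type == 1L] == 0))
  expect_true(all(st2$r_mult[st2$type == 2L] > 0 &
                    st2$r_mult[st2$type == 2L] < 1))
  expect_true(all(st2$u_res[st2$type == 3L] > 0))
  expect_true(all(st2$u_res[st2$type %in% c(1L, 2L)] == 0))
  expect_true(all(st2$on_log10[st2$type == 3L] == cfg$on_log10))
})

test_that("resuspension preserves frequencies and hits the bottleneck", {
  cfg <- sim_config(bottleneck = 1e6)
  st <- new_population_state(cfg, "D0Z0")
  st$counts[1, ] <- c(3.5e6, 0)
  st$counts <- rbind(st$counts, c(1.5e6, 0))  # allele at frequency 0.3
  st$id <- c(0L, 1L); st$type <- c(0L, 3L); st$r_mult <- c(1, 1)
  st$u_res <- c(0, 0.5); st$on_log10 <- c(3, 3); st$t_origin <- c(0, 0)
  st$preexisting <- c(FALSE, FALSE)

  below <- st; below$counts <- below$counts / 10
  expect_equal(resuspend(below, cfg)$counts, below$counts)  # no dilution

  set.seed(66)
  freqs <- replicate(2000, {
    rs <- resuspend(st, cfg)
    sum(rs$counts[rs$id == 1L, ]) / sum(rs$counts)
  })
  expect_true(all(replicate(20, sum(resuspend(st, cfg)$counts)) == 1e6))
  se <- sqrt(0.3 * 0.7 / 1e6) / sqrt(2000)
  expect_lt(abs(mean(freqs) - 0.3), 3 * se)
})

test_that("replicates are reproducible and inert without mutation", {
  cfg <- tiny_sim_config(mu_noZ = 0, mu_withZ = 0)
  r <- run_replicate(cfg, "D2Z0", seed = 5)
  expect_true(all(r$trajectory$mut_type == "ancestral"))
  expect_true(all(r$trajectory$frequency == 1))
  expect_identical(r$summary$half_life_days, Inf)
  expect_identical(r$summary$n_established, 0L)

  cfg2 <- tiny_sim_config()
  a <- run_replicate(cfg2, "D2Z2", seed = 11)
  b <- run_replicate(cfg2, "D2Z2", seed = 11)
  expect_identical(a$trajectory, b$trajectory)
  c <- run_replicate(cfg2, "D2Z2", seed = 12)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("allele frequencies sum to one at every recorded day", {
  cfg <- sim_config(duration_days = 8)
  r <- run_replicate(cfg, "D2Z2", seed = 3)
  sums <- tapply(r$trajectory$frequency, r$trajectory$day, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the all-ODE limit grows at the dominant eigenvalue", {
  cfg <- sim_config(stoch_threshold = 0, mu_noZ = 0, mu_withZ = 0,
                    init_drug = "equilibrated", bottleneck = 1e300)
  env <- parse_condition("D2Z0")
  st <- new_population_state(cfg, env)
  eq <- equilibrium_on_fraction(condition_switching_params(env))
  st$counts[1, ] <- 1e6 * c(1 - eq$on_fraction, eq$on_fraction)
  n0 <- sum(st$counts)
  for (h in 1:100) st <- step_growth(st, cfg, 1)
  rate <- log(sum(st$counts) / n0) / 100
  expect_equal(rate, eq$growth_rate, tolerance = 1e-6)
})

test_that("the pre-existing variant splits the mutant pool by phase", {
  ## high mutation rate so both phases certainly contribute
  cfg <- sim_config(duration_days = 3, mu_noZ = 3e-5, mu_withZ = 3e-5)
  r <- run_preexisting_variant(cfg, "D0Z0", seed = 21)
  tr <- r$trajectory[r$trajectory$day == 3, ]
  expect_true(any(tr$preexisting))                 # phase-1 alleles flagged
  expect_true(any(!tr$preexisting & tr$mut_type != "ancestral"))
  expect_true(r$summary$preexisting_fraction >= 0 &&
                r$summary$preexisting_fraction <= 1)

  ## no mutation in either phase: no pre-existing contribution
  cfg0 <- tiny_sim_config(mu_noZ = 0, mu_withZ = 0)
  r0 <- run_preexisting_variant(cfg0, "D2Z0", seed = 1)
  expect_true(is.na(r0$summary$preexisting_fraction))
})

test_that("ensemble summaries compute means, SEMs and sentinels", {
  mk <- function(hl, est = 2L) {
    list(half_life_days = hl, n_established = est,
         type_fractions = c(K = 0.5, T = 0.1, G = 0.2),
         mutant_type_share = c(K = 0.625, T = 0.125, G = 0.25),
         mutant_mass = 0.8, preexisting_fraction = 0.4, extinct = FALSE)
  }
  same <- summarize_ensemble(list(mk(10), mk(10), mk(10)))
  expect_equal(same$half_life$sem, 0)
  two <- summarize_ensemble(list(mk(10), mk(20)))
  expect_equal(two$half_life$mean, 15)
  expect_equal(two$half_life$sem, 5)
  sent <- summarize_ensemble(list(mk(10), mk(Inf), mk(20), mk(Inf)))
  expect_equal(sent$half_life$mean, 15)
  expect_equal(sent$half_life_reached_fraction, 0.5)
})

test_that("ensemble SEM agrees with a bootstrap standard error", {
  set.seed(88)
  vals <- rpois(60, 4)
  sums <- lapply(vals, function(v)
    list(half_life_days = Inf, n_established = v,
         type_fractions = c(K = 0, T = 0, G = 0),
         mutant_type_share = c(K = NA, T = NA, G = NA),
         mutant_mass = 0, preexisting_fraction = NA, extinct = FALSE))
  ens <- summarize_ensemble(sums)
  boot <- replicate(4000, mean(sample(vals, replace = TRUE)))
  expect_lt(abs(ens$n_established$sem - sd(boot)) / sd(boot), 0.2)
})
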