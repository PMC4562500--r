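## Detailed stochastic simulation framework: allele-level population
## dynamics with Off/On switching, K/T/G mutation entry as single cells,
## gradual drug uptake, periodic bottlenecks, and summary statistics.

#' Configuration of the detailed evolution simulator
#'
#' @param mu_noZ beneficial-mutation rate per genome per generation without
#'   zeocin (default `10^-6.2`)
#' @param mu_withZ rate with zeocin (default `10^-5.4`)
#' @param p_K,p_T,p_G mutation-type probabilities (defaults 0.225, 0.025,
#'   0.75; must sum to 1)
#' @param bottleneck resuspension bottleneck size in cells (default `10^6`)
#' @param resuspension_h resuspension interval in hours (12 or 24)
#' @param duration_days simulated evolution length (default 20)
#' @param n_replicates default ensemble size (default 100)
#' @param established_threshold allele frequency defining "established" at
#'   the final day (default 0.05)
#' @param stoch_threshold lineage size (cells) below which dynamics are
#'   simulated stochastically; larger lineages use the ODE propagator
#'   (default 1000; 0 makes the whole run deterministic)
#' @param dt_stoch time step of the stochastic updates, hours (default 0.05)
#' @param k_up_dox,k_up_zeo drug uptake rates (per hour): internal effective
#'   concentrations relax exponentially toward the external medium
#' @param k_death death-rate coupling to the zeocin kill term: cells die at
#'   `k_death * (1 - gamma1)` and divide at `gamma + k_death * (1 - gamma1)`
#'   so the net growth rate equals the cellular fitness `gamma` exactly
#' @param off_log10,on_log10 Off/On expression modes (log10 fluorescence)
#' @param init_drug `"zero"` (cells start drug- and inducer-free) or
#'   `"equilibrated"` (internal = external at t = 0)
#' @param fp a [fitness_params()] object
#' @param sw baseline switching parameters ([base_switching_params()])
#' @return an object of class `sim_config`
#' @export
sim_config <- function(mu_noZ = 10^-6.2, mu_withZ = 10^-5.4,
                       p_K = 0.225, p_T = 0.025, p_G = 0.75,
                       bottleneck = 1e6, resuspension_h = 12,
                       duration_days = 20, n_replicates = 100,
                       established_threshold = 0.05,
                       stoch_threshold = 1000, dt_stoch = 0.05,
                       k_up_dox = 1, k_up_zeo = 2, k_death = 0.01,
                       off_log10 = OFF_MODE_LOG10,
                       on_log10 = ON_MODE_LOG10,
                       init_drug = c("zero", "equilibrated"),
                       fp = fitness_params(),
                       sw = base_switching_params()) {
  p <- c(p_K, p_T, p_G)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("(p_K, p_T, p_G) must be non-negative and sum to 1", call. = FALSE)
  if (bottleneck < 1) stop("'bottleneck' must be >= 1", call. = FALSE)
  if (established_threshold <= 0 || established_threshold >= 1)
    stop("'established_threshold' must be in (0, 1)", call. = FALSE)
  if (mu_noZ < 0 || mu_withZ < 0)
    stop("mutation rates must be >= 0", call. = FALSE)
  structure(list(
    mu_noZ = mu_noZ, mu_withZ = mu_withZ,
    p_K = p_K, p_T = p_T, p_G = p_G,
    bottleneck = bottleneck, resuspension_h = resuspension_h,
    duration_days = duration_days, n_replicates = n_replicates,
    established_threshold = established_threshold,
    stoch_threshold = stoch_threshold, dt_stoch = dt_stoch,
    k_up_dox = k_up_dox, k_up_zeo = k_up_zeo, k_death = k_death,
    off_log10 = off_log10, on_log10 = on_log10,
    init_drug = match.arg(init_drug), fp = fp, sw = sw),
    class = "sim_config")
}

TYPE_LEVELS <- c("ancestral", "K", "T", "G")

#' Create an all-ancestral population state
#'
#' The population starts as `n0` ancestral Off-state cells; internal drug
#' levels start at zero (drug-free cells) unless the configuration says
#' `"equilibrated"`.
#'
#' @param config a [sim_config()]
#' @param env a [pf_environment()] or DxZy label
#' @param n0 initial cell count (default: the bottleneck size)
#' @return a population-state object (class `pf_population`)
#' @export
new_population_state <- function(config, env, n0 = config$bottleneck) {
  env <- as_pf_environment(env)
  drug <- if (config$init_drug == "equilibrated")
    c(dox = env$dox, zeo = env$zeo) else c(dox = 0, zeo = 0)
  st <- list(
    t = 0,
    env = env,
    counts = matrix(c(n0, 0), nrow = 1L,
                    dimnames = list(NULL, c("n_L", "n_H"))),
    id = 0L, type = 0L, r_mult = 1, u_res = 0,
    on_log10 = config$on_log10, t_origin = 0, preexisting = FALSE,
    drug = drug,
    ext = c(dox = env$dox, zeo = env$zeo),
    divisions = 0, anc_div_last = 0,
    next_id = 1L, extinct = FALSE,
    rates = NULL, drug_cache = c(NA_real_, NA_real_))
  class(st) <- "pf_population"
  st
}

## per-allele birth/death/switch rates at the current internal drug levels
compute_rates <- function(st, config) {
  fp <- config$fp
  C <- st$drug[[1L]]; Z <- st$drug[[2L]]
  F_off <- 10^config$off_log10
  g1_off_base <- gamma_zeocin(F_off, Z, fp)
  g2_off <- gamma_dox(F_off, C, fp)
  g1_off <- g1_off_base + st$u_res * (1 - g1_off_base)
  F_on <- 10^st$on_log10
  g1_on_base <- gamma_zeocin(F_on, Z, fp)
  g2_on <- gamma_dox(F_on, C, fp)
  g1_on <- g1_on_base + st$u_res * (1 - g1_on_base)
  d_L <- config$k_death * (1 - g1_off)
  d_H <- config$k_death * (1 - g1_on)
  b_L <- fp$gamma0 * g1_off * g2_off + d_L
  b_H <- fp$gamma0 * g1_on * g2_on + d_H
  r_on <- switch_rate_on(config$sw, C) * st$r_mult
  list(b_L = b_L, d_L = d_L, b_H = b_H, d_H = d_H,
       r = r_on, f = rep_len(config$sw$f, length(b_L)))
}

ensure_rates <- function(st, config) {
  if (is.null(st$rates) ||
      length(st$rates$b_L) != length(st$id) ||
      any(abs(st$drug - st$drug_cache) >
            1e-9 * (abs(st$drug) + 1e-12))) {
    st$rates <- compute_rates(st, config)
    st$drug_cache <- st$drug
  }
  st
}

#' Advance internal drug levels by gradual uptake
#'
#' Internal effective concentrations relax exponentially toward the
#' external medium: `c_int(t + dt) = c_ext + (c_int - c_ext) exp(-k dt)`.
#' Composition of two half-steps equals one full step exactly.
#'
#' @param state a `pf_population` state
#' @param env environment providing the external concentrations
#' @param dt step in hours (>= 0)
#' @param config a [sim_config()] (uptake rates)
#' @return the updated state
#' @export
update_drug_uptake <- function(state, env, dt, config) {
  if (dt < 0) stop("'dt' must be >= 0", call. = FALSE)
  env <- as_pf_environment(env)
  ext <- c(dox = env$dox, zeo = env$zeo)
  k <- c(config$k_up_dox, config$k_up_zeo)
  state$drug <- ext + (state$drug - ext) * exp(-k * dt)
  state$ext <- ext
  state$env <- env
  state
}

## exact divisions integral for the deterministic propagator:
## D = b . int_0^dt exp(A s) n0 ds, via solve(A, (M - I) n0)
det_divisions <- function(A, M, n0, n1, b, dt) {
  dtm <- det(A)
  if (is.finite(dtm) && abs(dtm) > 1e-12 * max(abs(A))^2) {
    v <- solve(A, (M %*% n0) - n0)
    sum(b * v)
  } else {
    dt * sum(b * (n0 + n1)) / 2
  }
}

#' Advance population growth, death and switching by one step
#'
#' Lineages at or above the stochastic-size threshold advance by the exact
#' two-state matrix exponential with allele-modified rates; smaller lineages
#' advance by tau-leap binomial division/death/switch events at the
#' configured fine time step. Cumulative division counts (total and
#' ancestral) are updated; ancestral divisions drive mutation entry.
#'
#' @param state a `pf_population` state
#' @param config a [sim_config()]
#' @param dt step in hours (must not exceed 24)
#' @return the updated state
#' @export
step_growth <- function(state, config, dt = 1) {
  if (dt < 0 || dt > 24) stop("'dt' must be in [0, 24] hours", call. = FALSE)
  st <- ensure_rates(state, config)
  rt <- st$rates
  tot <- st$counts[, 1L] + st$counts[, 2L]
  stoch <- tot < config$stoch_threshold & tot > 0
  div_total <- 0; div_anc <- 0

  det_idx <- which(!stoch & tot > 0)
  for (i in det_idx) {
    A <- matrix(c(rt$b_L[i] - rt$d_L[i] - rt$r[i], rt$r[i],
                  rt$f[i], rt$b_H[i] - rt$d_H[i] - rt$f[i]), nrow = 2L)
    M <- expm_2x2(A, dt)
    n0 <- st$counts[i, ]
    n1 <- pmax(as.vector(M %*% n0), 0)
    D <- det_divisions(A, M, n0, n1, c(rt$b_L[i], rt$b_H[i]), dt)
    st$counts[i, ] <- n1
    div_total <- div_total + D
    if (st$type[i] == 0L) div_anc <- div_anc + D
  }

  sidx <- which(stoch)
  if (length(sidx)) {
    nL <- st$counts[sidx, 1L]; nH <- st$counts[sidx, 2L]
    k <- length(sidx)
    h <- config$dt_stoch
    nsub <- max(1L, ceiling(dt / h))
    h <- dt / nsub
    pbL <- pmin(rt$b_L[sidx] * h, 1); pdL <- pmin(rt$d_L[sidx] * h, 1)
    pbH <- pmin(rt$b_H[sidx] * h, 1); pdH <- pmin(rt$d_H[sidx] * h, 1)
    pr <- pmin(rt$r[sidx] * h, 1); pf <- pmin(rt$f[sidx] * h, 1)
    is_anc <- st$type[sidx] == 0L
    for (s in seq_len(nsub)) {
      bL <- stats::rbinom(k, nL, pbL); dL <- stats::rbinom(k, nL, pdL)
      sLH <- stats::rbinom(k, nL, pr)
      bH <- stats::rbinom(k, nH, pbH); dH <- stats::rbinom(k, nH, pdH)
      sHL <- stats::rbinom(k, nH, pf)
      nL <- pmax(nL + bL - dL - sLH + sHL, 0)
      nH <- pmax(nH + bH - dH + sLH - sHL, 0)
      div_total <- div_total + sum(bL) + sum(bH)
      if (any(is_anc)) div_anc <- div_anc + sum(bL[is_anc]) + sum(bH[is_anc])
    }
    st$counts[sidx, 1L] <- nL; st$counts[sidx, 2L] <- nH
  }

  st$t <- st$t + dt
  st$divisions <- st$divisions + div_total
  st$anc_div_last <- div_anc
  st
}

#' Inject new mutant alleles as single cells
#'
#' The number of new mutants is Poisson with mean `mu` times the ancestral
#' divisions of the last growth step, where `mu` is the with-zeocin rate
#' when the environment contains zeocin and the no-zeocin rate otherwise.
#' Each mutant starts a new single-cell allele; its type is drawn from
#' `(p_K, p_T, p_G)`. Tweaking mutants draw an rtTA-activity factor
#' `u ~ Uniform(0, 1)` that scales the Off-to-On switching rate and places
#' the On-state expression at the matching intermediate level (log10
#' interpolation between the Off and On modes). Generic-resistance mutants
#' draw a resistance strength placing their zeocin survival uniformly
#' between the ancestral value and the value without zeocin (the zeocin-free
#' cap). T and G mutants inherit the parent's Off/On state (parent chosen
#' proportionally to division contribution); knockouts enter Off, since loss
#' of the activator collapses expression within a generation.
#'
#' @param state a `pf_population` state (after [step_growth()])
#' @param config a [sim_config()]
#' @param env the selective environment used to interpret resistance effect
#'   sizes (defaults to the state's current environment)
#' @param preexisting flag newly arising alleles as pre-existing (pre-phase
#'   of the variant runs)
#' @return the updated state
#' @export
inject_mutations <- function(state, config, env = state$env,
                             preexisting = FALSE) {
  env <- as_pf_environment(env)
  mu <- if (state$env$zeo > 0) config$mu_withZ else config$mu_noZ
  n_new <- stats::rpois(1L, mu * state$anc_div_last)
  if (n_new == 0L) return(state)
  st <- ensure_rates(state, config)
  types <- sample.int(3L, n_new, replace = TRUE,
                      prob = c(config$p_K, config$p_T, config$p_G))
  ## parent state: proportional to ancestral division contribution by state
  anc <- which(st$type == 0L)[1L]
  rt <- st$rates
  wL <- rt$b_L[anc] * st$counts[anc, 1L]
  wH <- rt$b_H[anc] * st$counts[anc, 2L]
  p_on <- if (wL + wH > 0) wH / (wL + wH) else 0
  from_on <- stats::runif(n_new) < p_on
  u <- stats::runif(n_new)

  r_mult <- ifelse(types == 1L, 0, ifelse(types == 2L, u, 1))
  on_lg <- ifelse(types == 2L,
                  config$off_log10 +
                    u * (config$on_log10 - config$off_log10),
                  config$on_log10)
  u_res <- ifelse(types == 3L, u, 0)
  from_on[types == 1L] <- FALSE  # knockouts enter Off

  newc <- cbind(n_L = as.numeric(!from_on), n_H = as.numeric(from_on))
  st$counts <- rbind(st$counts, newc)
  st$id <- c(st$id, seq.int(st$next_id, length.out = n_new))
  st$next_id <- st$next_id + n_new
  st$type <- c(st$type, types)
  st$r_mult <- c(st$r_mult, r_mult)
  st$u_res <- c(st$u_res, u_res)
  st$on_log10 <- c(st$on_log10, on_lg)
  st$t_origin <- c(st$t_origin, rep(st$t, n_new))
  st$preexisting <- c(st$preexisting, rep(preexisting, n_new))
  st$rates <- NULL  # force recompute (new rows)
  st
}

## drop extinct mutant lineages (the ancestral row is kept as a record)
prune_extinct <- function(st) {
  tot <- st$counts[, 1L] + st$counts[, 2L]
  keep <- tot > 0 | st$type == 0L
  if (all(keep)) return(st)
  st$counts <- st$counts[keep, , drop = FALSE]
  for (f in c("id", "type", "r_mult", "u_res", "on_log10", "t_origin",
              "preexisting"))
    st[[f]] <- st[[f]][keep]
  st$rates <- NULL
  st
}

#' Resuspend the culture: bottleneck sampling and fresh medium
#'
#' If the total population exceeds the bottleneck, per-(allele, state)
#' counts are drawn multinomially with expected frequencies preserved and
#' the new total equal to the bottleneck; otherwise counts are unchanged.
#' External drug concentrations are reset to the fresh-medium values;
#' internal effective concentrations persist (cells carry internalized
#' drug).
#'
#' @param state a `pf_population` state
#' @param config a [sim_config()]
#' @return the updated state
#' @export
resuspend <- function(state, config) {
  st <- state
  tot <- sum(st$counts)
  if (tot > config$bottleneck) {
    probs <- as.vector(st$counts) / tot
    drawn <- stats::rmultinom(1L, size = config$bottleneck, prob = probs)
    st$counts <- matrix(as.numeric(drawn), ncol = 2L,
                        dimnames = dimnames(st$counts))
    st <- prune_extinct(st)
  }
  st$ext <- c(dox = st$env$dox, zeo = st$env$zeo)
  st
}

record_frequencies <- function(st, day) {
  tot <- sum(st$counts)
  if (tot <= 0) return(NULL)
  freq <- (st$counts[, 1L] + st$counts[, 2L]) / tot
  data.frame(day = day, allele_id = st$id,
             mut_type = TYPE_LEVELS[st$type + 1L],
             frequency = freq, preexisting = st$preexisting)
}

## core engine: a sequence of phases (environment, duration, preexisting
## flag); records daily frequencies of the final phase
sim_run <- function(config, phases) {
  main <- phases[[length(phases)]]
  st <- new_population_state(config, phases[[1L]]$env)
  traj <- vector("list", config$duration_days + 1L)
  main_t0 <- sum(vapply(phases[-length(phases)],
                        function(p) p$hours, numeric(1)))
  for (ph in phases) {
    st <- update_drug_uptake(st, ph$env, 0, config)
    st$ext <- c(dox = ph$env$dox, zeo = ph$env$zeo)
    for (h in seq_len(ph$hours)) {
      st <- update_drug_uptake(st, ph$env, 1, config)
      st <- step_growth(st, config, 1)
      st <- inject_mutations(st, config, env = main$env,
                             preexisting = isTRUE(ph$preexisting))
      st <- prune_extinct(st)
      if (sum(st$counts) <= 0) { st$extinct <- TRUE; break }
      if ((st$t %% config$resuspension_h) == 0)
        st <- resuspend(st, config)
      t_main <- st$t - main_t0
      if (t_main >= 0 && (t_main %% 24) == 0) {
        traj[[t_main / 24 + 1L]] <- record_frequencies(st, t_main / 24)
      }
    }
    if (st$extinct) break
  }
  if (is.null(traj[[1L]])) {
    st0 <- new_population_state(config, main$env)
    traj[[1L]] <- record_frequencies(st0, 0)  # placeholder day-0 row
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  list(state = st, trajectory = trajectory, extinct = st$extinct)
}

summarize_run <- function(trajectory, config, extinct = FALSE) {
  anc <- trajectory[trajectory$mut_type == "ancestral", ]
  anc_series <- data.frame(time_day = anc$day, x_anc = anc$frequency)
  days <- sort(unique(trajectory$day))
  missing_days <- setdiff(0:config$duration_days, anc_series$time_day)
  if (length(missing_days))  # ancestral extinct: frequency 0 from then on
    anc_series <- rbind(anc_series,
                        data.frame(time_day = missing_days, x_anc = 0))
  anc_series <- anc_series[order(anc_series$time_day), ]
  last <- trajectory[trajectory$day == max(days), ]
  mut <- last[last$mut_type != "ancestral", ]
  mut_mass <- sum(mut$frequency)
  type_fractions <- vapply(c("K", "T", "G"), function(tp)
    sum(mut$frequency[mut$mut_type == tp]), numeric(1))
  share <- if (mut_mass > 0) type_fractions / mut_mass else
    c(K = NA_real_, T = NA_real_, G = NA_real_)
  pre_mass <- sum(mut$frequency[mut$preexisting])
  list(half_life_days = ancestral_half_life(anc_series),
       n_established = sum(mut$frequency > config$established_threshold),
       type_fractions = type_fractions,
       mutant_type_share = share,
       mutant_mass = mut_mass,
       preexisting_fraction = if (mut_mass > 0) pre_mass / mut_mass
                              else NA_real_,
       extinct = extinct)
}

#' Run one replicate of the detailed evolution simulation
#'
#' Loops drug uptake, growth/switching, mutation entry and periodic
#' resuspension for the configured duration, and returns daily allele
#' frequencies plus summary statistics. Fully reproducible from
#' `(config, env, seed)`.
#'
#' @param config a [sim_config()]
#' @param env a [pf_environment()] or DxZy label
#' @param seed integer RNG seed for this replicate
#' @return list with `trajectory` (data.frame: day, allele_id, mut_type,
#'   frequency, preexisting), `summary` (half-life in days with `Inf` as the
#'   not-reached sentinel, established-allele count at the final day, K/T/G
#'   population fractions and mutant-mass shares, pre-existing contribution)
#'   and `extinct` flag
#' @export
run_replicate <- function(config, env, seed = 1L) {
  set.seed(seed)
  env <- as_pf_environment(env)
  res <- sim_run(config, list(list(env = env,
                                   hours = config$duration_days * 24,
                                   preexisting = FALSE)))
  list(trajectory = res$trajectory,
       summary = summarize_run(res$trajectory, config, res$extinct),
       extinct = res$extinct)
}

#' Run one replicate of the pre-existing-mutation variant
#'
#' A 24-hour neutral pre-growth phase in D0Z0 (no drug, no inducer: all
#' mutation types are selectively neutral there) accumulates mutations at
#' the no-zeocin rate and flags them pre-existing; the environment is then
#' switched and the run proceeds as normal. The summary additionally
#' reports the fraction of day-20 mutant mass carried by pre-existing
#' alleles.
#'
#' @inheritParams run_replicate
#' @param pre_hours length of the neutral pre-phase (default 24)
#' @return as [run_replicate()]
#' @export
run_preexisting_variant <- function(config, env, seed = 1L, pre_hours = 24) {
  set.seed(seed)
  env <- as_pf_environment(env)
  res <- sim_run(config, list(
    list(env = parse_condition("D0Z0"), hours = pre_hours,
         preexisting = TRUE),
    list(env = env, hours = config$duration_days * 24,
         preexisting = FALSE)))
  list(trajectory = res$trajectory,
       summary = summarize_run(res$trajectory, config, res$extinct),
       extinct = res$extinct)
}

#' Derive independent replicate seeds from one master seed
#'
#' @param master_seed integer master seed
#' @param n number of replicate seeds
#' @return integer vector of length `n`
#' @export
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a replicate ensemble in one condition
#'
#' @param config a [sim_config()]
#' @param env a [pf_environment()] or DxZy label
#' @param n number of replicates (default `config$n_replicates`)
#' @param master_seed master seed from which replicate seeds are derived
#' @param variant `"standard"` or `"preexisting"` (24-h neutral pre-phase)
#' @return list with `summaries` (per-replicate summary lists) and
#'   `ensemble` (see [summarize_ensemble()])
#' @export
run_ensemble <- function(config, env, n = config$n_replicates,
                         master_seed = 1L,
                         variant = c("standard", "preexisting")) {
  variant <- match.arg(variant)
  seeds <- replicate_seeds(master_seed, n)
  runner <- if (variant == "preexisting") run_preexisting_variant
            else run_replicate
  summaries <- lapply(seq_len(n), function(i)
    runner(config, env, seed = seeds[i])$summary)
  list(summaries = summaries, ensemble = summarize_ensemble(summaries))
}

#' Ensemble means and standard errors of the summary statistics
#'
#' Half-life sentinels (`Inf`, not reached) are excluded from the half-life
#' mean; the fraction of replicates that reached half-life is reported
#' alongside.
#'
#' @param summaries list of per-replicate summaries (>= 2)
#' @return list of `mean`/`sem` pairs for half-life, established-allele
#'   count, K/T/G population fractions and mutant-mass shares, and the
#'   pre-existing contribution, plus `half_life_reached_fraction` and
#'   `n_replicates`
#' @export
summarize_ensemble <- function(summaries) {
  if (length(summaries) < 2L)
    stop("need >= 2 replicate summaries", call. = FALSE)
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  mfin <- function(x) mean(x[is.finite(x)])
  hl <- vapply(summaries, function(s) s$half_life_days, numeric(1))
  est <- vapply(summaries, function(s) as.numeric(s$n_established),
                numeric(1))
  tf <- t(vapply(summaries, function(s) s$type_fractions, numeric(3)))
  sh <- t(vapply(summaries, function(s) s$mutant_type_share, numeric(3)))
  pre <- vapply(summaries, function(s) s$preexisting_fraction, numeric(1))
  list(
    n_replicates = length(summaries),
    half_life = list(mean = mfin(hl), sem = sem(hl)),
    half_life_reached_fraction = mean(is.finite(hl)),
    n_established = list(mean = mean(est), sem = sem(est)),
    type_fractions = list(mean = colMeans(tf),
                          sem = apply(tf, 2L, sem)),
    mutant_type_share = list(mean = colMeans(sh, na.rm = TRUE),
                             sem = apply(sh, 2L, sem)),
    preexisting_fraction = list(mean = mean(pre, na.rm = TRUE),
                                sem = sem(pre[!is.na(pre)])))
}
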