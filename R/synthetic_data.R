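## Synthetic-data generators emulating every measurement layer the pipeline
## consumes: growth curves, single-cell fluorescence samples, sequencing
## observations with haplotype structure, and switching dose responses.

#' Configuration of the synthetic-data generators
#'
#' @param seed master seed recorded in every output
#' @param off_mean,on_mean log10-fluorescence means of the Off and On modes
#' @param mode_sd log10 standard deviation of each mode
#' @param n_cells cells per flow-cytometry sample
#' @param growth_noise_sd multiplicative (lognormal) noise sd of growth
#'   curves
#' @param coverage whole-genome sequencing depth per locus
#' @param n_clones clonal isolates Sanger-sequenced per time point
#' @param sampled_days days with sequencing observations (2 to 6 values)
#' @return an object of class `synth_config`
#' @export
synth_config <- function(seed = 1L,
                         off_mean = OFF_MODE_LOG10, on_mean = ON_MODE_LOG10,
                         mode_sd = MODE_SD_LOG10,
                         n_cells = 1e4, growth_noise_sd = 0.02,
                         coverage = 100L, n_clones = 20L,
                         sampled_days = c(4, 9, 14, 19)) {
  stopifnot(n_cells > 0, growth_noise_sd >= 0, coverage > 0, n_clones > 0,
            length(sampled_days) >= 2L, length(sampled_days) <= 6L)
  structure(list(seed = as.integer(seed), off_mean = off_mean,
                 on_mean = on_mean, mode_sd = mode_sd, n_cells = n_cells,
                 growth_noise_sd = growth_noise_sd,
                 coverage = as.integer(coverage),
                 n_clones = as.integer(n_clones),
                 sampled_days = sampled_days),
            class = "synth_config")
}

#' The 13-condition landscape-mapping design
#'
#' Zeocin alone (0.5, 1, 1.5, 2 mg/ml), doxycycline alone (0.2, 0.5, 1,
#' 2 ug/ml), doxycycline crossed with 2 mg/ml zeocin, and the untreated
#' control.
#'
#' @return list of [pf_environment()] objects (length 13)
#' @export
landscape_design <- function() {
  envs <- c(list(pf_environment(0, 0)),
            lapply(c(0.5, 1, 1.5, 2), function(z) pf_environment(0, z)),
            lapply(c(0.2, 0.5, 1, 2), function(d) pf_environment(d, 0)),
            lapply(c(0.2, 0.5, 1, 2), function(d) pf_environment(d, 2)))
  stats::setNames(envs, vapply(envs, function(e) e$label, character(1)))
}

#' Generate per-condition expression samples
#'
#' Mixture of two log-normal modes with the On weight set by the two-state
#' model's equilibrium composition in each environment.
#'
#' @param fp a [fitness_params()]
#' @param envs list of environments (default: the 13-condition design)
#' @param config a [synth_config()]
#' @param sw baseline switching parameters
#' @return data.frame `condition_label`, `timepoint_day`,
#'   `log10_fluorescence`
#' @export
gen_expression_samples <- function(fp = fitness_params(),
                                   envs = landscape_design(),
                                   config = synth_config(),
                                   sw = base_switching_params()) {
  set.seed(config$seed + 1L)
  out <- lapply(envs, function(env) {
    w <- equilibrium_on_fraction(
      condition_switching_params(env, fp, sw))$on_fraction
    on <- stats::runif(config$n_cells) < w
    data.frame(condition_label = env$label, timepoint_day = 3,
               log10_fluorescence = stats::rnorm(
                 config$n_cells,
                 mean = ifelse(on, config$on_mean, config$off_mean),
                 sd = config$mode_sd))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Generate growth curves over the condition design
#'
#' Exponential density trajectories at the model's population fitness (the
#' expression-sample average of cellular fitness) with multiplicative
#' lognormal noise, measured every 6 h over 72 h.
#'
#' @param fp a [fitness_params()]
#' @param envs list of environments (default: the 13-condition design)
#' @param config a [synth_config()]
#' @param expr expression samples from [gen_expression_samples()]; generated
#'   on the fly when omitted (same seed convention)
#' @param n_replicates replicate curves per condition
#' @param od0 inoculum density
#' @return data.frame `time_h`, `od`, `dox_ug_ml`, `zeo_mg_ml`, `replicate`
#' @export
gen_growth_curves <- function(fp = fitness_params(),
                              envs = landscape_design(),
                              config = synth_config(),
                              expr = NULL, n_replicates = 1L, od0 = 0.01) {
  if (is.null(expr)) expr <- gen_expression_samples(fp, envs, config)
  set.seed(config$seed + 2L)
  tt <- seq(6, 72, by = 6)
  out <- lapply(envs, function(env) {
    s <- expr$log10_fluorescence[expr$condition_label == env$label]
    rate <- population_fitness(s, env, fp)
    do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      noise <- exp(stats::rnorm(length(tt), 0, config$growth_noise_sd))
      data.frame(time_h = tt, od = od0 * exp(rate * tt) * noise,
                 dox_ug_ml = env$dox, zeo_mg_ml = env$zeo, replicate = rep)
    }))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Generate one flow-cytometry log10-fluorescence sample
#'
#' Bimodal log-normal mixture whose On weight follows the two-state
#' switching model propagated from the all-Off (uninduced) initial state.
#'
#' @param switch_params a fully specified [switching_params()]
#' @param env a [pf_environment()] or DxZy label
#' @param t_h time since induction, hours
#' @param config a [synth_config()]
#' @return numeric vector of `n_cells` log10-fluorescence values, with the
#'   generating On fraction in attribute `"on_fraction"`
#' @export
gen_flow_sample <- function(switch_params, env, t_h,
                            config = synth_config()) {
  env <- as_pf_environment(env)
  set.seed(config$seed + 3L)
  w <- propagate_two_state(c(1, 0), switch_params, t_h,
                           dox = if (is.null(switch_params$r_max)) NULL
                                 else env$dox)$on_fraction
  on <- stats::runif(config$n_cells) < w
  x <- stats::rnorm(config$n_cells,
                    mean = ifelse(on, config$on_mean, config$off_mean),
                    sd = config$mode_sd)
  attr(x, "on_fraction") <- w
  x
}

#' Generate sequencing observations from true allele trajectories
#'
#' Whole-genome frequencies are binomial draws at the configured coverage,
#' per mutation locus and sampled day. Sanger frequencies come from
#' multinomial clone draws over haplotypes (lineages), so linkage is
#' preserved in the clonal genotype table by construction. Haplotypes are
#' ancestral plus single-mutation lineages; a lineage may carry several
#' mutation loci (a linkage group).
#'
#' @param true_traj data.frame `lineage_id`, `day`, `frequency` of true
#'   lineage frequencies (mutant lineages only; the ancestral remainder is
#'   implied)
#' @param haplotypes named list mapping `lineage_id` to the character vector
#'   of allele (locus) ids it carries
#' @param config a [synth_config()]
#' @return list with `observations` (`allele_id`, `day`, `method`,
#'   `frequency`) and `clones` (`clone_id`, `day`, `allele_id`, `present`)
#' @export
gen_sequencing_observations <- function(true_traj, haplotypes,
                                        config = synth_config()) {
  stopifnot(all(true_traj$frequency >= 0), all(true_traj$frequency <= 1))
  set.seed(config$seed + 4L)
  days <- intersect(config$sampled_days, unique(true_traj$day))
  obs <- list(); clones <- list()
  for (d in days) {
    td <- true_traj[true_traj$day == d, ]
    f <- stats::setNames(td$frequency, td$lineage_id)
    f <- f[names(haplotypes)[names(haplotypes) %in% names(f)]]
    ## whole-genome: per locus
    for (ln in names(f)) for (al in haplotypes[[ln]]) {
      obs[[length(obs) + 1L]] <- data.frame(
        allele_id = al, day = d, method = "wgs",
        frequency = stats::rbinom(1L, config$coverage, f[[ln]]) /
          config$coverage)
    }
    ## Sanger: clone draws over haplotypes (+ ancestral remainder)
    p <- c(f, ancestral = max(0, 1 - sum(f)))
    draw <- as.vector(stats::rmultinom(1L, config$n_clones, p))
    names(draw) <- names(p)
    cl_id <- 0L
    for (ln in names(draw)) {
      for (i in seq_len(draw[[ln]])) {
        cl_id <- cl_id + 1L
        carried <- if (ln == "ancestral") character(0) else haplotypes[[ln]]
        all_loci <- unique(unlist(haplotypes))
        clones[[length(clones) + 1L]] <- data.frame(
          clone_id = sprintf("d%g_c%d", d, cl_id), day = d,
          allele_id = all_loci,
          present = as.integer(all_loci %in% carried))
      }
    }
    for (ln in names(f)) for (al in haplotypes[[ln]]) {
      obs[[length(obs) + 1L]] <- data.frame(
        allele_id = al, day = d, method = "sanger",
        frequency = draw[[ln]] / config$n_clones)
    }
    obs[[length(obs) + 1L]] <- data.frame(
      allele_id = "ancestral", day = d, method = "sanger",
      frequency = draw[["ancestral"]] / config$n_clones)
  }
  list(observations = do.call(rbind, obs), clones = do.call(rbind, clones))
}

#' Generate an On-fraction dose-response table
#'
#' On fractions from the two-state model (all-Off start) plus binomial
#' sampling noise at the configured cells per sample.
#'
#' @param switch_params a [switching_params()] with dose-dependent switching
#' @param dox_grid doxycycline concentrations (ug/ml)
#' @param timepoints_h measurement times (hours)
#' @param config a [synth_config()]
#' @return data.frame `time_h`, `dox_ug_ml`, `zeo_mg_ml`, `on_fraction`,
#'   `n_cells`
#' @export
gen_dose_response <- function(switch_params, dox_grid = c(0, 0.2, 0.5, 1, 2),
                              timepoints_h = c(24, 48, 72),
                              config = synth_config()) {
  set.seed(config$seed + 5L)
  grid <- expand.grid(time_h = timepoints_h, dox_ug_ml = dox_grid)
  p <- vapply(seq_len(nrow(grid)), function(i)
    propagate_two_state(c(1, 0), switch_params, grid$time_h[i],
                        dox = grid$dox_ug_ml[i])$on_fraction, numeric(1))
  n <- config$n_cells
  obs <- stats::rbinom(nrow(grid), n, p) / n
  data.frame(grid, zeo_mg_ml = 0, on_fraction = obs, n_cells = n)
}
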