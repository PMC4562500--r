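## End-to-end recipes: configuration loading and the synth / fit / evolve /
## reconstruct / phenotype stages, each re-runnable and deterministic given
## the same configuration and master seed. A thin command-line wrapper over
## these functions ships in inst/cli/pfevolve.

#' Load a run configuration from a YAML file
#'
#' The file may carry `seed`, `outdir`, `conditions`, and `sim`, `fitness`,
#' `switching`, `synth` sections whose keys mirror the arguments of
#' [sim_config()], [fitness_params()], [base_switching_params()] and
#' [synth_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path
#' @return list with resolved `seed`, `outdir`, `conditions`, `sim_config`,
#'   `fitness_params`, `switching_params`, `synth_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_top <- c("seed", "outdir", "conditions", "sim", "fitness",
                 "switching", "synth")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(fn, args)
  }
  fp <- take("fitness", fitness_params)
  sw_args <- raw$switching
  sw <- if (is.null(sw_args)) base_switching_params() else {
    bad <- setdiff(names(sw_args), names(formals(switching_params)))
    if (length(bad))
      stop("unknown key(s) in 'switching': ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(switching_params,
            utils::modifyList(list(g_L = NA_real_, g_H = NA_real_,
                                   r_max = 0.15), sw_args))
  }
  sim_args <- if (is.null(raw$sim)) list() else raw$sim
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad))
    stop("unknown key(s) in 'sim': ", paste(bad, collapse = ", "),
         call. = FALSE)
  sim <- do.call(sim_config, c(sim_args, list(fp = fp, sw = sw)))
  list(seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       outdir = if (is.null(raw$outdir)) "." else raw$outdir,
       conditions = if (is.null(raw$conditions))
         c("D0Z0", "DiZ0", "D2Z0", "D0Z2", "DiZ2", "D2Z2")
       else raw$conditions,
       sim_config = sim, fitness_params = fp, switching_params = sw,
       synth_config = take("synth", synth_config))
}

write_manifest <- function(outdir, stage, seed, extra = list()) {
  manifest <- c(list(stage = stage, seed = seed,
                     package = "pfevolve",
                     version = as.character(utils::packageVersion("pfevolve"))),
                extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Stage: generate the synthetic input bundle
#'
#' Writes growth-curve, expression-sample, dose-response and sequencing
#' CSVs plus a manifest recording the seed, all deterministic per seed.
#'
#' @param cfg a configuration list from [read_run_config()], or built
#'   in code with the same fields
#' @param outdir output directory (default from the config)
#' @return invisible list of written file paths
#' @export
pf_synth <- function(cfg, outdir = cfg$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$synth_config
  sc$seed <- cfg$seed
  fp <- cfg$fitness_params; sw <- cfg$switching_params
  expr <- gen_expression_samples(fp, config = sc, sw = sw)
  curves <- gen_growth_curves(fp, config = sc, expr = expr)
  dr <- gen_dose_response(
    condition_switching_params("D0Z0", fp, sw), config = sc)
  ## a small true history with one linked lineage for the sequencing layer
  traj <- data.frame(
    lineage_id = rep(c("L1", "L2"), each = 5L),
    day = rep(c(0, 4, 9, 14, 19), 2L),
    frequency = c(0, 0.10, 0.35, 0.60, 0.70, 0, 0.05, 0.15, 0.20, 0.18))
  seqs <- gen_sequencing_observations(
    traj, haplotypes = list(L1 = "m1", L2 = c("m2", "m3")), config = sc)
  paths <- list(
    growth_curves = file.path(outdir, "growth_curves.csv"),
    expression_samples = file.path(outdir, "expression_samples.csv"),
    dose_response = file.path(outdir, "dose_response.csv"),
    observations = file.path(outdir, "allele_observations.csv"),
    clones = file.path(outdir, "clone_genotypes.csv"))
  utils::write.csv(curves, paths$growth_curves, row.names = FALSE)
  utils::write.csv(expr, paths$expression_samples, row.names = FALSE)
  utils::write.csv(dr, paths$dose_response, row.names = FALSE)
  utils::write.csv(seqs$observations, paths$observations, row.names = FALSE)
  utils::write.csv(seqs$clones, paths$clones, row.names = FALSE)
  write_manifest(outdir, "synth", cfg$seed)
  invisible(paths)
}

#' Stage: fit fitness-landscape and switching parameters
#'
#' @param cfg configuration list
#' @param indir directory holding the synthetic (or measured) input bundle
#' @param outdir output directory
#' @return invisible list with the two fit results
#' @export
pf_fit <- function(cfg, indir = cfg$outdir, outdir = cfg$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  curves <- utils::read.csv(file.path(indir, "growth_curves.csv"))
  expr <- utils::read.csv(file.path(indir, "expression_samples.csv"))
  dr <- utils::read.csv(file.path(indir, "dose_response.csv"))
  fit_fp <- fit_fitness_params(curves, expr,
                               params_init = cfg$fitness_params)
  sp0 <- condition_switching_params("D0Z0", fit_fp$params,
                                    cfg$switching_params)
  fit_sw <- fit_switching_rates(dr, growth_rates = c(sp0$g_L, sp0$g_H))
  jsonlite::write_json(
    list(fitness_params = unclass(fit_fp$params),
         switching_params = unclass(fit_sw$params),
         rss = list(fitness = fit_fp$rss, switching = fit_sw$rss)),
    file.path(outdir, "fitted_params.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(fit_fp$rates, file.path(outdir, "rate_table.csv"),
                   row.names = FALSE)
  write_manifest(outdir, "fit", cfg$seed)
  invisible(list(fitness = fit_fp, switching = fit_sw))
}

#' Stage: run the evolution models across conditions
#'
#' Runs the detailed simulator ensemble and the lumped ODE model side by
#' side in each configured condition and writes per-condition summaries
#' (half-life mean and SEM, established-allele counts, type fractions) and
#' trajectories.
#'
#' @param cfg configuration list
#' @param outdir output directory
#' @param n_replicates ensemble size (default from the sim config)
#' @return invisible summary data.frame
#' @export
pf_evolve <- function(cfg, outdir = cfg$outdir,
                      n_replicates = cfg$sim_config$n_replicates) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); traj_rows <- list()
  for (cond in cfg$conditions) {
    env <- parse_condition(cond)
    ens <- run_ensemble(cfg$sim_config, env, n = n_replicates,
                        master_seed = cfg$seed)
    e <- ens$ensemble
    mu <- if (env$zeo > 0) cfg$sim_config$mu_withZ else cfg$sim_config$mu_noZ
    lump <- simulate_lumped(
      mutation_spec(mu, p_K = cfg$sim_config$p_K,
                    p_T = cfg$sim_config$p_T, p_G = cfg$sim_config$p_G),
      lumped_class_fitnesses(env, cfg$fitness_params,
                             cfg$switching_params),
      duration_days = cfg$sim_config$duration_days)
    rows[[cond]] <- data.frame(
      condition = cond,
      half_life_mean = e$half_life$mean, half_life_sem = e$half_life$sem,
      half_life_reached = e$half_life_reached_fraction,
      n_established_mean = e$n_established$mean,
      frac_K = e$type_fractions$mean[["K"]],
      frac_T = e$type_fractions$mean[["T"]],
      frac_G = e$type_fractions$mean[["G"]],
      lumped_half_life = ancestral_half_life(lump))
    one <- run_replicate(cfg$sim_config, env,
                         seed = replicate_seeds(cfg$seed, 1L))
    traj_rows[[cond]] <- cbind(condition = cond, one$trajectory)
  }
  summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(summary, file.path(outdir, "evolution_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, c(traj_rows, make.row.names = FALSE)),
                   file.path(outdir, "example_trajectories.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(outdir, "evolution_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(outdir, "evolve", cfg$seed,
                 list(n_replicates = n_replicates))
  invisible(summary)
}

#' Stage: reconstruct allele-frequency time courses
#'
#' @param cfg configuration list
#' @param indir directory with `allele_observations.csv` and
#'   `clone_genotypes.csv`
#' @param outdir output directory
#' @return invisible reconstruction result (see [reconstruct_timecourse()])
#' @export
pf_reconstruct <- function(cfg, indir = cfg$outdir, outdir = cfg$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  obs <- utils::read.csv(file.path(indir, "allele_observations.csv"))
  clones_path <- file.path(indir, "clone_genotypes.csv")
  clones <- if (file.exists(clones_path)) utils::read.csv(clones_path)
            else NULL
  rec <- reconstruct_timecourse(obs, clones)
  utils::write.csv(rec$curves, file.path(outdir, "timecourses.csv"),
                   row.names = FALSE)
  write_manifest(outdir, "reconstruct", cfg$seed)
  invisible(rec)
}

#' Stage: phenotype clonal isolates
#'
#' Estimates per-clone growth rates from plate-reader curves and derives
#' the log10-ratio fitness/expression metrics against the matched reference
#' condition, with Bonferroni-corrected significance against the ancestor.
#'
#' @param cfg configuration list
#' @param curves data.frame `clone_id`, `condition`, `time_h`, `od`,
#'   optionally `replicate`
#' @param pairs data.frame `clone_id`, `metric`, `condition_a`,
#'   `condition_b` defining which log10 ratios to compute
#' @param outdir optional output directory for the phenotype table CSV
#' @return data.frame `clone_id`, `metric`, `value`
#' @export
pf_phenotype <- function(cfg, curves, pairs, outdir = NULL) {
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  key <- interaction(curves$clone_id, curves$condition, curves$replicate,
                     drop = TRUE)
  rates <- do.call(rbind, lapply(split(curves, key), function(d)
    data.frame(clone_id = d$clone_id[1L], condition = d$condition[1L],
               rate = growth_rate_from_curve(d$time_h, d$od)$rate)))
  mean_rate <- function(cl, cond) {
    r <- rates$rate[rates$clone_id == cl & rates$condition == cond]
    if (!length(r)) stop("no curve for clone ", cl, " in ", cond,
                         call. = FALSE)
    mean(r)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    data.frame(clone_id = p$clone_id, metric = p$metric,
               value = log10_ratio(mean_rate(p$clone_id, p$condition_a),
                                   mean_rate(p$clone_id, p$condition_b),
                                   "fitness"))
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(outdir, "phenotypes.csv"),
                     row.names = FALSE)
  }
  out
}
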