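## Shared circuit-level defaults: the bimodal expression distribution and
## the baseline dose-dependent switching of the PF circuit. The Off and On
## modes sit two decades apart on the log10 fluorescence scale.

OFF_MODE_LOG10 <- 1.0
ON_MODE_LOG10 <- 3.0
MODE_SD_LOG10 <- 0.25

#' Baseline dose-dependent switching of the ancestral circuit
#'
#' Off-to-On switching is doxycycline-driven with a steep Hill dose
#' response; the On-to-Off (memory loss) rate is small and constant, giving
#' the circuit strong cellular memory.
#'
#' @return a [switching_params()] carrying only the switching side
#'   (growth rates are filled in per condition by
#'   [condition_switching_params()])
#' @export
base_switching_params <- function() {
  switching_params(g_L = NA_real_, g_H = NA_real_, r = NA_real_, f = 0.005,
                   r_max = 0.15, K_r = 0.51, n_r = 2)
}

#' Two-state parameters for a condition, derived from the fitness landscape
#'
#' Evaluates the Off- and On-state division rates at the expression modes
#' (`log10 F` = 1 and 3 by default) under the given environment, and the
#' Off-to-On rate at the environment's doxycycline level.
#'
#' @param env a [pf_environment()] or DxZy label
#' @param fp a [fitness_params()] object
#' @param sw baseline switching parameters ([base_switching_params()])
#' @param off_log10,on_log10 expression modes on the log10 scale
#' @return a fully specified [switching_params()]
#' @export
condition_switching_params <- function(env, fp = fitness_params(),
                                       sw = base_switching_params(),
                                       off_log10 = OFF_MODE_LOG10,
                                       on_log10 = ON_MODE_LOG10) {
  env <- as_pf_environment(env)
  g_L <- cellular_fitness(10^off_log10, env, fp)
  g_H <- cellular_fitness(10^on_log10, env, fp)
  switching_params(g_L = g_L, g_H = g_H,
                   r = switch_rate_on(sw, env$dox),
                   f = sw$f,
                   r_max = sw$r_max, K_r = sw$K_r, n_r = sw$n_r)
}
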