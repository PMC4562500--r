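#' Beneficial-mutation rate and type probabilities
#'
#' @param mu beneficial-mutation rate per genome per generation
#' @param p_K,p_T,p_G probabilities of a mutation being knockout, tweaking
#'   or generic; must sum to 1. The normalization identity
#'   `p_K = 1 - p_G - p_T` holds by construction when `p_K` is omitted.
#' @return an object of class `mutation_spec`
#' @examples
#' mutation_spec(10^-6.2, p_T = 0.025, p_G = 0.75)$p_K  # 0.225
#' @export
mutation_spec <- function(mu, p_K = NULL, p_T = 0.025, p_G = 0.75) {
  if (is.null(p_K)) p_K <- 1 - p_G - p_T
  p <- c(p_K, p_T, p_G)
  if (mu < 0 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12)
    stop("mu must be >= 0 and (p_K, p_T, p_G) must be probabilities ",
         "summing to 1", call. = FALSE)
  structure(list(mu = mu, p_K = p_K, p_T = p_T, p_G = p_G),
            class = "mutation_spec")
}

#' Fitness of a lumped mutant class
#'
#' Class-level division rates on the cellular fitness landscape:
#' * `ancestral` - the long-run growth rate of the intact two-state circuit
#'   (dominant eigenvalue of its growth/switching matrix);
#' * `K` (knockout) - fitness at the null-expression end of the landscape,
#'   deterministic;
#' * `T` (tweaking) - fitness at an intermediate expression level, uniform
#'   in log10 F between the Off and On modes (draw or expectation);
#' * `G` (generic resistance) - fitness uniform between the ancestral level
#'   and the level the same genotype would have without zeocin (draw or
#'   expectation).
#'
#' @param mut_type one of `"ancestral"`, `"K"`, `"T"`, `"G"`
#' @param env a [pf_environment()] or DxZy label
#' @param fp a [fitness_params()] object
#' @param sw baseline switching parameters (for the ancestral growth rate)
#' @param expectation if `TRUE` (default) return the expected class fitness;
#'   otherwise return `n` random draws
#' @param n number of draws when `expectation = FALSE`
#' @return division rate(s), per hour, all `<= gamma0`
#' @export
class_fitness <- function(mut_type = c("ancestral", "K", "T", "G"), env,
                          fp = fitness_params(),
                          sw = base_switching_params(),
                          expectation = TRUE, n = 1L) {
  mut_type <- match.arg(mut_type)
  env <- as_pf_environment(env)
  ## long-run ancestral growth from the uninduced (all-Off) start: the
  ## dominant eigenvalue, except that with r = 0 the On state is never
  ## reached and growth stays at g_L
  anc <- function(e) {
    sp <- condition_switching_params(e, fp, sw)
    if (sp$r == 0) sp$g_L else equilibrium_on_fraction(sp)$growth_rate
  }
  switch(mut_type,
    ancestral = anc(env),
    K = cellular_fitness(1, env, fp),  # lowest point of the log10 [0,4] grid
    T = {
      if (expectation) {
        u <- seq(OFF_MODE_LOG10, ON_MODE_LOG10, length.out = 513L)
        mean(cellular_fitness(10^u, env, fp))
      } else {
        u <- stats::runif(n, OFF_MODE_LOG10, ON_MODE_LOG10)
        cellular_fitness(10^u, env, fp)
      }
    },
    G = {
      lo <- anc(env)
      hi <- anc(pf_environment(env$dox, 0))
      hi <- max(hi, lo)
      if (expectation) (lo + hi) / 2 else stats::runif(n, lo, hi)
    })
}

#' Expected class fitnesses for a condition
#'
#' @inheritParams class_fitness
#' @return named numeric vector `c(ancestral, K, T, G)` of per-hour rates
#' @export
lumped_class_fitnesses <- function(env, fp = fitness_params(),
                                   sw = base_switching_params()) {
  vapply(c("ancestral", "K", "T", "G"), class_fitness, numeric(1),
         env = env, fp = fp, sw = sw)
}

#' Constant-population-size ODE model of the first evolutionary steps
#'
#' Integrates the replicator-with-mutation dynamics of the ancestral class
#' and the lumped K/T/G mutant classes, each characterized by a single
#' fitness:
#' \deqn{dx_i/dt = (\gamma_i - \bar\gamma(t))\,x_i + \mu_h p_i x_{anc}}
#' for the mutant classes, with the matching loss term for the ancestral
#' class. \eqn{\bar\gamma} is the population mean fitness (which keeps the
#' fractions summing to one), and the per-generation mutation rate is
#' converted to per-hour via the ancestral division rate
#' (\eqn{\mu_h = \mu\,\gamma_{anc}/\ln 2}). Mutant classes are seeded by the
#' continuous mutational influx only; they neither back-mutate nor mutate
#' further.
#'
#' @param spec a [mutation_spec()]
#' @param fitnesses named vector `c(ancestral, K, T, G)` of per-hour rates,
#'   e.g. from [lumped_class_fitnesses()]
#' @param duration_days length of the simulated evolution (days)
#' @param dt_out output grid spacing in hours (default 1)
#' @param x0 initial fractions (default: all ancestral)
#' @return data.frame with columns `time_day`, `x_anc`, `x_K`, `x_T`, `x_G`
#' @export
simulate_lumped <- function(spec, fitnesses, duration_days = 20,
                            dt_out = 1,
                            x0 = c(x_anc = 1, x_K = 0, x_T = 0, x_G = 0)) {
  if (duration_days <= 0) stop("'duration_days' must be > 0", call. = FALSE)
  stopifnot(all(c("ancestral", "K", "T", "G") %in% names(fitnesses)))
  gam <- unname(fitnesses[c("ancestral", "K", "T", "G")])
  mu_h <- spec$mu * fitnesses[["ancestral"]] / log(2)
  p <- c(spec$p_K, spec$p_T, spec$p_G)
  rhs <- function(t, x, parms) {
    gbar <- sum(gam * x)
    dx <- (gam - gbar) * x
    influx <- mu_h * p * x[1L]
    dx[1L] <- dx[1L] - sum(influx)
    dx[2:4] <- dx[2:4] + influx
    list(dx)
  }
  times <- seq(0, duration_days * 24, by = dt_out)
  sol <- deSolve::ode(y = unname(x0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0)
    stop("lumped-model integration failed", call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time_h", "x_anc", "x_K", "x_T", "x_G")
  ## guard tiny negative round-off and renormalize within tolerance
  xs <- as.matrix(out[, -1L])
  xs[xs < 0 & xs > -1e-12] <- 0
  out[, -1L] <- xs / rowSums(xs)
  data.frame(time_day = out$time_h / 24,
             out[, c("x_anc", "x_K", "x_T", "x_G")])
}

#' Half-life of the ancestral genotype
#'
#' Time until only 50 percent of the population still carries the ancestral
#' genome: the first downward crossing of the ancestral fraction below 0.5,
#' linearly interpolated between output times. `Inf` is returned as the
#' "not reached" sentinel.
#'
#' @param trajectory data.frame with columns `time_day` and `x_anc` (e.g.
#'   from [simulate_lumped()] or the detailed simulator)
#' @return half-life in days, or `Inf` when the ancestral fraction never
#'   drops below 0.5
#' @export
ancestral_half_life <- function(trajectory) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0L ||
      !all(c("time_day", "x_anc") %in% names(trajectory)))
    stop("trajectory must be a non-empty data.frame with time_day, x_anc",
         call. = FALSE)
  t <- trajectory$time_day; x <- trajectory$x_anc
  below <- which(x < 0.5)
  if (!length(below)) return(Inf)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (0.5 - x[i - 1L]) / (x[i] - x[i - 1L]) * (t[i] - t[i - 1L])
}
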