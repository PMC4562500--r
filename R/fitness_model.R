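#' Parameters of the cellular fitness model
#'
#' The division rate of a single cell with total yEGFP::ZeoR expression `F`
#' (arbitrary fluorescence units, linear scale) in environment `(C, Z)`
#' (doxycycline ug/ml, zeocin mg/ml) is modeled as
#' \deqn{\gamma = \gamma_0\,\gamma_1(F, Z)\,\gamma_2(F, C)}
#' where \eqn{\gamma_1 = 1/(1 + (Z_i/K_z)^{h_z})} is the zeocin survival
#' factor evaluated at the steady-state free internal zeocin \eqn{Z_i} of the
#' uptake/binding submodel (see [bound_zeocin_steady_state()]), and
#' \eqn{\gamma_2 = 1/(1 + (F\,C/(C + K_C)/K_d)^{h_d})} is the activator
#' (rtTA squelching) toxicity factor, with rtTA level taken proportional to
#' `F` and loaded by doxycycline through \eqn{C/(C+K_C)}.
#'
#' The binding submodel tracks internal free zeocin `Z_i`, bound complex `B`
#' and free protein `R = F - B`:
#' \deqn{dZ_i/dt = k_{in} Z - k_{out} Z_i - k_{on} Z_i R + k_{off} B}
#' \deqn{dB/dt = k_{on} Z_i R - k_{off} B - k_{deg} B}
#' The clearance `k_deg` of the bound complex represents destruction of
#' sequestered zeocin upon complex turnover; it is what makes protection
#' increase with expression `F`.
#'
#' Defaults are calibrated so that the six study conditions reproduce the
#' canonical landscape shapes: monotone decreasing in expression for
#' D2Z0/DiZ0, monotone increasing for D0Z2, and an interior fitness peak for
#' DiZ2/D2Z2.
#'
#' @param gamma0 maximal division rate (per hour)
#' @param k_in,k_out zeocin uptake and clearance rates (per hour)
#' @param k_on,k_off binding on/off rates (per hour, per concentration unit)
#' @param k_deg bound-complex clearance rate (per hour)
#' @param K_z kill constant: free internal zeocin at half-maximal kill
#' @param h_z Hill coefficient of the zeocin kill term (>= 1)
#' @param K_C doxycycline half-saturation of rtTA loading (ug/ml)
#' @param K_d toxicity constant for dox-loaded rtTA (expression units)
#' @param h_d Hill coefficient of the toxicity term (>= 1)
#' @return an object of class `fitness_params`
#' @export
fitness_params <- function(gamma0 = 0.45,
                           k_in = 1, k_out = 1,
                           k_on = 1, k_off = 0.1, k_deg = 0.02,
                           K_z = 0.3, h_z = 2,
                           K_C = 0.15, K_d = 1140, h_d = 2) {
  p <- list(gamma0 = gamma0, k_in = k_in, k_out = k_out, k_on = k_on,
            k_off = k_off, k_deg = k_deg, K_z = K_z, h_z = h_z,
            K_C = K_C, K_d = K_d, h_d = h_d)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("fitness parameters must be single positive finite numbers; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (h_z < 1 || h_d < 1)
    stop("Hill coefficients h_z and h_d must be >= 1", call. = FALSE)
  structure(p, class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat("<fitness_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

check_FZ <- function(F, Z) {
  if (!is.numeric(F) || !is.numeric(Z) || anyNA(F) || anyNA(Z) ||
      any(!is.finite(F)) || any(!is.finite(Z)))
    stop("expression and drug concentrations must be finite numbers",
         call. = FALSE)
  if (any(F < 0) || any(Z < 0))
    stop("expression and drug concentrations must be non-negative",
         call. = FALSE)
}

#' Steady state of the zeocin uptake/binding submodel
#'
#' Solves the joint steady state of internal free zeocin and bound complex
#' for total protein `F` and external zeocin `Z`. The steady state reduces
#' to a quadratic in the free internal zeocin; the unique non-negative root
#' is returned (the root product is `<= 0`, so exactly one root is
#' non-negative).
#'
#' @param F total yEGFP::ZeoR level (protein units, >= 0); vectorized
#' @param Z external zeocin (mg/ml, >= 0)
#' @param params a [fitness_params()] object
#' @return a data.frame with columns `Z_ext`, `Z_int` (free internal
#'   zeocin), `B` (bound complex), `R` (free protein) and `F`; one row per
#'   input `F`/`Z` pair
#' @examples
#' bound_zeocin_steady_state(100, 2, fitness_params())
#' @export
bound_zeocin_steady_state <- function(F, Z, params = fitness_params()) {
  check_FZ(F, Z)
  n <- max(length(F), length(Z))
  F <- rep_len(F, n); Z <- rep_len(Z, n)
  Zi <- zeocin_free_internal(F, Z, params)
  Km <- (params$k_off + params$k_deg) / params$k_on
  B <- F * Zi / (Zi + Km)
  B[Zi == 0] <- 0
  data.frame(Z_ext = Z, Z_int = Zi, B = B, R = F - B, F = F)
}

## unique non-negative root of
##   k_out Zi^2 + (k_out Km + k_deg F - k_in Z) Zi - k_in Z Km = 0
zeocin_free_internal <- function(F, Z, params) {
  Km <- (params$k_off + params$k_deg) / params$k_on
  a <- params$k_out
  b <- params$k_out * Km + params$k_deg * F - params$k_in * Z
  cc <- -params$k_in * Z * Km
  disc <- sqrt(b * b - 4 * a * cc)
  ## numerically stable positive root
  Zi <- ifelse(b <= 0, (-b + disc) / (2 * a), -2 * cc / (b + disc))
  pmax(Zi, 0)
}

#' Zeocin survival factor of cellular fitness
#'
#' \eqn{\gamma_1 \in (0, 1]}: 1 with no zeocin, non-increasing in zeocin,
#' non-decreasing in expression (more ZeoR sequesters more internal zeocin).
#'
#' @inheritParams bound_zeocin_steady_state
#' @param kz_multiplier scaling of the kill constant `K_z` (>= 1 for
#'   generic-resistance mutants; default 1)
#' @return numeric vector of survival factors in (0, 1]
#' @export
gamma_zeocin <- function(F, Z, params = fitness_params(), kz_multiplier = 1) {
  check_FZ(F, Z)
  Zi <- zeocin_free_internal(F, Z, params)
  1 / (1 + (Zi / (params$K_z * kz_multiplier))^params$h_z)
}

#' Doxycycline (rtTA squelching) toxicity factor of cellular fitness
#'
#' \eqn{\gamma_2 \in (0, 1]}: 1 with no doxycycline or no expression,
#' non-increasing in both the inducer and the expression level.
#'
#' @param F expression level (protein units, >= 0); proxies the rtTA level
#' @param C doxycycline concentration (ug/ml, >= 0)
#' @param params a [fitness_params()] object
#' @return numeric vector of toxicity factors in (0, 1]
#' @export
gamma_dox <- function(F, C, params = fitness_params()) {
  check_FZ(F, C)
  load <- F * C / (C + params$K_C)
  1 / (1 + (load / params$K_d)^params$h_d)
}

## core rate used everywhere: division rate at expression F under effective
## drug levels (C, Z), with optional resistance scaling of K_z
gamma_total <- function(F, C, Z, params, kz_multiplier = 1) {
  params$gamma0 *
    gamma_zeocin(F, Z, params, kz_multiplier) *
    gamma_dox(F, C, params)
}

#' Cellular fitness: division rate of a single cell
#'
#' Returns \eqn{\gamma_0 \gamma_1 \gamma_2} at expression `F` in the given
#' environment. Equals `gamma0` everywhere in D0Z0.
#'
#' @param F expression level(s), linear fluorescence units
#' @param env a [pf_environment()] or a DxZy label
#' @param params a [fitness_params()] object
#' @return division rate(s), per hour, in `[0, gamma0]`
#' @examples
#' cellular_fitness(10^seq(0, 4, length.out = 5), "D2Z2")
#' @export
cellular_fitness <- function(F, env, params = fitness_params()) {
  env <- as_pf_environment(env)
  gamma_total(F, env$dox, env$zeo, params)
}

#' Cellular fitness landscape over a log10-expression grid
#'
#' @param env a [pf_environment()] or DxZy label
#' @param params a [fitness_params()] object
#' @param log10_range range of log10 fluorescence (default `c(0, 4)`)
#' @param n grid size (default 201)
#' @return data.frame with columns `condition`, `log10_F`, `fitness_per_h`
#' @export
cellular_landscape <- function(env, params = fitness_params(),
                               log10_range = c(0, 4), n = 201L) {
  env <- as_pf_environment(env)
  lg <- seq(log10_range[1], log10_range[2], length.out = n)
  data.frame(condition = env$label, log10_F = lg,
             fitness_per_h = cellular_fitness(10^lg, env, params))
}

#' Population fitness: expression-distribution average of cellular fitness
#'
#' The population growth rate is the arithmetic mean of cellular fitness
#' over a sample of single-cell log10-fluorescence values, so it is linear
#' in mixture weights and equals the cellular fitness for a point mass.
#'
#' @param expr_sample numeric vector of log10 fluorescence values (non-empty)
#' @param env a [pf_environment()] or DxZy label
#' @param params a [fitness_params()] object
#' @return mean division rate, per hour
#' @export
population_fitness <- function(expr_sample, env, params = fitness_params()) {
  if (!is.numeric(expr_sample) || length(expr_sample) == 0L ||
      anyNA(expr_sample))
    stop("'expr_sample' must be a non-empty numeric vector of log10 values",
         call. = FALSE)
  mean(cellular_fitness(10^expr_sample, env, params))
}

#' Fit fitness-landscape parameters from growth curves
#'
#' Two-stage fit: a population growth rate is first extracted per condition
#' from the density time series (log-linear sliding-window regression, see
#' [growth_rate_from_curve()]), then the landscape parameters are estimated
#' by weighted least squares between those observed rates and the
#' model-predicted population fitness, using the per-condition expression
#' samples to average the cellular landscape. Optimization uses bounded
#' Levenberg-Marquardt least squares on log-transformed parameters with a
#' fixed grid of multi-starts, so the result is deterministic.
#'
#' @param curves data.frame with columns `time_h`, `od` (or `cell_count`),
#'   `dox_ug_ml`, `zeo_mg_ml` and optionally `replicate`
#' @param expr per-condition expression samples: data.frame with columns
#'   `condition_label` and `log10_fluorescence`
#' @param params_init starting [fitness_params()]; fixed parameters keep
#'   these values
#' @param free character vector of parameter names to estimate
#' @param n_starts number of multi-starts (fixed log-scale perturbations)
#' @return list with elements `params` (fitted [fitness_params()]),
#'   `rates` (per-condition observed vs fitted rate table), `rss`,
#'   `diagnostics` (identifiability flags, convergence info)
#' @export
fit_fitness_params <- function(curves, expr,
                               params_init = fitness_params(),
                               free = c("gamma0", "K_z", "h_z", "K_d", "h_d"),
                               n_starts = 8L) {
  stopifnot(is.data.frame(curves), is.data.frame(expr))
  dens_col <- if ("od" %in% names(curves)) "od" else "cell_count"
  need <- c("time_h", dens_col, "dox_ug_ml", "zeo_mg_ml")
  if (!all(need %in% names(curves)))
    stop("'curves' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("condition_label", "log10_fluorescence") %in% names(expr)))
    stop("'expr' must have columns condition_label, log10_fluorescence",
         call. = FALSE)
  if (length(unique(curves$zeo_mg_ml)) < 2L ||
      length(unique(curves$dox_ug_ml)) < 2L)
    stop("degenerate design: need >= 2 distinct zeocin and >= 2 distinct ",
         "doxycycline levels", call. = FALSE)

  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  key <- interaction(curves$dox_ug_ml, curves$zeo_mg_ml, curves$replicate,
                     drop = TRUE)
  per_rep <- lapply(split(curves, key), function(d) {
    fit <- growth_rate_from_curve(d$time_h, d[[dens_col]])
    data.frame(dox = d$dox_ug_ml[1L], zeo = d$zeo_mg_ml[1L],
               rate = fit$rate)
  })
  per_rep <- do.call(rbind, per_rep)
  agg <- stats::aggregate(rate ~ dox + zeo, data = per_rep, FUN = mean)
  nrep <- stats::aggregate(rate ~ dox + zeo, data = per_rep, FUN = length)
  agg$n_rep <- nrep$rate
  agg$condition <- mapply(condition_label, agg$dox, agg$zeo)

  samples <- split(expr$log10_fluorescence, expr$condition_label)
  missing_expr <- setdiff(agg$condition, names(samples))
  if (length(missing_expr))
    stop("no expression sample for condition(s): ",
         paste(missing_expr, collapse = ", "), call. = FALSE)

  predict_rates <- function(p) {
    vapply(seq_len(nrow(agg)), function(i) {
      Fv <- 10^samples[[agg$condition[i]]]
      mean(gamma_total(Fv, agg$dox[i], agg$zeo[i], p))
    }, numeric(1))
  }

  zeocin_pars <- c("k_in", "k_out", "k_on", "k_off", "k_deg", "K_z", "h_z")
  dox_pars <- c("K_C", "K_d", "h_d")
  diagnostics <- list(
    unidentifiable = character(0),
    converged = NA, n_conditions = nrow(agg))
  if (all(agg$zeo == 0) && any(free %in% zeocin_pars)) {
    diagnostics$unidentifiable <-
      c(diagnostics$unidentifiable, intersect(free, zeocin_pars))
  }
  if (all(agg$dox == 0) && any(free %in% dox_pars)) {
    diagnostics$unidentifiable <-
      c(diagnostics$unidentifiable, intersect(free, dox_pars))
  }
  free_eff <- setdiff(free, diagnostics$unidentifiable)

  p0 <- unlist(unclass(params_init))[free_eff]
  make_params <- function(logtheta) {
    p <- unclass(params_init)
    p[free_eff] <- exp(logtheta)
    class(p) <- "fitness_params"
    p
  }
  w <- sqrt(agg$n_rep)
  resid_fn <- function(logtheta) {
    p <- make_params(logtheta)
    w * (agg$rate - predict_rates(p))
  }

  if (length(free_eff)) {
    ## fixed multi-start scalings around the initial values
    scales <- c(1, 0.5, 2, 0.25, 4, 0.8, 1.25, 8)[seq_len(n_starts)]
    best <- NULL
    for (s in scales) {
      start <- log(p0 * s)
      fit <- try(minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best))
      stop("landscape optimization failed for all starts", call. = FALSE)
    params_hat <- make_params(best$par)
    diagnostics$converged <- best$info %in% 1:4
    diagnostics$deviance <- best$deviance
  } else {
    params_hat <- params_init
    diagnostics$converged <- NA
  }

  agg$fitted <- predict_rates(params_hat)
  list(params = params_hat,
       rates = agg[, c("condition", "dox", "zeo", "rate", "fitted", "n_rep")],
       rss = sum((agg$rate - agg$fitted)^2),
       diagnostics = diagnostics)
}
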