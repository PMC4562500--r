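#' Parameters of the two-state growth-and-switching model
#'
#' The bistable circuit's population composition is coarse-grained to an Off
#' (low expression) and an On (high expression) state:
#' \deqn{dn_L/dt = (g_L - r)\,n_L + f\,n_H}
#' \deqn{dn_H/dt = r\,n_L + (g_H - f)\,n_H}
#' with state-specific division rates `g_L`, `g_H` and switching rates `r`
#' (Off to On) and `f` (On to Off, "cellular memory"). The Off-to-On rate is
#' doxycycline-driven; when the dose-dependence parameters are supplied,
#' `r(C) = r_max C^n / (C^n + K^n)` and the scalar `r` is ignored.
#'
#' @param g_L,g_H Off/On division rates (per hour)
#' @param r Off-to-On switching rate (per hour); used when no dose
#'   dependence is given
#' @param f On-to-Off switching rate (per hour)
#' @param r_max,K_r,n_r optional Hill dose dependence of `r` on doxycycline
#' @return an object of class `switching_params`
#' @export
switching_params <- function(g_L = 0.45, g_H = 0.32, r = 0.15, f = 0.005,
                             r_max = NULL, K_r = 0.4, n_r = 4) {
  g <- c(g_L, g_H)
  if (any(!is.na(g) & !is.finite(g)))
    stop("growth rates g_L, g_H must be finite (NA allowed as placeholder)",
         call. = FALSE)
  if ((!is.na(r) && r < 0) || f < 0)
    stop("switching rates r, f must be >= 0", call. = FALSE)
  if (!is.null(r_max) && (r_max < 0 || K_r <= 0 || n_r <= 0))
    stop("dose-dependence parameters must be positive", call. = FALSE)
  structure(list(g_L = g_L, g_H = g_H, r = r, f = f,
                 r_max = r_max, K_r = K_r, n_r = n_r),
            class = "switching_params")
}

#' Doxycycline-dependent Off-to-On switching rate
#'
#' @param params a [switching_params()] object
#' @param C doxycycline concentration (ug/ml)
#' @return switching rate (per hour); the constant `r` when no dose
#'   dependence is configured
#' @export
switch_rate_on <- function(params, C) {
  if (is.null(params$r_max)) return(rep_len(params$r, length(C)))
  Cn <- C^params$n_r
  params$r_max * Cn / (Cn + params$K_r^params$n_r)
}

## pick the Off-to-On rate: an explicit dose wins; otherwise the resolved
## scalar r must be present
resolve_r <- function(params, dox) {
  if (!is.null(dox)) return(switch_rate_on(params, dox))
  if (is.na(params$r))
    stop("dose-dependent switching configured; supply 'dox'", call. = FALSE)
  params$r
}

## rate matrix of the two-state linear system
two_state_matrix <- function(g_L, g_H, r, f) {
  matrix(c(g_L - r, r, f, g_H - f), nrow = 2L)
}

## closed-form exp(A t) for a 2x2 matrix via eigen-decomposition with a
## series fallback when the eigenvalue gap is numerically degenerate
expm_2x2 <- function(A, t) {
  tr <- A[1L, 1L] + A[2L, 2L]
  det <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  disc <- tr * tr / 4 - det
  mu <- tr / 2
  scale <- max(abs(A)) + 1e-300
  if (disc > (1e-12 * scale)^2) {
    d <- sqrt(disc)
    l1 <- mu + d; l2 <- mu - d
    ## exp(At) = e2 I + (e1 - e2)/(l1 - l2) (A - l2 I) ... symmetric form
    e1 <- exp(l1 * t); e2 <- exp(l2 * t)
    c0 <- (l1 * e2 - l2 * e1) / (l1 - l2)
    c1 <- (e1 - e2) / (l1 - l2)
    M <- c1 * A
    M[1L, 1L] <- M[1L, 1L] + c0
    M[2L, 2L] <- M[2L, 2L] + c0
    M
  } else {
    ## nearly defective: exp(At) = e^{mu t} (I + (A - mu I) t) + O(disc t^2),
    ## refined by scaling and squaring of the quadratic Taylor term
    N <- A
    N[1L, 1L] <- N[1L, 1L] - mu
    N[2L, 2L] <- N[2L, 2L] - mu
    k <- max(0L, ceiling(log2(max(1, abs(t) * scale))) + 8L)
    h <- t / 2^k
    M <- diag(2L) + N * h + N %*% N * (h * h / 2)
    for (i in seq_len(k)) M <- M %*% M
    exp(mu * t) * M
  }
}

#' Propagate Off/On cell counts through the two-state linear model
#'
#' Advances counts by the exact matrix exponential of the rate matrix, so
#' propagation satisfies the semigroup property: two steps of `dt/2` equal
#' one step of `dt`.
#'
#' @param state numeric vector `c(n_L, n_H)` or a list with fields `n_L`,
#'   `n_H`
#' @param params a [switching_params()] object
#' @param dt time step in hours (>= 0)
#' @param dox optional doxycycline concentration; when given and the
#'   parameters carry a dose dependence, `r = r(dox)`
#' @return list with `n_L`, `n_H` and `on_fraction`
#' @export
propagate_two_state <- function(state, params, dt, dox = NULL) {
  n <- if (is.list(state)) c(state$n_L, state$n_H) else state
  if (length(n) != 2L || anyNA(n) || any(n < 0))
    stop("state must hold two non-negative counts (n_L, n_H)", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("'dt' must be a single non-negative number of hours", call. = FALSE)
  r <- resolve_r(params, dox)
  A <- two_state_matrix(params$g_L, params$g_H, r, params$f)
  ## spectral form with the dominant growth factored out, so the
  ## composition stays finite at any horizon even when the total count
  ## overflows double precision
  tr <- A[1L, 1L] + A[2L, 2L]
  det <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  disc <- tr * tr / 4 - det
  scale <- max(abs(A)) + 1e-300
  if (disc > (1e-12 * scale)^2) {
    d <- sqrt(disc)
    l1 <- tr / 2 + d; l2 <- tr / 2 - d
    ## projectors: P1 = (A - l2 I)/(l1 - l2), P2 = I - P1
    P1 <- (A - diag(l2, 2L)) / (l1 - l2)
    v <- pmax(as.vector(P1 %*% n + exp((l2 - l1) * dt) *
                          ((diag(2L) - P1) %*% n)), 0)
    out <- exp(l1 * dt) * v
  } else {
    out <- pmax(as.vector(expm_2x2(A, dt) %*% n), 0)
    v <- out
  }
  tot <- sum(v)
  list(n_L = out[1L], n_H = out[2L],
       on_fraction = if (tot > 0) v[2L] / tot else NA_real_)
}

#' Long-time On fraction of the two-state model
#'
#' The asymptotic composition is the dominant-eigenvalue eigenvector of the
#' rate matrix, normalized to a fraction. When the two eigenvalues tie to
#' numerical precision the limit of a long propagation is returned and the
#' result is flagged degenerate.
#'
#' @inheritParams propagate_two_state
#' @return list with `on_fraction`, `growth_rate` (dominant eigenvalue) and
#'   `degenerate` flag
#' @export
equilibrium_on_fraction <- function(params, dox = NULL) {
  r <- resolve_r(params, dox)
  A <- two_state_matrix(params$g_L, params$g_H, r, params$f)
  ev <- eigen(A)
  gap <- abs(ev$values[1L] - ev$values[2L])
  if (gap <= 1e-12 * max(1, abs(ev$values[1L]))) {
    st <- propagate_two_state(c(0.5, 0.5), params, 5000, dox = dox)
    return(list(on_fraction = st$on_fraction,
                growth_rate = Re(ev$values[1L]), degenerate = TRUE))
  }
  i <- which.max(Re(ev$values))
  v <- abs(Re(ev$vectors[, i]))
  list(on_fraction = v[2L] / sum(v), growth_rate = Re(ev$values[i]),
       degenerate = FALSE)
}

#' Infer switching rates from On-fraction dose-response series
#'
#' Fits the Hill dose dependence of the Off-to-On rate (`r_max`, `K_r`) and
#' the On-to-Off memory rate `f` to observed On fractions over time and
#' doxycycline dose, by bounded Levenberg-Marquardt least squares on
#' log-transformed parameters with fixed multi-starts. Cultures are assumed
#' to start all-Off (uninduced), matching the dose-response protocol.
#'
#' @param on_fraction_series data.frame with columns `time_h`, `dox_ug_ml`,
#'   `on_fraction` and optionally `n_cells` (binomial weights)
#' @param growth_rates numeric `c(g_L, g_H)` Off/On division rates (per
#'   hour), supplied from independent growth measurements
#' @param n_r Hill coefficient of the dose response (fixed, default 4)
#' @param params_init starting values for `(r_max, K_r, f)`
#' @param n_starts number of fixed multi-starts
#' @return list with `params` (a [switching_params()] with dose dependence),
#'   `rss`, and `diagnostics` (identifiability flags)
#' @export
fit_switching_rates <- function(on_fraction_series, growth_rates,
                                n_r = 2,
                                params_init = c(r_max = 0.1, K_r = 0.5,
                                                f = 0.005),
                                n_starts = 8L) {
  d <- on_fraction_series
  need <- c("time_h", "dox_ug_ml", "on_fraction")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stop("'on_fraction_series' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(d$time_h)) < 3L && length(unique(d$dox_ug_ml)) < 3L)
    stop("need >= 3 timepoints or >= 3 dose levels", call. = FALSE)
  if (all(d$on_fraction == 0) || all(d$on_fraction == 1))
    stop("identifiability error: all On fractions are ",
         d$on_fraction[1L], call. = FALSE)
  w <- if ("n_cells" %in% names(d)) sqrt(d$n_cells / max(d$n_cells)) else
    rep(1, nrow(d))

  diagnostics <- list(identifiable = TRUE, note = NULL)
  if (length(unique(d$time_h)) == 1L) {
    diagnostics$identifiable <- FALSE
    diagnostics$note <-
      "single timepoint: only the r/f balance is identifiable"
  }

  g_L <- growth_rates[[1L]]; g_H <- growth_rates[[2L]]
  predict_on <- function(r_max, K_r, f) {
    sp <- switching_params(g_L, g_H, f = f, r_max = r_max, K_r = K_r,
                           n_r = n_r)
    vapply(seq_len(nrow(d)), function(i) {
      propagate_two_state(c(1, 0), sp, d$time_h[i],
                          dox = d$dox_ug_ml[i])$on_fraction
    }, numeric(1))
  }
  resid_fn <- function(logtheta) {
    th <- exp(logtheta)
    w * (d$on_fraction - predict_on(th[1L], th[2L], th[3L]))
  }

  scales <- c(1, 0.5, 2, 0.25, 4, 0.8, 1.25, 8)[seq_len(n_starts)]
  best <- NULL
  for (s in scales) {
    fit <- try(minpack.lm::nls.lm(
      par = log(params_init * s), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("switching-rate optimization failed for all starts", call. = FALSE)
  th <- exp(best$par)
  list(params = switching_params(g_L, g_H, f = th[3L], r_max = th[1L],
                                 K_r = th[2L], n_r = n_r),
       rss = best$deviance,
       diagnostics = c(diagnostics, converged = best$info %in% 1:4))
}

#' Classify a fluorescence sample into Off/On and estimate the On fraction
#'
#' Cells are called On above a log10-fluorescence threshold. By default the
#' threshold is the midpoint of the two mixture-component means fitted by
#' 2-means clustering in log10 space; a fixed threshold can be supplied
#' instead.
#'
#' @param log10_sample numeric vector of log10 fluorescence values
#' @param threshold optional fixed threshold (log10 units)
#' @return list with `on_fraction`, `threshold`, `n`
#' @export
classify_on_fraction <- function(log10_sample, threshold = NULL) {
  if (!is.numeric(log10_sample) || length(log10_sample) < 2L)
    stop("need a numeric sample of >= 2 cells", call. = FALSE)
  if (is.null(threshold)) {
    centers <- sort(c(stats::quantile(log10_sample, 0.05),
                      stats::quantile(log10_sample, 0.95)))
    if (diff(centers) < sqrt(.Machine$double.eps)) {
      threshold <- centers[1L] + 1  # unimodal sample: everything one state
    } else {
      km <- stats::kmeans(log10_sample, centers = centers)
      threshold <- mean(km$centers)
    }
  }
  list(on_fraction = mean(log10_sample > threshold),
       threshold = unname(threshold), n = length(log10_sample))
}
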