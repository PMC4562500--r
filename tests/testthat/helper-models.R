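## shared fixtures and oracles for the test suite

## small/fast simulator configuration for unit tests (not the study
## conditions; those stay at the sim_config() defaults)
tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(duration_days = 4, n_replicates = 4, bottleneck = 1e5), list(...))
  do.call(sim_config, args)
}

## independent integrator oracle for the zeocin uptake/binding submodel
integrate_binding_ode <- function(F, Z, p, t_end = 5000) {
  rhs <- function(t, y, parms) {
    Zi <- y[1L]; B <- y[2L]; R <- F - B
    list(c(p$k_in * Z - p$k_out * Zi - p$k_on * Zi * R + p$k_off * B,
           p$k_on * Zi * R - p$k_off * B - p$k_deg * B))
  }
  out <- deSolve::ode(c(0, 0), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  list(Z_int = out[2L, 2L], B = out[2L, 3L])
}

## independent integrator oracle for the two-state linear system
integrate_two_state_ode <- function(n0, sp, dt, r = sp$r) {
  rhs <- function(t, y, parms)
    list(c((sp$g_L - r) * y[1L] + sp$f * y[2L],
           r * y[1L] + (sp$g_H - sp$f) * y[2L]))
  out <- deSolve::ode(n0, times = c(0, dt), func = rhs, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  c(n_L = unname(out[2L, 2L]), n_H = unname(out[2L, 3L]))
}

## closed-form extinction probability by time t of a linear birth-death
## process started from one cell
bd_extinction_prob <- function(b, d, t) {
  if (abs(b - d) < 1e-12) return(b * t / (1 + b * t))
  e <- exp((b - d) * t)
  d * (e - 1) / (b * e - d)
}

## logistic crossing time (days) for a two-class lumped takeover from
## initial mutant fraction x0 with selection coefficient s (per hour)
logistic_half_life_days <- function(x0, s) {
  log((1 - x0) / x0) / s / 24
}

## hand-built three-allele reconstruction fixture (used by the golden
## tests): m1 unlinked, m2+m3 linked in one lineage
golden_obs <- function() {
  data.frame(
    allele_id = c("m1", "m1", "m1", "m1", "m2", "m3", "m2", "m3", "m2",
                  "ancestral", "ancestral", "ancestral"),
    day = c(4, 4, 9, 14, 9, 9, 14, 14, 14, 4, 9, 14),
    method = c("sanger", "wgs", "wgs", "sanger", "wgs", "wgs", "wgs",
               "wgs", "sanger", "sanger", "sanger", "sanger"),
    frequency = c(0.10, 0.20, 0.40, 0.60, 0.30, 0.50, 0.60, 0.70, 0.60,
                  0.70, 0.30, 0.00))
}

golden_clones <- function() {
  ## day 14: 10 clones, 6 carry both m2 and m3 (linked), none carries only
  ## one of them; m1 appears alone in 3 clones
  rows <- list()
  add <- function(clone, carried) {
    rows[[length(rows) + 1L]] <<- data.frame(
      clone_id = clone, day = 14, allele_id = c("m1", "m2", "m3"),
      present = as.integer(c("m1", "m2", "m3") %in% carried))
  }
  for (i in 1:6) add(paste0("c", i), c("m2", "m3"))
  for (i in 7:9) add(paste0("c", i), "m1")
  add("c10", character(0))
  do.call(rbind, rows)
}
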