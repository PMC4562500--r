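#' Define a doxycycline/zeocin environment
#'
#' An environment is a constant combination of the inducer doxycycline
#' (`dox`, ug/ml) and the antibiotic zeocin (`zeo`, mg/ml), tagged with the
#' conventional `DxZy` label. `Di` stands for the intermediate inducer level
#' 0.2 ug/ml, so `"DiZ2"` is 0.2 ug/ml doxycycline + 2 mg/ml zeocin.
#'
#' @param dox doxycycline concentration in ug/ml (>= 0)
#' @param zeo zeocin concentration in mg/ml (>= 0)
#' @param label optional condition tag; derived from the concentrations when
#'   omitted
#' @return an object of class `pf_environment` with fields `dox`, `zeo`,
#'   `label`
#' @examples
#' pf_environment(2, 0)          # D2Z0
#' pf_environment(0.2, 2)        # DiZ2
#' parse_condition("D0Z2")
#' @export
pf_environment <- function(dox, zeo, label = NULL) {
  if (!is.numeric(dox) || length(dox) != 1L || !is.finite(dox) || dox < 0)
    stop("'dox' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(zeo) || length(zeo) != 1L || !is.finite(zeo) || zeo < 0)
    stop("'zeo' must be a single finite non-negative number", call. = FALSE)
  if (is.null(label)) label <- condition_label(dox, zeo)
  structure(list(dox = dox, zeo = zeo, label = label),
            class = "pf_environment")
}

#' @export
print.pf_environment <- function(x, ...) {
  cat(sprintf("<environment %s: dox = %g ug/ml, zeo = %g mg/ml>\n",
              x$label, x$dox, x$zeo))
  invisible(x)
}

DOX_INTERMEDIATE <- 0.2

#' Build a DxZy condition label from concentrations
#'
#' @param dox,zeo concentrations (ug/ml, mg/ml)
#' @return character label, e.g. `"D2Z0"`; 0.2 ug/ml doxycycline is written
#'   `Di`
#' @export
condition_label <- function(dox, zeo) {
  dtag <- if (isTRUE(all.equal(dox, DOX_INTERMEDIATE))) "i" else format(dox)
  paste0("D", dtag, "Z", format(zeo))
}

#' Parse a DxZy condition label into an environment
#'
#' Round-trips with [condition_label()]: `parse_condition(condition_label(d, z))`
#' recovers `(d, z)`.
#'
#' @param label character tag such as `"D2Z0"` or `"DiZ2"`
#' @return a [pf_environment()]
#' @export
parse_condition <- function(label) {
  if (!is.character(label) || length(label) != 1L)
    stop("'label' must be a single character string", call. = FALSE)
  m <- regmatches(label, regexec("^D(i|[0-9.]+)Z([0-9.]+)$", label))[[1L]]
  if (length(m) != 3L)
    stop("cannot parse condition label '", label, "' (expected DxZy)",
         call. = FALSE)
  dox <- if (m[2L] == "i") DOX_INTERMEDIATE else as.numeric(m[2L])
  pf_environment(dox, as.numeric(m[3L]), label = label)
}

#' The six standard study conditions
#'
#' @return named list of [pf_environment()] objects for D0Z0, DiZ0, D2Z0,
#'   D0Z2, DiZ2 and D2Z2
#' @export
standard_conditions <- function() {
  labs <- c("D0Z0", "DiZ0", "D2Z0", "D0Z2", "DiZ2", "D2Z2")
  stats::setNames(lapply(labs, parse_condition), labs)
}

is_pf_environment <- function(x) inherits(x, "pf_environment")

as_pf_environment <- function(x) {
  if (is_pf_environment(x)) return(x)
  if (is.character(x)) return(parse_condition(x))
  stop("expected a pf_environment or a DxZy label", call. = FALSE)
}
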