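## Reconstruction of allele-frequency time courses from mixed Sanger /
## whole-genome sequencing calls: per-day method merging, linkage-group
## averaging, ancestral clamping, and quadratic-spline interpolation.

#' Merge per-method allele-frequency calls into knots
#'
#' For a time point with calls from both sequencing methods the knot is the
#' arithmetic mean of the two frequencies; with one method, that method's
#' value; with neither, no knot is emitted.
#'
#' @param obs data.frame with columns `allele_id`, `day`, `method`
#'   (`"sanger"` or `"wgs"`) and `frequency` in `[0, 1]`
#' @return data.frame of knots: `allele_id`, `day`, `frequency`
#' @examples
#' obs <- data.frame(allele_id = "m1", day = 9,
#'                   method = c("sanger", "wgs"), frequency = c(0.4, 0.6))
#' merge_method_frequencies(obs)  # 0.5
#' @export
merge_method_frequencies <- function(obs) {
  need <- c("allele_id", "day", "method", "frequency")
  if (!is.data.frame(obs) || !all(need %in% names(obs)))
    stop("'obs' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(obs$frequency) |
                 obs$frequency < 0 | obs$frequency > 1)
  if (length(bad))
    stop("frequencies outside [0, 1] at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  if (!all(obs$method %in% c("sanger", "wgs")))
    stop("method must be 'sanger' or 'wgs'", call. = FALSE)
  if (anyDuplicated(obs[, c("allele_id", "day", "method")]))
    stop("duplicate (allele_id, day, method) rows", call. = FALSE)
  out <- stats::aggregate(frequency ~ allele_id + day, data = obs,
                          FUN = mean)
  out[order(out$allele_id, out$day), , drop = FALSE]
}

#' Resolve linked alleles by averaging member frequencies
#'
#' Whole-genome sequencing reports each mutation locus separately even when
#' mutations travel together in one lineage. For each linkage group (a set
#' of allele ids established as co-occurring in clonal isolates) the
#' whole-genome estimate of the linked allele is the mean of the member
#' frequencies; where a Sanger-derived linked-lineage frequency exists at
#' that day, the final knot is the mean of the whole-genome-linked value and
#' the Sanger value. Unlinked alleles pass through unchanged.
#'
#' @param knots per-(allele, day) whole-genome knots, as from
#'   [merge_method_frequencies()] applied to WGS-only calls
#' @param groups list of character vectors of allele ids (disjoint, each of
#'   size >= 2)
#' @param sanger_linked optional data.frame `group`, `day`, `frequency` of
#'   Sanger linked-lineage frequencies; `group` is the index into `groups`
#' @return data.frame `allele_id`, `day`, `frequency` where each linkage
#'   group is replaced by one linked allele id (members joined by `"+"`)
#' @export
resolve_linkage <- function(knots, groups, sanger_linked = NULL) {
  if (!length(groups)) return(knots)
  ids <- unlist(groups)
  if (anyDuplicated(ids))
    stop("linkage groups must be disjoint", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("linkage groups must have >= 2 members", call. = FALSE)
  out <- knots[!knots$allele_id %in% ids, , drop = FALSE]
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    sub <- knots[knots$allele_id %in% g, , drop = FALSE]
    for (d in sort(unique(sub$day))) {
      md <- sub[sub$day == d, ]
      if (nrow(md) < length(g)) {
        warning("linkage group ", paste(g, collapse = "+"),
                " missing a member at day ", d, "; group skipped there")
        next
      }
      val <- mean(md$frequency)
      if (!is.null(sanger_linked)) {
        sl <- sanger_linked[sanger_linked$group == gi &
                              sanger_linked$day == d, ]
        if (nrow(sl) == 1L) val <- mean(c(val, sl$frequency))
      }
      out <- rbind(out, data.frame(allele_id = paste(g, collapse = "+"),
                                   day = d, frequency = val))
    }
  }
  out[order(out$allele_id, out$day), , drop = FALSE]
}

#' Clamp the ancestral series at zero once it reaches zero
#'
#' Once the ancestral genotype reaches 0 percent it is kept at 0, even if
#' mutant alleles cannot account for 100 percent of the population
#' afterwards (mutant knots are deliberately left unnormalized).
#'
#' @param series data.frame with columns `day` and `frequency` (ancestral),
#'   or a bare numeric vector of frequencies in day order
#' @return the clamped series, same shape as the input
#' @examples
#' clamp_ancestral(c(1.0, 0.4, 0.0, 0.1))  # 1.0 0.4 0.0 0.0
#' @export
clamp_ancestral <- function(series) {
  vec <- if (is.data.frame(series)) {
    series <- series[order(series$day), , drop = FALSE]
    series$frequency
  } else series
  z <- which(vec <= 0)
  if (length(z)) vec[z[1L]:length(vec)] <- 0
  if (is.data.frame(series)) {
    series$frequency <- vec
    series
  } else vec
}

## interpolating quadratic spline: piecewise y_i + m_i (x - x_i) +
## c_i (x - x_i)^2 with derivative continuity; the first segment is linear
## (c_1 = 0), which closes the one-condition gap of order-2 splines
quad_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  m <- numeric(n - 1L); cc <- numeric(n - 1L)
  m[1L] <- (y[2L] - y[1L]) / h[1L]
  cc[1L] <- 0
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      m[i] <- 2 * (y[i] - y[i - 1L]) / h[i - 1L] - m[i - 1L]
      cc[i] <- ((y[i + 1L] - y[i]) / h[i] - m[i]) / h[i]
    }
  }
  seg <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  dx <- xout - x[seg]
  y[seg] + m[seg] * dx + cc[seg] * dx * dx
}

#' Interpolate an allele trajectory with a quadratic spline
#'
#' Second-order (quadratic) spline through the knots, evaluated on a
#' daily-or-finer grid. The curve passes through every knot exactly; with
#' only two knots it degrades to the linear segment. Spline overshoot is
#' clipped to `[0, 1]` for the `frequency` column; the raw spline is kept in
#' `frequency_raw`.
#'
#' @param knots data.frame with columns `day` and `frequency` (>= 2 rows)
#' @param step grid spacing in days (default 0.25)
#' @return data.frame `day`, `frequency` (clipped), `frequency_raw`,
#'   `source` (`"knot"` or `"interpolated"`)
#' @export
interpolate_trajectory <- function(knots, step = 0.25) {
  if (!is.data.frame(knots) || !all(c("day", "frequency") %in% names(knots)))
    stop("'knots' must have columns day, frequency", call. = FALSE)
  knots <- knots[order(knots$day), , drop = FALSE]
  if (nrow(knots) < 2L) {
    warning("fewer than 2 knots; interpolation skipped")
    return(data.frame(day = knots$day, frequency = knots$frequency,
                      frequency_raw = knots$frequency,
                      source = rep("knot", nrow(knots))))
  }
  grid <- sort(unique(c(seq(min(knots$day), max(knots$day), by = step),
                        knots$day)))
  raw <- quad_spline_eval(knots$day, knots$frequency, grid)
  is_knot <- grid %in% knots$day
  raw[is_knot] <- knots$frequency[match(grid[is_knot], knots$day)]
  data.frame(day = grid, frequency = pmin(pmax(raw, 0), 1),
             frequency_raw = raw,
             source = ifelse(is_knot, "knot", "interpolated"))
}

## derive linkage groups (graph components of clone co-occurrence) and
## Sanger linked-lineage frequencies (clone proportions) from a clonal
## genotype table (clone_id, day, allele_id, present)
linkage_from_clones <- function(clones) {
  need <- c("clone_id", "day", "allele_id", "present")
  if (!is.data.frame(clones) || !all(need %in% names(clones)))
    stop("'clones' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  pres <- clones[clones$present == 1, , drop = FALSE]
  ids <- sort(unique(pres$allele_id))
  if (!length(ids)) return(list(groups = list(), sanger_linked = NULL))
  ## union-find over alleles co-occurring in any clone
  parent <- stats::setNames(ids, ids)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  for (cl in split(pres$allele_id, paste(pres$clone_id, pres$day))) {
    cl <- unique(cl)
    if (length(cl) > 1L)
      for (b in cl[-1L]) parent[[find(b)]] <- find(cl[[1L]])
  }
  comp <- vapply(ids, find, character(1))
  groups <- split(ids, comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
  if (!length(groups)) return(list(groups = list(), sanger_linked = NULL))
  ## Sanger linked frequency: proportion of clones carrying the full group
  sl <- list()
  nclones <- stats::aggregate(clone_id ~ day, clones,
                              FUN = function(x) length(unique(x)))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (d in nclones$day) {
      pd <- pres[pres$day == d & pres$allele_id %in% g, ]
      carriers <- table(pd$clone_id)
      k <- sum(carriers == length(g))
      n <- nclones$clone_id[nclones$day == d]
      sl[[length(sl) + 1L]] <- data.frame(group = gi, day = d,
                                          frequency = k / n)
    }
  }
  list(groups = groups, sanger_linked = do.call(rbind, sl))
}

#' Full allele time-course reconstruction
#'
#' Applies the reconstruction pipeline: per-day method merging, linkage
#' resolution from clonal genotypes (whole-genome member averaging, then
#' averaging with the Sanger linked-lineage frequency), day-0 anchoring of
#' mutant alleles at 0 (unless observed), ancestral clamping, and quadratic
#' spline interpolation.
#'
#' @param obs observation table (`allele_id`, `day`, `method`, `frequency`);
#'   rows with `allele_id == "ancestral"` form the ancestral series
#' @param clones optional clonal genotype table (`clone_id`, `day`,
#'   `allele_id`, `present`) from which linkage is derived
#' @param step interpolation grid spacing in days
#' @return list with `knots` (post-merge, post-linkage) and `curves`
#'   (long data.frame: `allele_id`, `day`, `frequency`, `frequency_raw`,
#'   `source`)
#' @export
reconstruct_timecourse <- function(obs, clones = NULL, step = 0.25) {
  merged <- merge_method_frequencies(obs)
  anc <- merged[merged$allele_id == "ancestral", , drop = FALSE]
  mut <- merged[merged$allele_id != "ancestral", , drop = FALSE]
  if (!is.null(clones)) {
    lk <- linkage_from_clones(clones)
    if (length(lk$groups)) {
      ## linkage averaging applies to the whole-genome estimates
      wgs <- merge_method_frequencies(
        obs[obs$method == "wgs" & obs$allele_id != "ancestral", ,
            drop = FALSE])
      linked_ids <- unlist(lk$groups)
      mut <- rbind(mut[!mut$allele_id %in% linked_ids, , drop = FALSE],
                   resolve_linkage(wgs[wgs$allele_id %in% linked_ids, ,
                                       drop = FALSE],
                                   lk$groups, lk$sanger_linked))
    }
  }
  ## anchor mutant alleles at day 0 unless observed there
  for (a in unique(mut$allele_id)) {
    if (!any(mut$day[mut$allele_id == a] == 0))
      mut <- rbind(mut, data.frame(allele_id = a, day = 0, frequency = 0))
  }
  if (nrow(anc)) anc <- clamp_ancestral(anc)
  knots <- rbind(anc, mut)
  knots <- knots[order(knots$allele_id, knots$day), , drop = FALSE]
  curves <- do.call(rbind, lapply(split(knots, knots$allele_id), function(k) {
    ik <- interpolate_trajectory(k[, c("day", "frequency")], step = step)
    if (k$allele_id[1L] == "ancestral") {
      ik$frequency <- clamp_ancestral(ik$frequency)
      ik$frequency_raw <- clamp_ancestral(ik$frequency_raw)
    }
    cbind(allele_id = k$allele_id[1L], ik)
  }))
  rownames(curves) <- NULL
  list(knots = knots, curves = curves)
}
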