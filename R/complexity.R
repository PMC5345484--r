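# Aggregation of per-aperture y/A into arc and plan complexity.
#
# M = (1/MU) * sum_i MU_i * y_i/A_i  over included control points.
# Closed apertures (A = 0) have no defined y/A; they are excluded from both
# the numerator and the MU denominator, so a plan with a parked-closed
# control point is scored on the MU it actually delivers through open field.

cp_table <- function(arc, min_gap = 0.5) {
  rows <- lapply(arc$control_points, function(cp) {
    a <- open_area(cp$aperture, min_gap)
    y <- side_perimeter(cp$aperture, min_gap)
    data.frame(
      beam_id = arc$beam_id,
      cp_index = cp$index,
      gantry_deg = cp$gantry_angle,
      mu = cp$mu,
      area_mm2 = a,
      perimeter_mm = y,
      complexity_mm_inv = if (a > 0) y / a else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Arc complexity
#'
#' MU-weighted mean of per-control-point y/A over the arc's included control
#' points (open aperture).  Control points with a closed aperture are
#' excluded from both sums and counted in `excluded_cp_count`; those with
#' MU = 0 (the ends of an arc under the midpoint rule, when weights repeat)
#' appear in the profile but contribute nothing to M.
#'
#' @param arc an [rt_arc()]
#' @param min_gap closed-pair gap tolerance in mm, see
#'   [effective_open_intervals()]
#' @return an `arc_complexity` object: `beam_id`, `M` (1/mm), `included_mu`,
#'   `excluded_cp_count`, and `profile` (the per-control-point table with
#'   columns beam_id, cp_index, gantry_deg, mu, area_mm2, perimeter_mm,
#'   complexity_mm_inv; NA marks a closed aperture)
#' @export
arc_complexity <- function(arc, min_gap = 0.5) {
  stopifnot(inherits(arc, "rt_arc"))
  tab <- cp_table(arc, min_gap)
  excluded <- is.na(tab$complexity_mm_inv)
  if (any(excluded & tab$mu > 0)) {
    warning("arc ", arc$beam_id, ": ", sum(excluded & tab$mu > 0),
            " control point(s) with MU > 0 have a closed aperture; ",
            "excluded from the metric", call. = FALSE)
  }
  inc <- !excluded
  included_mu <- sum(tab$mu[inc])
  if (!any(inc) || included_mu <= 0) {
    abort("all apertures empty (or zero MU through open apertures) in arc ",
          arc$beam_id)
  }
  M <- sum(tab$mu[inc] * tab$complexity_mm_inv[inc]) / included_mu
  structure(
    list(beam_id = arc$beam_id, M = M, included_mu = included_mu,
         excluded_cp_count = sum(excluded), profile = tab,
         beam_type = arc$beam_type),
    class = "arc_complexity"
  )
}

#' Plan complexity
#'
#' The plan metric: a single MU-weighted sum of y/A over every included
#' control point of every arc.  Equals the included-MU-weighted mean of the
#' per-arc values.
#'
#' @param plan an [rt_plan()]
#' @inheritParams arc_complexity
#' @return a `plan_complexity` object: `plan_id`, `M` (1/mm), `per_arc` (list
#'   of [arc_complexity()] results), `total_mu`, `included_mu`,
#'   `excluded_cp_count`
#' @export
plan_complexity <- function(plan, min_gap = 0.5) {
  stopifnot(inherits(plan, "rt_plan"))
  per_arc <- lapply(plan$arcs, arc_complexity, min_gap = min_gap)
  inc_mu <- vapply(per_arc, `[[`, numeric(1), "included_mu")
  M <- sum(vapply(per_arc, `[[`, numeric(1), "M") * inc_mu) / sum(inc_mu)
  structure(
    list(plan_id = plan$plan_id, M = M, per_arc = per_arc,
         total_mu = plan$total_mu, included_mu = sum(inc_mu),
         excluded_cp_count = sum(vapply(per_arc, `[[`, numeric(1),
                                        "excluded_cp_count"))),
    class = "plan_complexity"
  )
}

#' Per-control-point complexity profile
#'
#' One (gantry angle, y/A) point per control point in delivery order, the
#' series behind the "complexity vs gantry angle" view planners use to spot
#' which parts of an arc drive modulation.  Values are per control point,
#' not MU-weighted; closed apertures appear as NA gaps.
#'
#' @inheritParams arc_complexity
#' @return data.frame with columns beam_id, cp_index, gantry_deg, mu,
#'   area_mm2, perimeter_mm, complexity_mm_inv
#' @export
complexity_profile <- function(arc, min_gap = 0.5) {
  stopifnot(inherits(arc, "rt_arc"))
  cp_table(arc, min_gap)
}

#' Export a per-control-point table as CSV
#'
#' @param x a `plan_complexity` or `arc_complexity` object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(x, path) {
  tab <- if (inherits(x, "plan_complexity")) {
    do.call(rbind, lapply(x$per_arc, `[[`, "profile"))
  } else if (inherits(x, "arc_complexity")) {
    x$profile
  } else {
    abort("write_profile_csv: need a plan_complexity or arc_complexity")
  }
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Plan summary as a JSON-ready list
#'
#' @param pc a [plan_complexity()] result
#' @return list mirroring the JSON summary: plan M, per-arc M, excluded
#'   counts, MU bookkeeping; complexities reported at full precision, with a
#'   3-decimal display value alongside
#' @export
plan_summary <- function(pc) {
  stopifnot(inherits(pc, "plan_complexity"))
  list(
    plan_id = pc$plan_id,
    complexity_mm_inv = pc$M,
    complexity_display = round(pc$M, 3),
    total_mu = pc$total_mu,
    included_mu = pc$included_mu,
    excluded_cp_count = pc$excluded_cp_count,
    arcs = lapply(pc$per_arc, function(a) {
      list(beam_id = a$beam_id, complexity_mm_inv = a$M,
           complexity_display = round(a$M, 3),
           included_mu = a$included_mu,
           excluded_cp_count = a$excluded_cp_count,
           beam_type = a$beam_type)
    })
  )
}

#' @export
print.plan_complexity <- function(x, ...) {
  cat("<plan_complexity> ", x$plan_id, ": M = ",
      formatC(x$M, format = "f", digits = 3), " mm^-1 (",
      length(x$per_arc), " arc(s), ", x$excluded_cp_count,
      " excluded control point(s))\n", sep = "")
  for (a in x$per_arc) {
    cat("  arc ", a$beam_id, ": M = ",
        formatC(a$M, format = "f", digits = 3), " mm^-1, included MU ",
        format(a$included_mu), "\n", sep = "")
  }
  invisible(x)
}
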