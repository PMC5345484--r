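# Synthetic plan and cohort generators.
#
# These emulate the two kinds of input the toolchain consumes so that every
# module is testable without clinical data: (a) VMAT arcs whose aperture
# irregularity is controlled by a single leaf-perturbation scale sigma, and
# (b) labeled cohorts drawn from truncated-normal pass/fail complexity
# distributions.  They are fixtures with stated statistical properties, not
# emulations of a treatment planning optimizer.

#' Rectangular-aperture test plan
#'
#' Every control point carries the identical rectangular aperture of the
#' given width, spanning `n_bands` whole central leaf bands.  The plan
#' complexity has the closed form `M = 2 * width / (width * height) =
#' 2 / height` (the two side edges over the area), independent of width and
#' of the MU split -- the analytic anchor for pipeline tests.
#'
#' @param width field width along leaf travel, mm
#' @param n_bands number of whole leaf bands spanned (centred on the middle
#'   of the bank)
#' @param n_cp number of control points
#' @param mu_total beam monitor units
#' @param geometry an [mlc_geometry()] (default Varian Millennium-style)
#' @param arc_span gantry arc length in degrees
#' @return an [rt_plan()]
#' @export
make_rectangle_plan <- function(width, n_bands = 10L, n_cp = 30L,
                                mu_total = 400,
                                geometry = varian_millennium_geometry(),
                                arc_span = 358) {
  if (!is.finite(width) || width <= 0) abort("width must be > 0")
  b <- geometry$leaf_boundaries
  if (n_bands < 1L || n_bands > geometry$n_pairs) abort("invalid n_bands")
  first <- (geometry$n_pairs - n_bands) %/% 2L + 1L
  open_pairs <- seq(first, first + n_bands - 1L)
  if (width / 2 > 200) abort("width exceeds leaf travel range")

  left <- rep(0, geometry$n_pairs)   # parked closed at midline
  right <- rep(0, geometry$n_pairs)
  left[open_pairs] <- -width / 2
  right[open_pairs] <- width / 2
  y_lo <- b[first]; y_hi <- b[first + n_bands]
  jaws <- c(-width / 2 - 5, width / 2 + 5, y_lo, y_hi)

  cps <- lapply(seq_len(n_cp), function(k) {
    control_point(
      index = k - 1L,
      gantry_angle = (181 + (k - 1L) * arc_span / (n_cp - 1L)) %% 360,
      cumulative_weight = (k - 1L) / (n_cp - 1L),
      aperture = aperture(left, right, jaws, geometry)
    )
  })
  rt_plan("RECT", list(rt_arc("ARC1", mu_total, geometry, cps)))
}

#' Modulation specification for a synthetic VMAT arc
#'
#' @param n_control_points control points in the arc (>= 2)
#' @param arc_span arc length in degrees
#' @param target_radius radius of the (spherical) target in mm; its beam's-
#'   eye-view projection is a circle of this radius at every gantry angle
#' @param sigma leaf perturbation scale in mm (>= 0); 0 gives the exactly
#'   conformal arc
#' @param seed integer RNG seed
#' @param mu_total beam monitor units
#' @param geometry an [mlc_geometry()]
#' @return a `modulation_spec` list
#' @export
modulation_spec <- function(n_control_points = 90L, arc_span = 358,
                            target_radius = 40, sigma = 0, seed = 1L,
                            mu_total = 400,
                            geometry = varian_millennium_geometry()) {
  if (n_control_points < 2L) abort("need >= 2 control points")
  if (!is.finite(target_radius) || target_radius <= 0) {
    abort("target_radius must be > 0")
  }
  if (!is.finite(sigma) || sigma < 0) abort("sigma must be >= 0")
  structure(
    list(n_control_points = as.integer(n_control_points),
         arc_span = arc_span, target_radius = target_radius, sigma = sigma,
         seed = as.integer(seed), mu_total = mu_total, geometry = geometry),
    class = "modulation_spec"
  )
}

# conformal half-widths: pair j opens to +/- sqrt(R^2 - d^2) where d is the
# band's smallest |y|; pairs clear of the circle stay parked closed
conformal_halfwidths <- function(geometry, radius) {
  b <- geometry$leaf_boundaries
  lo <- b[-length(b)]; hi <- b[-1]
  d <- pmax(pmax(lo, -hi), 0)          # distance from band to the y axis
  w <- rep(0, geometry$n_pairs)
  inside <- d < radius
  w[inside] <- sqrt(radius^2 - d[inside]^2)
  w
}

#' Synthetic modulated VMAT plan
#'
#' One full arc whose base aperture is conformal to a spherical target's
#' circular projection at every control point.  Modulation is injected by
#' retracting each leaf *away* from the field centre by an independent
#' `|N(0, sigma)|` draw, so the target stays covered and the staircase
#' mismatch between adjacent leaf pairs (extra side perimeter) grows faster
#' than the open area: mean plan complexity increases with `sigma`.
#' `sigma = 0` reproduces the conformal plan exactly; a fixed seed gives a
#' bit-identical plan on repeat.
#'
#' @param spec a [modulation_spec()]
#' @return an [rt_plan()]
#' @export
make_modulated_plan <- function(spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  g <- spec$geometry
  w0 <- conformal_halfwidths(g, spec$target_radius)
  jaw <- spec$target_radius + 4 * spec$sigma + 10
  jaws <- c(-jaw, jaw, -jaw, jaw)
  n <- spec$n_control_points

  set.seed(spec$seed)
  cps <- lapply(seq_len(n), function(k) {
    noise_l <- abs(rnorm(g$n_pairs, 0, spec$sigma))
    noise_r <- abs(rnorm(g$n_pairs, 0, spec$sigma))
    open <- w0 > 0
    left <- rep(0, g$n_pairs)
    right <- rep(0, g$n_pairs)
    left[open] <- -(w0[open] + noise_l[open])
    right[open] <- w0[open] + noise_r[open]
    control_point(
      index = k - 1L,
      gantry_angle = (181 + (k - 1L) * spec$arc_span / (n - 1L)) %% 360,
      cumulative_weight = (k - 1L) / (n - 1L),
      aperture = aperture(left, right, jaws, g)
    )
  })
  rt_plan(sprintf("MOD-s%g-seed%d", spec$sigma, spec$seed),
          list(rt_arc("ARC1", spec$mu_total, g, cps)))
}

#' Cohort specification
#'
#' Defaults follow the published institutional reference cohort this package
#' ships (649 passing and 62 failing VMAT plans; passing complexity
#' 0.132 +/- 0.036 1/mm, failing 0.170 +/- 0.040 1/mm).
#'
#' @param n_pass,n_fail class sizes
#' @param mean_pass,sd_pass,mean_fail,sd_fail class complexity distributions,
#'   1/mm; draws are normal truncated at 0
#' @param seed integer RNG seed
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_pass = 649L, n_fail = 62L,
                        mean_pass = 0.132, sd_pass = 0.036,
                        mean_fail = 0.170, sd_fail = 0.040, seed = 1L) {
  if (mean_pass <= 0 || mean_fail <= 0 || sd_pass < 0 || sd_fail < 0) {
    abort("cohort_spec: means must be > 0 and sds >= 0")
  }
  structure(
    list(n_pass = as.integer(n_pass), n_fail = as.integer(n_fail),
         mean_pass = mean_pass, sd_pass = sd_pass,
         mean_fail = mean_fail, sd_fail = sd_fail, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtruncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a labeled QA cohort
#'
#' Complexities drawn from class-specific normal distributions truncated at
#' 0 and labeled pass/fail.  A deliberate simplification of real cohorts
#' (which are right-skewed): adequate for exercising counting, ROC and
#' threshold machinery, not for reproducing clinical histogram shapes.
#'
#' @param spec a [cohort_spec()]
#' @param site site label for the records (default "all")
#' @return cohort data.frame compatible with [cohort_summary()] and
#'   [roc_curve()]
#' @export
simulate_cohort <- function(spec = cohort_spec(), site = "all") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pass_x <- rtruncnorm0(spec$n_pass, spec$mean_pass, spec$sd_pass)
  fail_x <- rtruncnorm0(spec$n_fail, spec$mean_fail, spec$sd_fail)
  n <- spec$n_pass + spec$n_fail
  data.frame(
    plan_id = sprintf("sim%05d", seq_len(n)),
    site = site,
    fractionation = "unknown",
    complexity_mm_inv = c(pass_x, fail_x),
    qa_pass = rep(c(TRUE, FALSE), c(spec$n_pass, spec$n_fail)),
    stringsAsFactors = FALSE
  )
}
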