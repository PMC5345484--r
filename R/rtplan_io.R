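# Plan model and DICOM-RT Plan I/O.
#
# A plan is a list of arcs; an arc is one treatment beam's ordered control
# points, each carrying gantry angle, cumulative meterset weight, the MLC/jaw
# aperture, and (derived) the monitor units MU_i attributed to that control
# point.  DICOM stores cumulative weights, not per-control-point MU, so MU_i
# is allocated from the beam meterset at read time (see control_point_mu).

#' Allocate beam monitor units to control points
#'
#' DICOM records a cumulative meterset weight per control point; the metric
#' needs the MU delivered *through* each aperture.  The default midpoint rule
#' attributes to control point i half of each adjacent delivery interval,
#' reflecting that the machine interpolates apertures between control points:
#' \eqn{MU_i = MU_{beam} (w_{i+1} - w_{i-1}) / (2W)} for interior points, and
#' half-intervals at the ends.  The `forward` alternative attributes each
#' interval wholly to its starting control point (last point gets 0); it is
#' provided for sensitivity checks.
#'
#' Both rules conserve total MU: `sum(result) == beam_mu` up to floating
#' point.
#'
#' @param cumulative_weights non-decreasing numeric vector, first element 0,
#'   last element W > 0
#' @param beam_mu total beam monitor units
#' @param method `"midpoint"` (default) or `"forward"`
#' @return numeric vector of MU_i, same length as `cumulative_weights`
#' @export
control_point_mu <- function(cumulative_weights, beam_mu,
                             method = c("midpoint", "forward")) {
  method <- match.arg(method)
  w <- as.numeric(cumulative_weights)
  n <- length(w)
  if (n < 2L) abort("control_point_mu: need at least 2 control points")
  if (any(diff(w) < 0)) abort("control_point_mu: cumulative weights must be non-decreasing")
  W <- w[n] - w[1]
  if (W <= 0) abort("control_point_mu: final cumulative weight must exceed the first")
  if (!is.finite(beam_mu) || beam_mu < 0) abort("control_point_mu: invalid beam_mu")
  frac <- switch(method,
    midpoint = c(w[2] - w[1], w[seq_len(n - 2L) + 2L] - w[seq_len(n - 2L)],
                 w[n] - w[n - 1L]) / (2 * W),
    forward = c(diff(w), 0) / W
  )
  beam_mu * frac
}

#' Construct a control point record
#'
#' @param index 0-based control point index
#' @param gantry_angle gantry angle in degrees, reduced to `[0, 360)`
#' @param cumulative_weight cumulative meterset weight at this control point
#' @param aperture an [aperture()]
#' @param mu monitor units attributed to this control point (filled by
#'   [rt_arc()] when `NA`)
#' @return a `control_point` object
#' @export
control_point <- function(index, gantry_angle, cumulative_weight, aperture,
                          mu = NA_real_) {
  stopifnot(inherits(aperture, "aperture"))
  structure(
    list(index = as.integer(index),
         gantry_angle = as.numeric(gantry_angle) %% 360,
         cumulative_weight = as.numeric(cumulative_weight),
         mu = as.numeric(mu),
         aperture = aperture),
    class = "control_point"
  )
}

#' Construct an arc (one treatment beam)
#'
#' Validates the cumulative-weight ramp and allocates `beam_mu` over control
#' points with [control_point_mu()].
#'
#' @param beam_id character beam identifier
#' @param beam_mu beam meterset in MU (> 0)
#' @param geometry the beam's [mlc_geometry()]
#' @param control_points list of [control_point()]s in delivery order
#' @param beam_type `"DYNAMIC"` (VMAT) or `"STATIC"`; static beams are scored
#'   but tagged, since the metric was validated on VMAT
#' @param mu_method MU allocation rule, see [control_point_mu()]
#' @return an `rt_arc` object
#' @export
rt_arc <- function(beam_id, beam_mu, geometry, control_points,
                   beam_type = "DYNAMIC", mu_method = "midpoint") {
  stopifnot(inherits(geometry, "mlc_geometry"))
  if (length(control_points) < 2L) abort("rt_arc: need >= 2 control points")
  if (!is.finite(beam_mu) || beam_mu <= 0) abort("rt_arc: beam_mu must be > 0")
  w <- vapply(control_points, `[[`, numeric(1), "cumulative_weight")
  mu <- control_point_mu(w, beam_mu, mu_method)
  cps <- Map(function(cp, m) { cp$mu <- m; cp }, control_points, mu)
  structure(
    list(beam_id = as.character(beam_id), beam_mu = beam_mu,
         geometry = geometry, beam_type = beam_type,
         control_points = cps),
    class = "rt_arc"
  )
}

#' Construct a treatment plan
#'
#' @param plan_id character plan identifier
#' @param arcs list of [rt_arc()]s
#' @param site_label optional body-site label (free text)
#' @return an `rt_plan` object; `total_mu` is the sum of arc metersets
#' @export
rt_plan <- function(plan_id, arcs, site_label = NA_character_) {
  if (length(arcs) < 1L) abort("rt_plan: need >= 1 arc")
  stopifnot(all(vapply(arcs, inherits, logical(1), "rt_arc")))
  total_mu <- sum(vapply(arcs, `[[`, numeric(1), "beam_mu"))
  if (total_mu <= 0) abort("rt_plan: total MU must be > 0")
  structure(
    list(plan_id = as.character(plan_id), site_label = site_label,
         arcs = arcs, total_mu = total_mu),
    class = "rt_plan"
  )
}

#' @export
print.rt_plan <- function(x, ...) {
  cat("<rt_plan> ", x$plan_id, ": ", length(x$arcs), " arc(s), ",
      format(x$total_mu), " MU total\n", sep = "")
  invisible(x)
}

# ---- writing ---------------------------------------------------------------

serialize_bld_boundaries <- function(geometry) {
  list(
    # x jaws, y jaws, then the MLC with its leaf-position boundaries
    c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
      dcm_is(0x300A, 0x00BC, 1L)),
    c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
      dcm_is(0x300A, 0x00BC, 1L)),
    c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
      dcm_is(0x300A, 0x00BC, geometry$n_pairs),
      dcm_ds(0x300A, 0x00BE, geometry$leaf_boundaries))
  )
}

serialize_control_point <- function(cp) {
  ap <- cp$aperture
  bld_items <- list(
    c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
      dcm_ds(0x300A, 0x011C, ap$jaws[1:2])),
    c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
      dcm_ds(0x300A, 0x011C, ap$jaws[3:4])),
    c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
      dcm_ds(0x300A, 0x011C, c(ap$left, ap$right)))
  )
  c(dcm_is(0x300A, 0x0112, cp$index),
    dcm_sq(0x300A, 0x011A, bld_items),
    dcm_ds(0x300A, 0x011E, cp$gantry_angle),
    dcm_ds(0x300A, 0x0134, cp$cumulative_weight))
}

serialize_beam <- function(arc, beam_number) {
  cps <- arc$control_points
  final_w <- cps[[length(cps)]]$cumulative_weight
  c(dcm_sq(0x300A, 0x00B6, serialize_bld_boundaries(arc$geometry)),
    dcm_is(0x300A, 0x00C0, beam_number),
    dcm_str(0x300A, 0x00C2, "LO", arc$beam_id),
    dcm_str(0x300A, 0x00C4, "CS", arc$beam_type),
    dcm_str(0x300A, 0x00CE, "CS", "TREATMENT"),
    dcm_ds(0x300A, 0x010E, final_w),
    dcm_is(0x300A, 0x0110, length(cps)),
    dcm_sq(0x300A, 0x0111, lapply(cps, serialize_control_point)))
}

#' Write a plan as a DICOM-RT Plan file
#'
#' Emits a minimal but standard-conformant RTPLAN (Explicit VR Little Endian):
#' one dynamic-gantry beam per arc with MLC and jaw sequences, per-control-
#' point cumulative meterset weights, and per-beam metersets in the fraction
#' group.  Round-trips through [read_rtplan()].
#'
#' @param plan an [rt_plan()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "rt_plan"))
  n_beams <- length(plan$arcs)
  ref_beams <- lapply(seq_len(n_beams), function(i) {
    c(dcm_ds(0x300A, 0x0086, plan$arcs[[i]]$beam_mu),
      dcm_is(0x300C, 0x0006, i))
  })
  fraction_group <- list(
    c(dcm_is(0x300A, 0x0071, 1L),
      dcm_is(0x300A, 0x0078, 1L),
      dcm_is(0x300A, 0x0080, n_beams),
      dcm_sq(0x300C, 0x0004, ref_beams))
  )
  # UID derived from plan content so identical plans serialize identically
  # (and the writer never touches the RNG stream)
  content_tag <- sum(utf8ToInt(plan$plan_id)) * 1000L +
    (round(plan$total_mu * 100) %% 1000)
  sop_uid <- dcm_uid(paste0(n_beams, ".", content_tag))
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTPLAN_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str(0x300A, 0x0002, "SH", substr(plan$plan_id, 1, 16)),
    dcm_str(0x300A, 0x0003, "LO", plan$plan_id),
    dcm_sq(0x300A, 0x0070, fraction_group),
    dcm_sq(0x300A, 0x00B0, lapply(seq_len(n_beams), function(i)
      serialize_beam(plan$arcs[[i]], i)))
  )
  dcm_write_file(path, UID_RTPLAN_STORAGE, sop_uid, dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reading ---------------------------------------------------------------

read_beam <- function(beam, beam_mu, mu_method) {
  bld <- beam[["300A,00B6"]]
  mlc <- NULL
  for (dev in bld) {
    type <- dev[["300A,00B8"]]
    if (!is.null(type) && grepl("^MLC", type)) mlc <- dev
  }
  if (is.null(mlc)) return(NULL)
  boundaries <- mlc[["300A,00BE"]]
  if (is.null(boundaries)) {
    abort("unsupported device: MLC without leaf position boundaries in beam ",
          beam[["300A,00C2"]] %||% "?")
  }
  geometry <- mlc_geometry(boundaries)
  n <- geometry$n_pairs

  cps_raw <- beam[["300A,0111"]]
  if (is.null(cps_raw) || length(cps_raw) < 1L) abort("beam has no control points")

  # carried-forward state: DICOM only stores positions when they change
  jaw_x <- c(-200, 200)
  jaw_y <- range(geometry$leaf_boundaries)
  leaves <- NULL
  gantry <- 0
  cps <- vector("list", length(cps_raw))
  for (k in seq_along(cps_raw)) {
    cp <- cps_raw[[k]]
    if (!is.null(cp[["300A,011E"]])) gantry <- cp[["300A,011E"]]
    for (dev in cp[["300A,011A"]]) {
      type <- dev[["300A,00B8"]]
      pos <- dev[["300A,011C"]]
      if (is.null(type) || is.null(pos)) next
      if (type %in% c("X", "ASYMX")) jaw_x <- pos[1:2]
      else if (type %in% c("Y", "ASYMY")) jaw_y <- pos[1:2]
      else if (grepl("^MLC", type)) {
        if (length(pos) != 2L * n) {
          abort("unsupported device: expected ", 2L * n,
                " MLC leaf positions, got ", length(pos))
        }
        leaves <- pos
      }
    }
    if (is.null(leaves)) abort("first control point carries no MLC positions")
    weight <- cp[["300A,0134"]]
    if (is.null(weight)) abort("control point missing cumulative meterset weight")
    cps[[k]] <- control_point(
      index = cp[["300A,0112"]] %||% (k - 1L),
      gantry_angle = gantry,
      cumulative_weight = weight,
      aperture = aperture(leaves[seq_len(n)], leaves[n + seq_len(n)],
                          c(sort(jaw_x), sort(jaw_y)), geometry)
    )
  }

  beam_type <- beam[["300A,00C4"]] %||% "STATIC"
  if (!identical(beam_type, "DYNAMIC")) {
    warning("beam ", beam[["300A,00C2"]] %||% "?",
            " is not a dynamic-gantry (VMAT) beam; scored but tagged ",
            beam_type, call. = FALSE)
  }
  if (length(cps) < 2L) abort("beam has fewer than 2 control points")
  rt_arc(beam_id = beam[["300A,00C2"]] %||% as.character(beam[["300A,00C0"]]),
         beam_mu = beam_mu, geometry = geometry, control_points = cps,
         beam_type = beam_type, mu_method = mu_method)
}

#' Read a DICOM-RT Plan file
#'
#' Builds the plan model from an RTPLAN: one arc per treatment beam carrying
#' an MLC, with leaf/jaw positions carried forward between control points and
#' per-control-point MU allocated from the beam meterset (see
#' [control_point_mu()]).  Setup beams (zero or missing meterset) are skipped
#' with a warning; non-dynamic beams are accepted with a warning and tagged.
#'
#' @param path path to an RTPLAN DICOM file
#' @param mu_method MU allocation rule, see [control_point_mu()]
#' @return an [rt_plan()]
#' @export
read_rtplan <- function(path, mu_method = "midpoint") {
  f <- dcm_read_file(path)
  modality <- f$data[["0008,0060"]]
  if (is.null(modality) || !identical(modality, "RTPLAN")) {
    abort("not an RTPLAN: modality is ",
          if (is.null(modality)) "<missing>" else modality)
  }
  fgs <- f$data[["300A,0070"]]
  if (is.null(fgs) || length(fgs) < 1L) abort("RTPLAN has no fraction group")
  if (length(fgs) > 1L) {
    message("multiple fraction groups; using the first")
  }
  metersets <- list()
  for (rb in fgs[[1]][["300C,0004"]]) {
    num <- as.character(rb[["300C,0006"]])
    if (!is.null(rb[["300A,0086"]]) && is.null(metersets[[num]])) {
      metersets[[num]] <- rb[["300A,0086"]]
    }
  }

  beams <- f$data[["300A,00B0"]]
  if (is.null(beams)) abort("no MLC beam: RTPLAN has no beam sequence")
  arcs <- list()
  for (beam in beams) {
    num <- as.character(beam[["300A,00C0"]])
    mu <- metersets[[num]]
    delivery <- beam[["300A,00CE"]] %||% "TREATMENT"
    if (is.null(mu) || mu <= 0 || !identical(delivery, "TREATMENT")) {
      warning("skipping beam ", beam[["300A,00C2"]] %||% num,
              " (setup or zero meterset)", call. = FALSE)
      next
    }
    arc <- read_beam(beam, mu, mu_method)
    if (is.null(arc)) next                    # beam without an MLC
    arcs[[length(arcs) + 1L]] <- arc
  }
  if (length(arcs) == 0L) abort("no MLC beam: no treatment beam with an MLC device")
  rt_plan(plan_id = f$data[["300A,0002"]] %||% f$data[["0008,0018"]] %||% path,
          arcs = arcs)
}
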