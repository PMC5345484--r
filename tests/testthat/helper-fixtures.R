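# Shared fixtures: small geometries, parameterised apertures, and random
# staircase generators.  Everything is built in code; no binary fixtures.

# single leaf pair of the given band height: y/A = 2/height exactly,
# convenient for arcs with prescribed per-aperture complexity
single_pair_rect <- function(width, height) {
  g <- mlc_geometry(c(-height / 2, height / 2))
  aperture(-width / 2, width / 2,
           c(-width / 2 - 5, width / 2 + 5, -height / 2, height / 2), g)
}

closed_aperture <- function(height = 20) {
  g <- mlc_geometry(c(-height / 2, height / 2))
  aperture(0, 0, c(-50, 50, -height / 2, height / 2), g)
}

# 12 x 5 mm band geometry used by staircase tests
staircase_geometry <- function(n_pairs = 12L, band = 5) {
  mlc_geometry(seq(0, n_pairs * band, by = band) - n_pairs * band / 2)
}

# random staircase aperture: arbitrary (off-grid) leaf positions, some pairs
# parked closed, jaws clipping both axes
random_staircase <- function(n_pairs = 12L, band = 5) {
  g <- staircase_geometry(n_pairs, band)
  centers <- runif(n_pairs, -10, 10)
  half <- runif(n_pairs, 0, 25)
  closed <- runif(n_pairs) < 0.2
  left <- centers - half
  right <- centers + half
  left[closed] <- 0
  right[closed] <- 0
  span <- n_pairs * band / 2
  # keep jaw-clipped band heights >= 0.5 mm: the raster oracle cannot see
  # slivers thinner than a pixel, and the discretization tolerance assumes
  # every feature spans at least one pixel
  jaws <- c(-40 - runif(1, 0, 10), 40 + runif(1, 0, 10),
            -span + runif(1, 0.5, band - 0.5), span - runif(1, 0.5, band - 0.5))
  aperture(left, right, jaws, g)
}

# arc whose control points carry the given apertures; cumulative weights
# chosen by the caller to steer the MU split
fixture_arc <- function(apertures, weights, beam_mu = 100,
                        geometry = apertures[[1]]$geometry, id = "ARC1") {
  cps <- lapply(seq_along(apertures), function(k) {
    control_point(k - 1L, gantry_angle = (k - 1L) * 10,
                  cumulative_weight = weights[k], aperture = apertures[[k]])
  })
  rt_arc(id, beam_mu, geometry, cps)
}

# uniformly scale every coordinate of an aperture by s
scale_aperture <- function(ap, s) {
  g <- mlc_geometry(ap$geometry$leaf_boundaries * s)
  aperture(ap$left * s, ap$right * s, ap$jaws * s, g)
}

# independent brute-force re-count used against cohort_summary()
recount_group <- function(rec, threshold) {
  above <- rec$complexity_mm_inv > threshold
  fail <- !is.na(rec$qa_pass) & !rec$qa_pass
  c(total = nrow(rec), failing = sum(fail), above = sum(above),
    failing_above = sum(fail & above))
}
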