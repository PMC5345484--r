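# Arc/plan aggregation of y/A.

test_that("arc_complexity reproduces the MU-weighted arithmetic", {
  # apertures with y/A = 0.1 (h = 20) and 0.2 (h = 10); weights chosen so the
  # midpoint rule delivers MU 30 through the first and 70 through the second
  A <- single_pair_rect(40, 20)
  B <- single_pair_rect(40, 10)
  arc <- fixture_arc(list(A, B, B), weights = c(0, 0.6, 1), beam_mu = 100,
                     geometry = A$geometry)
  ac <- arc_complexity(arc)
  expect_equal(ac$M, 0.17)
  expect_equal(ac$included_mu, 100)
  expect_equal(ac$excluded_cp_count, 0L)

  # constant aperture: any MU split gives the aperture's own y/A
  rect <- single_pair_rect(100, 50)
  arc2 <- fixture_arc(rep(list(rect), 5), weights = c(0, .1, .35, .8, 1),
                      beam_mu = 333)
  expect_equal(arc_complexity(arc2)$M, 0.04)
})

test_that("closed apertures are excluded from both sums, with a warning", {
  # closed aperture gets MU 10, open (y/A = 0.1) gets MU 90
  C <- closed_aperture(20)
  O <- single_pair_rect(40, 20)
  arc <- fixture_arc(list(C, O, O), weights = c(0, 0.2, 1), beam_mu = 100,
                     geometry = C$geometry)
  expect_warning(ac <- arc_complexity(arc), "closed aperture")
  expect_equal(ac$M, 0.1)
  expect_equal(ac$excluded_cp_count, 1L)
  expect_equal(ac$included_mu, 90)

  # no includable control point at all
  arc_empty <- fixture_arc(list(C, C), weights = c(0, 1), beam_mu = 50)
  expect_error(suppressWarnings(arc_complexity(arc_empty)),
               "all apertures empty")
})

test_that("plan_complexity is the included-MU-weighted mean of arc values", {
  arc1 <- fixture_arc(rep(list(single_pair_rect(40, 20)), 2),
                      weights = c(0, 1), beam_mu = 100, id = "A1")
  arc2 <- fixture_arc(rep(list(single_pair_rect(40, 10)), 2),
                      weights = c(0, 1), beam_mu = 300, id = "A2")
  pc <- plan_complexity(rt_plan("P", list(arc1, arc2)))
  expect_equal(pc$M, 0.175)                       # (100*0.1 + 300*0.2) / 400

  # one-arc plan: plan M equals arc M
  pc1 <- plan_complexity(rt_plan("P1", list(arc1)))
  expect_equal(pc1$M, arc_complexity(arc1)$M)

  # plan M also equals the direct pooled Eq-style sum over all control points
  prof <- do.call(rbind, lapply(pc$per_arc, `[[`, "profile"))
  inc <- !is.na(prof$complexity_mm_inv)
  expect_equal(pc$M, sum(prof$mu[inc] * prof$complexity_mm_inv[inc]) /
                 sum(prof$mu[inc]))
})

test_that("M is invariant under MU rescaling and scales as 1/s with geometry", {
  plan <- make_modulated_plan(modulation_spec(n_control_points = 10L,
                                              sigma = 2, seed = 9))
  M0 <- plan_complexity(plan)$M

  # multiply every MU by 5 (via the beam meterset: MU_i scale together)
  arcs5 <- lapply(plan$arcs, function(a) {
    rt_arc(a$beam_id, a$beam_mu * 5, a$geometry, a$control_points)
  })
  expect_equal(plan_complexity(rt_plan("x5", arcs5))$M, M0)

  # geometric scaling by s
  for (s in c(0.5, 2)) {
    arcs_s <- lapply(plan$arcs, function(a) {
      g_s <- mlc_geometry(a$geometry$leaf_boundaries * s)
      cps <- lapply(a$control_points, function(cp) {
        control_point(cp$index, cp$gantry_angle, cp$cumulative_weight,
                      scale_aperture(cp$aperture, s))
      })
      rt_arc(a$beam_id, a$beam_mu, g_s, cps)
    })
    # gap tolerance scales with the geometry (see test-mlc-model)
    expect_equal(plan_complexity(rt_plan("s", arcs_s), min_gap = 0.5 * s)$M,
                 M0 / s)
  }
})

test_that("plan M lies within [min, max] of included per-aperture y/A", {
  set.seed(77)
  for (k in 1:10) {
    n_cp <- sample(4:12, 1)
    aps <- replicate(n_cp, random_staircase(), simplify = FALSE)
    w <- cumsum(c(0, runif(n_cp - 1)))
    arc <- tryCatch(fixture_arc(aps, w, beam_mu = 200,
                                geometry = aps[[1]]$geometry),
                    error = function(e) NULL)
    if (is.null(arc)) next
    ac <- tryCatch(suppressWarnings(arc_complexity(arc)),
                   error = function(e) NULL)
    if (is.null(ac)) next
    cx <- ac$profile$complexity_mm_inv
    inc <- !is.na(cx) & ac$profile$mu > 0
    expect_gte(ac$M, min(cx[inc]) - 1e-12)
    expect_lte(ac$M, max(cx[inc]) + 1e-12)
  }
})

test_that("complexity_profile reports per-control-point values with NA gaps", {
  rect <- single_pair_rect(100, 50)
  arc <- fixture_arc(rep(list(rect), 4), weights = c(0, .3, .6, 1))
  prof <- complexity_profile(arc)
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$complexity_mm_inv, rep(0.04, 4))   # flat profile

  C <- closed_aperture(50)
  arc2 <- fixture_arc(list(rect, C, rect), weights = c(0, .5, 1),
                      geometry = rect$geometry)
  prof2 <- complexity_profile(arc2)
  expect_true(is.na(prof2$complexity_mm_inv[2]))
  expect_equal(prof2$gantry_deg, c(0, 10, 20))
})

test_that("profile CSV export round-trips the table", {
  plan <- make_rectangle_plan(80, n_bands = 6L, n_cp = 5L)
  pc <- plan_complexity(plan)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(pc, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 5L)
  expect_equal(got$complexity_mm_inv, pc$per_arc[[1]]$profile$complexity_mm_inv)
})
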