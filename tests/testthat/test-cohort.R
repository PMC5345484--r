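# Cohort CSV I/O, summaries, histogram and percentile.

write_cohort_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("plan_id,site,fractionation,complexity_mm_inv,qa_pass", lines),
             path)
  path
}

test_that("load_cohort parses valid rows, blanks and rejects bad ones", {
  path <- write_cohort_lines(c(
    "p1,Head and Neck,standard,0.141,TRUE",
    "p2,Brain,SBRT,0.21,FALSE",
    "p3,Liver,,0.09,"
  ))
  rec <- load_cohort(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$fractionation, c("standard", "SBRT", "unknown"))
  expect_equal(rec$qa_pass, c(TRUE, FALSE, NA))

  # non-positive complexity names the offending line (header is line 1)
  bad <- write_cohort_lines(c("p1,Brain,standard,0.1,TRUE",
                              "p2,Brain,standard,-0.1,TRUE"))
  expect_error(load_cohort(bad), "line 3")
  bad2 <- write_cohort_lines("p1,Brain,standard,0.1,maybe")
  expect_error(load_cohort(bad2), "qa_pass")
  # missing column
  path3 <- tempfile(fileext = ".csv")
  writeLines(c("plan_id,complexity_mm_inv", "p1,0.1"), path3)
  expect_error(load_cohort(path3), "missing column")
})

test_that("save_cohort / load_cohort round-trips including unlabeled rows", {
  co <- simulate_cohort(cohort_spec(n_pass = 20L, n_fail = 5L, seed = 3))
  co$qa_pass[3] <- NA
  path <- tempfile(fileext = ".csv")
  save_cohort(co, path)
  got <- load_cohort(path)
  expect_equal(got$plan_id, co$plan_id)
  expect_equal(got$qa_pass, co$qa_pass)
  expect_equal(got$complexity_mm_inv, co$complexity_mm_inv, tolerance = 1e-12)
})

test_that("cohort_summary matches a brute-force recount on a seeded cohort", {
  co <- rbind(
    simulate_cohort(cohort_spec(n_pass = 120L, n_fail = 15L, seed = 21),
                    site = "Head and Neck"),
    simulate_cohort(cohort_spec(n_pass = 40L, n_fail = 8L, seed = 22),
                    site = "Brain"))
  co$fractionation[seq(1, nrow(co), by = 4)] <- "SBRT"
  t <- 0.16
  s <- cohort_summary(co, t)
  groups <- ifelse(co$fractionation == "SBRT", paste(co$site, "SBRT"), co$site)
  for (i in seq_len(nrow(s))) {
    rec <- if (s$group[i] == "All") co else co[groups == s$group[i], ]
    expect_equal(unname(unlist(s[i, c("total", "failing", "above",
                                      "failing_above")])),
                 unname(recount_group(rec, t)))
    fail_x <- rec$complexity_mm_inv[!rec$qa_pass]
    if (length(fail_x) >= 2) expect_equal(s$sd_fail[i], sd(fail_x))
  }
  # groups partition the total; failing_above bounded by both margins
  expect_equal(sum(s$total[-1]), s$total[1])
  expect_true(all(s$failing_above <= pmin(s$failing, s$above)))
})

test_that("cohort_summary handles degenerate groups the way tables print them", {
  co <- data.frame(
    plan_id = c("a", "b", "c"), site = "Liver", fractionation = "standard",
    complexity_mm_inv = c(0.12, 0.15, 0.19),
    qa_pass = c(TRUE, FALSE, FALSE))
  s <- cohort_summary(co, 0.18)
  liver <- s[s$group == "Liver", ]
  expect_equal(liver$failing_above, 1)             # 0.19 above, 0.15 below
  # single record, passing, below threshold
  s1 <- cohort_summary(co[1, ], 0.18)
  expect_equal(unname(unlist(s1[1, c("total", "failing", "above",
                                     "failing_above")])), c(1, 0, 0, 0))
  expect_true(is.na(s1$mean_fail[1]))              # dash: no failing plans
  expect_true(is.na(s1$sd_pass[1]))                # lone plan: mean, no SD
  f <- format_cohort_summary(s1)
  expect_equal(f$failing_complexity[1], "-")
  expect_equal(f$passing_complexity[1], "0.120")
  # ties at the threshold are not "above"
  expect_equal(cohort_summary(co, 0.19)[1, "above"], 0)
})

test_that("histogram bins anchored at 0 conserve counts and honour filters", {
  co <- data.frame(plan_id = c("a", "b", "c"),
                   site = c("Brain", "Brain", "Lung"),
                   fractionation = "standard",
                   complexity_mm_inv = c(0.005, 0.015, 0.015),
                   qa_pass = TRUE)
  h <- cohort_histogram(co, bin_width = 0.01)
  expect_equal(h$count, c(1L, 2L))
  expect_equal(h$bin_lo, c(0, 0.01))
  expect_equal(sum(h$count), nrow(co))

  hb <- cohort_histogram(co, site_filter = "Brain", bin_width = 0.01)
  expect_equal(sum(hb$count), 2L)
  expect_error(cohort_histogram(co, site_filter = "Pelvis"), "site filter")
  expect_error(cohort_histogram(co, bin_width = 0), "bin_width")

  set.seed(31)
  co2 <- simulate_cohort(cohort_spec(n_pass = 500L, n_fail = 50L, seed = 31))
  expect_equal(sum(cohort_histogram(co2)$count), 550L)
})

test_that("percentile_of is the mid-rank percentile and is monotone", {
  co <- data.frame(plan_id = "a", site = "all", fractionation = "standard",
                   complexity_mm_inv = 0.15, qa_pass = TRUE)
  expect_equal(percentile_of(0.15, co), 50)        # equal to the only record
  expect_equal(percentile_of(0.99, co), 100)

  co101 <- data.frame(plan_id = as.character(1:101), site = "all",
                      fractionation = "standard",
                      complexity_mm_inv = seq(0.05, 0.25, length.out = 101),
                      qa_pass = TRUE)
  expect_equal(percentile_of(co101$complexity_mm_inv[51], co101), 50)

  set.seed(41)
  co3 <- simulate_cohort(cohort_spec(n_pass = 200L, n_fail = 20L, seed = 41))
  ms <- sort(runif(20, 0.05, 0.3))
  ps <- vapply(ms, percentile_of, numeric(1), records = co3)
  expect_true(all(diff(ps) >= 0))
})
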