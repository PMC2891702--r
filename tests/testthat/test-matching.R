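# small helper: a trace data.frame for one cluster
make_trace <- function(intensity, times = seq_along(intensity) - 1,
                       mz = 610.8, rt = 30) {
  data.frame(cluster_id = 1L, cluster_mz = mz, rt = rt,
             digestion_time = times, intensity = intensity)
}

test_that("match_clusters keeps exactly the clusters near observed peaks", {
  db <- build_database(substrate("s", "RTKAWNRQLYPEW"))
  peaks <- data.frame(mz = 610.8, rt_min = 30, intensity = 1e6,
                      digestion_time = 1)
  m <- match_clusters(db, peaks, 0.5)
  expect_true(all(abs(m$cluster_mz - 610.8) <= 0.5))
  expect_true(nrow(m) >= 1)
  expect_equal(nrow(match_clusters(db, transform(peaks, mz = 612.0), 0.5)),
               sum(abs(db$clusters$cluster_mz - 612.0) <= 0.5))
  # zero tolerance means exact equality only
  exact <- db$clusters$cluster_mz[5]
  m0 <- match_clusters(db, data.frame(mz = exact, rt_min = 1, intensity = 1,
                                      digestion_time = 1), 0)
  expect_equal(m0$cluster_mz, exact)
  expect_error(match_clusters(db, peaks[0, ], 0.5), "no peak lists")
})

test_that("detect_peaks finds apexes above the S/N threshold", {
  rt <- seq(0, 10, 0.1)
  gauss <- function(mu, a) a * exp(-(rt - mu)^2 / 0.1)
  # single apex 10x the baseline median
  xic <- data.frame(rt = rt, intensity = gauss(5, 1000) + 100)
  pk <- detect_peaks(xic, delta = 2, noise_floor = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$rt, 5)
  # flat noise: no peaks at delta = 2
  flat <- data.frame(rt = rt, intensity = rep(100, length(rt)))
  expect_equal(nrow(detect_peaks(flat, 2)), 0L)
  # two resolved apexes both > 2x noise
  two <- data.frame(rt = rt, intensity = gauss(3, 800) + gauss(7, 900) + 50)
  pk2 <- detect_peaks(two, 2)
  expect_equal(sort(pk2$rt), c(3, 7))
  # all-zero trace: no peaks
  expect_equal(nrow(detect_peaks(data.frame(rt = rt, intensity = 0), 2)), 0L)
})

test_that("kinetic_filter applies the t = 0 and monotonicity criteria", {
  p <- filter_params()
  # monotone rise is kept with t_max at the last time
  k1 <- kinetic_filter(make_trace(c(0, 2e6, 5e6, 8e6)), p)
  expect_equal(nrow(k1), 1L)
  expect_equal(k1$t_max, 3)
  # contaminant: t = 0 intensity >= MAX
  expect_equal(nrow(kinetic_filter(make_trace(c(2e7, 3e7, 4e7, 5e7)), p)), 0L)
  # rise then fall: kept only when re-entry is allowed
  rf <- c(0, 5e6, 9e6, 4e6)
  k2 <- kinetic_filter(make_trace(rf), p)
  expect_equal(k2$t_max, 2)
  p_nore <- filter_params(allow_reentry = FALSE)
  expect_equal(nrow(kinetic_filter(make_trace(rf), p_nore)), 0L)
  # non-monotone zig-zag is rejected either way
  expect_equal(nrow(kinetic_filter(make_trace(c(0, 5e6, 1e6, 8e6)), p)), 0L)
  # a dip within epsilon is tolerated
  dip <- c(0, 4e6, 4e6 * 0.97, 8e6)
  expect_equal(nrow(kinetic_filter(make_trace(dip), p)), 1L)
  # shape decision is scale invariant (only the absolute MAX test changes)
  expect_equal(nrow(kinetic_filter(make_trace(rf / 100), p)), 1L)
  expect_equal(nrow(kinetic_filter(make_trace(rf * 0.5), p_nore)), 0L)
  # short traces warn and are rejected
  expect_warning(k3 <- kinetic_filter(make_trace(5e6, times = 0), p),
                 "fewer than 2")
  expect_equal(nrow(k3), 0L)
})

test_that("t_max ties resolve to the earliest time", {
  tied <- make_trace(c(0, 7e6, 7e6, 7e6))
  expect_equal(kinetic_filter(tied, filter_params())$t_max, 1)
})

test_that("group_candidates balances subgroups under d_max", {
  rec <- data.frame(cluster_id = 1:40, cluster_mz = 500 + 1:40,
                    rt = 30, t_max = 8)
  incl <- group_candidates(rec, 15)
  expect_equal(incl$n_groups, 1L)
  expect_equal(incl$n_subgroups, 3L)
  expect_equal(sort(as.integer(table(incl$entries$subgroup_id)),
                    decreasing = TRUE), c(14L, 13L, 13L))
  # every candidate lands in exactly one subgroup
  expect_equal(nrow(incl$entries), 40L)
  expect_equal(anyDuplicated(incl$entries$mz), 0L)
  # group of <= d_max stays whole (boundary: exactly 15)
  incl15 <- group_candidates(rec[1:15, ], 15)
  expect_equal(incl15$n_subgroups, 1L)
  # two t_max values give two groups
  rec2 <- rbind(rec, transform(rec, t_max = 24, cluster_mz = 600 + 1:40))
  incl2 <- group_candidates(rec2, 15)
  expect_equal(incl2$n_groups, 2L)
  expect_equal(incl2$n_subgroups, 6L)
  expect_equal(group_candidates(rec[0, ], 15)$n_groups, 0L)
})

test_that("inclusion CSV is written with the documented columns", {
  rec <- data.frame(cluster_id = 1:3, cluster_mz = c(500.1, 600.2, 700.3),
                    rt = c(10, 20, 30), t_max = c(8, 8, 24))
  csv <- tempfile(fileext = ".csv")
  write_inclusion_csv(group_candidates(rec, 15), csv)
  d <- read.csv(csv)
  expect_equal(names(d), c("mz", "charge", "rt_center_min", "rt_window_min",
                           "t_max", "group_id", "subgroup_id"))
  expect_equal(nrow(d), 3L)
})

test_that("compare_rt uses the strict 0.5-minute window", {
  expect_true(compare_rt(41.3, 41.6))
  expect_false(compare_rt(41.3, 42.0))
  expect_true(compare_rt(41.3, 41.3))
  expect_false(compare_rt(41.0, 41.5))  # boundary is strict
})

test_that("peak lists round-trip through CSV and MGF", {
  peaks <- data.frame(mz = c(500.1, 600.25, 700.333),
                      rt_min = c(10.5, 20.1, 30.9),
                      intensity = c(1e5, 2e6, 3e7),
                      digestion_time = c(0, 1, 1))
  csv <- tempfile(fileext = ".csv")
  write_peaklist_csv(peaks, csv)
  expect_equal(read_peaklist(csv), peaks, tolerance = 1e-9)
  mgf <- tempfile(fileext = ".mgf")
  write_peaklist_mgf(peaks, mgf)
  back <- read_peaklist(mgf)
  back <- back[order(back$digestion_time, back$mz), ]
  rownames(back) <- NULL
  expect_equal(back, peaks, tolerance = 1e-4)
  expect_error(read_peaklist_csv(tempfile()), "not found")
})
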