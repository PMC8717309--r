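test_that("hourly resampling keeps the fix nearest each hour and preserves gaps", {
  t0 <- as.POSIXct("2020-06-01", tz = "UTC")
  hourly <- hourly_track(cbind(1:5 * 100, 0))
  expect_equal(track_resample_hourly(hourly), hourly)
  # 10-minute data: one fix in six survives
  dense <- tibble::tibble(individual_id = "h1",
                          timestamp = t0 + 600 * (0:35),
                          x = as.numeric(0:35), y = 0)
  rs <- track_resample_hourly(dense)
  expect_equal(nrow(rs), 7)   # one fix per whole hour 0..6
  hours <- round(as.numeric(rs$timestamp - t0, units = "hours"))
  expect_equal(hours, 0:6)
  # each retained fix is within tolerance of its hour mark
  expect_true(all(abs(as.numeric(rs$timestamp - t0, units = "secs") -
                        hours * 3600) <= 600))
  # a 3-hour gap stays a gap
  gappy <- tibble::tibble(individual_id = "h1",
                          timestamp = t0 + 3600 * c(0, 1, 4, 5),
                          x = c(0, 1, 2, 3), y = 0)
  expect_equal(nrow(track_resample_hourly(gappy)), 4)
  expect_equal(max(diff(as.numeric(track_resample_hourly(gappy)$timestamp))),
               3 * 3600)
  # off-hour fixes beyond tolerance are dropped
  off <- tibble::tibble(individual_id = "h1",
                        timestamp = t0 + c(0, 3600 + 20 * 60),
                        x = c(0, 1), y = 0)
  expect_equal(nrow(track_resample_hourly(off)), 1)
  bad <- gappy[c(2, 1, 3, 4), ]
  expect_error(track_resample_hourly(bad), "increasing")
})

test_that("patch assignment is point-in-polygon with matrix fallback and edge rule", {
  p <- grid_patches(2, 1, 1000, c("grassland", "field"))
  fx <- hourly_track(rbind(c(500, 500), c(1500, 500), c(5000, 5000),
                           c(1000, 500)))
  a <- assign_patches(fx, p)
  expect_equal(a$patch_id[1:2], c("p01", "p02"))
  expect_equal(a$landuse[1:2], c("grassland", "field"))
  expect_equal(a$landuse[3], "matrix")
  expect_true(is.na(a$patch_id[3]))
  # shared boundary x = 1000: lexicographically smallest id wins
  expect_equal(a$patch_id[4], "p01")
  # overlapping layer is an error naming the offenders
  overlap <- make_patches(c("q1", "q2"), c("field", "field"),
                          list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                               cbind(c(5, 15, 15, 5), c(0, 0, 10, 10))))
  expect_error(assign_patches(hourly_track(cbind(7, 5)), overlap),
               "Overlapping.*q1.*q2")
})

test_that("centroid distances and habitat-pair classes are correct", {
  p <- grid_patches(2, 1, 1000, c("grassland", "field"))
  pd <- patch_distance_matrix(p)
  expect_equal(pd$distances["p01", "p02"], 1000)
  expect_equal(pd$classes$mean_m[pd$classes$class == "differing"], 1000)
  expect_equal(pd$classes$n_pairs[pd$classes$class == "field-field"], 0)
  # three collinear patches 0, 1, 2 km apart: mean pairwise distance 4/3 km
  tri <- make_patches(paste0("t", 1:3), rep("field", 3), lapply(0:2, function(k) {
    cbind(c(0, 10, 10, 0) + 1000 * k, c(0, 0, 10, 10))
  }))
  pdt <- patch_distance_matrix(tri)
  expect_equal(mean(pdt$distances[upper.tri(pdt$distances)]), 4000 / 3)
  expect_equal(pdt$classes$n_pairs[pdt$classes$class == "differing"], 0)
  expect_warning(patch_distance_matrix(p[1, ]), "Fewer than two")
})

test_that("sliding windows follow the closed-interval rule with gap truncation", {
  trk <- hourly_track(cbind(0:9 * 100, 0))
  w7 <- sliding_windows(trk, 7)
  expect_equal(nrow(w7), 10)
  expect_equal(w7$n_fixes[1], 8)            # hours 0..7 inclusive
  expect_false(w7$truncated[1])
  expect_true(w7$truncated[10])             # single-fix tail window
  w56 <- sliding_windows(trk, 5.6)
  expect_true(all(w56$n_fixes <= 6))        # floor(5.6) + 1
  expect_equal(w56$n_fixes[1], 6)
  # track shorter than T: truncated from the start
  short <- hourly_track(cbind(0:2 * 100, 0))
  ws <- sliding_windows(short, 7)
  expect_true(all(ws$truncated))
  expect_equal(ws$n_fixes, c(3L, 2L, 1L))
  # gaps truncate
  t0 <- as.POSIXct("2020-06-01", tz = "UTC")
  gap <- tibble::tibble(individual_id = "h1",
                        timestamp = t0 + 3600 * c(0:2, 6:8),
                        x = 0, y = 0)
  wg <- sliding_windows(gap, 7)
  expect_equal(wg$n_fixes[1], 3)
  expect_error(sliding_windows(trk, 0), "retention_hours")
})

test_that("moving windows agree with a brute-force oracle on random tracks", {
  set.seed(61)
  t0 <- as.POSIXct("2020-06-01", tz = "UTC")
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    hours <- cumsum(sample(c(1, 1, 1, 1, 2, 3), n, replace = TRUE))
    trk <- tibble::tibble(individual_id = "h1", timestamp = t0 + 3600 * hours,
                          x = rnorm(n), y = rnorm(n))
    Th <- sample(c(5.6, 7, 8.4), 1)
    w <- sliding_windows(trk, Th)
    expect_equal(w$rows, brute_force_windows(trk, Th))
  }
})

test_that("window counts are monotone in retention time", {
  set.seed(62)
  p <- grid_patches(5, 5, 300,
                    sample(c("field", "grassland", "forest"), 25, TRUE))
  trk <- sim_track(p, n_steps = 60, step_scale = 150, seed = 7)
  a <- assign_patches(trk, p)
  types_by_T <- sapply(c(5.6, 7, 8.4), function(Th) {
    w <- sliding_windows(a, Th)
    sapply(w$rows, function(r) window_connectivity(r, a)$n_types)
  })
  expect_true(all(types_by_T[, 1] <= types_by_T[, 2]))
  expect_true(all(types_by_T[, 2] <= types_by_T[, 3]))
})

test_that("window connectivity counts types and unique patches per type", {
  a <- tibble::tibble(individual_id = "h1", timestamp = Sys.time() + 1:4,
                      x = 0, y = 0,
                      patch_id = c("P1", "P1", "P2", "P3"),
                      landuse = c("grassland", "grassland", "field", "field"))
  wc <- window_connectivity(1:4, a)
  expect_equal(wc$n_types, 2)
  expect_equal(wc$patches_per_type$n_patches[wc$patches_per_type$landuse == "field"], 2)
  expect_equal(wc$patches_per_type$n_patches[wc$patches_per_type$landuse == "grassland"], 1)
  one <- window_connectivity(1:2, a)
  expect_equal(one$n_types, 1)
  allm <- a; allm$landuse <- "matrix"; allm$patch_id <- NA
  wm <- window_connectivity(1:4, allm)
  expect_equal(wm$n_types, 0)
  expect_true(wm$all_matrix)
})

test_that("travel distance sums steps, distinguishes net displacement, and is rigid-motion invariant", {
  trk <- hourly_track(rbind(c(0, 0), c(3000, 4000), c(3000, 4000)))
  expect_equal(window_travel_distance(1:2, trk), 5)
  expect_equal(window_travel_distance(1:3, trk), 5)
  loop <- hourly_track(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 0)))
  expect_gt(window_travel_distance(1:4, loop), 0)
  expect_equal(window_travel_distance(1:4, loop, mode = "net"), 0)
  expect_equal(window_travel_distance(1, trk), 0)
  # rotation + translation leave path length unchanged
  th <- 0.7
  rot <- loop
  rot$x <- cos(th) * loop$x - sin(th) * loop$y + 5000
  rot$y <- sin(th) * loop$x + cos(th) * loop$y - 2000
  expect_equal(window_travel_distance(1:4, rot),
               window_travel_distance(1:4, loop))
})

test_that("connectivity summary handles sedentary and alternating toy tracks", {
  p <- grid_patches(2, 1, 1000, c("field", "field"))
  # never leaves patch p01
  sed <- hourly_track(matrix(rep(c(500, 500), 30), ncol = 2, byrow = TRUE) +
                        cbind(runif(30, -5, 5), runif(30, -5, 5)))
  cs <- connectivity_summary(sed, p, min_days = 0)
  expect_true(all(cs$per_individual$mean_types == 1))
  # alternates between the two field patches every hour
  alt <- hourly_track(matrix(rep(c(500, 500, 1500, 500), 15),
                             ncol = 2, byrow = TRUE))
  ca <- connectivity_summary(alt, p, min_days = 0)
  ppt7 <- ca$per_type[ca$per_type$retention_h == 7, ]
  expect_equal(ppt7$mean_unique_patches[ppt7$landuse == "field"], 2)
  # composition: all transitions are field-field
  expect_equal(ca$composition$pair, "field-field")
  expect_equal(ca$composition$pct, 100)
})

test_that("connection composition classifies unordered land-use pairs", {
  p <- make_patches(c("F1", "F2", "G1"), c("field", "field", "grassland"),
                    list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                         cbind(c(20, 30, 30, 20), c(0, 0, 10, 10)),
                         cbind(c(40, 50, 50, 40), c(0, 0, 10, 10))))
  # F1 -> F2 -> G1 -> F2 : field-field once, field-grassland twice
  trk <- hourly_track(rbind(c(5, 5), c(25, 5), c(45, 5), c(25, 5)))
  cs <- connectivity_summary(trk, p, min_days = 0, retention_hours = 7)
  comp <- cs$composition
  expect_equal(sum(comp$pct), 100)
  expect_equal(comp$pct[comp$pair == "field-grassland"], 200 / 3)
  expect_equal(comp$pct[comp$pair == "field-field"], 100 / 3)
})

test_that("individuals below the minimum tracking duration are excluded", {
  p <- grid_patches(1, 1, 1000, "field")
  long_trk <- hourly_track(matrix(rep(c(500, 500), 250), ncol = 2, byrow = TRUE),
                           id = "long")
  short_trk <- hourly_track(matrix(rep(c(500, 500), 5), ncol = 2, byrow = TRUE),
                            id = "short")
  both <- dplyr::bind_rows(long_trk, short_trk)
  expect_message(cs <- connectivity_summary(both, p, min_days = 10), "short")
  expect_equal(cs$excluded, "short")
  expect_setequal(unique(cs$per_individual$individual_id), "long")
  expect_error(suppressMessages(connectivity_summary(short_trk, p, min_days = 10)),
               "minimum tracking duration")
})
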