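test_that("habitability is strict: cells at exactly the limit are excluded", {
  g <- gradient_grid(nr = 10, nc = 4)   # T = 25 - 0.5 lat, rows warm southward
  row5_T <- g$values[5, 1]
  hab <- habitable_mask(g, row5_T)      # limit equals row 5's temperature
  expect_false(any(hab[5, ]))           # "warmer than" is strict
  expect_true(all(hab[6:10, ]))         # warmer rows qualify
  expect_false(any(hab[1:5, ]))

  expect_true(all(habitable_mask(g, min(g$values) - 1)))
  empty <- habitable_mask(g, max(g$values) + 1)
  expect_false(any(empty))
  expect_true(attr(empty, "empty"))

  g$values[2, 2] <- NA                  # masked cells never habitable
  expect_false(habitable_mask(g, -100)[2, 2])
})

test_that("queen connectivity joins diagonals; rook does not", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  q <- label_clumps(m, connectivity = 8)
  r <- label_clumps(m, connectivity = 4)
  expect_equal(attr(q, "n_clumps"), 1L)
  expect_equal(attr(r, "n_clumps"), 2L)
})

test_that("clump labelling matches the flood-fill oracle on random masks", {
  set.seed(19)
  for (i in 1:30) {
    m <- matrix(runif(400) < 0.45, 20, 20)
    for (conn in c(4, 8)) {
      got <- label_clumps(m, connectivity = conn)
      want <- flood_fill_labels(m, connectivity = conn)
      expect_identical(unname(got[,]), want,
                       info = paste("case", i, "conn", conn))
    }
  }
})

test_that("antimeridian wrap joins components across the seam", {
  m <- matrix(FALSE, 3, 8)
  m[2, 1] <- TRUE; m[2, 8] <- TRUE
  expect_equal(attr(label_clumps(m, wrap = FALSE), "n_clumps"), 2L)
  expect_equal(attr(label_clumps(m, wrap = TRUE), "n_clumps"), 1L)
})

test_that("clump filter drops below 5% of the largest and keeps exact ties", {
  fx <- make_fixtures()
  labs <- label_clumps(fx$clump_grid)
  fc <- filter_clumps(labs)
  expect_setequal(fc$census$area[fc$census$kept], c(100, 6))
  expect_setequal(fc$census$area[!fc$census$kept], 4)

  # sizes {40, 2}: threshold is exactly 2 and "less than" keeps the tie
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:8] <- TRUE
  m[8, c(1, 2)] <- TRUE
  fc2 <- filter_clumps(label_clumps(m))
  expect_true(all(fc2$census$kept))

  # single clump is kept; filtering never increases area
  single <- filter_clumps(label_clumps(matrix(TRUE, 3, 3)))
  expect_true(all(single$census$kept))
  expect_lte(sum(fc$mask), sum(labs > 0))
})

test_that("cos-latitude clump areas weight poleward cells less", {
  m <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
  labs <- label_clumps(m, connectivity = 4)     # two 1-cell clumps
  fc <- filter_clumps(labs, lat = c(80, 0), area = "coslat")
  expect_equal(sort(fc$census$area), sort(c(cos(80 * pi / 180), 1)),
               tolerance = 1e-12)
})

test_that("latitudinal overlap restriction keeps intersecting clumps and crops longitudes", {
  g <- gradient_grid(nr = 10, nc = 10)
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:4] <- TRUE      # clump A (poleward)
  m[7:9, 6:9] <- TRUE      # clump B (equatorward)
  labs <- label_clumps(m)
  # observed extent overlapping only clump B
  fin <- restrict_to_observed(labs, g$lat, g$lon,
                              lat_range = range(g$lat[7:8]),
                              lon_range = range(g$lon[6:8]))
  expect_false(attr(fin, "no_overlap"))
  expect_equal(sum(fin), sum(m[7:9, 6:8]))   # cropped to observed longitudes
  # sharing a single latitude row suffices (closed intervals)
  fin2 <- restrict_to_observed(labs, g$lat, g$lon,
                               lat_range = c(g$lat[3], g$lat[3] + 2),
                               lon_range = range(g$lon))
  expect_true(any(fin2[2:3, ]))
  none <- restrict_to_observed(labs, g$lat, g$lon,
                               lat_range = c(-60, -50),
                               lon_range = range(g$lon))
  expect_true(attr(none, "no_overlap"))
})

test_that("projected boundary latitude is the median poleward cell latitude", {
  g <- gradient_grid(nr = 10, nc = 6)
  rect <- matrix(FALSE, 10, 6); rect[4:8, 2:5] <- TRUE
  expect_equal(as.numeric(project_crb(rect, g$lat, g$lon, "N")), g$lat[4])

  # staircase with poleward rows at latitudes 40, 41, 42 -> median 41
  lat <- seq(42.5, 38.5, by = -1); lon <- seq(0.5, 2.5)
  st <- matrix(FALSE, 5, 3)
  st[3:5, 1] <- TRUE; st[2:5, 2] <- TRUE; st[1:5, 3] <- TRUE
  expect_equal(as.numeric(project_crb(st, lat, lon, "N")), 41.5)

  empty <- project_crb(matrix(FALSE, 3, 3), lat[1:3], lon, "N")
  expect_true(is.na(empty) && attr(empty, "empty"))
})

test_that("uniform warming shifts the projected boundary by delta over gradient", {
  g <- gradient_grid(nr = 60, nc = 12, res = 1, lat_top = 60,
                     a = 25, b = 0.5)          # 0.5 degC per degree latitude
  fut <- climate_grid(g$values + 2, g$lat, g$lon)
  obs <- block_mask(g, 20:50, 3:10, "sp")
  t_limit <- g$values[20, 1] - 0.25            # edge sits near row 20
  cur_p <- project_range(t_limit, g, obs, "N")
  fut_p <- project_range(t_limit, fut, obs, "N")
  expect_equal(shift_deg(cur_p, fut_p, "N"), 4, tolerance = 1e-9)
  # identical climates shift zero
  expect_equal(shift_deg(cur_p, cur_p, "N"), 0)
})

test_that("southern-hemisphere shifts are sign-normalised poleward-positive", {
  expect_equal(shift_deg(-30, -26, "S"), -4)   # equatorward retreat
  expect_equal(shift_deg(-26, -30, "S"), 4)    # poleward expansion
  und <- shift_deg(NA_real_, -30, "S")
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("warming never retreats the projected boundary", {
  set.seed(29)
  g <- gradient_grid(nr = 40, nc = 10, res = 1, lat_top = 40)
  g$values <- g$values + matrix(rnorm(400, 0, 0.3), 40, 10)
  obs <- block_mask(g, 15:35, 2:9, "sp")
  for (i in 1:10) {
    tl <- runif(1, min(g$values) + 1, g$values[15, 1])
    cur <- project_range(tl, g, obs, "N")
    warm <- climate_grid(g$values + runif(1, 0.5, 3), g$lat, g$lon)
    fut <- project_range(tl, warm, obs, "N")
    if (!is.na(cur$crb_lat) && !is.na(fut$crb_lat))
      expect_gte(fut$crb_lat, cur$crb_lat)
  }
})
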