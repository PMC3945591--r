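test_that("cyclone frequency matches the brute-force great-circle oracle", {
  spec <- grid_spec(8, 8, 1, 100, 14)   # 1-deg cells around 10N
  # one straight west-east track across the middle, category 2 (100 km)
  tr <- data.frame(event_id = 1L, point_index = 1:6,
                   lon = seq(101.5, 106.5, 1), lat = 10.2, category = 2L)
  got <- cyclone_frequency(tr, spec)
  expect_identical(got$values, oracle_cyclone_freq(tr, spec,
                                                   default_cyclone_radii))
  expect_true(any(got$values == 1))
  expect_true(all(got$values %in% c(0, 1)))

  # two identical events double the covered cells
  tr2 <- rbind(tr, transform(tr, event_id = 2L))
  expect_identical(cyclone_frequency(tr2, spec)$values, got$values * 2)

  # a track passing one cell many times still tallies once per event
  loop <- data.frame(event_id = 1L, point_index = 1:5,
                     lon = c(103.5, 103.6, 103.4, 103.5, 103.5),
                     lat = c(10.5, 10.5, 10.5, 10.4, 10.6), category = 1L)
  got <- cyclone_frequency(loop, spec)
  expect_true(max(got$values) == 1)

  # empty list -> all-zero grid; unknown category -> error
  z <- cyclone_frequency(tr[0, ], spec)
  expect_true(all(z$values == 0))
  expect_error(cyclone_frequency(transform(tr, category = 9L), spec),
               "category")
  expect_error(cyclone_frequency(tr, spec, radii_km = c(`1` = 100, `2` = 50)),
               "non-decreasing")
})

test_that("cyclone frequency agrees with the oracle on random tracks", {
  set.seed(11)
  spec <- grid_spec(10, 10, 1, 0, 5)
  tracks <- do.call(rbind, lapply(1:6, function(id) {
    n <- sample(3:6, 1)
    data.frame(event_id = id, point_index = seq_len(n),
               lon = runif(1, 0, 10) + cumsum(runif(n, -1, 1)),
               lat = runif(1, -5, 5) + cumsum(runif(n, -1, 1)),
               category = sample(1:6, 1))
  }))
  expect_identical(cyclone_frequency(tracks, spec)$values,
                   oracle_cyclone_freq(tracks, spec, default_cyclone_radii))
})

test_that("flood frequency counts events containing the cell centre", {
  spec <- grid_spec(5, 5, 1, 0, 5)
  ev <- data.frame(event_id = 1L, lon_min = 2, lat_min = 1,
                   lon_max = 3, lat_max = 2)
  got <- flood_frequency(ev, spec)
  expect_equal(sum(got$values), 1)          # exactly one 1-deg cell hit
  expect_equal(got$values[4, 3], 1)         # centre (2.5, 1.5)

  # additivity: same cell flooded by 3 events
  got3 <- flood_frequency(ev[c(1, 1, 1), ], spec)
  expect_equal(got3$values, got$values * 3)

  # event outside the grid contributes nothing; degenerate box errors
  outside <- data.frame(event_id = 2L, lon_min = 40, lat_min = 40,
                        lon_max = 42, lat_max = 42)
  expect_true(all(flood_frequency(outside, spec)$values == 0))
  expect_error(flood_frequency(
    data.frame(event_id = 1, lon_min = 2, lat_min = 2,
               lon_max = 2, lat_max = 3), spec), "degenerate")
})

test_that("event frequencies are additive over event-list concatenation", {
  set.seed(21)
  spec <- grid_spec(6, 6, 1, 0, 3)
  mk <- function(ids) data.frame(
    event_id = ids,
    lon_min = floor(runif(length(ids), 0, 5)),
    lat_min = floor(runif(length(ids), -3, 2)),
    lon_max = NA, lat_max = NA) |>
    transform(lon_max = lon_min + 1, lat_max = lat_min + 1)
  a <- mk(1:4); b <- mk(5:10)
  expect_equal(flood_frequency(rbind(a, b), spec)$values,
               flood_frequency(a, spec)$values +
                 flood_frequency(b, spec)$values)
})

test_that("drought event detection follows the 50%-of-median run rule", {
  # constant series: every month equals its median, never qualifies
  expect_equal(detect_drought_events(rep(80, 48)), 0)

  # one 4-month span at 40% of the per-month medians -> one event
  s <- rep(100, 48)
  s[13:16] <- 40
  expect_equal(detect_drought_events(s), 1)
  expect_equal(oracle_drought_events(s), 1)

  # a 2-month deficit is below the 3-month run minimum
  s <- rep(100, 48)
  s[20:21] <- 40
  expect_equal(detect_drought_events(s), 0)

  # two separated runs count twice
  s <- rep(100, 60)
  s[10:12] <- 10
  s[30:33] <- 10
  expect_equal(detect_drought_events(s), 2)

  # hyper-arid cell: all-zero precipitation, median below the floor
  expect_equal(detect_drought_events(rep(0, 48)), 0)

  expect_error(detect_drought_events(c(1, 2)), "shorter")
  expect_error(detect_drought_events(c(-1, rep(5, 40))), "negative")
})

test_that("drought detection equals the exhaustive-scan oracle on 1000 series", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(36:72, 1)
    s <- rgamma(n, shape = 2, rate = 1 / 40)
    # inject occasional deficits to exercise run boundaries
    k <- sample(0:6, 1)
    if (k > 0) {
      idx <- sample(n, k)
      s[idx] <- s[idx] * 0.1
    }
    sm <- sample(1:12, 1)
    expect_equal(detect_drought_events(s, start_month = sm),
                 oracle_drought_events(s, start_month = sm))
  }
})

test_that("drought frequency maps detection over cube cells", {
  spec <- grid_spec(2, 2, 2.5, 0, 5)
  cube <- array(100, c(2, 2, 48))
  cube[1, 2, 13:16] <- 40              # one injected 4-month deficit
  got <- drought_frequency(precip_cube(cube, spec))
  expect_equal(got$values, matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))

  # constant cube -> all zero
  expect_true(all(drought_frequency(
    precip_cube(array(50, c(2, 2, 48)), spec))$values == 0))
  expect_error(precip_cube(array(1, c(2, 2, 12)), spec), "36")
})

test_that("valid-cell mask applies the density-or-agriculture rule", {
  spec <- grid_spec(1, 3, 1, 0, 0.5)   # equator row, area ~12364 km2
  area <- cell_areas(spec)$values[1, 1]
  pop <- hx_raster(matrix(c(4, 4, 5) * area, 1, 3), spec)
  ag0 <- hx_raster(matrix(c(0, 1, 0), 1, 3), spec)
  m <- valid_cell_mask(pop, cell_areas(spec), ag0)
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE))
  expect_error(valid_cell_mask(pop, cell_areas(grid_spec(2, 2, 1, 0, 10)),
                               ag0), "specs")
})

test_that("decile binning matches the rank oracle and the tie rules", {
  spec <- grid_spec(10, 10, 1, 0, 10)
  # 100 distinct counts 1..100 -> exactly 10 cells per decile
  freq <- hx_raster(matrix(sample(1:100), 10, 10), spec)
  d <- to_deciles(freq)
  expect_equal(as.vector(table(d$values)), rep(10, 10))
  expect_equal(d$values[freq$values == 100], 10)
  expect_equal(d$values[freq$values == 1], 1)

  # all positive counts identical -> all decile 10 (degenerate tie rule)
  freq <- hx_raster(matrix(c(rep(0, 50), rep(7, 50)), 10, 10), spec)
  d <- to_deciles(freq)
  expect_true(all(d$values[freq$values == 7] == 10))
  expect_true(all(d$values[freq$values == 0] == 0))

  # invalid cells and zero counts get decile 0 and never rank
  freq <- hx_raster(matrix(rpois(100, 3), 10, 10), spec)
  mask <- matrix(rep(c(TRUE, FALSE), 50), 10, 10)
  d <- to_deciles(freq, mask)
  expect_true(all(d$values[!mask] == 0))
  expect_true(all(d$values[freq$values == 0] == 0))

  # no positive cells -> all-zero grid, no error
  expect_true(all(to_deciles(hx_raster(matrix(0, 10, 10), spec))$values == 0))
})

test_that("deciles are order-isomorphic to counts and nearly balanced", {
  set.seed(51)
  spec <- grid_spec(15, 15, 1, 0, 10)
  for (i in 1:20) {
    freq <- random_raster(spec, function(n) rpois(n, sample(2:20, 1)))
    mask <- matrix(runif(225) < 0.8, 15, 15)
    d <- to_deciles(freq, mask)
    pos <- mask & freq$values > 0
    cnt <- freq$values[pos]; dec <- d$values[pos]
    expect_identical(dec, oracle_deciles(cnt))
    # order isomorphism: equal counts share a decile, order preserved
    expect_true(all(tapply(dec, cnt, function(x) length(unique(x))) == 1))
    o <- order(cnt)
    expect_true(all(diff(dec[o]) >= 0))
    # balance bound holds when counts are distinct
    ucnt <- unique(cnt)
    if (length(ucnt) == length(cnt) && length(ucnt) >= 10) {
      tab <- table(factor(dec, levels = 1:10))
      n <- length(cnt)
      expect_true(all(tab >= floor(n / 10) - 1 & tab <= ceiling(n / 10) + 1))
    }
  }
})

test_that("decile weights are H = decile/10 exactly", {
  spec <- grid_spec(1, 11, 1, 0, 10)
  d <- hx_raster(matrix(0:10, 1, 11), spec)
  w <- decile_weights(d)
  expect_identical(as.vector(w$values), (0:10) / 10)
  expect_error(decile_weights(hx_raster(matrix(11, 1, 1),
                                        grid_spec(1, 1, 1, 0, 10))),
               "0..10")
})
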