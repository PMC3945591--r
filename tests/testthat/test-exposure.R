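test_that("cell exposure is the population x weight product", {
  spec <- grid_spec(2, 2, 1, 0, 10)
  pop <- hx_raster(matrix(c(200, 100, 0, NA), 2, 2, byrow = TRUE), spec)
  H <- hx_raster(matrix(c(1, 0.3, 0.8, 0.5), 2, 2, byrow = TRUE), spec)
  e <- cell_exposure(pop, H)
  expect_equal(as.vector(t(e$values)), c(200, 30, 0, 0))
  expect_error(cell_exposure(pop, hx_raster(1, grid_spec(1, 1, 1, 0, 10))),
               "specs")
})

test_that("multi-hazard exposure is the equally-weighted sum", {
  spec <- grid_spec(1, 1, 1, 0, 10)
  mk <- function(x) hx_raster(matrix(x, 1, 1), spec)
  expect_equal(multi_hazard(mk(10), mk(20), mk(30))$values[1, 1], 60)
  expect_equal(multi_hazard(mk(0), mk(0), mk(7))$values[1, 1], 7)
  # all three hazards at maximum: 3 x population
  P <- 1234
  expect_equal(multi_hazard(mk(P), mk(P), mk(P))$values[1, 1], 3 * P)
})

test_that("country exposure follows sum(exposure)/sum(population)", {
  spec <- grid_spec(1, 2, 1, 0, 10)
  pop <- hx_raster(matrix(c(100, 300), 1, 2), spec)
  H <- hx_raster(matrix(c(0.2, 0.6), 1, 2), spec)
  zones <- hx_raster(matrix(1, 1, 2), spec)
  tab <- country_exposure(cell_exposure(pop, H), pop, zones)
  expect_equal(tab$score, 0.5)           # (20 + 180) / 400
  expect_equal(tab$population, 400)

  # top decile everywhere -> exactly 1.0; hazard absent -> 0
  tab <- country_exposure(cell_exposure(pop, hx_raster(matrix(1, 1, 2), spec)),
                          pop, zones)
  expect_identical(tab$score, 1)
  tab <- country_exposure(cell_exposure(pop, hx_raster(matrix(0, 1, 2), spec)),
                          pop, zones)
  expect_identical(tab$score, 0)

  # zero-population stratum reports missing, with a warning
  stratum <- matrix(c(FALSE, FALSE), 1, 2)
  expect_warning(
    tab <- country_exposure(cell_exposure(pop, H), pop, zones, stratum),
    "missing")
  expect_true(is.na(tab$score))
})

test_that("aggregation identities hold on random synthetic worlds", {
  set.seed(91)
  for (i in 1:100) {
    cfg <- world_config(seed = i, n_rows = 10, n_cols = 10, n_countries = 4,
                        n_cyclones = 0L, n_floods = 0L, n_months = 36L,
                        precip_coarse_factor = 2L)
    w <- generate_world(cfg)
    spec <- w$population$spec
    # random decile weights stand in for the hazard stack
    H <- lapply(1:3, function(j)
      decile_weights(hx_raster(matrix(sample(0:10, 100, TRUE), 10, 10), spec)))
    names(H) <- c("cyclone", "drought", "flood")
    ex <- lapply(H, function(h) cell_exposure(w$population, h))
    ur <- classify_urban_rural(w$population, w$zones, w$urban_fractions)
    tab <- exposure_table(ex, w$population, w$zones, ur)

    # bounds
    single <- tab$score[tab$hazard != "multi" & !is.na(tab$score)]
    expect_true(all(single >= 0 & single <= 1))
    multi <- tab$score[tab$hazard == "multi" & !is.na(tab$score)]
    expect_true(all(multi >= 0 & multi <= 3))

    # decomposition: total score x total pop = urban part + rural part
    for (hz in unique(tab$hazard)) {
      sub <- tab[tab$hazard == hz, ]
      piv <- function(st, col) sub[[col]][sub$stratum == st]
      num <- function(st) {
        s <- piv(st, "score"); p <- piv(st, "population")
        ifelse(is.na(s), 0, s * p)
      }
      expect_equal(num("total"), num("urban") + num("rural"),
                   tolerance = 1e-12)
    }
  }
})

test_that("vectorized scores equal the per-cell loop oracle on 20x20 worlds", {
  set.seed(101)
  spec <- grid_spec(20, 20, 1, 0, 10)
  for (i in 1:5) {
    pop <- random_raster(spec, function(n) round(rlnorm(n, 5, 1)))
    zones <- random_raster(spec, function(n) sample(1:5, n, TRUE))
    H <- decile_weights(random_raster(spec,
                                      function(n) sample(0:10, n, TRUE)))
    e <- cell_exposure(pop, H)
    stratum <- matrix(runif(400) < 0.5, 20, 20)
    tab_all <- country_exposure(e, pop, zones)
    tab_str <- suppressWarnings(country_exposure(e, pop, zones, stratum))
    for (id in 1:5) {
      expect_equal(tab_all$score[tab_all$country_id == id],
                   oracle_country_score(e, pop, zones, id),
                   tolerance = 1e-12)
      expect_equal(tab_str$score[tab_str$country_id == id],
                   oracle_country_score(e, pop, zones, id, stratum),
                   tolerance = 1e-12)
    }
  }
})

test_that("raising a cell's decile never lowers an aggregate score", {
  set.seed(111)
  spec <- grid_spec(8, 8, 1, 0, 4)
  pop <- random_raster(spec, function(n) round(rlnorm(n, 5, 1)))
  zones <- random_raster(spec, function(n) sample(1:2, n, TRUE))
  d <- matrix(sample(0:9, 64, TRUE), 8, 8)
  base <- country_exposure(
    cell_exposure(pop, decile_weights(hx_raster(d, spec))), pop, zones)
  for (i in 1:20) {
    d2 <- d
    cell <- sample(64, 1)
    d2[cell] <- d2[cell] + 1
    bumped <- country_exposure(
      cell_exposure(pop, decile_weights(hx_raster(d2, spec))), pop, zones)
    expect_true(all(bumped$score >= base$score - 1e-12))
  }
})

test_that("scores are invariant to scaling a country's population", {
  spec <- grid_spec(4, 4, 1, 0, 2)
  set.seed(121)
  pop <- random_raster(spec, function(n) round(rlnorm(n, 5, 1)))
  zones <- hx_raster(matrix(rep(1:2, each = 8), 4, 4), spec)
  H <- decile_weights(random_raster(spec, function(n) sample(0:10, n, TRUE)))
  base <- country_exposure(cell_exposure(pop, H), pop, zones)
  pop2 <- pop
  pop2$values[zones$values == 1] <- pop2$values[zones$values == 1] * 17
  scaled <- country_exposure(cell_exposure(pop2, H), pop2, zones)
  expect_equal(scaled$score, base$score, tolerance = 1e-12)
})

test_that("development-class averages are person-weighted", {
  tab <- data.frame(country_id = 1:2, hazard = "flood", stratum = "total",
                    score = c(0.2, 0.4), population = c(1000, 1000))
  hdi <- data.frame(country_id = 1:2, hdi_class = c("Low", "Low"))
  avg <- hdi_class_average(tab, hdi)
  expect_equal(avg$score[avg$hdi_class == "Low"], 0.3)
  expect_equal(avg$score[avg$hdi_class == "Global"], 0.3)
  expect_true(is.na(avg$score[avg$hdi_class == "High"]))  # empty class

  # single-country class reports that country's score; unequal weights pull
  tab$population <- c(3000, 1000)
  hdi$hdi_class <- c("Low", "Medium")
  avg <- hdi_class_average(tab, hdi)
  expect_equal(avg$score[avg$hdi_class == "Low"], 0.2)
  expect_equal(avg$score[avg$hdi_class == "Medium"], 0.4)
  expect_equal(avg$score[avg$hdi_class == "Global"],
               (0.2 * 3000 + 0.4 * 1000) / 4000)
  expect_error(hdi_class_average(tab, data.frame(country_id = 1:2,
                                                 hdi_class = c("Lo", "Hi"))),
               "unknown HDI class")
})

test_that("relative difference is reported in percent of the reference", {
  expect_equal(relative_difference(0.24, 0.12), 100)
  expect_equal(relative_difference(0.12, 0.12), 0)
  expect_equal(relative_difference(0.06, 0.12), -50)
  expect_true(is.na(relative_difference(0.5, 0)))
})
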