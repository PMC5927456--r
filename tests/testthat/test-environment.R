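test_that("anoxic top is the shallowest depth of a sustained oxygen deficit", {
  # fully oxygenated column
  oxic <- make_profile(0:40, rep(15, 41), rep(6, 41))
  expect_true(is.na(detect_anoxic_top(oxic)))

  # anoxia from 27 m to the bottom
  deep <- make_profile(0:60, rep(15, 61), ifelse(0:60 >= 27, 0.2, 6))
  expect_equal(detect_anoxic_top(deep), 27)

  # a transient dip that recovers below is not an anoxic top
  dip <- make_profile(0:40, rep(15, 41),
                      ifelse(0:40 == 20, 0.5, 6))
  expect_true(is.na(detect_anoxic_top(dip)))

  expect_error(detect_anoxic_top(make_profile(numeric(), numeric(),
                                              numeric())),
               class = "plastinorm_input_error")
})

test_that("anoxic top is invariant to row order and monotone in threshold", {
  set.seed(11)
  oxy <- c(rep(6, 30), rep(0.4, 10), rep(0.05, 21))
  prof <- make_profile(0:60, rep(15, 61), oxy)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(detect_anoxic_top(prof), detect_anoxic_top(shuffled))
  # raising the threshold can only move the top up (never deepen it)
  tops <- vapply(c(0.1, 0.5, 1, 5),
                 function(th) detect_anoxic_top(prof, th), numeric(1))
  expect_true(all(diff(tops) <= 0))
})

test_that("oxygenated-layer temperature excludes the surface and the anoxic layer", {
  iso <- make_profile(0:40, rep(15, 41), rep(6, 41))
  res <- oxygenated_layer_temperature(iso)
  expect_equal(res$mean_temperature, 15)
  expect_equal(res$sd_temperature, 0)
  expect_equal(res$n_depths, 39)  # depths 2..40 (surface metre excluded)

  # two-layer column with anoxia below 26 m: hand summation over 2..25 m
  temps <- ifelse(1:30 <= 20, 17, 15)
  prof <- make_profile(1:30, temps, rep(6, 30))
  included <- temps[1:30 > 1 & 1:30 < 26]
  res2 <- oxygenated_layer_temperature(prof, anoxic_top = 26)
  expect_equal(res2$mean_temperature, sum(included) / length(included))
  expect_equal(res2$n_depths, 24)
  expect_equal(res2$sd_temperature, sd(included))

  # order invariance of the mean
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(oxygenated_layer_temperature(shuffled, 26)$mean_temperature,
               res2$mean_temperature)

  expect_error(oxygenated_layer_temperature(prof, anoxic_top = 1.5),
               class = "plastinorm_degenerate_error")
})

test_that("phytoplankton biomass follows the geometric volume conversion", {
  empty <- tibble::tibble(taxon = character(), shape = character(),
                          dim1_um = numeric(), dim2_um = numeric(),
                          cells_per_ml = numeric())
  expect_equal(phyto_biomass(empty), 0)

  sphere <- tibble::tibble(taxon = "diatom", shape = "sphere",
                           dim1_um = 50, dim2_um = NA,
                           cells_per_ml = 20000)
  expect_equal(phyto_biomass(sphere), pi / 6 * 50^3 * 20000 * 1e-9)

  cyl <- tibble::tibble(taxon = "c", shape = "cylinder", dim1_um = 10,
                        dim2_um = 20, cells_per_ml = 1000)
  expect_equal(phyto_biomass(cyl), pi / 4 * 10^2 * 20 * 1000 * 1e-9)

  spheroid <- tibble::tibble(taxon = "s", shape = "prolate_spheroid",
                             dim1_um = 20, dim2_um = 10,
                             cells_per_ml = 100)
  expect_equal(phyto_biomass(spheroid), pi / 6 * 20 * 10^2 * 100 * 1e-9)

  expect_error(phyto_biomass(tibble::tibble(
    taxon = "x", shape = "cube", dim1_um = 5, dim2_um = NA,
    cells_per_ml = 1)), class = "plastinorm_input_error")
})

test_that("phyto_biomass is additive over taxa and linear in density", {
  set.seed(21)
  shapes <- sample(c("sphere", "cylinder", "prolate_spheroid"), 6,
                   replace = TRUE)
  tab <- tibble::tibble(taxon = letters[1:6], shape = shapes,
                        dim1_um = runif(6, 5, 60),
                        dim2_um = runif(6, 1, 5),
                        cells_per_ml = runif(6, 10, 1e4))
  tab$dim2_um <- pmin(tab$dim2_um, tab$dim1_um)
  total <- phyto_biomass(tab)
  by_taxon <- vapply(seq_len(6), function(i) phyto_biomass(tab[i, ]),
                     numeric(1))
  expect_equal(total, sum(by_taxon))
  tab2 <- dplyr::mutate(tab, cells_per_ml = cells_per_ml * 3)
  expect_equal(phyto_biomass(tab2), 3 * total)
})

test_that("thermal covariates summarise a monthly series", {
  tc <- thermal_covariates(c(14.9, 18.1))
  expect_equal(tc$tar, 3.2)
  expect_equal(tc$t_min, 14.9)
  expect_equal(tc$t_max, 18.1)

  const <- thermal_covariates(c(20, 20, 20))
  expect_equal(const$tar, 0)
  expect_equal(const$ts, 0)

  s <- thermal_covariates(c(10, 12, 20))
  expect_equal(s$t_min, 10)
  expect_equal(s$t_max, 20)
  expect_equal(s$tar, 10)
  expect_equal(s$ts, sd(c(10, 12, 20)))
  expect_true(s$tar >= 0)

  expect_error(thermal_covariates(15), class = "plastinorm_input_error")
})

test_that("summarise_environment builds one row per month with biomass attached", {
  profiles <- dplyr::bind_rows(
    make_profile(0:30, rep(15, 31), rep(6, 31), as.Date("2008-01-15")),
    make_profile(0:30, rep(17, 31), ifelse(0:30 >= 25, 0.3, 6),
                 as.Date("2008-06-15")))
  phyto <- tibble::tibble(
    date = as.Date(c("2008-01-15", "2008-01-15")),
    depth_m = c(10, 25), taxon = "d", shape = "sphere",
    dim1_um = 50, dim2_um = NA, cells_per_ml = c(1000, 3000))
  env <- summarise_environment(profiles, phyto)
  expect_equal(env$month, c("2008-01", "2008-06"))
  expect_equal(env$anoxic_top_m, c(NA, 25))
  expect_equal(env$mean_temperature, c(15, 17))
  vol <- pi / 6 * 50^3 * 1e-9
  expect_equal(env$phyto_biomass_mgl, c(mean(c(1000, 3000)) * vol, NA))
})
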