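make_series <- function(id, species, lat, sizes, temps,
                        unit = "dry-ug") {
  tibble::tibble(population_id = id, species = species,
                 latitude_deg = lat, habitat = "lacustrine",
                 month = seq_along(sizes), size_value = sizes,
                 size_unit = unit, temperature_c = temps)
}

test_that("short series are excluded with a reason and nothing is lost", {
  pops <- dplyr::bind_rows(
    make_series("p1", "A a", 40, runif(12, 5, 10), runif(12, 5, 15)),
    make_series("p2", "B b", 30, runif(4, 5, 10), runif(4, 5, 15)),
    make_series("p3", "C c", 20, runif(5, 5, 10), runif(5, 5, 15)))
  flt <- filter_short_series(pops, min_months = 5)
  expect_equal(sort(unique(flt$kept$population_id)), c("p1", "p3"))
  expect_equal(flt$excluded$population_id, "p2")
  expect_match(flt$excluded$reason, "4 monthly records")
  # conservation: kept + excluded = input populations
  expect_equal(length(unique(flt$kept$population_id)) +
                 nrow(flt$excluded),
               length(unique(pops$population_id)))
  expect_error(filter_short_series(pops, 1),
               class = "plastinorm_input_error")
})

test_that("length series are bridged with rank-fallback models", {
  registry <- tibble::tibble(
    taxon = c("Leptodiaptomus garciai", "Acartia", "any"),
    rank = c("species", "genus", "default"),
    a = c(7.9e-7, 1e-6, 5e-7), b = c(2.33, 2.2, 2.4),
    length_unit = "um")
  pops <- dplyr::bind_rows(
    make_series("native", "X x", 40, c(10, 5), c(5, 15)),
    make_series("sp", "Leptodiaptomus garciai", 19.4, c(821, 1025),
                c(18.1, 14.9), unit = "length-um"),
    make_series("gen", "Acartia tonsa", 35, c(900, 1000), c(10, 20),
                unit = "length-um"),
    make_series("def", "Unknown sp", 50, c(800, 900), c(8, 18),
                unit = "length-um"))
  out <- bridge_length_to_biomass(pops, registry)
  expect_true(all(out$size_unit == "dry-ug"))
  sp <- dplyr::filter(out, population_id == "sp")
  expect_equal(sp$size_value, 7.9e-7 * c(821, 1025)^2.33)
  # the study species' August length maps onto the printed dry mass
  expect_equal(round(sp$size_value[1], 2), 4.88)
  expect_match(dplyr::filter(out, population_id == "gen")$lw_model[1],
               "genus")
  expect_match(dplyr::filter(out, population_id == "def")$lw_model[1],
               "default")
  expect_equal(dplyr::filter(out, population_id == "native")$size_value,
               c(10, 5))
  expect_error(bridge_length_to_biomass(
    dplyr::filter(pops, population_id == "def"), registry[1:2, ]),
    "Unknown sp")
})

test_that("population rows combine PPI, thermal covariates and intensity", {
  pops <- make_series("p1", "A a", -19.4, c(10, 5), c(14.9, 18.1))
  row <- population_ppi(pops)
  expect_equal(row$ppi_pct, 50)
  expect_equal(row$tar, 3.2)
  expect_equal(row$abs_latitude, 19.4)
  expect_equal(row$zone, "tropical")
  expect_equal(row$intensity_pct_per_c, 50 / 3.2)
  # constant sizes: PPI 0, intensity 0 when TAR > 0
  const <- population_ppi(make_series("p2", "B b", 45, c(7, 7, 7),
                                      c(5, 10, 15)))
  expect_equal(const$ppi_pct, 0)
  expect_equal(const$intensity_pct_per_c, 0)
  expect_equal(const$zone, "extratropical")
})

test_that("zone classification uses a strict tropical cutoff", {
  expect_equal(zone_classify(19.4), "tropical")
  expect_equal(zone_classify(45), "extratropical")
  expect_equal(zone_classify(23.5), "extratropical")
  expect_error(zone_classify(95), class = "plastinorm_input_error")
})

test_that("species maxima dominate their populations and break ties deterministically", {
  rows <- population_ppi(dplyr::bind_rows(
    make_series("a1", "A a", 40, c(10, 7), c(5, 15)),      # PPI 30
    make_series("a2", "A a", 42, c(10, 5), c(5, 15)),      # PPI 50
    make_series("b1", "B b", 30, c(8, 6), c(6, 12)),       # PPI 25
    make_series("c1", "C c", 20, c(9, 6.3), c(20, 24)),    # PPI 30
    make_series("c2", "C c", 10, c(90, 63), c(21, 25))))   # PPI 30 (tie)
  sp <- species_maximum(rows)
  expect_equal(nrow(sp), 3)
  expect_equal(dplyr::filter(sp, species == "A a")$population_id, "a2")
  expect_equal(dplyr::filter(sp, species == "B b")$population_id, "b1")
  # tie broken by lexicographic id, flagged
  c_row <- dplyr::filter(sp, species == "C c")
  expect_equal(c_row$population_id, "c1")
  expect_true(c_row$ppi_tie)
  # species-maximum PPI >= every population PPI of that species
  for (s in sp$species) {
    expect_gte(dplyr::filter(sp, species == s)$ppi_pct,
               max(dplyr::filter(rows, species == s)$ppi_pct))
  }
})

test_that("the latitudinal report is order-invariant and exact on monotone data", {
  db <- simulate_population_database(seed = 44)
  rows <- population_ppi(db$populations)
  rep1 <- latitudinal_report(rows)
  shuffled <- rows[sample(nrow(rows)), ]
  rep2 <- latitudinal_report(shuffled)
  expect_equal(rep1$correlations, rep2$correlations)
  expect_equal(dplyr::arrange(rep1$zone_means, zone, variable),
               dplyr::arrange(rep2$zone_means, zone, variable))

  # PPI an exact decreasing function of t_max -> Spearman -1 in that cell
  mono <- dplyr::mutate(rows, ppi_pct = 100 - t_max,
                        intensity_pct_per_c = ppi_pct / tar)
  cell <- dplyr::filter(latitudinal_report(mono)$correlations,
                        response == "ppi_pct", predictor == "t_max")
  expect_equal(cell$rho, -1)

  # one zone empty -> group tests skipped with a warning
  expect_warning(
    rep3 <- latitudinal_report(dplyr::filter(rows,
                                             zone == "extratropical")),
    "zone")
  expect_equal(nrow(rep3$zone_tests), 0)
})
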