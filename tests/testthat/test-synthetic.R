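test_that("attribute tables hit the specified population moments", {
  # population quoted for nitrogen on the full calibration summary scale
  sp <- list(attribute_spec("nitrogen", "%", mean = 3.2, sd = 0.7,
                            min = 0.4, max = 4.65))
  names(sp) <- "nitrogen"
  tab <- generate_attribute_table(sp, n_plants = 10000, seed = 101)
  whole <- tab$nitrogen[tab$tissue == "whole"]
  se <- 0.7 / sqrt(10000)
  expect_lt(abs(mean(whole) - 3.2), 3 * se + 0.01)   # +0.01 clipping allowance
  expect_lt(abs(sd(whole) - 0.7), 3 * 0.7 / sqrt(2 * 10000) + 0.01)
  expect_true(all(whole >= 0.4 & whole <= 4.65))
})

test_that("statistical fidelity holds for every default attribute at n = 1000", {
  tab <- generate_attribute_table(n_plants = 1000, seed = 102)
  for (sp in default_attribute_specs()) {
    whole <- tab[[sp$name]][tab$tissue == "whole"]
    se_mean <- sp$sd / sqrt(1000)
    se_sd <- sp$sd / sqrt(2 * 1000)
    # 3-SE bands plus a small clipping allowance for wide distributions
    expect_lt(abs(mean(whole) - sp$mean), 3 * se_mean + 0.03 * sp$sd)
    expect_lt(abs(sd(whole) - sp$sd), 3 * se_sd + 0.05 * sp$sd)
  }
})

test_that("degenerate spread collapses all values to the mean", {
  sp <- list(attribute_spec("flat", "u", mean = 7, sd = 1e-9, min = 0, max = 10))
  names(sp) <- "flat"
  tab <- generate_attribute_table(sp, n_plants = 50, seed = 103)
  expect_lt(max(abs(tab$flat[tab$tissue == "whole"] - 7)), 1e-6)
})

test_that("PS/BL offset and coupling are realized", {
  sp <- list(attribute_spec("nitrogen", "%", mean = 3.2, sd = 0.5,
                            min = 0.4, max = 6,
                            ps_bl_shift = -1.1, ps_bl_r2 = 0.83))
  names(sp) <- "nitrogen"
  tab <- generate_attribute_table(sp, n_plants = 1000, seed = 104)
  ps <- tab$nitrogen[tab$tissue == "PS"]
  bl <- tab$nitrogen[tab$tissue == "BL"]
  se <- sd(bl - ps) / sqrt(1000)
  expect_lt(abs((mean(bl) - mean(ps)) - 1.1), 3 * se)
  expect_gt(cor(ps, bl)^2, 0.75)
  expect_lt(cor(ps, bl)^2, 0.90)
})

test_that("generation is deterministic and input validation bites", {
  t1 <- generate_attribute_table(n_plants = 20, seed = 7)
  t2 <- generate_attribute_table(n_plants = 20, seed = 7)
  expect_identical(t1, t2)
  expect_error(generate_attribute_table(n_plants = 1, seed = 1), "n_plants")
  expect_error(attribute_spec("x", "u", 1, sd = 0, min = 0, max = 2), "sd")
  expect_error(attribute_spec("x", "u", 1, sd = 1, min = 2, max = 1), "min < max")
})

test_that("cubes are deterministic and carry the documented geometry", {
  row <- as.list(fixture_table[fixture_table$plant_id == "plant_004" &
                                 fixture_table$tissue == "BL", ])
  s1 <- generate_cube(row, the_library, tiny_scene(seed = 5))
  s2 <- generate_cube(row, the_library, tiny_scene(seed = 5))
  expect_identical(s1$raw$irradiance, s2$raw$irradiance)
  expect_identical(s1$refs$dark, s2$refs$dark)
  expect_identical(dim(s1$raw$irradiance), c(40L, 32L, 235L))
  expect_identical(sum(s1$truth_mask), as.integer(round(0.35 * 40 * 32)))
  expect_error(scene_config(plant_fraction = 0), "plant_fraction")
  expect_error(scene_config(plant_fraction = 1), "plant_fraction")
})

test_that("background stays below the segmentation threshold at 1080 nm", {
  row <- as.list(fixture_table[fixture_table$plant_id == "plant_005" &
                                 fixture_table$tissue == "BL", ])
  sim <- generate_cube(row, the_library, tiny_scene(noise_sd = 0))
  b <- band_index(sim$wavelengths, 1080)
  plane <- sim$reflectance$reflectance[, , b]
  expect_lt(max(plane[!sim$truth_mask]), 0.3)
  expect_gte(min(plane[sim$truth_mask]), 0.3)
})

test_that("raising a concentration monotonically deepens its features", {
  lib <- the_library
  row <- as.list(fixture_table[fixture_table$plant_id == "plant_001" &
                                 fixture_table$tissue == "BL", ])
  centers <- lib$features$center_nm[lib$features$attribute == "nitrogen"]
  idx <- vapply(centers, function(nm) band_index(lib$wavelengths, nm), 1L)
  concs <- seq(1, 5, by = 0.5)
  refl <- sapply(concs, function(cc) {
    r <- row; r$nitrogen <- cc
    grasshsi:::tissue_reflectance(lib, r, "BL")[idx]
  })
  # each feature-center row of the concentration sweep is non-increasing
  expect_true(all(apply(refl, 1, function(v) all(diff(v) <= 0))))
})

test_that("changing nitrogen moves the spectrum most inside its feature bands", {
  lib <- the_library
  row <- as.list(fixture_table[fixture_table$plant_id == "plant_002" &
                                 fixture_table$tissue == "BL", ])
  hi <- row; hi$nitrogen <- 4.0
  lo <- row; lo$nitrogen <- 2.0
  sc <- tiny_scene(noise_sd = 0, lighting_gradient = 0)
  cube_hi <- generate_cube(hi, lib, sc)
  cube_lo <- generate_cube(lo, lib, sc)
  ms <- function(sim) {
    refl <- calibrate(sim$raw, sim$refs)
    mean_spectrum(refl, segment(refl))$spectrum
  }
  delta <- abs(snv(ms(cube_hi)) - snv(ms(cube_lo)))
  # brute force over all 235 bands: the biggest movement sits within 2
  # bands of a configured nitrogen feature center
  centers <- lib$features$center_nm[lib$features$attribute == "nitrogen"]
  nearest <- vapply(centers, function(nm) band_index(lib$wavelengths, nm), 1L)
  top <- order(delta, decreasing = TRUE)[1:3]
  expect_true(all(vapply(top, function(b) min(abs(b - nearest)) <= 2, TRUE)))
})

test_that("a simulated scene round-trips through its ENVI export", {
  row <- as.list(fixture_table[fixture_table$plant_id == "plant_006" &
                                 fixture_table$tissue == "PS", ])
  sim <- generate_cube(row, the_library,
                       tiny_scene(lines = 12L, samples = 10L), tissue = "PS")
  d <- withr::local_tempdir()
  write_simulated_scene(sim, d, "sc")
  back <- read_envi(file.path(d, "sc.hdr"))
  expect_equal(back$irradiance, sim$raw$irradiance)
  expect_equal(back$wavelengths, sim$wavelengths)
  mask <- utils::read.csv(file.path(d, "sc_mask.csv"))
  expect_identical(nrow(mask), sum(sim$truth_mask))
})
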