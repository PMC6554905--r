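# Shared fixtures, built in code. The moderate study is simulated once per
# test run and reused by the roi / pipeline / mapping tests.

tiny_scene <- function(...) {
  args <- list(lines = 40L, samples = 32L, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

# small uniform reflectance cube: every pixel carries `spectrum`
uniform_cube <- function(spectrum, lines = 5L, samples = 4L,
                         wavelengths = seq_along(spectrum) * 10 + 500) {
  nb <- length(spectrum)
  arr <- aperm(array(rep(spectrum, each = lines * samples),
                     dim = c(lines, samples, nb)), c(1, 2, 3))
  reflectance_cube(arr, wavelengths)
}

# cube with explicitly given pixel spectra: `spectra` is a list indexed by
# [line, sample] position pairs; everything else is `fill`
cube_from_pixels <- function(lines, samples, wavelengths, fill = 0,
                             pixels = list()) {
  nb <- length(wavelengths)
  arr <- array(fill, dim = c(lines, samples, nb))
  for (px in pixels) {
    arr[px$line, px$sample, ] <- px$spectrum
  }
  reflectance_cube(arr, wavelengths)
}

the_library <- endmember_library()
the_specs <- default_attribute_specs()

calibrate_sim <- function(sim) calibrate(sim$raw, sim$refs)

# one small attribute table, drawn once
fixture_table <- generate_attribute_table(the_specs, n_plants = 6, seed = 42)

# moderate shared study: simulated lazily, cached for the whole run
shared_study_env <- new.env()
shared_study <- function() {
  if (is.null(shared_study_env$study)) {
    cfg <- study_config(n_plants = 60L, n_tissue_plants = 10L,
                        attributes = c("nitrogen", "sugars"),
                        scene = scene_config(lines = 60L, samples = 48L),
                        reps = 5L)
    shared_study_env$cfg <- cfg
    shared_study_env$study <- simulate_study(cfg)
  }
  list(cfg = shared_study_env$cfg, study = shared_study_env$study)
}
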