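# Shared configuration for the analysis scripts. Each script can be run on
# its own; the simulated study is cached under results/ so later stages
# reuse the same deterministic dataset.

library(grasshsi)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

ALL_ATTRIBUTES <- names(default_attribute_specs())

base_config <- function(...) {
  args <- utils::modifyList(
    list(n_plants = 185L, n_tissue_plants = 15L,
         attributes = c("nitrogen", "sugars"),
         seeds = list(sim = 11L, split = 12L, cv = 13L)),
    list(...))
  do.call(study_config, args)
}

# simulate once, reuse across scripts (runtime cache, not a repo artifact)
load_study <- function(cfg = base_config()) {
  cache <- file.path(RESULTS_DIR, "study_cache.rds")
  if (file.exists(cache)) {
    study <- readRDS(cache)
    if (identical(study$config$seeds, cfg$seeds) &&
        study$config$n_plants == cfg$n_plants) {
      return(study)
    }
  }
  message("simulating ", cfg$n_plants, "-plant study (cached afterwards) ...")
  study <- simulate_study(cfg)
  saveRDS(study, cache)
  study
}
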