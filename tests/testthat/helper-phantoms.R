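# Shared phantom fixtures, built once per test run.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, config) {
  if (!exists(key, .phantom_cache)) {
    assign(key, generate_phantom(config), .phantom_cache)
  }
  get(key, .phantom_cache)
}

# default study-condition phantom
std_phantom <- function() {
  cached_phantom("std", phantom_config(seed = 5))
}

# noise-free, identity-misalignment phantom: every downstream quantity
# is exactly computable
clean_phantom <- function() {
  cached_phantom("clean", phantom_config(
    seed = 3,
    misalignment = list(rotation_deg = 0, scale = 1, translation_um = c(0, 0)),
    noise = list(fm_sigma = 0, msi_poisson_scale = 0, mz_jitter_ppm = 0)))
}

phantom_species_table <- function(ph) {
  data.frame(species = ph$truth$species$species, mz = ph$truth$species$mz)
}

# per-type species profile lookup from a config
type_profile <- function(config, type, species) {
  ct <- Filter(function(x) x$name == type, config$cell_types)[[1]]
  as.numeric(ct$species_profile[species])
}
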