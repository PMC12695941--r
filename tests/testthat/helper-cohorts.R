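# Shared desk-scale synthetic cohorts, cached across test files. Durations and
# sampling rates are reduced relative to the generator defaults so the suite
# stays fast; variance scales are the generator's study conditions.

.fixture_cache <- new.env(parent = emptyenv())

desk_meow_spec <- function(n_individuals = 8, calls_per_individual = 15,
                           between = 1, within = 1, seed = 1) {
  cohort_spec(n_individuals, calls_per_individual, "meow",
              between_sd_scale = between, within_sd_scale = within,
              sample_rate = 16000, seed = seed,
              base = list(duration_center = 0.5, duration_between_sd = 0.12,
                          duration_range = c(0.2, 1.0)))
}

desk_purr_spec <- function(n_individuals = 8, calls_per_individual = 15,
                           between = 1, within = 1, seed = 1) {
  cohort_spec(n_individuals, calls_per_individual, "purr",
              between_sd_scale = between, within_sd_scale = within,
              sample_rate = 8000, seed = seed,
              base = list(duration_center = 2, duration_between_sd = 0.6,
                          duration_range = c(1, 4), duration_sd_unit = 0.3))
}

desk_features <- function(spec, key = NULL) {
  if (is.null(key)) return(extract_features(generate_cohort(spec)))
  if (!exists(key, envir = .fixture_cache))
    assign(key, extract_features(generate_cohort(spec)), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard balanced desk cohorts (meow between 1, purr between 3)
desk_meow_features <- function() desk_features(desk_meow_spec(), "meow8x15")
desk_purr_features <- function() desk_features(desk_purr_spec(between = 3), "purr8x15")

ind_formula <- function(features) {
  stats::reformulate(mfcc_columns(features), response = "individual_id")
}

default_meow_profile <- function(...) {
  args <- utils::modifyList(
    list(individual_id = "m1", call_type = "meow", f0_mean = 400,
         duration_mean = 0.5, formant_centers = c(1100, 2600),
         formant_bandwidths = c(220, 350)),
    list(...))
  do.call(individual_profile, args)
}

default_purr_profile <- function(...) {
  args <- utils::modifyList(
    list(individual_id = "p1", call_type = "purr", f0_mean = 25,
         duration_mean = 1.5, burst_center = 300, burst_bandwidth = 180,
         pulse_duty_cycle = 0.35, envelope_asymmetry = 0.8, resp_rate = 1),
    list(...))
  do.call(individual_profile, args)
}
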