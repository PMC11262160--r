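# Shared fixtures, built in code at test time.

# Down-scaled survey configuration: same structure and intake parameters as
# the default, smaller strata so tests stay fast.
small_config <- function(seed = 42L, n = c(80L, 120L, 40L, 15L, 20L, 2L, 60L, 90L, 8L)) {
  cfg <- default_population_config(seed = seed)
  cfg$strata$n <- as.integer(n)
  cfg
}

# Three-food toy composition table (per 100 g).
toy_fct <- function() {
  data.frame(
    food_code = c("teff", "lentil", "kale"),
    energy_kcal_100g = c(101, 116, 35),
    zinc_mg_100g = c(1.2, 1.9, 0.3),
    folate_ug_dfe_100g = c(18, 45, 120),
    stringsAsFactors = FALSE
  )
}

# A single-stratum config for distributional checks.
one_stratum_config <- function(n, median_zinc = 6.9, log_sd = 0.5,
                               seed = 7L, ratios = NULL) {
  cfg <- default_population_config(seed = seed)
  cfg$strata <- data.frame(region = "AddisAbaba", residence = "urban",
                           life_stage = "woman_15_49y", n = as.integer(n),
                           stringsAsFactors = FALSE)
  cfg$intake_params$median[cfg$intake_params$nutrient == "zinc"] <- median_zinc
  cfg$intake_params$log_sd <- log_sd
  if (!is.null(ratios)) cfg$variance_ratios <- ratios
  cfg
}

# Variance-ratio table with arbitrary entries (bypasses the file reader).
ratio_table <- function(zinc_child = 0.47, zinc_adult = 0.61,
                        folate_child = 0.72, folate_adult = 0.89) {
  structure(data.frame(
    nutrient = c("zinc", "zinc", "folate", "folate"),
    age_class = c("child", "adult", "child", "adult"),
    ratio = c(zinc_child, zinc_adult, folate_child, folate_adult),
    stringsAsFactors = FALSE
  ), class = c("variance_ratio_table", "data.frame"))
}

# Reference table with effectively unbinding ULs (constraint never active).
unbounded_refs <- function() {
  refs <- nutrient_references()
  refs$ul <- 1e9
  refs
}
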