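#' Default synthetic-survey configuration
#'
#' Builds the configuration for [generate_population()]. The defaults
#' emulate a two-region (Addis Ababa, Somali) cross-sectional dietary
#' survey: stratum sizes mirror the study's participant table (422 Addis
#' children, 722 Addis women, 86 Addis men; 414/603/24 in Somali with 17%
#' urban), Addis Ababa is urban-only, SES quintiles are heavily skewed
#' upward in Addis, usual-intake medians match the study's baseline median
#' intakes by group and region, between-person variability defaults to a
#' log-SD of 0.5, within-person day-to-day noise follows the imputed
#' variance ratios (zinc 0.47/0.61, folate 0.72/0.89 for children/adults),
#' adult total salt is centred at 8.3 g/d with region-by-sex offsets, and
#' child energy is about 0.45 times adult energy.
#'
#' @param seed Integer root seed. Per-stratum substreams are derived by
#'   hashing stratum labels, so adding a stratum never perturbs the others.
#' @param within_interpretation How to read the variance table:
#'   `"ratio"` (within = ratio x between log-variance, the default) or
#'   `"absolute"` (entries are absolute log-scale within-person variances).
#' @return A list of class `population_config`.
#' @export
default_population_config <- function(seed = 20130601L,
                                      within_interpretation = c("ratio", "absolute")) {
  within_interpretation <- match.arg(within_interpretation)
  strata <- data.frame(
    region = rep(c("AddisAbaba", "Somali", "Somali"), each = 3),
    residence = rep(c("urban", "urban", "rural"), each = 3),
    life_stage = rep(c("child_1_3y", "woman_15_49y", "man_19_45y"), 3),
    n = c(422L, 722L, 86L,    # Addis Ababa, urban only
          70L, 103L, 4L,      # Somali urban (17% of each group)
          344L, 500L, 20L),   # Somali rural
    stringsAsFactors = FALSE
  )
  # quintile probabilities ordered lowest -> highest
  ses_probs <- list(
    AddisAbaba = c(0, 0, 0, 0.10, 0.90),
    Somali     = c(0.22, 0.26, 0.28, 0.15, 0.09)
  )
  intake_params <- data.frame(
    nutrient  = rep(c("zinc", "folate"), each = 6),
    region    = rep(rep(c("AddisAbaba", "Somali"), each = 3), 2),
    life_stage = rep(c("child_1_3y", "woman_15_49y", "man_19_45y"), 4),
    median    = c(2.5, 6.9, 9.2, 1.8, 4.2, 5.4,        # zinc mg/d
                  126, 457, 552, 62, 115, 207),        # folate ug DFE/d
    log_sd    = 0.5,
    stringsAsFactors = FALSE
  )
  # total (not discretionary) salt, g/d; group means chosen so that
  # 0.9 x mean reproduces the reported discretionary intakes by region/sex
  salt_group_means <- data.frame(
    region = c("AddisAbaba", "AddisAbaba", "Somali", "Somali"),
    sex = c("male", "female", "male", "female"),
    mean_g_day = c(8.5, 6.7, 6.8, 5.3) / 0.9,
    stringsAsFactors = FALSE
  )
  phys_probs <- list(  # none, pregnant, lactating among women
    AddisAbaba = c(none = 0.65, pregnant = 0.03, lactating = 0.32),
    Somali     = c(none = 0.37, pregnant = 0.12, lactating = 0.51)
  )
  config <- list(
    strata = strata,
    ses_probs = ses_probs,
    phys_probs = phys_probs,
    intake_params = intake_params,
    variance_ratios = variance_ratio_table(),
    within_interpretation = within_interpretation,
    salt_params = list(mean_g_day = 8.3, sd_g_day = 1.8,
                       group_means = salt_group_means),
    energy_params = list(adult_mean_kcal = 2100, adult_sd_kcal = 350,
                         child_ratio = 0.45, child_sd_kcal = 160),
    covariate_rates = c(weekend = 2 / 7, sick = 0.10, unusual = 0.10),
    seed = as.integer(seed)
  )
  class(config) <- c("population_config", "list")
  config
}

validate_population_config <- function(config) {
  stopifnot(is.list(config))
  s <- config$strata
  if (any(s$n < 0)) stop("stratum sizes must be non-negative")
  if (any(s$region == "AddisAbaba" & s$residence == "rural" & s$n > 0)) {
    stop("Addis Ababa strata are urban-only")
  }
  for (p in config$ses_probs) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("SES probabilities must be non-negative and sum to 1")
    }
  }
  for (p in config$phys_probs) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("physiological-status probabilities must be non-negative and sum to 1")
    }
  }
  if (any(config$intake_params$median <= 0)) stop("intake medians must be positive")
  if (any(config$intake_params$log_sd < 0)) stop("log_sd must be non-negative")
  if (config$salt_params$sd_g_day < 0 || config$salt_params$mean_g_day <= 0) {
    stop("salt parameters must be positive")
  }
  if (config$energy_params$adult_mean_kcal <= 0 ||
      config$energy_params$child_ratio <= 0) {
    stop("energy parameters must be positive")
  }
  rates <- config$covariate_rates
  if (any(rates < 0 | rates > 1)) stop("covariate rates must lie in [0, 1]")
  invisible(config)
}

# deterministic 31-adic hash of a label, folded into [0, 2^31 - 2];
# exact in double arithmetic because intermediates stay below 2^53
stratum_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

sex_of <- function(life_stage) {
  unname(c(child_1_3y = NA_character_, woman_15_49y = "female",
           man_19_45y = "male")[life_stage])
}

#' Generate a synthetic survey population
#'
#' Draws one row per participant with known ground truth. Per stratum
#' (region x residence x life stage): true usual intakes are lognormal with
#' the configured median and between-person log-SD; the observed one-day
#' intake multiplies the true usual intake by lognormal noise whose
#' log-scale variance equals the within-to-between variance ratio times the
#' between-person log variance. Adult total salt is normal truncated at
#' zero; children carry no salt of their own (derived later from energy).
#'
#' @param config A [default_population_config()]-style list.
#' @return A data frame with one row per participant: identifiers,
#'   demographic stratifiers, covariate flags, energy, adult total salt,
#'   and per-nutrient observed one-day and true usual intakes.
#' @export
#' @examples
#' cfg <- default_population_config(seed = 1)
#' cfg$strata$n <- c(30L, 30L, 30L, 10L, 10L, 2L, 20L, 20L, 5L)
#' pop <- generate_population(cfg)
#' nrow(pop)
generate_population <- function(config = default_population_config()) {
  validate_population_config(config)
  nutrients <- unique(config$intake_params$nutrient)
  out <- vector("list", nrow(config$strata))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(nrow(config$strata))) {
    st <- config$strata[i, ]
    if (st$n == 0L) next
    label <- paste(st$region, st$residence, st$life_stage, sep = "|")
    set.seed(stratum_seed(config$seed, label))
    n <- st$n
    is_child <- st$life_stage == "child_1_3y"
    sex <- sex_of(st$life_stage)
    status <- if (st$life_stage == "woman_15_49y") {
      p <- config$phys_probs[[st$region]]
      sample(names(p), n, replace = TRUE, prob = p)
    } else rep("none", n)
    ses <- sample(1:5, n, replace = TRUE, prob = config$ses_probs[[st$region]])
    rates <- config$covariate_rates
    ep <- config$energy_params
    energy <- if (is_child) {
      pmax(stats::rnorm(n, ep$child_ratio * ep$adult_mean_kcal, ep$child_sd_kcal), 100)
    } else {
      pmax(stats::rnorm(n, ep$adult_mean_kcal, ep$adult_sd_kcal), 500)
    }
    salt <- rep(NA_real_, n)
    if (!is_child) {
      sp <- config$salt_params
      gm <- sp$group_means
      hit <- gm$mean_g_day[gm$region == st$region & gm$sex == sex]
      mu <- if (length(hit) == 1) hit else sp$mean_g_day
      salt <- pmax(stats::rnorm(n, mu, sp$sd_g_day), 0)
    }
    row <- data.frame(
      id = paste0(substr(st$region, 1, 2), "_", substr(st$residence, 1, 1), "_",
                  sub("_.*", "", st$life_stage), "_", seq_len(n)),
      region = st$region, residence = st$residence,
      life_stage = st$life_stage, sex = sex, phys_status = status,
      ses_quintile = ses, energy_kcal_day = energy,
      total_salt_g_day = salt,
      weekend = stats::runif(n) < rates["weekend"],
      sick = stats::runif(n) < rates["sick"],
      unusual = stats::runif(n) < rates["unusual"],
      stringsAsFactors = FALSE
    )
    age_class <- age_class_of(st$life_stage)
    for (nut in nutrients) {
      ip <- config$intake_params
      sel <- ip$nutrient == nut & ip$region == st$region &
        ip$life_stage == st$life_stage
      if (!any(sel)) stop("no intake parameters for ", nut, " in ", label)
      med <- ip$median[sel][1]
      sdlog <- ip$log_sd[sel][1]
      ratio <- variance_ratio(config$variance_ratios, nut, age_class)
      sd_within <- if (config$within_interpretation == "ratio") {
        sqrt(ratio) * sdlog
      } else {
        sqrt(ratio)
      }
      true_usual <- stats::rlnorm(n, log(med), sdlog)
      day <- true_usual * exp(stats::rnorm(n, 0, sd_within))
      row[[day_col(nut)]] <- day
      row[[true_col(nut)]] <- true_usual
    }
    out[[i]] <- row
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(generate_empty_population(nutrients))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

generate_empty_population <- function(nutrients) {
  res <- data.frame(
    id = character(), region = character(), residence = character(),
    life_stage = character(), sex = character(), phys_status = character(),
    ses_quintile = integer(), energy_kcal_day = numeric(),
    total_salt_g_day = numeric(), weekend = logical(), sick = logical(),
    unusual = logical(), stringsAsFactors = FALSE
  )
  for (nut in nutrients) {
    res[[day_col(nut)]] <- numeric()
    res[[true_col(nut)]] <- numeric()
  }
  res
}

nutrient_unit <- function(nutrient) {
  switch(nutrient, zinc = "mg_d", folate = "ug_dfe_d",
         stop("unknown nutrient: ", nutrient))
}

day_col <- function(nutrient) paste0(nutrient, "_day_", nutrient_unit(nutrient))
true_col <- function(nutrient) paste0(nutrient, "_usual_true_", nutrient_unit(nutrient))

#' Write a synthetic population as survey + ground-truth CSVs
#'
#' The survey file carries only what a real survey would (observed one-day
#' intakes); true usual intakes go to a separate ground-truth file.
#'
#' @param population Output of [generate_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_cols <- grep("_usual_true_", names(population), value = TRUE)
  survey <- population[, setdiff(names(population), truth_cols)]
  truth <- population[, c("id", truth_cols)]
  sp <- file.path(dir, "survey.csv")
  tp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(survey, sp, row.names = FALSE)
  utils::write.csv(truth, tp, row.names = FALSE)
  invisible(c(survey = sp, ground_truth = tp))
}
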