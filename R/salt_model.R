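#' Convert urinary sodium to salt
#'
#' `salt_g = sodium_mg x factor / 1000`. The default factor 2.5 matches the
#' WHO equivalence of 2000 mg sodium/day with 5 g salt/day (rather than the
#' molar 2.542), reproducing the arithmetic this modelling convention uses.
#'
#' @param sodium_mg_day Urinary sodium excretion, mg/d (vectorized).
#' @param factor Grams of salt per gram of sodium.
#' @return Salt in g/d.
#' @export
#' @examples
#' sodium_to_salt(2000) # 5 g/d
sodium_to_salt <- function(sodium_mg_day, factor = 2.5) {
  if (any(sodium_mg_day < 0)) stop("sodium must be non-negative")
  sodium_mg_day * factor / 1000
}

#' Discretionary salt from total salt
#'
#' Total salt (urinary-sodium derived) times the discretionary fraction;
#' by convention 90% of total salt comes from discretionary salt and
#' manufactured foods. Full precision is kept; rounding happens only in
#' reports.
#'
#' @param total_salt_g_day Total salt, g/d (vectorized).
#' @param fraction Discretionary fraction in `[0, 1]`.
#' @export
#' @examples
#' discretionary_salt_adult(8.3)  # 7.47, reported as 7.5 g/d
discretionary_salt_adult <- function(total_salt_g_day, fraction = 0.9) {
  if (any(total_salt_g_day < 0)) stop("total salt must be non-negative")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  total_salt_g_day * fraction
}

#' Child salt scaled by energy intake
#'
#' Children have no urinary-sodium data, so their salt is taken
#' proportional to energy: `adult_salt x child_energy / adult_energy`.
#'
#' @param adult_salt_g_day Adult (discretionary) salt base, g/d.
#' @param child_energy_kcal Child one-day energy intake, kcal.
#' @param adult_energy_kcal Adult reference energy intake, kcal (> 0).
#' @export
child_salt_from_energy <- function(adult_salt_g_day, child_energy_kcal,
                                   adult_energy_kcal) {
  if (any(adult_energy_kcal <= 0)) stop("adult energy must be positive")
  adult_salt_g_day * (child_energy_kcal / adult_energy_kcal)
}

#' Build a per-person discretionary-salt scenario
#'
#' Two scenarios are supported. `"calculated"`: adults get
#' `total_salt x fraction`; each child gets the mean adult discretionary
#' salt of their scaling stratum (region by default, sex-pooled) scaled by
#' their energy relative to the mean adult energy of that stratum.
#' `"recommended"`: every adult gets exactly `adult_recommended_g_day`
#' (WHO 5 g/d); children get that amount scaled by their energy relative to
#' the overall adult mean energy, irrespective of sex and residence.
#'
#' @param participants Survey data frame (needs `life_stage`, `region`,
#'   `energy_kcal_day`; adults need `total_salt_g_day` for the calculated
#'   scenario).
#' @param name `"calculated"` or `"recommended"`.
#' @param discretionary_fraction Fraction of total salt that is
#'   discretionary (default 0.9).
#' @param adult_recommended_g_day Recommended adult discretionary salt,
#'   g/d (default 5).
#' @param child_base Stratum over which the adult scaling base is averaged
#'   for the calculated scenario: `"region"` (default) or `"overall"`.
#' @return A data frame of class `salt_scenario`: `participant_id`,
#'   `scenario`, `discretionary_salt_g_day`, with the parameters stored as
#'   an attribute. Participant records are not modified.
#' @export
build_salt_scenario <- function(participants,
                                name = c("calculated", "recommended"),
                                discretionary_fraction = 0.9,
                                adult_recommended_g_day = 5,
                                child_base = c("region", "overall")) {
  name <- match.arg(name)
  child_base <- match.arg(child_base)
  is_child <- participants$life_stage == "child_1_3y"
  adults <- participants[!is_child, , drop = FALSE]
  if (anyNA(participants$energy_kcal_day)) {
    stop("missing energy_kcal_day for participant(s): ",
         paste(utils::head(participants$id[is.na(participants$energy_kcal_day)], 5),
               collapse = ", "))
  }
  salt <- numeric(nrow(participants))
  if (name == "calculated") {
    if (anyNA(adults$total_salt_g_day)) {
      stop("missing total_salt_g_day for adult(s): ",
           paste(utils::head(adults$id[is.na(adults$total_salt_g_day)], 5),
                 collapse = ", "))
    }
    salt[!is_child] <- discretionary_salt_adult(adults$total_salt_g_day,
                                                discretionary_fraction)
    if (any(is_child)) {
      if (!nrow(adults)) stop("calculated child salt needs adult records")
      kids <- participants[is_child, , drop = FALSE]
      if (child_base == "region") {
        base_salt <- tapply(salt[!is_child], adults$region, mean)
        base_energy <- tapply(adults$energy_kcal_day, adults$region, mean)
        bs <- base_salt[kids$region]
        be <- base_energy[kids$region]
        miss <- is.na(bs)
        if (any(miss)) {  # region without adults: fall back to overall
          bs[miss] <- mean(salt[!is_child])
          be[miss] <- mean(adults$energy_kcal_day)
        }
      } else {
        bs <- mean(salt[!is_child])
        be <- mean(adults$energy_kcal_day)
      }
      salt[is_child] <- child_salt_from_energy(as.numeric(bs),
                                               kids$energy_kcal_day,
                                               as.numeric(be))
    }
  } else {
    salt[!is_child] <- adult_recommended_g_day
    if (any(is_child)) {
      adult_energy <- if (nrow(adults)) mean(adults$energy_kcal_day) else
        stop("recommended child salt needs adult records for the energy base")
      salt[is_child] <- child_salt_from_energy(
        adult_recommended_g_day,
        participants$energy_kcal_day[is_child], adult_energy)
    }
  }
  out <- data.frame(participant_id = participants$id, scenario = name,
                    discretionary_salt_g_day = salt, stringsAsFactors = FALSE)
  attr(out, "parameters") <- list(
    name = name, discretionary_fraction = discretionary_fraction,
    adult_recommended_g_day = adult_recommended_g_day, child_base = child_base)
  class(out) <- c("salt_scenario", "data.frame")
  out
}
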