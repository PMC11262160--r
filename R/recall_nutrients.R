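#' Per-person one-day intakes from 24-h recall items
#'
#' Converts item-level recall records (grams of each food consumed) to
#' per-person one-day energy, zinc and folate intakes through a food
#' composition table: intake = sum over items of
#' `amount_g x composition_per_100g / 100`.
#'
#' @param items Data frame with `participant_id`, `food_code`, `amount_g`.
#' @param fct Food composition data frame with `food_code` and per-100 g
#'   columns `energy_kcal_100g`, `zinc_mg_100g`, `folate_ug_dfe_100g`.
#' @param mode `"strict"` (default) errors on food codes absent from the
#'   composition table, listing them; `"lenient"` drops such items with a
#'   warning giving the count, which silently undercounts nutrients and is
#'   therefore opt-in.
#' @param participant_ids Optional vector of ids that must appear in the
#'   output; participants with no items get all-zero intakes.
#' @return Data frame: `participant_id`, `energy_kcal_day`, `zinc_day_mg_d`,
#'   `folate_day_ug_dfe_d`.
#' @export
#' @examples
#' fct <- data.frame(food_code = "injera", energy_kcal_100g = 90,
#'                   zinc_mg_100g = 2.5, folate_ug_dfe_100g = 30)
#' items <- data.frame(participant_id = "p1", food_code = "injera",
#'                     amount_g = 200)
#' compute_day_intake(items, fct)  # 5 mg zinc
compute_day_intake <- function(items, fct, mode = c("strict", "lenient"),
                               participant_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("participant_id", "food_code", "amount_g") %in% names(items)))
  if (any(items$amount_g < 0)) stop("amount_g must be non-negative")
  idx <- match(items$food_code, fct$food_code)
  if (anyNA(idx)) {
    missing_codes <- unique(items$food_code[is.na(idx)])
    if (mode == "strict") {
      stop("food codes missing from composition table: ",
           paste(missing_codes, collapse = ", "))
    }
    warning(sum(is.na(idx)), " recall item(s) dropped (",
            length(missing_codes), " unmatched food code(s))")
    items <- items[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  cols <- c(energy_kcal_day = "energy_kcal_100g",
            zinc_day_mg_d = "zinc_mg_100g",
            folate_day_ug_dfe_d = "folate_ug_dfe_100g")
  ids <- unique(c(as.character(items$participant_id),
                  as.character(participant_ids)))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  f <- factor(items$participant_id, levels = ids)
  for (nm in names(cols)) {
    per_item <- items$amount_g * fct[[cols[[nm]]]][idx] / 100
    totals <- tapply(per_item, f, sum, default = 0)
    out[[nm]] <- as.numeric(totals[ids])
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  out
}

#' Merge food composition tables with a fallback order
#'
#' The primary table wins wherever it has a value; otherwise the first
#' fallback with a non-missing value supplies it (mirroring how folate is
#' typically filled from foreign composition tables when the national table
#' lacks it). A `<column>_source` column records the winning source.
#'
#' @param primary Primary FCT (`food_code` plus per-100 g nutrient columns).
#' @param fallbacks Ordered list of fallback FCTs; names are used as source
#'   labels (defaults to `fallback1`, `fallback2`, ...).
#' @param columns Nutrient columns to merge; defaults to every per-100 g
#'   column present in the primary table.
#' @return The merged table with provenance columns.
#' @export
merge_fct_sources <- function(primary, fallbacks = list(), columns = NULL) {
  if (is.null(columns)) {
    columns <- grep("_100g$", names(primary), value = TRUE)
  }
  if (length(fallbacks) && is.null(names(fallbacks))) {
    names(fallbacks) <- paste0("fallback", seq_along(fallbacks))
  }
  out <- primary
  for (col in columns) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
    src <- ifelse(is.na(out[[col]]), NA_character_, "primary")
    for (nm in names(fallbacks)) {
      fb <- fallbacks[[nm]]
      if (!col %in% names(fb)) next
      idx <- match(out$food_code, fb$food_code)
      fill <- is.na(out[[col]]) & !is.na(idx) & !is.na(fb[[col]][idx])
      out[[col]][fill] <- fb[[col]][idx][fill]
      src[fill] <- nm
    }
    out[[paste0(col, "_source")]] <- src
  }
  out
}
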