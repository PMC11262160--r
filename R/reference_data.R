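#' Nutrient reference values (EAR and UL)
#'
#' Loads the table of estimated average requirements (EAR) and tolerable
#' upper intake levels (UL) by nutrient and demographic group. The packaged
#' defaults use the low-bioavailability zinc EAR set (3.6 mg/d for children
#' 1-3 y, 12.7 mg/d for adult men, 9.9-13.7 mg/d for women of reproductive
#' age depending on physiological status) and dietary-folate-equivalent EARs
#' (120 ug DFE/d children, 320-520 ug DFE/d adults). ULs are IOM values; the
#' folate UL applies to the synthetic folic-acid (fortificant) component
#' only, which the `ul_basis` column records (`"total"` vs `"fortificant"`).
#'
#' @param path Optional path to a user CSV with the same columns
#'   (`nutrient, life_stage, status, ear, ul, ul_basis, units, source`);
#'   overrides the packaged table.
#' @return A data frame of class `nutrient_references`.
#' @export
#' @examples
#' refs <- nutrient_references()
#' lookup_ear(refs, "zinc", "child_1_3y")
nutrient_references <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ear_ul.csv", package = "saltfort")
  }
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("nutrient", "life_stage", "status", "ear", "ul", "ul_basis")
  missing <- setdiff(required, names(refs))
  if (length(missing)) {
    stop("reference file lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(refs$ear <= 0)) stop("all EAR values must be positive")
  if (any(refs$ul <= refs$ear & refs$ul_basis == "total")) {
    stop("UL must exceed EAR for total-intake references")
  }
  class(refs) <- c("nutrient_references", "data.frame")
  refs
}

#' Within-to-between person variance ratios
#'
#' Ratios of within-person (day-to-day) to between-person variance on the
#' log scale, externally imputed because a single 24-h recall per person
#' cannot separate the two components. Defaults: zinc 0.47 (children) and
#' 0.61 (adults); folate 0.72 (children) and 0.89 (adults).
#'
#' @param path Optional user CSV (`nutrient, age_class, ratio`).
#' @return A data frame of class `variance_ratio_table`.
#' @export
variance_ratio_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variance_ratios.csv", package = "saltfort")
  }
  vr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nutrient", "age_class", "ratio") %in% names(vr))) {
    stop("variance-ratio file needs columns nutrient, age_class, ratio")
  }
  if (any(vr$ratio <= 0)) stop("variance ratios must be positive")
  class(vr) <- c("variance_ratio_table", "data.frame")
  vr
}

norm_nutrient <- function(nutrient) {
  # folic_acid is the fortificant form of folate; same reference rows
  ifelse(nutrient == "folic_acid", "folate", nutrient)
}

ref_lookup <- function(refs, column, nutrient, life_stage, status) {
  nutrient <- norm_nutrient(nutrient)
  n <- max(length(nutrient), length(life_stage), length(status))
  nutrient <- rep_len(nutrient, n)
  life_stage <- rep_len(life_stage, n)
  status <- rep_len(status, n)
  bad <- status != "none" & life_stage != "woman_15_49y"
  if (any(bad)) {
    stop("physiological status other than 'none' only applies to women 15-49 y")
  }
  key <- paste(refs$nutrient, refs$life_stage, refs$status)
  idx <- match(paste(nutrient, life_stage, status), key)
  if (anyNA(idx)) {
    miss <- unique(paste(nutrient, life_stage, status)[is.na(idx)])
    stop("no reference entry for: ", paste(miss, collapse = "; "))
  }
  refs[[column]][idx]
}

#' Look up the estimated average requirement
#'
#' @param refs A [nutrient_references()] table.
#' @param nutrient `"zinc"` or `"folate"` (alias `"folic_acid"`).
#' @param life_stage One of `"child_1_3y"`, `"woman_15_49y"`, `"man_19_45y"`.
#' @param status Physiological status, `"none"`, `"pregnant"` or
#'   `"lactating"` (women only). All arguments are vectorized.
#' @return EAR in mg/d (zinc) or ug DFE/d (folate).
#' @export
lookup_ear <- function(refs, nutrient, life_stage, status = "none") {
  ref_lookup(refs, "ear", nutrient, life_stage, status)
}

#' Look up the tolerable upper intake level
#'
#' For folate the UL applies to the fortificant (folic acid) amount only;
#' see the `ul_basis` column of [nutrient_references()].
#'
#' @inheritParams lookup_ear
#' @return UL in the nutrient's units per day.
#' @export
lookup_ul <- function(refs, nutrient, life_stage, status = "none") {
  ref_lookup(refs, "ul", nutrient, life_stage, status)
}

#' Basis of the UL check for a nutrient
#'
#' @inheritParams lookup_ear
#' @return `"total"` (compare total usual intake) or `"fortificant"`
#'   (compare fortificant-delivered amount only).
#' @export
lookup_ul_basis <- function(refs, nutrient, life_stage, status = "none") {
  ref_lookup(refs, "ul_basis", nutrient, life_stage, status)
}

#' Look up a within-to-between variance ratio
#'
#' @param table A [variance_ratio_table()].
#' @param nutrient `"zinc"` or `"folate"`.
#' @param age_class `"child"` or `"adult"`.
#' @return The dimensionless ratio.
#' @export
variance_ratio <- function(table, nutrient, age_class) {
  nutrient <- norm_nutrient(nutrient)
  idx <- match(paste(nutrient, age_class),
               paste(table$nutrient, table$age_class))
  if (anyNA(idx)) {
    stop("no variance ratio for ",
         paste(unique(paste(nutrient, age_class)[is.na(idx)]), collapse = "; "))
  }
  table$ratio[idx]
}

#' Age class of a life stage
#'
#' @param life_stage Character vector of life stages.
#' @return `"child"` for children 1-3 y, `"adult"` otherwise.
#' @export
age_class_of <- function(life_stage) {
  ifelse(life_stage == "child_1_3y", "child", "adult")
}
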