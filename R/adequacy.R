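#' Prevalence of inadequate intake (EAR cut-point method)
#'
#' Percentage of the stratum whose usual intake falls strictly below the
#' estimated average requirement. Applied to the empirical distribution of
#' per-person usual-intake estimates; ties at exactly the EAR count as
#' adequate.
#'
#' @param intake Usual intakes (one per person).
#' @param ear Per-person EAR (recycled if scalar).
#' @return Percentage in `[0, 100]`.
#' @export
prevalence_inadequate <- function(intake, ear) {
  if (!length(intake)) stop("empty stratum: prevalence undefined")
  100 * mean(intake < ear)
}

#' Prevalence of excess intake (above the UL)
#'
#' Percentage strictly above the tolerable upper intake level. The intake
#' basis should be total usual intake for zinc and the fortificant-
#' delivered amount for folic acid (see [nutrient_references()]).
#'
#' @param intake Intake on the appropriate basis (one per person).
#' @param ul Per-person UL (recycled if scalar).
#' @return Percentage in `[0, 100]`.
#' @export
prevalence_excess <- function(intake, ul) {
  if (!length(intake)) stop("empty stratum: prevalence undefined")
  100 * mean(intake > ul)
}

#' Closed-form lognormal cut-point prevalence
#'
#' Parametric variant of the cut-point method: if usual intake is lognormal
#' with log-mean `mu` and log-SD `sigma`, the fraction below a threshold is
#' the normal CDF on the log scale. Used as the analytic cross-check of the
#' empirical cut-point.
#'
#' @param threshold Cut-point (EAR or UL) on the natural scale.
#' @param mu,sigma Log-scale mean and SD of the usual-intake distribution.
#' @param tail `"below"` (inadequacy) or `"above"` (excess).
#' @return Percentage.
#' @export
lognormal_cutpoint <- function(threshold, mu, sigma,
                               tail = c("below", "above")) {
  tail <- match.arg(tail)
  p <- stats::pnorm((log(threshold) - mu) / sigma)
  100 * if (tail == "below") p else 1 - p
}

strata_definitions <- c("group_region", "sex_urban", "residence", "ses")

stratum_assignment <- function(participants, strata_type) {
  adult <- participants$life_stage != "child_1_3y"
  switch(strata_type,
    group_region = list(
      keep = rep(TRUE, nrow(participants)),
      label = paste(participants$region, participants$life_stage, sep = ".")),
    sex_urban = list(
      keep = adult & participants$residence == "urban",
      label = participants$sex),
    residence = list(keep = adult, label = participants$residence),
    ses = list(keep = adult, label = paste0("Q", participants$ses_quintile)),
    stop("unknown strata type: ", strata_type)
  )
}

#' Stratified adequacy report
#'
#' The outcome surface of the simulation: per stratum, nutrient and
#' scenario, the median intake, the prevalence of inadequate intake
#' (usual intake below the person's EAR), the prevalence of excess intake
#' (total usual above the UL for zinc; fortificant-delivered amount above
#' the folic-acid UL for folate), and the percentage-point reduction in
#' inadequacy relative to baseline. Stratifications: demographic group by
#' region (everyone), and sex among urban adults, residence, and SES
#' quintile (adults only). Values are kept at full precision; round at
#' reporting time (the printed tables this mirrors use integers for
#' percentages and one decimal for medians).
#'
#' @param intakes Long intake table combining [baseline_intakes()] and one
#'   or more [apply_fortification()] outputs.
#' @param participants Survey data frame with stratifiers.
#' @param refs A [nutrient_references()] table.
#' @param strata Character vector of stratifications to include (subset of
#'   `"group_region"`, `"sex_urban"`, `"residence"`, `"ses"`).
#' @return Data frame of class `adequacy_report`: `strata_type`, `stratum`,
#'   `nutrient`, `scenario`, `n`, `median_intake`, `pct_inadequate`,
#'   `pct_excess`, `pp_reduction`.
#' @export
adequacy_report <- function(intakes, participants, refs,
                            strata = strata_definitions) {
  strata <- match.arg(strata, strata_definitions, several.ok = TRUE)
  if (!"baseline" %in% intakes$scenario) {
    stop("intake table must include baseline rows (see baseline_intakes())")
  }
  pidx <- match(intakes$participant_id, participants$id)
  if (anyNA(pidx)) stop("intake rows with unknown participant ids")
  ear <- lookup_ear(refs, intakes$nutrient,
                    participants$life_stage[pidx],
                    participants$phys_status[pidx])
  ul <- lookup_ul(refs, intakes$nutrient,
                  participants$life_stage[pidx],
                  participants$phys_status[pidx])
  basis <- lookup_ul_basis(refs, intakes$nutrient,
                           participants$life_stage[pidx],
                           participants$phys_status[pidx])
  excess_value <- ifelse(basis == "fortificant", intakes$delivered,
                         intakes$fortified_usual)
  rows <- list()
  for (stype in strata) {
    assign <- stratum_assignment(participants, stype)
    keep <- assign$keep[pidx]
    lab <- assign$label[pidx]
    sub <- cbind(intakes[keep, , drop = FALSE],
                 .ear = ear[keep], .ul = ul[keep],
                 .excess_value = excess_value[keep], .stratum = lab[keep])
    keyf <- interaction(sub$.stratum, sub$nutrient, sub$scenario, drop = TRUE)
    for (piece in split(sub, keyf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strata_type = stype,
        stratum = piece$.stratum[1L],
        nutrient = piece$nutrient[1L],
        scenario = piece$scenario[1L],
        n = nrow(piece),
        median_intake = stats::median(piece$fortified_usual),
        pct_inadequate = prevalence_inadequate(piece$fortified_usual, piece$.ear),
        pct_excess = prevalence_excess(piece$.excess_value, piece$.ul),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  base <- report[report$scenario == "baseline", ]
  bidx <- match(paste(report$strata_type, report$stratum, report$nutrient),
                paste(base$strata_type, base$stratum, base$nutrient))
  if (anyNA(bidx)) stop("scenario stratum without a baseline counterpart")
  report$pp_reduction <- base$pct_inadequate[bidx] - report$pct_inadequate
  report <- report[order(report$strata_type, report$stratum,
                         report$nutrient, report$scenario), ]
  rownames(report) <- NULL
  class(report) <- c("adequacy_report", "data.frame")
  report
}

#' Round an adequacy report for display
#'
#' Percentages to integers and medians to one decimal, matching the
#' conventional table precision; the unrounded report remains the
#' machine-readable output.
#'
#' @param report An [adequacy_report()].
#' @export
round_report <- function(report) {
  report$median_intake <- round(report$median_intake, 1)
  for (col in c("pct_inadequate", "pct_excess", "pp_reduction")) {
    report[[col]] <- round(report[[col]])
  }
  report
}
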