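test_that("cut-point prevalences count strictly beyond the threshold", {
  expect_equal(prevalence_inadequate(c(5, 6, 7), 4), 0)
  expect_equal(prevalence_inadequate(c(1, 2, 3, 9), 4), 75)
  expect_equal(prevalence_inadequate(4, 4), 0)  # tie counts as adequate
  expect_equal(prevalence_excess(c(rep(1, 19), 99), 50), 5)
  expect_equal(prevalence_excess(50, 50), 0)    # tie is not excess
  expect_error(prevalence_inadequate(numeric(0), 4), "empty stratum")
  expect_error(prevalence_excess(numeric(0), 4), "empty stratum")
})

test_that("empirical cut-point matches the lognormal closed form", {
  set.seed(12)
  mu <- log(6.9); sigma <- 0.5
  intakes <- rlnorm(50000, mu, sigma)
  for (thr in c(3.6, 9.9, 12.7)) {
    expect_lt(abs(prevalence_inadequate(intakes, thr) -
                    lognormal_cutpoint(thr, mu, sigma)), 1)
    expect_lt(abs(prevalence_excess(intakes, thr) -
                    lognormal_cutpoint(thr, mu, sigma, "above")), 1)
  }
})

make_report_inputs <- function(seed = 25L) {
  pop <- generate_population(small_config(seed = seed))
  usual <- suppressMessages(estimate_usual_population(pop))$estimates
  sc <- build_salt_scenario(pop, "calculated")
  fort <- apply_fortification(usual, sc,
                              fortification_spec(zinc_mg_g = 0.6,
                                                 folic_acid_ug_g = 22))
  list(pop = pop, usual = usual, intakes = rbind(baseline_intakes(usual), fort))
}

test_that("the report covers all strata with coherent percentages", {
  inp <- make_report_inputs()
  refs <- nutrient_references()
  rep <- adequacy_report(inp$intakes, inp$pop, refs)
  gr <- rep[rep$strata_type == "group_region", ]
  expect_equal(sort(unique(as.character(gr$stratum))),
               sort(c(t(outer(c("AddisAbaba", "Somali"),
                              c("child_1_3y", "woman_15_49y", "man_19_45y"),
                              paste, sep = ".")))))
  expect_true(all(rep$pct_inadequate >= 0 & rep$pct_inadequate <= 100))
  expect_true(all(rep$pct_excess >= 0 & rep$pct_excess <= 100))
  expect_true(all(rep$pp_reduction[rep$scenario == "baseline"] == 0))
  # pp_reduction is the stated difference, exactly
  base <- rep[rep$scenario == "baseline", ]
  sc <- rep[rep$scenario == "calculated", ]
  idx <- match(paste(sc$strata_type, sc$stratum, sc$nutrient),
               paste(base$strata_type, base$stratum, base$nutrient))
  expect_equal(sc$pp_reduction, base$pct_inadequate[idx] - sc$pct_inadequate)
  # adult-only stratifications exclude children
  expect_false("child_1_3y" %in% rep$stratum[rep$strata_type == "residence"])
})

test_that("inadequate / in-range / excess partition each stratum (zinc)", {
  inp <- make_report_inputs(seed = 26L)
  refs <- nutrient_references()
  zinc <- inp$intakes[inp$intakes$nutrient == "zinc" &
                        inp$intakes$scenario == "calculated", ]
  p <- inp$pop[match(zinc$participant_id, inp$pop$id), ]
  ear <- lookup_ear(refs, "zinc", p$life_stage, p$phys_status)
  ul <- lookup_ul(refs, "zinc", p$life_stage, p$phys_status)
  below <- prevalence_inadequate(zinc$fortified_usual, ear)
  above <- prevalence_excess(zinc$fortified_usual, ul)
  mid <- 100 * mean(zinc$fortified_usual >= ear & zinc$fortified_usual <= ul)
  expect_equal(below + mid + above, 100)
})

test_that("the report is invariant to participant row order", {
  inp <- make_report_inputs(seed = 27L)
  refs <- nutrient_references()
  r1 <- adequacy_report(inp$intakes, inp$pop, refs)
  set.seed(1)
  shuffled <- inp$intakes[sample(nrow(inp$intakes)), ]
  r2 <- adequacy_report(shuffled, inp$pop, refs)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("identical fortified and baseline tables give identical rows", {
  inp <- make_report_inputs(seed = 28L)
  refs <- nutrient_references()
  zero <- apply_fortification(inp$usual,
                              build_salt_scenario(inp$pop, "calculated"),
                              fortification_spec())
  rep <- adequacy_report(rbind(baseline_intakes(inp$usual), zero),
                         inp$pop, refs, strata = "group_region")
  base <- rep[rep$scenario == "baseline", c("stratum", "nutrient",
                                            "median_intake", "pct_inadequate",
                                            "pct_excess")]
  sc <- rep[rep$scenario == "calculated", c("stratum", "nutrient",
                                            "median_intake", "pct_inadequate",
                                            "pct_excess")]
  rownames(base) <- rownames(sc) <- NULL
  expect_equal(sc, base)
})

test_that("folate excess is judged on the fortificant-delivered amount", {
  pop <- generate_population(small_config(seed = 29L))
  usual <- suppressMessages(estimate_usual_population(pop))$estimates
  sc <- build_salt_scenario(pop, "recommended")
  # an absurd folic-acid rate: total folate high AND delivered > UL
  fort <- apply_fortification(usual, sc,
                              fortification_spec(folic_acid_ug_g = 500))
  refs <- nutrient_references()
  rep <- adequacy_report(rbind(baseline_intakes(usual), fort), pop, refs,
                         strata = "group_region")
  fol <- rep[rep$nutrient == "folate" & rep$scenario == "recommended" &
               grepl("man|woman", rep$stratum), ]
  # adults: delivered = 5 g x 500 ug/g = 2500 ug > 1000 ug UL, so 100%
  expect_true(all(fol$pct_excess == 100))
  # baseline delivered is zero, so baseline folate excess is zero
  expect_true(all(rep$pct_excess[rep$nutrient == "folate" &
                                   rep$scenario == "baseline"] == 0))
})
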