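opt_inputs <- function(seed = 33L, n = c(40L, 60L, 35L, 0L, 0L, 0L, 30L, 35L, 0L)) {
  pop <- generate_population(small_config(seed = seed, n = n))
  usual <- suppressMessages(estimate_usual_population(pop))$estimates
  sc <- build_salt_scenario(pop, "calculated")
  list(pop = pop, usual = usual, sc = sc)
}

# exhaustive evaluation of every grid point, written independently of
# optimize_rate(): best feasible objective, ties to the lowest rate
brute_force_rate <- function(inp, nutrient, grid, refs, threshold = 5) {
  est <- inp$usual[inp$usual$nutrient == nutrient, ]
  best <- list(rate = NA_real_, objective = NA_real_, feasible = FALSE)
  for (r in grid) {
    spec <- if (nutrient == "zinc") fortification_spec(zinc_mg_g = r) else
      fortification_spec(folic_acid_ug_g = r)
    fort <- apply_fortification(est, inp$sc, spec)
    rep <- adequacy_report(rbind(baseline_intakes(est), fort), inp$pop, refs,
                           strata = "group_region")
    sc_rows <- rep[rep$scenario != "baseline", ]
    obj <- weighted.mean(sc_rows$pp_reduction, sc_rows$n)
    if (max(sc_rows$pct_excess) < threshold &&
        (!best$feasible || obj > best$objective)) {
      best <- list(rate = r, objective = obj, feasible = TRUE)
    }
  }
  best
}

test_that("grid search equals exhaustive brute force, feasible or not", {
  refs <- nutrient_references()
  for (seed in c(33L, 35L)) {
    inp <- opt_inputs(seed = seed)
    grid <- seq(0, 1.5, length.out = 11)
    res <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc", grid, refs = refs)
    oracle <- brute_force_rate(inp, "zinc", grid, refs)
    expect_equal(res$feasible, oracle$feasible)
    expect_equal(res$chosen_rate, oracle$rate)
    expect_equal(res$objective, oracle$objective)
    if (res$feasible) expect_lt(res$constraint_margin, 5)

    fa_grid <- seq(0, 50, by = 5)
    res_fa <- optimize_rate(inp$pop, inp$usual, inp$sc, "folate", fa_grid,
                            refs = refs)
    oracle_fa <- brute_force_rate(inp, "folate", fa_grid, refs)
    expect_equal(res_fa$feasible, oracle_fa$feasible)
    expect_equal(res_fa$chosen_rate, oracle_fa$rate)
    expect_equal(res_fa$objective, oracle_fa$objective)
  }
})

test_that("degenerate grids and unbinding constraints behave as closed form", {
  inp <- opt_inputs(seed = 34L)
  res0 <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc", 0,
                        refs = unbounded_refs())
  expect_equal(res0$chosen_rate, 0)
  expect_equal(res0$objective, 0)

  # UL effectively infinite: the constraint never binds, objective is
  # monotone in rate, so the maximum of the grid is chosen
  grid <- seq(0, 1.5, 0.15)
  res <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc", grid,
                       refs = unbounded_refs())
  expect_equal(res$chosen_rate, max(grid))
  expect_true(all(res$grid_trace$feasible))
})

test_that("excess is monotone so the feasible set is a prefix of the grid", {
  inp <- opt_inputs(seed = 35L)
  refs <- nutrient_references()
  grid <- seq(0, 1.5, 0.1)
  res <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc", grid, refs = refs)
  tr <- res$grid_trace
  expect_true(all(diff(tr$max_excess) >= 0))
  expect_true(all(diff(tr$objective) >= -1e-12))
  if (any(tr$feasible)) {
    last_feasible <- max(which(tr$feasible))
    expect_true(all(tr$feasible[seq_len(last_feasible)]))
    # tie-break to the lowest rate attaining the feasible maximum
    expect_equal(res$objective, tr$objective[last_feasible])
    expect_equal(res$chosen_rate,
                 tr$rate[min(which(tr$feasible &
                                     tr$objective == res$objective))])
  }
})

test_that("grid refinement never decreases the attained objective", {
  inp <- opt_inputs(seed = 36L)
  refs <- unbounded_refs()
  coarse <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc",
                          seq(0, 1.5, 0.5), refs = refs)
  fine <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc",
                        seq(0, 1.5, 0.1), refs = refs)
  expect_gte(fine$objective, coarse$objective)
})

test_that("an infeasible grid returns a trace, not an exception", {
  inp <- opt_inputs(seed = 37L)
  refs <- nutrient_references()
  refs$ul[refs$nutrient == "zinc"] <- 0.01  # everything is excess
  res <- optimize_rate(inp$pop, inp$usual, inp$sc, "zinc",
                       seq(0.1, 1, 0.1), refs = refs)
  expect_false(res$feasible)
  expect_true(is.na(res$chosen_rate))
  expect_equal(nrow(res$grid_trace), 10L)
  expect_error(optimize_rate(inp$pop, inp$usual, inp$sc, "zinc",
                             c(2, 1), refs = refs), "sorted")
})
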