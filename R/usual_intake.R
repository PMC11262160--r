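#' Fit a usual-intake model from single 24-h recalls
#'
#' Estimates the usual (long-run average) intake distribution of a stratum
#' from one recall per person, using an externally imputed within-person
#' variance ratio. The standard external-variance shrinkage is applied on a
#' transformed scale: intakes are transformed (natural log by default),
#' nuisance recall-day effects (weekend, sickness, unusual consumption) are
#' removed by a linear model and the intakes re-expressed as
#' predicted-at-reference-day + residual, the observed variance is
#' decomposed using the ratio `r` of within- to between-person variance
#' (`var_between = var_obs / (1 + r)`), and individual deviations from the
#' stratum mean are shrunk by `sqrt(1 / (1 + r))` before back-transforming.
#'
#' @param formula Model formula: one-day intake on the left, nuisance
#'   recall-day covariates on the right (use `~ 1` for none), e.g.
#'   `zinc_day_mg_d ~ weekend + sick + unusual`.
#' @param data Data frame with one row per participant.
#' @param ratio Within-to-between person variance ratio on the transformed
#'   scale (e.g. 0.61 for zinc in adults); must be `>= 0`.
#' @param transform `"log"` (default) or `"boxcox"`; for Box-Cox, `lambda`
#'   is profile-likelihood estimated via [MASS::boxcox()] when `NULL`.
#' @param lambda Optional fixed Box-Cox exponent.
#' @param reference Where to predict the recall-day covariates when
#'   recentring: `"baseline"` (all nuisance covariates at their reference
#'   level, the default) or `"mean"` (average over the observed covariate
#'   distribution).
#' @param min_n Minimum stratum size; smaller strata should be pooled
#'   upstream and fitting errors out below this floor.
#' @param zero_policy Handling of non-positive intakes under a log
#'   transform: `"half_min"` replaces them by half the smallest positive
#'   observed value (with a message), `"error"` refuses.
#' @return An object of class `usual_intake_fit` with components including
#'   `mu_t`, `var_obs_t`, `var_between_t`, `var_within_t`, `shrinkage`,
#'   covariate `coefficients`, and the adjusted transformed intakes.
#' @seealso [predict.usual_intake_fit()], [estimate_usual_population()]
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(zinc = rlnorm(200, log(7), 0.6),
#'                 weekend = runif(200) < 2 / 7)
#' fit <- fit_usual_intake(zinc ~ weekend, d, ratio = 0.61)
#' fit
#' head(predict(fit))
fit_usual_intake <- function(formula, data, ratio,
                             transform = c("log", "boxcox"), lambda = NULL,
                             reference = c("baseline", "mean"),
                             min_n = 30, zero_policy = c("half_min", "error")) {
  transform <- match.arg(transform)
  reference <- match.arg(reference)
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio >= 0)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  x <- stats::model.response(mf)
  n <- length(x)
  if (n < min_n) {
    stop("stratum has ", n, " participants (< ", min_n,
         "); pool strata before fitting")
  }
  zero_replacement <- NA_real_
  if (any(x <= 0)) {
    if (zero_policy == "error") stop("non-positive intakes under transform")
    zero_replacement <- min(x[x > 0]) / 2
    message(sum(x <= 0), " non-positive intake(s) replaced by ",
            signif(zero_replacement, 3))
    x[x <= 0] <- zero_replacement
  }
  if (transform == "boxcox" && is.null(lambda)) {
    prof <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.05), plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }
  y <- transform_intake(x, transform, lambda)

  covars <- attr(stats::terms(mf), "term.labels")
  if (length(covars)) {
    lmfit <- stats::lm(stats::reformulate(covars, response = "y"),
                       data = cbind(mf[-1L], y = y))
    beta <- stats::coef(lmfit)
    if (anyNA(beta)) {
      warning("dropping aliased covariate term(s): ",
              paste(names(beta)[is.na(beta)], collapse = ", "))
    }
    ref_level <- switch(reference,
      baseline = unname(beta[1L]),              # intercept = all nuisance at reference
      mean = mean(stats::fitted(lmfit))
    )
    y_adj <- unname(ref_level + stats::residuals(lmfit))
    coefficients <- beta
  } else {
    y_adj <- unname(y)
    coefficients <- c(`(Intercept)` = mean(y))
  }

  var_obs <- stats::var(y_adj)
  var_between <- var_obs / (1 + ratio)
  var_within <- var_obs * ratio / (1 + ratio)
  shrinkage <- sqrt(1 / (1 + ratio))

  structure(list(
    call = match.call(),
    formula = formula,
    transform = transform, lambda = lambda,
    reference = reference,
    ratio = ratio, n = n,
    coefficients = coefficients,
    mu_t = mean(y_adj),
    var_obs_t = var_obs,
    var_between_t = var_between,
    var_within_t = var_within,
    shrinkage = shrinkage,
    y_adj = y_adj,
    zero_replacement = zero_replacement
  ), class = "usual_intake_fit")
}

transform_intake <- function(x, transform, lambda) {
  if (transform == "log") return(log(x))
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

back_transform_intake <- function(y, transform, lambda) {
  if (transform == "log") return(exp(y))
  if (abs(lambda) < 1e-8) exp(y) else pmax(lambda * y + 1, 0)^(1 / lambda)
}

#' Per-person usual-intake estimates from a fitted model
#'
#' Shrinks each person's (adjusted, transformed) one-day intake towards the
#' stratum mean and back-transforms: `usual_t = mu + shrinkage * (y - mu)`.
#' Point estimates use the plain inverse transform; medians and cut-point
#' prevalences are invariant to any lognormal mean correction because the
#' back-transform is monotone.
#'
#' @param object A `usual_intake_fit`.
#' @param newdata Optional data frame on which to predict (transformed and
#'   covariate-adjusted with the stored coefficients); defaults to the
#'   fitting data.
#' @param type `"response"` (natural scale, default) or `"transformed"`.
#' @param ... Unused.
#' @return Numeric vector of usual-intake estimates.
#' @export
predict.usual_intake_fit <- function(object, newdata = NULL,
                                     type = c("response", "transformed"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    y_adj <- object$y_adj
  } else {
    mf <- stats::model.frame(object$formula, newdata,
                             na.action = stats::na.fail)
    x <- stats::model.response(mf)
    if (any(x <= 0)) {
      repl <- object$zero_replacement
      if (is.na(repl)) stop("non-positive intakes in newdata")
      x[x <= 0] <- repl
    }
    y <- transform_intake(x, object$transform, object$lambda)
    covars <- attr(stats::terms(mf), "term.labels")
    if (length(covars)) {
      X <- stats::model.matrix(stats::reformulate(covars), mf)
      beta <- object$coefficients
      beta[is.na(beta)] <- 0
      nuisance <- drop(X %*% beta) - beta[1L]
      ref <- switch(object$reference, baseline = 0,
                    mean = object$mu_t - beta[1L])
      y_adj <- y - nuisance + ref
    } else {
      y_adj <- y
    }
  }
  usual_t <- unname(object$mu_t + object$shrinkage * (y_adj - object$mu_t))
  if (type == "transformed") usual_t
  else back_transform_intake(usual_t, object$transform, object$lambda)
}

#' @export
print.usual_intake_fit <- function(x, digits = 4, ...) {
  cat("Usual-intake model (external-variance shrinkage)\n")
  cat("  transform:", x$transform,
      if (x$transform == "boxcox") paste0("(lambda = ", signif(x$lambda, 3), ")"),
      "  n =", x$n, "\n")
  cat("  variance ratio (within/between):", format(x$ratio), "\n")
  cat("  var_obs =", signif(x$var_obs_t, digits),
      " var_between =", signif(x$var_between_t, digits),
      " shrinkage =", signif(x$shrinkage, digits), "\n")
  invisible(x)
}

#' @export
summary.usual_intake_fit <- function(object, ...) {
  usual <- predict(object)
  structure(list(
    fit = object,
    usual_quantiles = stats::quantile(usual, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    observed_quantiles = stats::quantile(
      back_transform_intake(object$y_adj, object$transform, object$lambda),
      c(0.05, 0.25, 0.5, 0.75, 0.95))
  ), class = "summary.usual_intake_fit")
}

#' @export
print.summary.usual_intake_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCovariate coefficients (transformed scale):\n")
  print(x$fit$coefficients)
  cat("\nObserved one-day intake quantiles:\n")
  print(signif(x$observed_quantiles, 4))
  cat("Estimated usual intake quantiles:\n")
  print(signif(x$usual_quantiles, 4))
  invisible(x)
}

#' @export
coef.usual_intake_fit <- function(object, ...) object$coefficients

#' @export
residuals.usual_intake_fit <- function(object, ...) object$y_adj - object$mu_t

#' Simulate usual intakes from the fitted distribution
#'
#' Draws from the parametric (lognormal on the transformed scale)
#' usual-intake distribution implied by the fit: mean `mu_t`, variance
#' `var_between_t`. Used by the parametric (closed-form) prevalence variant.
#'
#' @param object A `usual_intake_fit`.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
simulate.usual_intake_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rnorm(nsim, object$mu_t, sqrt(object$var_between_t))
  back_transform_intake(y, object$transform, object$lambda)
}

#' Remove nuisance recall-day effects from transformed intakes
#'
#' Standalone version of the covariate adjustment performed inside
#' [fit_usual_intake()]: fits a linear model of the transformed intake on
#' the nuisance covariates and returns predicted-at-reference + residual.
#' Stratifier covariates (region, SES, residence, sex) should not be passed
#' here; they are retained for stratification, not removed.
#'
#' @param y Transformed intakes.
#' @param data Data frame with the covariates.
#' @param formula RHS-only formula of nuisance covariates, e.g.
#'   `~ weekend + sick + unusual`.
#' @param reference `"baseline"` or `"mean"` (see [fit_usual_intake()]).
#' @return List with `adjusted` values and the fitted `coefficients`.
#' @export
adjust_covariates <- function(y, data, formula = ~ weekend + sick + unusual,
                              reference = c("baseline", "mean")) {
  reference <- match.arg(reference)
  covars <- attr(stats::terms(formula), "term.labels")
  if (!length(covars)) {
    return(list(adjusted = y, coefficients = c(`(Intercept)` = mean(y))))
  }
  lmfit <- stats::lm(stats::reformulate(covars, response = "y"),
                     data = cbind(data, y = y))
  beta <- stats::coef(lmfit)
  if (anyNA(beta)) {
    warning("dropping aliased covariate term(s): ",
            paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  ref_level <- switch(reference, baseline = unname(beta[1L]),
                      mean = mean(stats::fitted(lmfit)))
  list(adjusted = ref_level + stats::residuals(lmfit), coefficients = beta)
}

#' Usual-intake estimates for a whole survey population
#'
#' Fits one usual-intake model per fitting stratum (region x life stage by
#' default) and nutrient, then predicts per-person usual intakes. Strata
#' below `min_n` participants are pooled across regions within life stage
#' (with a message), since the variance ratio depends only on age class.
#'
#' @param participants Survey data frame as produced by
#'   [generate_population()] (or [compute_day_intake()] merged with
#'   stratifiers): must carry `region`, `life_stage`, the recall covariates
#'   and per-nutrient one-day intake columns (`zinc_day_mg_d`,
#'   `folate_day_ug_dfe_d`).
#' @param nutrients Nutrients to process.
#' @param ratios A [variance_ratio_table()].
#' @param covariate_formula RHS-only nuisance covariate formula.
#' @param min_n Stratum floor before pooling.
#' @param ... Passed on to [fit_usual_intake()].
#' @return List with `estimates` (long data frame: `participant_id`,
#'   `nutrient`, `usual_intake`) and `models` (named list of fits).
#' @export
estimate_usual_population <- function(participants,
                                      nutrients = c("zinc", "folate"),
                                      ratios = variance_ratio_table(),
                                      covariate_formula = ~ weekend + sick + unusual,
                                      min_n = 30, ...) {
  covars <- attr(stats::terms(covariate_formula), "term.labels")
  est <- list()
  models <- list()
  for (nut in nutrients) {
    col <- day_col(nut)
    if (!col %in% names(participants)) {
      stop("participants lack column ", col)
    }
    for (stage in unique(participants$life_stage)) {
      sub_stage <- participants[participants$life_stage == stage, , drop = FALSE]
      counts <- table(sub_stage$region)
      pool <- any(counts < min_n) || length(counts) == 1L
      if (any(counts < min_n) && length(counts) > 1L) {
        message("pooling regions for ", stage, " (smallest stratum n = ",
                min(counts), " < ", min_n, ")")
      }
      groups <- if (pool) list(pooled = sub_stage) else
        split(sub_stage, sub_stage$region)
      r <- variance_ratio(ratios, nut, age_class_of(stage))
      for (gname in names(groups)) {
        g <- groups[[gname]]
        fml <- stats::reformulate(if (length(covars)) covars else "1",
                                  response = col)
        fit <- fit_usual_intake(fml, g, ratio = r, min_n = min_n, ...)
        models[[paste(nut, stage, gname, sep = ".")]] <- fit
        est[[length(est) + 1L]] <- data.frame(
          participant_id = g$id, nutrient = nut,
          usual_intake = predict(fit), stringsAsFactors = FALSE
        )
      }
    }
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  list(estimates = estimates, models = models)
}
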