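# Back-transformed-scale goodness of fit and the model-selection rule.
#
# R2 and MAPE are computed on the arithmetic (kg) scale against the
# bias-corrected back-transformed predictions, not on the log scale: the
# quantity users care about is mass, and the correction factor changes the
# arithmetic-scale error but not the log-scale one.

#' Coefficient of determination on the arithmetic scale
#'
#' `R2 = 1 - sum((W - What)^2) / sum((W - Wbar)^2)`. May be negative when
#' predictions do worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2, kg.
#' @return Dimensionless R2 <= 1.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values are constant; R2 undefined")
  1 - sum((observed - predicted)^2) / tss
}

#' Mean absolute prediction error
#'
#' `MAPE = mean(|W - What| / W)`, a scale-free fraction.
#'
#' @param observed,predicted Numeric vectors of equal length; `observed`
#'   strictly positive.
#' @return MAPE as a fraction (0.10 means 10% mean absolute error).
#' @export
mape <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (any(observed <= 0)) stop("'observed' must be strictly positive")
  mean(abs(observed - predicted) / observed)
}

#' Relative MAPE reduction of an alternative model
#'
#' How much lower (in percent) the alternative's MAPE is than the
#' reference's: `100 * (ref - alt) / ref`.
#'
#' @param mape_reference,mape_alternative Positive MAPE values.
#' @return Reduction in percent (negative if the alternative is worse).
#' @examples
#' mape_reduction(0.110, 0.071) # 35.45
#' @export
mape_reduction <- function(mape_reference, mape_alternative) {
  stopifnot(is.numeric(mape_reference), is.numeric(mape_alternative))
  if (any(mape_reference <= 0) || any(mape_alternative <= 0)) {
    stop("MAPE values must be positive")
  }
  100 * (mape_reference - mape_alternative) / mape_reference
}

#' Per-coefficient t tests
#'
#' Two-sided t tests with `n - k` degrees of freedom, from the fit's
#' coefficient covariance.
#'
#' @param fit An `allom_fit` (or any object with coefficients, vcov, n, k).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with columns term, estimate, se, t, p, significant.
#' @export
coefficient_significance <- function(fit, alpha = 0.05) {
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(se == 0)) stop("zero standard error; t statistic undefined")
  df <- fit$n - fit$k
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  data.frame(term = names(beta), estimate = unname(beta), se = unname(se),
             t = unname(tval), p = unname(pval),
             significant = unname(pval < alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluation statistics for one fitted candidate
#'
#' @param fit An `allom_fit`.
#' @param trees Evaluation records; the fitting data if omitted.
#' @return List with `r2`, `mape`, `n` (back-transformed, CF-corrected).
#' @export
eval_stats <- function(fit, trees = NULL) {
  trees <- if (is.null(trees)) fit$trees else validate_trees(trees)
  obs <- trees[[biomass_cols()[fit$component]]]
  pred <- predict(fit, trees)
  list(r2 = r_squared(obs, pred), mape = mape(obs, pred), n = length(obs))
}

# comparison values rounded to 6 decimals so float noise cannot break ties
.round6 <- function(x) round(x, 6)

#' Select the best candidate model for one component
#'
#' Fits all candidates (or a supplied subset), computes CF-corrected
#' back-transformed R2 and MAPE, and applies the selection rule:
#' a model is *eligible* when every non-intercept coefficient is
#' significant at `alpha` (the intercept does not gate eligibility); among
#' eligible models the lowest MAPE wins; ties (after rounding to 6
#' decimals) go to the higher R2, then to fewer coefficients, then to the
#' lower model index. If nothing is eligible the lowest-MAPE model overall
#' is returned with `eligible_choice = FALSE` and a warning.
#'
#' @param trees Records of one age group.
#' @param component Component to model.
#' @param specs List of [allom_spec()]s; all six by default.
#' @param alpha Significance level gating eligibility (strict `p < alpha`).
#' @param cf_df Passed to [fit_allom()].
#' @return Object of class `allom_selection`: the chosen `allom_fit`, a
#'   per-model comparison table, all fits, and a text rationale trail.
#' @export
select_allom <- function(trees, component, specs = allom_specs(),
                         alpha = 0.05, cf_df = c("residual", "classic")) {
  cf_df <- match.arg(cf_df)
  trees <- validate_trees(trees)
  if (length(specs) == 0) stop("no candidate specifications supplied")
  fits <- lapply(specs, function(sp) {
    fit_allom(trees, component, sp, cf_df = cf_df)
  })
  stats_tab <- do.call(rbind, lapply(fits, function(f) {
    es <- eval_stats(f)
    # a perfect fit pins every coefficient exactly; treat slopes as
    # significant rather than dividing by a zero standard error
    slope_ok <- if (f$sigma2 == 0) TRUE else {
      sig <- coefficient_significance(f, alpha = alpha)
      all(sig$significant[sig$term != "(Intercept)"])
    }
    data.frame(model = f$spec$id, k = f$k, r2 = es$r2, mape = es$mape,
               eligible = slope_ok, stringsAsFactors = FALSE)
  }))
  rownames(stats_tab) <- NULL
  idx <- as.integer(sub("^M", "", stats_tab$model))

  pick <- function(rows) {
    # lowest MAPE, then highest R2, then fewest coefficients, then index
    o <- order(.round6(stats_tab$mape[rows]), -.round6(stats_tab$r2[rows]),
               stats_tab$k[rows], idx[rows])
    rows[o[1]]
  }
  trail <- character(0)
  elig_rows <- which(stats_tab$eligible)
  if (length(elig_rows)) {
    best <- pick(elig_rows)
    skipped <- which(!stats_tab$eligible &
                       .round6(stats_tab$mape) < .round6(stats_tab$mape[best]))
    for (s in skipped) {
      trail <- c(trail, sprintf(
        "%s has lower MAPE (%.4f) but non-significant slope(s); skipped",
        stats_tab$model[s], stats_tab$mape[s]))
    }
    eligible_choice <- TRUE
  } else {
    best <- pick(seq_len(nrow(stats_tab)))
    eligible_choice <- FALSE
    trail <- c(trail, "no candidate had all slopes significant; fell back to lowest MAPE overall")
    warning("no eligible candidate for ", component,
            "; returning lowest-MAPE model with a flag")
  }
  trail <- c(trail, sprintf(
    "chose %s: MAPE %.4f, R2 %.4f, %d coefficients",
    stats_tab$model[best], stats_tab$mape[best], stats_tab$r2[best],
    stats_tab$k[best]))
  structure(list(
    component = component,
    group = as.character(trees$group[1]),
    chosen = fits[[best]],
    comparison = stats_tab,
    fits = fits,
    eligible_choice = eligible_choice,
    alpha = alpha,
    rationale = trail
  ), class = "allom_selection")
}

#' @export
print.allom_selection <- function(x, ...) {
  cat(sprintf("Model selection: %s biomass (%s group)\n", x$component,
              x$group))
  print(transform(x$comparison, r2 = round(r2, 4), mape = round(mape, 4)))
  cat("chosen:", x$chosen$spec$id,
      if (!x$eligible_choice) "(fallback: no eligible model)" else "", "\n")
  invisible(x)
}

#' Select component models for every component in one age group
#'
#' @inheritParams select_allom
#' @return Named list of [select_allom()] results (trunk, branch, leaf,
#'   root).
#' @export
select_all_components <- function(trees, specs = allom_specs(), alpha = 0.05,
                                  cf_df = c("residual", "classic")) {
  cf_df <- match.arg(cf_df)
  stats::setNames(lapply(components(), function(cm) {
    select_allom(trees, cm, specs = specs, alpha = alpha, cf_df = cf_df)
  }), components())
}
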