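# Joint estimation of the four selected component equations by seemingly
# unrelated regression (iterated feasible GLS), and additive prediction of
# total biomass.
#
# The four log-scale equations share the same trees, so their errors are
# contemporaneously correlated; stacking them and weighting by the inverse
# of the estimated 4x4 cross-equation covariance yields more efficient
# coefficient estimates than equation-by-equation OLS whenever the
# regressor sets differ. Predicted total biomass is defined as the exact
# sum of the four bias-corrected component predictions, so additivity holds
# by construction rather than through a fifth fitted equation.

#' System specification for the additive biomass model
#'
#' One candidate form per component, typically the [select_allom()] choices
#' for one age group.
#'
#' @param trunk,branch,leaf,root [allom_spec()] objects or model ids.
#' @return Object of class `sur_spec`: named list of four `allom_spec`s.
#' @export
sur_spec <- function(trunk, branch, leaf, root) {
  specs <- lapply(list(trunk = trunk, branch = branch, leaf = leaf,
                       root = root),
                  function(s) if (is.character(s)) allom_spec(s) else s)
  stopifnot(all(vapply(specs, inherits, logical(1), "allom_spec")))
  structure(specs, class = "sur_spec")
}

#' System specification from per-component selection results
#'
#' @param selections Named list of `allom_selection` objects with elements
#'   trunk, branch, leaf, root (as from [select_all_components()]).
#' @return A [sur_spec()].
#' @export
sur_spec_from_selection <- function(selections) {
  stopifnot(all(components() %in% names(selections)))
  do.call(sur_spec, lapply(selections[components()],
                           function(s) s$chosen$spec))
}

#' Fit the four-equation biomass system by seemingly unrelated regression
#'
#' Iterated feasible generalized least squares on the stacked log-scale
#' system: (1) per-equation OLS provides starting residuals; (2) the
#' cross-equation error covariance is estimated as
#' `Sigma[i, j] = sum(e_i * e_j) / n` (maximum-likelihood divisor);
#' (3) GLS solves the stacked system weighted by `Sigma^{-1} (x) I_n`;
#' steps 2-3 repeat until the largest absolute coefficient change drops
#' below `tol` or `max_iter` is reached. Per-equation `sigma2` and
#' correction factors are recomputed from the final system residuals with
#' the [fit_allom()] degrees-of-freedom convention.
#'
#' When all four equations share an identical regressor matrix, or when
#' `Sigma` is diagonal, the SUR estimates coincide with per-equation OLS
#' (the classical identical-regressors result); both cases fall out of the
#' algebra and are kept as regression tests.
#'
#' @param trees Records of one age group (the same trees feed all four
#'   equations).
#' @param system A [sur_spec()].
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE` and a warning.
#' @param cf_df Degrees-of-freedom convention for `sigma2`/CF, as in
#'   [fit_allom()].
#' @param ridge Non-negative jitter added to the diagonal of `Sigma` before
#'   inversion, for near-singular covariance estimates; 0 by default.
#' @param sigma_structure `"full"` estimates the complete cross-equation
#'   covariance; `"diagonal"` zeroes the off-diagonal terms (independence
#'   working covariance), under which the estimates reduce to per-equation
#'   OLS.
#' @return Object of class `sur_fit`: per-equation coefficient vectors and
#'   covariance blocks, `Sigma` (4x4 cross-equation covariance), per-equation
#'   `sigma2` and `cf`, log-scale residual matrix, iteration count and
#'   convergence flag.
#' @export
fit_sur <- function(trees, system, tol = 1e-8, max_iter = 100,
                    cf_df = c("residual", "classic"), ridge = 0,
                    sigma_structure = c("full", "diagonal")) {
  stopifnot(inherits(system, "sur_spec"))
  cf_df <- match.arg(cf_df)
  sigma_structure <- match.arg(sigma_structure)
  trees <- validate_trees(trees)
  n <- nrow(trees)
  comps <- components()
  designs <- lapply(comps, function(cm) build_design(system[[cm]], trees, cm))
  names(designs) <- comps
  ks <- vapply(designs, function(d) ncol(d$X), integer(1))
  if (any(n <= ks)) {
    stop("sample size must exceed every equation's coefficient count")
  }
  Xs <- lapply(designs, `[[`, "X")
  ys <- lapply(designs, `[[`, "y")
  m <- length(comps)
  offs <- c(0, cumsum(ks))

  # cached cross-products X_i' X_j and X_i' y_j for the block GLS system
  XtX <- lapply(seq_len(m), function(i) {
    lapply(seq_len(m), function(j) crossprod(Xs[[i]], Xs[[j]]))
  })
  Xty <- lapply(seq_len(m), function(i) {
    lapply(seq_len(m), function(j) crossprod(Xs[[i]], ys[[j]]))
  })

  beta <- unlist(lapply(seq_len(m), function(i) {
    stats::lm.fit(Xs[[i]], ys[[i]])$coefficients
  }), use.names = FALSE)

  resid_mat <- function(beta) {
    vapply(seq_len(m), function(i) {
      bi <- beta[(offs[i] + 1):offs[i + 1]]
      ys[[i]] - drop(Xs[[i]] %*% bi)
    }, numeric(n))
  }

  Sigma <- NULL
  iter <- 0L
  converged <- FALSE
  A <- matrix(0, sum(ks), sum(ks))
  b <- numeric(sum(ks))
  repeat {
    iter <- iter + 1L
    E <- resid_mat(beta)
    Sigma <- crossprod(E) / n
    if (sigma_structure == "diagonal") Sigma <- diag(diag(Sigma))
    if (ridge > 0) Sigma <- Sigma + diag(ridge, m)
    Sinv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) {
      stop("cross-equation covariance is (near-)singular; ",
           "consider a positive 'ridge'")
    })
    for (i in seq_len(m)) {
      ri <- (offs[i] + 1):offs[i + 1]
      b[ri] <- Reduce(`+`, lapply(seq_len(m), function(j) {
        Sinv[i, j] * Xty[[i]][[j]]
      }))
      for (j in seq_len(m)) {
        A[ri, (offs[j] + 1):offs[j + 1]] <- Sinv[i, j] * XtX[[i]][[j]]
      }
    }
    beta_new <- drop(solve(A, b))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("SUR did not converge in %d iterations (last max change %.3g)",
                    max_iter, delta))
  }

  E <- resid_mat(beta)
  Sigma <- crossprod(E) / n
  vcov_full <- solve(A)
  coef_list <- lapply(seq_len(m), function(i) {
    bi <- beta[(offs[i] + 1):offs[i + 1]]
    names(bi) <- colnames(Xs[[i]])
    bi
  })
  names(coef_list) <- comps
  vcov_list <- lapply(seq_len(m), function(i) {
    ri <- (offs[i] + 1):offs[i + 1]
    v <- vcov_full[ri, ri, drop = FALSE]
    dimnames(v) <- list(colnames(Xs[[i]]), colnames(Xs[[i]]))
    v
  })
  names(vcov_list) <- comps
  dfs <- if (cf_df == "classic") rep(n - 2L, m) else n - ks
  sigma2 <- colSums(E^2) / dfs
  names(sigma2) <- comps
  colnames(E) <- comps
  dimnames(Sigma) <- list(comps, comps)
  structure(list(
    coefficients = coef_list,
    vcov = vcov_list,
    vcov_full = vcov_full,
    Sigma = Sigma,
    sigma2 = sigma2,
    cf = correction_factor(sigma2),
    residuals = E,
    n = n, k = stats::setNames(as.integer(ks), comps),
    iterations = iter,
    converged = converged,
    system = system,
    cf_df = cf_df,
    trees = trees
  ), class = "sur_fit")
}

#' @export
coef.sur_fit <- function(object, ...) object$coefficients

#' @export
vcov.sur_fit <- function(object, ...) object$vcov

#' @export
residuals.sur_fit <- function(object, ...) object$residuals

#' @export
print.sur_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Additive biomass system (SUR, %d trees, %d iterations%s)\n",
              x$n, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  for (cm in components()) {
    cat(sprintf("  %-6s %s: ", cm, x$system[[cm]]$id))
    cat(paste(sprintf("%s=%.*f", names(x$coefficients[[cm]]), digits,
                      x$coefficients[[cm]]), collapse = "  "),
        sprintf(" CF=%.*f", digits, x$cf[cm]), "\n")
  }
  invisible(x)
}

#' @export
summary.sur_fit <- function(object, alpha = 0.05, ...) {
  tabs <- lapply(components(), function(cm) {
    f <- list(coefficients = object$coefficients[[cm]],
              vcov = object$vcov[[cm]],
              n = object$n, k = object$k[[cm]])
    class(f) <- "allom_fit"
    coefficient_significance(f, alpha = alpha)
  })
  names(tabs) <- components()
  structure(list(fit = object, coefficients = tabs,
                 cross_correlation = residual_cross_correlation(object),
                 alpha = alpha),
            class = "summary.sur_fit")
}

#' @export
print.summary.sur_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCross-equation residual correlation:\n")
  print(round(x$cross_correlation, 3))
  invisible(x)
}

#' Bias-corrected component predictions from a fitted system
#'
#' @param fit A `sur_fit`.
#' @param newdata Tree data.frame; the fitting data if omitted.
#' @return Matrix (trees x 4) of predicted trunk/branch/leaf/root biomass,
#'   kg; strictly positive.
#' @export
predict_components <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "sur_fit"))
  trees <- if (is.null(newdata)) fit$trees else validate_trees(newdata)
  out <- vapply(components(), function(cm) {
    X <- .design_matrix(fit$system[[cm]], trees)
    exp(drop(X %*% fit$coefficients[[cm]])) * fit$cf[[cm]]
  }, numeric(nrow(trees)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, components()))
  out
}

#' Additive total-biomass prediction
#'
#' Defined as the exact sum of the four component predictions — additivity
#' is an identity of the predictor, never re-fitted.
#'
#' @inheritParams predict_components
#' @return Numeric vector of predicted total biomass, kg.
#' @export
predict_total <- function(fit, newdata = NULL) {
  rowSums(predict_components(fit, newdata))
}

#' @describeIn fit_sur Predict from a fitted system: component matrix,
#'   total vector, or both.
#' @param object A `sur_fit`.
#' @param newdata Tree data.frame; the fitting data if omitted.
#' @param type `"components"`, `"total"`, or `"both"`.
#' @param ... Unused.
#' @export
predict.sur_fit <- function(object, newdata = NULL,
                            type = c("components", "total", "both"), ...) {
  type <- match.arg(type)
  comp <- predict_components(object, newdata)
  switch(type,
         components = comp,
         total = rowSums(comp),
         both = cbind(comp, total = rowSums(comp)))
}

#' Cross-equation residual correlation matrix
#'
#' The estimated 4x4 error covariance rescaled to unit diagonal — the
#' contemporaneous correlations that motivate joint estimation.
#'
#' @param fit A `sur_fit`.
#' @return 4x4 correlation matrix with unit diagonal.
#' @export
residual_cross_correlation <- function(fit) {
  stopifnot(inherits(fit, "sur_fit"))
  if (any(diag(fit$Sigma) == 0)) {
    stop("an equation has zero residual variance; correlation undefined")
  }
  stats::cov2cor(fit$Sigma)
}

#' Simulate component biomasses from a fitted system
#'
#' Draws log-scale errors from the fitted multivariate normal
#' `N(0, Sigma)` and back-transforms, giving parametric-bootstrap
#' populations on the fitted trees (or `newdata`).
#'
#' @param object A `sur_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed.
#' @param newdata Tree data.frame; the fitting data if omitted.
#' @param ... Unused.
#' @return List of `nsim` matrices (trees x 4) of simulated biomass, kg.
#' @export
simulate.sur_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  trees <- if (is.null(newdata)) object$trees else validate_trees(newdata)
  mu <- vapply(components(), function(cm) {
    X <- .design_matrix(object$system[[cm]], trees)
    drop(X %*% object$coefficients[[cm]])
  }, numeric(nrow(trees)))
  lapply(seq_len(nsim), function(s) {
    eps <- MASS::mvrnorm(nrow(trees), mu = rep(0, 4), Sigma = object$Sigma)
    exp(mu + eps)
  })
}

#' Predicted-vs-observed plot for a fitted system
#'
#' @param x A `sur_fit`.
#' @param which `"total"` or a component name.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sur_fit <- function(x, which = "total", ...) {
  which <- match.arg(which, components(include_total = TRUE))
  if (which == "total") {
    obs <- total_biomass(x$trees)
    pred <- predict_total(x)
  } else {
    obs <- x$trees[[biomass_cols()[which]]]
    pred <- predict_components(x)[, which]
  }
  graphics::plot(obs, pred, xlab = "observed biomass (kg)",
                 ylab = "predicted biomass (kg)",
                 main = sprintf("%s biomass", which), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
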