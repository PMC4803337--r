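# Six candidate log-linear allometric forms, their OLS fits on the log
# scale, and bias-corrected back-transformation.
#
# On the arithmetic scale the candidates are power laws in D (diameter at
# breast height, cm), H (total height, m) and CR (crown radius, m):
#   M1: W = alpha D^b            M4: W = alpha (D^2 H)^b
#   M2: W = alpha D^b H^c        M5: W = alpha (D^2 H)^b CR^c
#   M3: W = alpha D^b CR^c       M6: W = alpha D^b H^c CR^d
# each linearised by natural logarithms to ln W = a + (terms), a = ln alpha.

.model_terms <- list(
  M1 = "lnD",
  M2 = c("lnD", "lnH"),
  M3 = c("lnD", "lnCR"),
  M4 = "lnD2H",
  M5 = c("lnD2H", "lnCR"),
  M6 = c("lnD", "lnH", "lnCR")
)

#' Candidate allometric model specification
#'
#' @param id One of `"M1"` to `"M6"`.
#' @return An object of class `allom_spec`: list with `id` and `terms`
#'   (ordered regressor names from `lnD`, `lnH`, `lnD2H`, `lnCR`; an
#'   intercept is always implied).
#' @examples
#' allom_spec("M5")
#' @export
allom_spec <- function(id) {
  id <- match.arg(id, names(.model_terms))
  structure(list(id = id, terms = .model_terms[[id]]), class = "allom_spec")
}

#' All six candidate specifications
#'
#' @return Named list of [allom_spec()] objects, M1 through M6.
#' @export
allom_specs <- function() {
  stats::setNames(lapply(names(.model_terms), allom_spec),
                  names(.model_terms))
}

#' @export
print.allom_spec <- function(x, ...) {
  cat(sprintf("<allom_spec %s> ln(W) = a + %s\n", x$id,
              paste(paste0("b_", x$terms), collapse = " + ")))
  invisible(x)
}

# regressor values for one term; lnD2H = ln(D^2 H) = 2 lnD + lnH
.term_value <- function(term, trees) {
  switch(term,
    lnD   = log(trees$dbh_cm),
    lnH   = log(trees$height_m),
    lnCR  = log(trees$crown_radius_m),
    lnD2H = 2 * log(trees$dbh_cm) + log(trees$height_m),
    stop("unknown term: ", term)
  )
}

# intercept + term columns; robust to single-row inputs
.design_matrix <- function(spec, trees) {
  n <- nrow(trees)
  X <- matrix(1, n, 1L + length(spec$terms))
  for (j in seq_along(spec$terms)) {
    X[, j + 1L] <- .term_value(spec$terms[j], trees)
  }
  colnames(X) <- c("(Intercept)", spec$terms)
  X
}

#' Build the log-scale design matrix and response
#'
#' Columns: intercept, then the spec's terms in order; response is the
#' natural log of the chosen component's dry mass.
#'
#' @param spec An [allom_spec()].
#' @param trees Validated tree data.frame.
#' @param component One of `"trunk"`, `"branch"`, `"leaf"`, `"root"`.
#' @return List with `X` (n x k matrix) and `y` (length-n response).
#' @export
build_design <- function(spec, trees, component) {
  stopifnot(inherits(spec, "allom_spec"))
  trees <- validate_trees(trees)
  component <- match.arg(component, components())
  X <- .design_matrix(spec, trees)
  qrX <- qr(X)
  if (nrow(X) >= ncol(X) && qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  y <- log(trees[[biomass_cols()[component]]])
  list(X = X, y = y)
}

#' Lognormal retransformation correction factor
#'
#' `CF = exp(sigma2 / 2)` where `sigma2` is the log-scale mean-square error
#' of the fitted regression. Back-transforming a log-scale prediction by
#' plain exponentiation systematically underestimates the arithmetic-scale
#' mean; multiplying by CF removes that bias under lognormal errors.
#'
#' @param sigma2 Log-scale mean-square error, >= 0.
#' @return Correction factor, >= 1.
#' @examples
#' correction_factor(0.02)
#' @export
correction_factor <- function(sigma2) {
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 < 0)) {
    stop("'sigma2' must be finite and non-negative")
  }
  exp(sigma2 / 2)
}

#' Fit one candidate allometric model by log-scale OLS
#'
#' Ordinary least squares of `ln(W_component)` on the candidate's log
#' regressors. The residual variance is `sigma2 = RSS / (n - k)` with `k`
#' estimated coefficients (`cf_df = "classic"` forces the two-coefficient
#' convention `n - 2` regardless of `k`), the correction factor is
#' `exp(sigma2 / 2)` and the coefficient covariance `sigma2 (X'X)^{-1}`.
#'
#' @param trees Validated tree data.frame (pass one age group's records to
#'   fit group-wise).
#' @param component Component to model.
#' @param spec An [allom_spec()] or a model id `"M1"`..`"M6"`.
#' @param cf_df `"residual"` for `n - k` (default) or `"classic"` for `n - 2`.
#' @return Object of class `allom_fit`: coefficients, `vcov`, `sigma2`,
#'   `cf`, residuals and fitted values (log scale), `n`, `k`, the spec and
#'   component, and the fitting data.
#' @export
fit_allom <- function(trees, component, spec = "M1",
                      cf_df = c("residual", "classic")) {
  if (is.character(spec)) spec <- allom_spec(spec)
  cf_df <- match.arg(cf_df)
  trees <- validate_trees(trees)
  component <- match.arg(component, components())
  d <- build_design(spec, trees, component)
  n <- nrow(d$X); k <- ncol(d$X)
  if (n <= k) {
    stop(sprintf("n = %d records cannot identify %d coefficients plus error",
                 n, k))
  }
  fit <- stats::lm.fit(d$X, d$y)
  beta <- fit$coefficients
  res <- d$y - drop(d$X %*% beta)
  df <- if (cf_df == "classic") n - 2L else n - k
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(d$X)))
  dimnames(XtX_inv) <- list(colnames(d$X), colnames(d$X))
  structure(list(
    coefficients = beta,
    vcov = sigma2 * XtX_inv,
    sigma2 = sigma2,
    cf = correction_factor(sigma2),
    residuals = res,
    fitted_log = drop(d$X %*% beta),
    n = n, k = k, df = df,
    spec = spec,
    component = component,
    cf_df = cf_df,
    trees = trees
  ), class = "allom_fit")
}

#' @export
coef.allom_fit <- function(object, ...) object$coefficients

#' @export
vcov.allom_fit <- function(object, ...) object$vcov

#' @export
residuals.allom_fit <- function(object, ...) object$residuals

#' @export
print.allom_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Log-linear allometric fit: %s biomass, model %s (n = %d)\n",
              x$component, x$spec$id, x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("sigma2 = %.*f  CF = %.*f\n", digits, x$sigma2, digits, x$cf))
  invisible(x)
}

#' @export
summary.allom_fit <- function(object, alpha = 0.05, ...) {
  tab <- coefficient_significance(object, alpha = alpha)
  structure(list(fit = object, coefficients = tab, alpha = alpha),
            class = "summary.allom_fit")
}

#' @export
print.summary.allom_fit <- function(x, ...) {
  print(x$fit)
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "t", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Bias-corrected biomass prediction
#'
#' Back-transforms the log-scale linear prediction and multiplies by the
#' fit's correction factor: `What = exp(ln What) * CF`. Always strictly
#' positive.
#'
#' @param object An `allom_fit`.
#' @param newdata Tree data.frame to predict for; the fitting data if
#'   omitted.
#' @param correct Apply the correction factor? (`FALSE` gives the naive
#'   exponentiated prediction.)
#' @param ... Unused.
#' @return Numeric vector of predicted component biomass, kg.
#' @export
predict.allom_fit <- function(object, newdata = NULL, correct = TRUE, ...) {
  trees <- if (is.null(newdata)) object$trees else validate_trees(newdata)
  X <- .design_matrix(object$spec, trees)
  pred <- exp(drop(X %*% object$coefficients))
  if (correct) pred * object$cf else pred
}
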