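# Supporting analyses: allocation ANOVA across age groups, residual
# normality for total-biomass predictions, and tabular report output.

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = (SSB / df_between) / (SSW / df_within)` with the p-value from the F
#' distribution. Used to test whether a component's allocation share
#' differs among age groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (factor or character), same length.
#' @return List with `F`, `p`, `df_between`, `df_within`, `group_means`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  groups <- droplevels(groups)
  counts <- table(groups)
  if (any(counts < 2)) stop("every group needs at least 2 values")
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(counts * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssw == 0) stop("zero within-group variance; F undefined")
  Fstat <- (ssb / dfb) / (ssw / dfw)
  list(F = Fstat, p = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw,
       group_means = as.numeric(gm))
}

#' Shapiro-Wilk normality test with Q-Q data
#'
#' Royston's approximation of the Shapiro-Wilk W statistic and p-value
#' (via [stats::shapiro.test()]), together with normal Q-Q pairs using Blom
#' plotting positions `(i - 0.375) / (n + 0.25)`.
#'
#' @param x Numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `W`, `p`, `n`, and `qq_pairs` (data.frame of
#'   theoretical and sample quantiles, sorted by the theoretical ones).
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size must be in [3, 5000]")
  if (stats::sd(x) == 0) stop("constant sample; normality test undefined")
  sw <- stats::shapiro.test(x)
  pp <- (seq_len(n) - 0.375) / (n + 0.25)
  qq <- data.frame(theoretical = stats::qnorm(pp), sample = sort(x))
  list(W = unname(sw$statistic), p = sw$p.value, n = n, qq_pairs = qq)
}

#' Mean biomass allocation by age group
#'
#' Per-tree component fractions averaged within each group (the mean of
#' per-tree proportions, not the proportion of group-mean totals — the two
#' differ whenever allocation covaries with tree size). Rows sum to 1.
#'
#' @param trees Validated tree data.frame.
#' @return Matrix, one row per group present, columns trunk/branch/leaf/root.
#' @export
allocation_table <- function(trees) {
  trees <- validate_trees(trees)
  prop <- allocation_proportions(trees)
  present <- age_groups()[age_groups() %in% as.character(unique(trees$group))]
  out <- t(vapply(present, function(g) {
    colMeans(prop[trees$group == g, , drop = FALSE])
  }, numeric(4)))
  rownames(out) <- present
  out
}

#' Run the full additive-biomass analysis
#'
#' Chains the whole workflow on one tree table: per-group candidate fits
#' and model selection for each component, joint SUR estimation of the
#' selected system, allocation ANOVA for each component's share across age
#' groups, and the normality check on arithmetic-scale total-biomass
#' residuals (observed minus predicted totals).
#'
#' @param trees Validated tree data.frame containing all groups of
#'   interest.
#' @param alpha Significance level for selection and reporting.
#' @param cf_df Degrees-of-freedom convention, as in [fit_allom()].
#' @return Object of class `biomass_analysis`: per-group `selection` lists,
#'   `sur` fits, `allocation` table, per-component allocation `anova`, and
#'   per-group total-residual `normality` results.
#' @export
run_biomass_analysis <- function(trees, alpha = 0.05,
                                 cf_df = c("residual", "classic")) {
  cf_df <- match.arg(cf_df)
  trees <- validate_trees(trees)
  present <- age_groups()[age_groups() %in% as.character(unique(trees$group))]
  selections <- lapply(present, function(g) {
    select_all_components(trees[trees$group == g, ], alpha = alpha,
                          cf_df = cf_df)
  })
  names(selections) <- present
  surs <- lapply(present, function(g) {
    fit_sur(trees[trees$group == g, ],
            sur_spec_from_selection(selections[[g]]), cf_df = cf_df)
  })
  names(surs) <- present
  prop <- allocation_proportions(trees)
  anovas <- lapply(components(), function(cm) {
    anova_oneway(prop[, cm], trees$group)
  })
  names(anovas) <- components()
  normality <- lapply(present, function(g) {
    sub <- trees[trees$group == g, ]
    shapiro_wilk(total_biomass(sub) - predict_total(surs[[g]]))
  })
  names(normality) <- present
  structure(list(trees = trees, selections = selections, sur = surs,
                 allocation = allocation_table(trees), anova = anovas,
                 normality = normality, alpha = alpha),
            class = "biomass_analysis")
}

#' @export
print.biomass_analysis <- function(x, ...) {
  cat("Additive biomass analysis:", nrow(x$trees), "trees,",
      length(x$sur), "age group(s)\n\n")
  cat("Mean allocation (fraction of total):\n")
  print(round(x$allocation, 3))
  cat("\nSelected models and SUR coefficients:\n")
  for (g in names(x$sur)) print(x$sur[[g]])
  cat("\nTotal-residual normality (Shapiro-Wilk p):",
      paste(sprintf("%s %.3f", names(x$normality),
                    vapply(x$normality, `[[`, numeric(1), "p")),
            collapse = ", "), "\n")
  invisible(x)
}

# flat per-model comparison rows for one group's selections
.selection_table <- function(selection_list, group) {
  do.call(rbind, lapply(components(), function(cm) {
    sel <- selection_list[[cm]]
    do.call(rbind, lapply(seq_along(sel$fits), function(i) {
      f <- sel$fits[[i]]
      co <- stats::setNames(rep(NA_real_, 4), c("a", "b", "c", "d"))
      st <- stats::setNames(rep("", 4), c("a", "b", "c", "d"))
      if (f$sigma2 == 0) {
        co[seq_len(f$k)] <- stats::coef(f)
        st[seq_len(f$k)] <- "*"
      } else {
        sig <- coefficient_significance(f, alpha = sel$alpha)
        co[seq_len(f$k)] <- sig$estimate
        st[seq_len(f$k)] <- ifelse(sig$significant, "*", "")
      }
      data.frame(group = group, component = cm, model = f$spec$id,
                 a = co[["a"]], b = co[["b"]], c = co[["c"]], d = co[["d"]],
                 sig_a = st[["a"]], sig_b = st[["b"]], sig_c = st[["c"]],
                 sig_d = st[["d"]],
                 r2 = sel$comparison$r2[i], mape = sel$comparison$mape[i],
                 chosen = f$spec$id == sel$chosen$spec$id,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Write the analysis report bundle
#'
#' Deterministically ordered CSV tables: one per-group candidate comparison
#' table (6 models x 4 components), one joint-system coefficient table
#' across groups, per-group predicted-vs-observed pairs for the four
#' components and the total, and per-group Q-Q pairs of the total
#' residuals.
#'
#' @param analysis A [run_biomass_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "biomass_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  for (g in names(analysis$selections)) {
    wr(.selection_table(analysis$selections[[g]], g),
       sprintf("selection_%s.csv", g))
  }
  sur_tab <- do.call(rbind, lapply(names(analysis$sur), function(g) {
    f <- analysis$sur[[g]]
    do.call(rbind, lapply(components(), function(cm) {
      b <- f$coefficients[[cm]]
      pad <- c(b, rep(NA_real_, 4 - length(b)))
      data.frame(group = g, component = cm, model = f$system[[cm]]$id,
                 a = pad[1], b = pad[2], c = pad[3], d = pad[4],
                 sigma2 = f$sigma2[[cm]], cf = f$cf[[cm]],
                 stringsAsFactors = FALSE)
    }))
  }))
  wr(sur_tab, "sur_coefficients.csv")
  for (g in names(analysis$sur)) {
    f <- analysis$sur[[g]]
    sub <- analysis$trees[analysis$trees$group == g, ]
    pred <- predict(f, type = "both")
    obs <- cbind(as.matrix(sub[, biomass_cols()]), total_biomass(sub))
    colnames(obs) <- components(include_total = TRUE)
    po <- data.frame(tree_id = sub$tree_id)
    for (cm in components(include_total = TRUE)) {
      po[[paste0("obs_", cm)]] <- obs[, cm]
      po[[paste0("pred_", cm)]] <- pred[, cm]
    }
    wr(po, sprintf("pred_vs_obs_%s.csv", g))
    wr(analysis$normality[[g]]$qq_pairs, sprintf("qq_total_%s.csv", g))
  }
  invisible(written)
}
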