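# Small in-code fixtures shared across test files.

# minimal valid tree table with independent lognormal predictors and
# biomasses; not meant to be allometrically realistic
make_trees <- function(n, seed = 1, group = "young") {
  set.seed(seed)
  data.frame(
    tree_id = seq_len(n),
    group = group,
    dbh_cm = exp(rnorm(n, log(10), 0.4)),
    height_m = exp(rnorm(n, log(12), 0.3)),
    crown_radius_m = exp(rnorm(n, log(3), 0.3)),
    w_trunk_kg = exp(rnorm(n, log(50), 0.5)),
    w_branch_kg = exp(rnorm(n, log(8), 0.5)),
    w_leaf_kg = exp(rnorm(n, log(5), 0.5)),
    w_root_kg = exp(rnorm(n, log(20), 0.5))
  )
}

# trees whose component biomasses follow exact log-linear laws (no noise)
make_noisefree_trees <- function(n, seed = 1,
                                 betas = list(
                                   trunk  = list(spec = "M2",
                                                 beta = c(-3.599, 2.274, 0.709)),
                                   branch = list(spec = "M3",
                                                 beta = c(-2.436, 1.123, 0.953)),
                                   leaf   = list(spec = "M3",
                                                 beta = c(-2.158, 1.211, 0.640)),
                                   root   = list(spec = "M5",
                                                 beta = c(-3.983, 0.771, 0.625))
                                 )) {
  tr <- make_trees(n, seed)
  for (cm in names(betas)) {
    sp <- allom_spec(betas[[cm]]$spec)
    X <- cbind(1, sapply(sp$terms, function(t) {
      switch(t,
        lnD = log(tr$dbh_cm), lnH = log(tr$height_m),
        lnCR = log(tr$crown_radius_m),
        lnD2H = 2 * log(tr$dbh_cm) + log(tr$height_m))
    }))
    col <- paste0("w_", cm, "_kg")
    tr[[col]] <- exp(drop(X %*% betas[[cm]]$beta))
  }
  tr
}

# independent least-squares oracle: explicit normal equations
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# independent iterated-FGLS oracle on the fully stacked system:
# dense 4n x sum(k) design with kronecker-product weighting
stacked_gls_oracle <- function(Xs, ys, tol = 1e-8, max_iter = 100) {
  m <- length(Xs)
  n <- nrow(Xs[[1]])
  ks <- vapply(Xs, ncol, integer(1))
  Xbig <- matrix(0, m * n, sum(ks))
  off <- c(0, cumsum(ks))
  for (i in seq_len(m)) {
    Xbig[((i - 1) * n + 1):(i * n), (off[i] + 1):off[i + 1]] <- Xs[[i]]
  }
  ybig <- unlist(ys, use.names = FALSE)
  beta <- numeric(sum(ks))
  for (i in seq_len(m)) {
    beta[(off[i] + 1):off[i + 1]] <- ols_oracle(Xs[[i]], ys[[i]])
  }
  for (it in seq_len(max_iter)) {
    E <- matrix(ybig - Xbig %*% beta, n, m)
    Sigma <- crossprod(E) / n
    W <- kronecker(solve(Sigma), diag(n))
    beta_new <- drop(solve(t(Xbig) %*% W %*% Xbig, t(Xbig) %*% W %*% ybig))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# brute-force one-way ANOVA sums of squares
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in lv) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- length(lv) - 1
  dfw <- length(values) - length(lv)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE))
}
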