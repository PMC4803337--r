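test_that("age-group assignment follows the class boundaries", {
  expect_equal(as.character(assign_age_group(c(1, 5, 5.5, 6, 15, 15.1, 40))),
               c("young", "young", "middle", "middle", "middle",
                 "mature", "mature"))
  expect_true(is.ordered(assign_age_group(3)))
  expect_equal(levels(assign_age_group(3)), c("young", "middle", "mature"))
  expect_error(assign_age_group(0), "positive")
  expect_error(assign_age_group(-2), "positive")
  expect_error(assign_age_group(5.5, strict = TRUE), "unassignable")
  expect_equal(as.character(assign_age_group(5, strict = TRUE)), "young")
})

test_that("dry weight is segment fresh weight times mean subsample ratio", {
  seg <- function(fresh, ratios) {
    list(fresh_kg = fresh,
         pairs = cbind(fresh_g = rep(500, length(ratios)),
                       dry_g = 500 * ratios))
  }
  expect_equal(compute_dry_weight(list(seg(100, c(1, 1, 1)))), 100)
  expect_equal(compute_dry_weight(list(seg(80, c(0.5, 0.5, 0.5)))), 40)
  expect_equal(compute_dry_weight(list(seg(60, rep(0.5, 3)),
                                       seg(30, rep(0.4, 3)),
                                       seg(10, rep(0.3, 3)))), 45)
  # homogeneous of degree 1 in fresh segment weights
  segs <- list(seg(60, c(0.4, 0.5)), seg(25, c(0.3, 0.35, 0.4)))
  scaled <- lapply(segs, function(s) { s$fresh_kg <- 3 * s$fresh_kg; s })
  expect_equal(compute_dry_weight(scaled), 3 * compute_dry_weight(segs))
  expect_error(compute_dry_weight(list(list(fresh_kg = 10,
                                            pairs = cbind(numeric(0),
                                                          numeric(0))))),
               "no subsample")
  expect_error(
    compute_dry_weight(list(list(fresh_kg = 10,
                                 pairs = cbind(500, 600)))),
    "exceeds fresh")
})

test_that("total biomass is the exact, permutation-invariant component sum", {
  tr <- make_trees(1)
  tr[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(12.388, 2.593, 2.958, 5.008)
  expect_equal(total_biomass(tr), 22.947)
  tr2 <- tr
  tr2[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(91.731, 11.208, 7.618, 29.106)
  expect_equal(total_biomass(tr2), 139.663)
  tr3 <- tr
  tr3[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(5.008, 12.388, 2.593, 2.958)
  expect_equal(total_biomass(tr3), total_biomass(tr))
  tr4 <- tr
  tr4[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(1, 1, 1, 1)
  expect_equal(total_biomass(tr4), 4)
})

test_that("allocation proportions lie on the simplex", {
  tr <- make_trees(1)
  tr[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(1, 1, 1, 1)
  expect_equal(drop(allocation_proportions(tr)),
               c(trunk = 0.25, branch = 0.25, leaf = 0.25, root = 0.25))
  tr[, c("w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")] <-
    list(12.388, 2.593, 2.958, 5.008)
  expect_equal(allocation_proportions(tr)[1, "trunk"], 12.388 / 22.947,
               tolerance = 1e-12, ignore_attr = TRUE)
  # property: random positive quadruples always sum to one
  set.seed(7)
  many <- make_trees(200, seed = 7)
  expect_true(all(abs(rowSums(allocation_proportions(many)) - 1) < 1e-12))
  # zero biomass violates the record invariant
  bad <- make_trees(1)
  bad$w_root_kg <- 0
  expect_error(allocation_proportions(bad), "non-positive")
})

test_that("CSV round trip preserves records and rejects invalid rows", {
  tr <- make_trees(3, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trees(tr, f)
  back <- read_trees(f)
  for (cn in c("dbh_cm", "height_m", "crown_radius_m",
               "w_trunk_kg", "w_branch_kg", "w_leaf_kg", "w_root_kg")) {
    expect_identical(back[[cn]], tr[[cn]])
  }
  expect_equal(as.character(back$group), as.character(tr$group))

  bad <- tr
  bad$dbh_cm[2] <- 0
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(transform(bad, group = as.character(group)), f2,
            row.names = FALSE)
  expect_error(read_trees(f2), "row.*2")

  nogrp <- tr
  nogrp$group <- NULL
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(nogrp, f3, row.names = FALSE)
  expect_error(read_trees(f3), "age_years.*group|group.*age_years")

  # group labels without ages are accepted verbatim
  expect_equal(as.character(read_trees(f)$group), rep("young", 3))

  # column mapping renames a non-standard header
  ren <- tr
  names(ren)[names(ren) == "dbh_cm"] <- "DBH"
  f4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(transform(ren, group = as.character(group)), f4,
            row.names = FALSE)
  expect_equal(read_trees(f4, column_map = c(dbh_cm = "DBH"))$dbh_cm,
               tr$dbh_cm)
  expect_error(read_trees(f4), "missing column")
})

test_that("group labels inconsistent with ages are rejected", {
  tr <- make_trees(2)
  tr$age_years <- c(3, 20)
  tr$group <- c("young", "young")
  expect_error(validate_trees(tr), "inconsistent")
  tr$group <- NULL
  expect_equal(as.character(validate_trees(tr)$group), c("young", "mature"))
})

test_that("group summaries use the sample-SD convention", {
  tr <- make_trees(2, seed = 3)
  tr$dbh_cm <- c(2, 4)
  s <- summarize_group(tr, "young")
  expect_equal(s["mean", "D"], 3)
  expect_equal(s["sd", "D"], sqrt(2))
  expect_equal(attr(s, "n"), 2)
  expect_true(all(s["min", ] <= s["mean", ] & s["mean", ] <= s["max", ]))

  same <- rbind(make_trees(1, seed = 5), make_trees(1, seed = 5))
  same$tree_id <- 1:2
  s2 <- summarize_group(same, "young")
  expect_true(all(s2["sd", ] == 0))

  expect_error(summarize_group(make_trees(1), "young"), "at least 2")
  expect_error(summarize_group(make_trees(3), "mature"), "at least 2")
})
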