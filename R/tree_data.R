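# Domain types and ingestion for destructively sampled tree records.
#
# A tree table is an ordinary data.frame with columns
#   tree_id, age_years (optional), group (young/middle/mature),
#   dbh_cm, height_m, crown_radius_m,
#   w_trunk_kg, w_branch_kg, w_leaf_kg, w_root_kg
# validated by validate_trees(). Total biomass is always derived, never stored.

#' Age-group levels, in developmental order
#'
#' @return Character vector `c("young", "middle", "mature")`.
#' @export
age_groups <- function() c("young", "middle", "mature")

#' Biomass component keys
#'
#' The four measured components plus the derived total.
#'
#' @param include_total Include `"total"` (derived, never an input column)?
#' @return Character vector of component names.
#' @export
components <- function(include_total = FALSE) {
  out <- c("trunk", "branch", "leaf", "root")
  if (include_total) c(out, "total") else out
}

# column names holding component dry masses, in canonical order
biomass_cols <- function() {
  c(trunk = "w_trunk_kg", branch = "w_branch_kg",
    leaf = "w_leaf_kg", root = "w_root_kg")
}

predictor_cols <- function() {
  c(D = "dbh_cm", H = "height_m", CR = "crown_radius_m")
}

#' Assign a stand-development age group from tree age
#'
#' Young stands are at most 5 years old, mature stands are older than
#' 15 years, and everything in between is middle-aged. The source class
#' definition leaves ages in (5, 6) formally unassigned; by default they are
#' folded into the middle class (continuity of its upper interval downward).
#' With `strict = TRUE` such ages are rejected instead.
#'
#' @param age_years Numeric vector of tree ages in years, all positive.
#' @param strict If `TRUE`, ages strictly between 5 and 6 are an error.
#' @return Factor with levels `young < middle < mature`.
#' @examples
#' assign_age_group(c(3, 5, 15, 16))
#' @export
assign_age_group <- function(age_years, strict = FALSE) {
  if (!is.numeric(age_years) || any(!is.finite(age_years)) ||
      any(age_years <= 0)) {
    stop("'age_years' must be finite and positive")
  }
  if (strict && any(age_years > 5 & age_years < 6)) {
    stop("ages in (5, 6) years are unassignable under strict class intervals")
  }
  lab <- ifelse(age_years <= 5, "young",
                ifelse(age_years <= 15, "middle", "mature"))
  factor(lab, levels = age_groups(), ordered = TRUE)
}

#' Dry weight of a component from fresh weights and subsample ratios
#'
#' Field protocol: each component (the trunk typically in three segments) is
#' weighed fresh in the field; small subsamples are weighed fresh and again
#' after oven-drying. The component dry mass is the sum over segments of the
#' segment fresh weight times that segment's mean subsample dry:fresh ratio.
#'
#' @param segments A list; each element is a list/record with
#'   `fresh_kg` (segment fresh weight, kg) and `pairs`, a two-column matrix
#'   or data.frame of subsample `(fresh_g, dry_g)` weights.
#' @return Component dry weight in kg.
#' @examples
#' compute_dry_weight(list(list(
#'   fresh_kg = 80,
#'   pairs = cbind(fresh_g = c(500, 500, 500), dry_g = c(250, 250, 250))
#' )))
#' @export
compute_dry_weight <- function(segments) {
  if (!is.list(segments) || length(segments) == 0) {
    stop("'segments' must be a non-empty list")
  }
  ratios_x_fresh <- vapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    pairs <- as.matrix(as.data.frame(seg$pairs))
    if (is.null(seg$fresh_kg) || length(seg$fresh_kg) != 1 ||
        !is.finite(seg$fresh_kg) || seg$fresh_kg <= 0) {
      stop(sprintf("segment %d: fresh weight must be a positive scalar", i))
    }
    if (nrow(pairs) == 0) {
      stop(sprintf("segment %d: no subsample fresh/dry pairs", i))
    }
    if (any(pairs <= 0)) {
      stop(sprintf("segment %d: subsample weights must be positive", i))
    }
    if (any(pairs[, 2] > pairs[, 1])) {
      stop(sprintf("segment %d: subsample dry weight exceeds fresh weight", i))
    }
    seg$fresh_kg * mean(pairs[, 2] / pairs[, 1])
  }, numeric(1))
  sum(ratios_x_fresh)
}

#' Total tree biomass
#'
#' The exact sum of the four component dry masses; the total is always
#' derived from components, never carried as its own measurement.
#'
#' @param trees Validated tree data.frame (see [validate_trees()]).
#' @return Numeric vector of per-tree total biomass, kg.
#' @export
total_biomass <- function(trees) {
  trees <- validate_trees(trees)
  rowSums(trees[, biomass_cols(), drop = FALSE])
}

#' Per-tree biomass allocation proportions
#'
#' Each component's share of the tree's total dry mass. Rows sum to 1 to
#' machine precision.
#'
#' @param trees Validated tree data.frame.
#' @return Numeric matrix, one row per tree, columns trunk/branch/leaf/root.
#' @export
allocation_proportions <- function(trees) {
  trees <- validate_trees(trees)
  w <- as.matrix(trees[, biomass_cols(), drop = FALSE])
  colnames(w) <- components()
  w / rowSums(w)
}

#' Validate a tree table
#'
#' Checks the column contract and per-row invariants: all of D, H, CR and
#' the four component biomasses strictly positive (their logarithms must
#' exist), a `group` column consistent with `age_years` where both are
#' present, and at least one of `age_years`/`group` supplied. A missing
#' `group` is filled from `age_years`.
#'
#' @param trees data.frame of tree records.
#' @param strict Passed to [assign_age_group()] for the (5, 6) year gap.
#' @return The validated data.frame with `group` as an ordered factor.
#' @export
validate_trees <- function(trees, strict = FALSE) {
  stopifnot(is.data.frame(trees))
  need <- c(predictor_cols(), biomass_cols())
  missing_cols <- setdiff(unname(need), names(trees))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("age_years" %in% names(trees)) && !("group" %in% names(trees))) {
    stop("at least one of 'age_years' or 'group' is required")
  }
  for (cn in unname(need)) {
    v <- trees[[cn]]
    if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", cn))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("column '%s': non-positive or missing value in row(s) %s",
                   cn, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if ("age_years" %in% names(trees)) {
    derived <- assign_age_group(trees$age_years, strict = strict)
    if ("group" %in% names(trees)) {
      given <- factor(as.character(trees$group), levels = age_groups(),
                      ordered = TRUE)
      if (anyNA(given)) {
        stop("column 'group': labels must be one of ",
             paste(age_groups(), collapse = "/"))
      }
      bad <- which(given != derived)
      if (length(bad)) {
        stop("group label inconsistent with age_years in row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      trees$group <- given
    } else {
      trees$group <- derived
    }
  } else {
    given <- factor(as.character(trees$group), levels = age_groups(),
                    ordered = TRUE)
    if (anyNA(given)) {
      stop("column 'group': labels must be one of ",
           paste(age_groups(), collapse = "/"))
    }
    trees$group <- given
  }
  if (!("tree_id" %in% names(trees))) trees$tree_id <- seq_len(nrow(trees))
  trees
}

#' Read tree records from CSV
#'
#' Expects a UTF-8, comma-separated file with a header carrying the column
#' contract of [validate_trees()] (a `column_map` can rename non-standard
#' headers). Rows violating the invariants abort with a row-indexed message.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping standard names
#'   to the file's header names, e.g. `c(dbh_cm = "DBH")`.
#' @param strict Passed to [validate_trees()].
#' @return Validated tree data.frame.
#' @export
read_trees <- function(path, column_map = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!(src %in% names(df))) stop("mapped column not in file: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  validate_trees(df, strict = strict)
}

#' Write tree records to CSV
#'
#' Inverse of [read_trees()]: plain comma-separated UTF-8 with `.` decimal
#' points, round-tripping all values representable in the dialect.
#'
#' @param trees Validated tree data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  trees <- validate_trees(trees)
  out <- trees
  out$group <- as.character(out$group)
  # 17 significant digits so doubles survive the text round trip exactly
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      out[[cn]] <- formatC(out[[cn]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Group summary of tree variables and component biomasses
#'
#' Per-variable mean, sample SD (n - 1 divisor), maximum and minimum for one
#' age group, in the layout of a stand-inventory summary table.
#'
#' @param trees Validated tree data.frame.
#' @param group One of `"young"`, `"middle"`, `"mature"`.
#' @return data.frame with rows Mean/SD/Max/Min and one column per variable
#'   (D, H, CR, trunk, branch, leaf, root), plus attribute `n`.
#' @export
summarize_group <- function(trees, group) {
  trees <- validate_trees(trees)
  group <- match.arg(group, age_groups())
  sub <- trees[trees$group == group, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop(sprintf("group '%s' has %d record(s); need at least 2 (SD undefined)",
                 group, nrow(sub)))
  }
  vars <- c(predictor_cols(), biomass_cols())
  m <- sapply(unname(vars), function(cn) {
    v <- sub[[cn]]
    c(mean = mean(v), sd = stats::sd(v), max = max(v), min = min(v))
  })
  colnames(m) <- names(vars)
  out <- as.data.frame(m)
  attr(out, "n") <- nrow(sub)
  attr(out, "group") <- group
  out
}

#' Summaries for every age group present
#'
#' @param trees Validated tree data.frame.
#' @return Named list of [summarize_group()] tables.
#' @export
summarize_groups <- function(trees) {
  trees <- validate_trees(trees)
  present <- age_groups()[age_groups() %in% as.character(unique(trees$group))]
  stats::setNames(lapply(present, function(g) summarize_group(trees, g)),
                  present)
}
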