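#' Per-sample collection of assigned molecular formulas
#'
#' A `formula_table` wraps a data.frame of formula records (element counts
#' plus intensity and optional observed m/z / ppm error) and carries all
#' derived columns: O/C, H/C, DBE, elemental class, van Krevelen compound
#' class and the CRAM flag. Duplicate formulas are collapsed to the
#' highest-intensity record (with a warning naming the collision count).
#'
#' @param records data.frame with columns `c,h,n,o,s,intensity` (optionally
#'   `mz_observed`, `mass_error_ppm`).
#' @param sample_id label for the sample.
#' @return object of class `formula_table`: the record data.frame with
#'   derived columns, plus attributes `sample_id` and `total_intensity`.
#' @export
formula_table <- function(records, sample_id = "sample") {
  validate_formula(records)
  if (is.null(records$intensity)) stop("records need an 'intensity' column", call. = FALSE)
  if (any(records$intensity < 0) || any(!is.finite(records$intensity))) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  key <- format_formula(records)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(sprintf("formula_table '%s': %d duplicate formula(s) collapsed to highest intensity",
                    sample_id, n_dup), call. = FALSE)
    ord <- order(key, -records$intensity)
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(key[ord]), , drop = FALSE]
    key <- format_formula(records)
  }
  records$formula <- key
  records$oc <- records$o / records$c
  records$hc <- records$h / records$c
  records$dbe <- dbe(records)
  records$elemental_class <- elemental_class(records)
  records$compound_class <- compound_class(records)
  records$is_cram <- is_cram(records)
  rownames(records) <- NULL
  structure(records,
            sample_id = sample_id,
            total_intensity = sum(records$intensity),
            class = c("formula_table", "data.frame"))
}

#' @export
print.formula_table <- function(x, ...) {
  cat(sprintf("formula_table '%s': %d formulas, total intensity %.4g\n",
              attr(x, "sample_id"), nrow(x), attr(x, "total_intensity")))
  cls <- class_profile(x, weighting = "count")
  top <- sort(cls[cls > 0], decreasing = TRUE)
  cat("  count profile (%):",
      paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

stopifnot_formula_table <- function(x) {
  if (!inherits(x, "formula_table")) stop("expected a formula_table", call. = FALSE)
  if (nrow(x) == 0) stop("formula_table is empty", call. = FALSE)
  invisible(x)
}

#' Compound-class profile of a formula table
#'
#' Fractions (in percent) of each of the seven van Krevelen classes plus
#' "unclassified", by formula count or by summed intensity; the profile
#' always sums to 100.
#'
#' @param table a [formula_table()].
#' @param weighting `"count"` or `"intensity"`.
#' @return named numeric vector of percentages over [compound_class_levels()].
#' @export
class_profile <- function(table, weighting = c("count", "intensity")) {
  stopifnot_formula_table(table)
  weighting <- match.arg(weighting)
  lv <- compound_class_levels()
  cls <- factor(table$compound_class, levels = lv)
  w <- if (weighting == "count") rep(1, nrow(table)) else table$intensity
  tot <- sum(w)
  if (tot <= 0) stop("total weight is zero; cannot form a profile", call. = FALSE)
  sums <- tapply(w, cls, sum, default = 0)
  stats::setNames(100 * as.numeric(sums) / tot, lv)
}

#' Jaccard similarity between two formula sets
#'
#' Two variants: `as_printed` computes Jsi = c / (a + b), where c is the
#' number of formulas common to both samples and a, b are the set sizes
#' (maximum attainable value 0.5); `conventional` computes the usual
#' c / (a + b - c). The `as_printed` form is the default.
#'
#' @param tableA,tableB [formula_table()] objects.
#' @param variant `"as_printed"` or `"conventional"`.
#' @return similarity in [0, 1] (in [0, 0.5] for `as_printed`).
#' @export
jaccard_similarity <- function(tableA, tableB,
                               variant = c("as_printed", "conventional")) {
  stopifnot_formula_table(tableA)
  stopifnot_formula_table(tableB)
  variant <- match.arg(variant)
  a <- nrow(tableA)
  b <- nrow(tableB)
  cc <- length(intersect(tableA$formula, tableB$formula))
  if (variant == "as_printed") cc / (a + b) else cc / (a + b - cc)
}

#' Shared and table-unique formula sets across samples
#'
#' @param tables list of [formula_table()] objects (>= 2).
#' @return list with `shared` (formulas present in every table), `unique`
#'   (per-table list of formulas absent from every other table), and
#'   `class_counts` (per-class counts of the shared set and each unique set).
#' @export
shared_unique <- function(tables) {
  if (length(tables) < 2) stop("need at least two tables", call. = FALSE)
  lapply(tables, stopifnot_formula_table)
  keys <- lapply(tables, function(t) t$formula)
  shared <- Reduce(intersect, keys)
  uniq <- lapply(seq_along(keys), function(i) {
    others <- unique(unlist(keys[-i]))
    setdiff(keys[[i]], others)
  })
  names(uniq) <- vapply(tables, attr, "", which = "sample_id")
  count_classes <- function(k) {
    if (length(k) == 0) {
      stats::setNames(integer(length(compound_class_levels())), compound_class_levels())
    } else {
      cls <- compound_class(parse_formula(k))
      table(factor(cls, levels = compound_class_levels())) |> c()
    }
  }
  list(shared = shared,
       unique = uniq,
       class_counts = c(list(shared = count_classes(shared)),
                        lapply(uniq, count_classes)))
}

#' Molecule fate between two incubation time points
#'
#' Labels every formula seen at either time point as `produced` (absent at
#' t0, or relative intensity up by at least `fold_threshold`), `consumed`
#' (the mirror case) or `resistant`, and reports the per-class change of
#' intensity-weighted class share in percentage points (sums to 0 across
#' classes).
#'
#' @param t0,t_end [formula_table()] objects at the two time points.
#' @param fold_threshold fold change of within-sample relative intensity
#'   that promotes a persisting formula to produced/consumed (default 2).
#' @return object of class `fate_table`: data.frame with columns `formula`,
#'   `compound_class`, `is_cram`, `rel_t0`, `rel_end`, `fate`; attribute
#'   `class_change` holds the per-class share changes.
#' @export
molecule_fate <- function(t0, t_end, fold_threshold = 2.0) {
  stopifnot_formula_table(t0)
  stopifnot_formula_table(t_end)
  if (fold_threshold < 1) stop("fold_threshold must be >= 1", call. = FALSE)
  rel0 <- stats::setNames(t0$intensity / attr(t0, "total_intensity"), t0$formula)
  rel1 <- stats::setNames(t_end$intensity / attr(t_end, "total_intensity"), t_end$formula)
  keys <- union(t0$formula, t_end$formula)
  r0 <- rel0[keys]; r0[is.na(r0)] <- 0
  r1 <- rel1[keys]; r1[is.na(r1)] <- 0
  fate <- rep("resistant", length(keys))
  fate[r0 == 0 & r1 > 0] <- "produced"
  fate[r1 == 0 & r0 > 0] <- "consumed"
  both <- r0 > 0 & r1 > 0
  fate[both & r1 >= fold_threshold * r0 & fold_threshold > 1] <- "produced"
  fate[both & r0 >= fold_threshold * r1 & fold_threshold > 1] <- "consumed"
  f <- parse_formula(keys)
  out <- data.frame(formula = keys,
                    compound_class = compound_class(f),
                    is_cram = is_cram(f),
                    rel_t0 = unname(r0), rel_end = unname(r1),
                    fate = fate, stringsAsFactors = FALSE)
  change <- class_profile(t_end, "intensity") - class_profile(t0, "intensity")
  structure(out, class_change = change, class = c("fate_table", "data.frame"))
}

#' @export
print.fate_table <- function(x, ...) {
  cat(sprintf("fate_table: %d formulas (%d consumed, %d produced, %d resistant)\n",
              nrow(x), sum(x$fate == "consumed"), sum(x$fate == "produced"),
              sum(x$fate == "resistant")))
  ch <- attr(x, "class_change")
  cat("  class share change (pp):",
      paste(sprintf("%s %+0.2f", names(ch), ch), collapse = ", "), "\n")
  invisible(x)
}
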