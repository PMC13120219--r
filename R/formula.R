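#' Monoisotopic atomic masses (Da)
#'
#' Masses used throughout the package for neutral-mass computation:
#' C 12 (exact), H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117.
#' @keywords internal
ATOMIC_MASS <- c(
  c = 12.0,
  h = 1.00782503,
  n = 14.00307401,
  o = 15.99491462,
  s = 31.97207117
)

#' Mass of a proton (Da), for [M-H]- de/reprotonation
#' @keywords internal
PROTON_MASS <- 1.007276466

ELEMENTS <- c("c", "h", "n", "o", "s")

#' Construct a table of molecular formulas
#'
#' A molecular formula in this package is a row of integer element counts
#' over C, H, N, O, S. All formula-level operations ([dbe()],
#' [neutral_mass()], [elemental_class()], [compound_class()], [is_cram()])
#' are vectorised over such tables.
#'
#' @param c,h,n,o,s integer element counts (recycled to common length).
#'   Carbon must be >= 1; all others >= 0.
#' @return a `data.frame` with columns `c,h,n,o,s`.
#' @examples
#' molecular_formula(c = 6, h = 12, o = 6) # glucose
#' @export
molecular_formula <- function(c, h, n = 0, o = 0, s = 0) {
  df <- data.frame(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                   o = as.integer(o), s = as.integer(s))
  validate_formula(df)
  df
}

validate_formula <- function(df) {
  if (!all(ELEMENTS %in% names(df))) {
    stop("formula table must have columns c,h,n,o,s", call. = FALSE)
  }
  for (el in ELEMENTS) {
    x <- df[[el]]
    if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
      stop(sprintf("element counts must be nonnegative integers (column '%s')", el),
           call. = FALSE)
    }
  }
  if (any(df$c < 1)) stop("carbon count must be >= 1", call. = FALSE)
  invisible(df)
}

#' Parse formula strings like "C16H20O8"
#'
#' Case-sensitive Hill-style parser restricted to C, H, N, O, S.
#'
#' @param x character vector of formula strings.
#' @return data.frame of element counts (see [molecular_formula()]).
#' @export
parse_formula <- function(x) {
  parse_one <- function(s) {
    counts <- c(c = 0L, h = 0L, n = 0L, o = 0L, s = 0L)
    m <- gregexpr("([CHNOS])([0-9]*)", s)[[1]]
    if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(s)) {
      stop(sprintf("cannot parse formula string '%s'", s), call. = FALSE)
    }
    pieces <- regmatches(s, list(m))[[1]]
    for (p in pieces) {
      el <- tolower(substr(p, 1, 1))
      ct <- substr(p, 2, nchar(p))
      counts[el] <- counts[el] + if (nzchar(ct)) as.integer(ct) else 1L
    }
    counts
  }
  out <- t(vapply(x, parse_one, integer(5)))
  df <- as.data.frame(out)
  rownames(df) <- NULL
  validate_formula(df)
  df
}

#' Format formulas back to strings
#' @param df formula table.
#' @return character vector, e.g. "C16H20O8" (elements in C,H,N,O,S order,
#'   zero counts omitted, count 1 written explicitly as in "N1"? no - omitted).
#' @export
format_formula <- function(df) {
  validate_formula(df)
  out <- character(nrow(df))
  sym <- c(c = "C", h = "H", n = "N", o = "O", s = "S")
  for (el in ELEMENTS) {
    ct <- df[[el]]
    piece <- ifelse(ct == 0, "",
                    ifelse(ct == 1, sym[el], paste0(sym[el], ct)))
    out <- paste0(out, piece)
  }
  out
}

#' Double-bond equivalents
#'
#' DBE = 1 + C - H/2 + N/2 with the usual valences (C=4, H=1, N=3); divalent
#' O and S contribute nothing. May be negative for impossible formulas;
#' callers filter.
#'
#' @param formula a formula table (columns c,h,n,o,s).
#' @return numeric vector of DBE values.
#' @examples
#' dbe(parse_formula("C6H12O6")) # 1
#' @export
dbe <- function(formula) {
  validate_formula(formula)
  1 + formula$c - formula$h / 2 + formula$n / 2
}

#' Neutral monoisotopic mass (Da)
#'
#' @param formula a formula table.
#' @return numeric vector of neutral monoisotopic masses.
#' @examples
#' neutral_mass(parse_formula("C6H12O6")) # 180.06339
#' @export
neutral_mass <- function(formula) {
  validate_formula(formula)
  as.numeric(as.matrix(formula[ELEMENTS]) %*% ATOMIC_MASS[ELEMENTS])
}

#' Elemental (heteroatom) class
#'
#' Classes formulas as CHO / CHON / CHOS / CHONS by the presence of N and S.
#' Oxygen-free formulas are still classed by their N/S content.
#'
#' @param formula a formula table.
#' @return character vector in {CHO, CHON, CHOS, CHONS}.
#' @export
elemental_class <- function(formula) {
  validate_formula(formula)
  has_n <- formula$n > 0
  has_s <- formula$s > 0
  out <- rep("CHO", nrow(formula))
  out[has_n & !has_s] <- "CHON"
  out[!has_n & has_s] <- "CHOS"
  out[has_n & has_s] <- "CHONS"
  out
}

#' van Krevelen compound-class windows
#'
#' The seven (O/C, H/C) windows evaluated in order; each bound pair is a
#' half-open interval [lower, upper) so adjacent windows never double-claim
#' a point. First match wins; points outside every window are "unclassified".
#' @return data.frame of class names and window bounds in evaluation order.
#' @export
compound_class_windows <- function() {
  data.frame(
    class  = c("lipids", "proteins", "lignins", "carbohydrates",
               "unsaturated hydrocarbons", "condensed aromatics", "tannins"),
    oc_lo  = c(0,    0.3,  0.3,  0.67, 0,    0,    0.67),
    oc_hi  = c(0.3,  0.67, 0.67, 1.2,  0.3,  0.67, 1.0),
    hc_lo  = c(1.5,  1.5,  0.7,  1.5,  0.7,  0.2,  0.5),
    hc_hi  = c(2.0,  2.2,  1.5,  2.4,  1.5,  0.7,  1.5),
    stringsAsFactors = FALSE
  )
}

#' All compound-class labels (seven windows + unclassified)
#' @export
compound_class_levels <- function() {
  c(compound_class_windows()$class, "unclassified")
}

#' Classify (O/C, H/C) points into van Krevelen compound classes
#'
#' @param oc,hc numeric vectors of O/C and H/C atomic ratios.
#' @return character vector of class labels.
#' @export
classify_vk <- function(oc, hc) {
  w <- compound_class_windows()
  out <- rep("unclassified", length(oc))
  claimed <- rep(FALSE, length(oc))
  for (i in seq_len(nrow(w))) {
    hit <- !claimed & oc >= w$oc_lo[i] & oc < w$oc_hi[i] &
      hc >= w$hc_lo[i] & hc < w$hc_hi[i]
    out[hit] <- w$class[i]
    claimed <- claimed | hit
  }
  out
}

#' van Krevelen compound class of molecular formulas
#'
#' @param formula a formula table.
#' @return character vector of class labels (see [compound_class_levels()]).
#' @examples
#' compound_class(parse_formula(c("C6H12O6", "C10H12O6", "C16H10")))
#' @export
compound_class <- function(formula) {
  validate_formula(formula)
  classify_vk(formula$o / formula$c, formula$h / formula$c)
}

#' Carboxylic-acid-rich alicyclic molecule (CRAM) test
#'
#' A formula is a CRAM when all three ratio windows hold strictly:
#' 0.3 < DBE/C < 0.68, 0.2 < DBE/H < 0.95, 0.77 < DBE/O < 1.75.
#' Formulas with H = 0 or O = 0 are never CRAM (ratio undefined).
#'
#' @param formula a formula table.
#' @return logical vector.
#' @export
is_cram <- function(formula) {
  validate_formula(formula)
  d <- dbe(formula)
  ok <- formula$h > 0 & formula$o > 0
  rc <- d / formula$c
  rh <- ifelse(formula$h > 0, d / formula$h, NA_real_)
  ro <- ifelse(formula$o > 0, d / formula$o, NA_real_)
  out <- ok &
    rc > 0.3 & rc < 0.68 &
    rh > 0.2 & rh < 0.95 &
    ro > 0.77 & ro < 1.75
  out[is.na(out)] <- FALSE
  out
}
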