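#' Configuration for molecular-formula assignment
#'
#' Settings for enumerating candidate CHNOS formulas against [M-H]- peaks.
#' Defaults reflect common practice for dissolved organic matter in negative
#' electrospray: <= 1 ppm mass tolerance, C 1-60, H 1-120, N 0-3, O 0-30,
#' S 0-2, plausibility windows H/C in [0.2, 2.5] and O/C in [0, 1.2], and a
#' nonnegative integer DBE for the neutral (even-electron) molecule.
#'
#' @param tolerance_ppm maximum |mass error| in ppm (> 0).
#' @param c_range,h_range,n_range,o_range,s_range integer c(min, max) bounds.
#' @param hc_window,oc_window plausibility ratio windows c(lo, hi), inclusive.
#' @param dbe_o_max maximum DBE - O (default 10, a common plausibility rule
#'   for natural organic matter that rejects implausibly condensed
#'   oxygen-poor candidates at high mass; set to Inf to disable).
#' @param max_heteroatoms cap on N + S combined (default 3): formulas with
#'   both N and S near their individual maxima are vanishingly rare in lake
#'   DOM (CHONS is the least abundant elemental class) but are frequent
#'   false candidates at high mass; set to Inf to disable.
#' @param mz_range acquisition m/z range in Da.
#' @param ion_mode only "negative" ([M-H]-) is supported.
#' @return object of class `assignment_config`.
#' @export
assignment_config <- function(tolerance_ppm = 1.0,
                              c_range = c(1L, 60L),
                              h_range = c(1L, 120L),
                              n_range = c(0L, 3L),
                              o_range = c(0L, 30L),
                              s_range = c(0L, 2L),
                              hc_window = c(0.2, 2.5),
                              oc_window = c(0, 1.2),
                              dbe_o_max = 10,
                              max_heteroatoms = 3,
                              mz_range = c(100, 1600),
                              ion_mode = "negative") {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)
  ion_mode <- match.arg(ion_mode, "negative")
  cfg <- list(tolerance_ppm = tolerance_ppm,
              c_range = as.integer(c_range), h_range = as.integer(h_range),
              n_range = as.integer(n_range), o_range = as.integer(o_range),
              s_range = as.integer(s_range),
              hc_window = hc_window, oc_window = oc_window,
              dbe_o_max = dbe_o_max, max_heteroatoms = max_heteroatoms,
              mz_range = mz_range, ion_mode = ion_mode,
              proton_mass = PROTON_MASS)
  # pre-enumerate the (c, n, o, s) lattice once; h is solved per peak
  grid <- expand.grid(c = seq(cfg$c_range[1], cfg$c_range[2]),
                      n = seq(cfg$n_range[1], cfg$n_range[2]),
                      o = seq(cfg$o_range[1], cfg$o_range[2]),
                      s = seq(cfg$s_range[1], cfg$s_range[2]))
  grid <- grid[grid$n + grid$s <= cfg$max_heteroatoms, , drop = FALSE]
  grid$base_mass <- grid$c * ATOMIC_MASS["c"] + grid$n * ATOMIC_MASS["n"] +
    grid$o * ATOMIC_MASS["o"] + grid$s * ATOMIC_MASS["s"]
  cfg$grid <- grid
  structure(cfg, class = "assignment_config")
}

#' Assign candidate molecular formulas to one peak
#'
#' Enumerates CHNOS formulas within the configured element bounds whose
#' neutral monoisotopic mass matches `mz + proton mass` (negative-ion
#' [M-H]-) within the ppm tolerance, then filters by the H/C and O/C
#' plausibility windows and by a nonnegative integer DBE. Candidates are
#' ranked by |mass error| (ties: fewer heteroatoms N+S, then formula string).
#'
#' @param mz observed mass-to-charge (Da); must lie in `config$mz_range`.
#' @param config an [assignment_config()].
#' @return data.frame with columns `c,h,n,o,s,formula,neutral_mass,
#'   mass_error_ppm,dbe`; zero rows when nothing matches.
#' @examples
#' cfg <- assignment_config()
#' assign_formulas(179.05611, cfg) # glucose as [M-H]-
#' @export
assign_formulas <- function(mz, config = assignment_config()) {
  if (!inherits(config, "assignment_config")) stop("config must be an assignment_config", call. = FALSE)
  if (length(mz) != 1 || !is.finite(mz)) stop("mz must be a single finite number", call. = FALSE)
  if (mz < config$mz_range[1] || mz > config$mz_range[2]) {
    stop(sprintf("mz %.5f outside acquisition range [%g, %g]",
                 mz, config$mz_range[1], config$mz_range[2]), call. = FALSE)
  }
  target <- mz + config$proton_mass # neutral monoisotopic mass
  g <- config$grid
  tol_da <- target * config$tolerance_ppm * 1e-6
  h_float <- (target - g$base_mass) / ATOMIC_MASS["h"]
  # candidate integer H counts adjacent to the exact solution
  hits <- list()
  for (h_cand in c("floor", "ceiling")) {
    h <- if (h_cand == "floor") floor(h_float) else ceiling(h_float)
    mass <- g$base_mass + h * ATOMIC_MASS["h"]
    keep <- h >= config$h_range[1] & h <= config$h_range[2] &
      abs(mass - target) <= tol_da
    if (any(keep)) {
      hits[[h_cand]] <- data.frame(c = g$c[keep], h = h[keep], n = g$n[keep],
                                   o = g$o[keep], s = g$s[keep],
                                   neutral_mass = mass[keep])
    }
  }
  cand <- do.call(rbind, hits)
  if (is.null(cand) || nrow(cand) == 0) return(empty_assignment())
  cand <- unique(cand)
  hc <- cand$h / cand$c
  oc <- cand$o / cand$c
  d <- 1 + cand$c - cand$h / 2 + cand$n / 2
  keep <- hc >= config$hc_window[1] & hc <= config$hc_window[2] &
    oc >= config$oc_window[1] & oc <= config$oc_window[2] &
    d >= 0 & d == round(d) & (d - cand$o) <= config$dbe_o_max
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_assignment())
  cand$formula <- format_formula(cand)
  cand$mass_error_ppm <- (cand$neutral_mass - target) / target * 1e6
  cand$dbe <- 1 + cand$c - cand$h / 2 + cand$n / 2
  ord <- order(abs(cand$mass_error_ppm), cand$n + cand$s, cand$formula)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("c", "h", "n", "o", "s", "formula", "neutral_mass",
           "mass_error_ppm", "dbe")]
}

empty_assignment <- function() {
  data.frame(c = integer(), h = integer(), n = integer(), o = integer(),
             s = integer(), formula = character(), neutral_mass = numeric(),
             mass_error_ppm = numeric(), dbe = numeric())
}

#' Annotate a whole peak list with its top-ranked formulas
#'
#' Runs [assign_formulas()] on every peak and keeps the rank-1 candidate;
#' peaks with no candidate are dropped.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param config an [assignment_config()].
#' @param sample_id label for the resulting table.
#' @return a [formula_table()] with `mz_observed` and `mass_error_ppm` kept.
#' @export
annotate_peaks <- function(peaks, config = assignment_config(),
                           sample_id = "sample") {
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    stop("peaks need columns 'mz' and 'intensity'", call. = FALSE)
  }
  in_range <- peaks$mz >= config$mz_range[1] & peaks$mz <= config$mz_range[2]
  if (!all(in_range)) {
    warning(sprintf("%d peak(s) outside the acquisition range dropped",
                    sum(!in_range)), call. = FALSE)
    peaks <- peaks[in_range, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- assign_formulas(peaks$mz[i], config)
    if (nrow(cand) == 0) return(NULL)
    top <- cand[1, , drop = FALSE]
    data.frame(c = top$c, h = top$h, n = top$n, o = top$o, s = top$s,
               intensity = peaks$intensity[i],
               mz_observed = peaks$mz[i],
               mass_error_ppm = top$mass_error_ppm)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no peak could be assigned a formula", call. = FALSE)
  }
  formula_table(rows, sample_id = sample_id)
}
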