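#' Fast nonnegative least squares on normal equations
#'
#' Solves min ||Z b - x||^2 s.t. b >= 0 given G = Z'Z and m = Z'x, by the
#' active-set method of Bro & de Jong. Problem sizes here are tiny
#' (k <= 7 components), so the active set converges in a handful of steps.
#' @keywords internal
fnnls <- function(G, m, eps = 1e-12) {
  k <- length(m)
  passive <- rep(FALSE, k)
  b <- numeric(k)
  w <- m - G %*% b
  iter <- 0
  while (any(!passive & w > eps) && iter < 30 * k) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      p <- which(passive)
      s[p] <- tryCatch(solve(G[p, p, drop = FALSE], m[p]),
                       error = function(e) rep(0, length(p)))
      if (all(s[p] > eps)) { b <- s; break }
      neg <- p[s[p] <= eps]
      alpha <- min(b[neg] / (b[neg] - s[neg] + 1e-300))
      b <- b + alpha * (s - b)
      passive[b <= eps] <- FALSE
      b[!passive] <- 0
      if (!any(passive)) break
    }
    w <- m - G %*% b
  }
  b
}

khatri_rao <- function(A, B) {
  # column-wise Kronecker: rows of B vary fastest
  k <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), k)
  for (r in seq_len(k)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# solve F = argmin ||X_(n) - F Z'||^2, F >= 0 row-wise, given M = X_(n) Z
# and G = Z'Z. Fast path is the unconstrained solution; rows with negative
# entries are re-solved in groups sharing a passive-set pattern
# (Van Benthem & Keenan style), with KKT verification and a per-row
# active-set fallback for anything left over.
nnls_update <- function(M, G, eps = 1e-12) {
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(Ginv)) { # rank-deficient G: do everything row-wise
    out <- t(apply(M, 1, function(m) fnnls(G, m)))
    return(out)
  }
  Fmat <- M %*% Ginv
  bad <- which(rowSums(Fmat < 0) > 0)
  if (!length(bad)) return(Fmat)
  k <- ncol(M)
  Msub <- M[bad, , drop = FALSE]
  Xsub <- pmax(Fmat[bad, , drop = FALSE], 0)
  P <- Fmat[bad, , drop = FALSE] > 0
  unresolved <- seq_along(bad)
  for (pass in seq_len(10 * k)) {
    if (!length(unresolved)) break
    pat <- apply(P[unresolved, , drop = FALSE], 1, paste, collapse = "")
    for (pp in unique(pat)) {
      rows <- unresolved[pat == pp]
      p <- P[rows[1], ]
      X <- matrix(0, length(rows), k)
      if (any(p)) {
        sol <- tryCatch(
          Msub[rows, p, drop = FALSE] %*%
            chol2inv(chol(G[p, p, drop = FALSE])),
          error = function(e) NULL)
        if (is.null(sol)) {
          for (r in rows) Xsub[r, ] <- fnnls(G, Msub[r, ])
          unresolved <- setdiff(unresolved, rows)
          next
        }
        X[, p] <- sol
      }
      Xsub[rows, ] <- X
    }
    # clamp passive negatives
    negs <- P & Xsub < -eps
    has_neg <- rowSums(negs[unresolved, , drop = FALSE]) > 0
    P[unresolved[has_neg], ] <- P[unresolved[has_neg], , drop = FALSE] &
      !negs[unresolved[has_neg], , drop = FALSE]
    Xsub[negs] <- 0
    still <- unresolved[has_neg]
    done_rows <- setdiff(unresolved, still)
    if (length(done_rows)) {
      # KKT: gradient on active entries must be <= 0
      W <- Msub[done_rows, , drop = FALSE] -
        Xsub[done_rows, , drop = FALSE] %*% G
      viol <- !P[done_rows, , drop = FALSE] & W > eps * (1 + abs(Msub[done_rows, , drop = FALSE]))
      bad_kkt <- rowSums(viol) > 0
      if (any(bad_kkt)) {
        idx <- done_rows[bad_kkt]
        # admit the most violating variable and iterate again
        for (r in idx) {
          j <- which.max(ifelse(P[r, ], -Inf, Msub[r, ] - Xsub[r, ] %*% G))
          P[r, j] <- TRUE
        }
        still <- c(still, idx)
      }
    }
    unresolved <- still
  }
  # anything not settled: exact per-row fallback
  for (r in unresolved) Xsub[r, ] <- fnnls(G, Msub[r, ])
  Xsub[Xsub < 0] <- 0
  Fmat[bad, ] <- Xsub
  Fmat
}

#' Nonnegative PARAFAC by alternating least squares
#'
#' Decomposes an EEM stack (samples x emission x excitation tensor) into
#' `k` trilinear components with nonnegativity on all three modes. Each
#' mode update solves exact nonnegative least-squares subproblems, so the
#' reconstruction error is nonincreasing across iterations. The best of
#' `n_starts` seeded random initialisations is returned; emission and
#' excitation loadings are normalised to unit Euclidean norm (magnitude in
#' the sample scores) and components are sorted by total score.
#'
#' @param stack an [eem_stack()] (preprocessed; see [preprocess_eem()]).
#' @param k number of components (the 2-7 range is standard; values outside
#'   it draw a warning).
#' @param n_starts random initialisations (default 10).
#' @param tol relative change of fit error that stops a run (default 1e-8).
#' @param max_iter iteration cap per run (default 2500).
#' @param seed integer seed (required).
#' @return object of class `parafac_model`: list with `k`, `scores`
#'   (samples x k), `em_loadings`, `ex_loadings` (grid x k, unit norm),
#'   `fit_error` (relative residual sum of squares), `n_iter`, `error_trace`,
#'   `ex_grid`, `em_grid`, `sample_ids`, `seed`.
#' @export
parafac_als <- function(stack, k, n_starts = 10, tol = 1e-8, max_iter = 2500,
                        seed) {
  stopifnot(inherits(stack, "eem_stack"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (k < 2 || k > 7) warning("k outside the usual 2-7 component range")
  dims <- dim(stack$data)
  S <- dims[1]; E <- dims[2]; Xn <- dims[3]
  if (S < 2 * k) warning(sprintf("only %d samples for %d components; model may not be identifiable", S, k))
  X <- stack$data
  normX2 <- sum(X^2)
  if (normX2 == 0) stop("stack is all zero", call. = FALSE)
  # mode unfoldings, computed once
  X1 <- matrix(X, S, E * Xn)                       # cols: (em, ex), em fastest
  X2 <- matrix(aperm(X, c(2, 1, 3)), E, S * Xn)    # cols: (sample, ex)
  X3 <- matrix(aperm(X, c(3, 1, 2)), Xn, S * E)    # cols: (sample, em)

  set.seed(as.integer(seed))
  best <- NULL
  for (start in seq_len(n_starts)) {
    B <- matrix(stats::runif(E * k, 0.1, 1), E, k)
    C <- matrix(stats::runif(Xn * k, 0.1, 1), Xn, k)
    A <- matrix(0, S, k)
    err_prev <- Inf
    trace <- numeric(0)
    n_iter <- 0
    for (it in seq_len(max_iter)) {
      n_iter <- it
      BtB <- crossprod(B); CtC <- crossprod(C)
      A <- nnls_update(X1 %*% khatri_rao(C, B), BtB * CtC)
      AtA <- crossprod(A)
      B <- nnls_update(X2 %*% khatri_rao(C, A), AtA * CtC)
      BtB <- crossprod(B)
      M3 <- X3 %*% khatri_rao(B, A)
      C <- nnls_update(M3, AtA * BtB)
      ssr <- normX2 - 2 * sum(C * M3) + sum((AtA * BtB) * crossprod(C))
      err <- max(ssr, 0) / normX2
      trace <- c(trace, err)
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err_prev, 1e-300)) {
        err_prev <- err
        break
      }
      err_prev <- err
    }
    if (is.null(best) || err_prev < best$fit_error) {
      best <- list(A = A, B = B, C = C, fit_error = err_prev,
                   n_iter = n_iter, error_trace = trace)
    }
  }
  # normalise: unit-norm spectral loadings, magnitude in scores
  A <- best$A; B <- best$B; C <- best$C
  for (r in seq_len(k)) {
    nb <- sqrt(sum(B[, r]^2)); nc <- sqrt(sum(C[, r]^2))
    if (nb > 0) B[, r] <- B[, r] / nb
    if (nc > 0) C[, r] <- C[, r] / nc
    A[, r] <- A[, r] * nb * nc
  }
  ord <- order(colSums(A), decreasing = TRUE)
  structure(list(k = k, scores = A[, ord, drop = FALSE],
                 em_loadings = B[, ord, drop = FALSE],
                 ex_loadings = C[, ord, drop = FALSE],
                 fit_error = best$fit_error, n_iter = best$n_iter,
                 error_trace = best$error_trace,
                 ex_grid = stack$ex_grid, em_grid = stack$em_grid,
                 sample_ids = stack$sample_ids, seed = seed),
            class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("PARAFAC model: %d components, fit error %.3g (%d iterations)\n",
              x$k, x$fit_error, x$n_iter))
  for (r in seq_len(x$k)) {
    cat(sprintf("  comp %d: Ex max %d nm / Em max %d nm\n", r,
                x$ex_grid[which.max(x$ex_loadings[, r])],
                x$em_grid[which.max(x$em_loadings[, r])]))
  }
  invisible(x)
}

#' Tucker congruence coefficient between two loading vectors
#'
#' dot(u, v) / (||u|| ||v||); comparisons elsewhere use its absolute value.
#'
#' @param u,v equal-length numeric vectors with nonzero norm.
#' @return coefficient in [-1, 1].
#' @export
tucker_congruence <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm input", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# greedy one-to-one assignment maximising `score[i, j]`
greedy_match <- function(score) {
  n <- min(nrow(score), ncol(score))
  pairs <- matrix(NA_integer_, n, 2)
  s <- score
  for (step in seq_len(n)) {
    idx <- arrayInd(which.max(s), dim(s))
    pairs[step, ] <- idx
    s[idx[1], ] <- -Inf
    s[, idx[2]] <- -Inf
  }
  pairs
}

# Overfactored trilinear models commonly split one true component into two
# whose spectra divide the original's peaks but whose sample scores are the
# same vector (the split parts always co-occur). Such a pair carries no
# independent concentration information, so the model is rejected as
# degenerate. Centred correlation of score vectors separates this cleanly:
# a split pair correlates near 1, while independently varying components
# correlate near 0 (raw cosines of all-positive score vectors do not
# discriminate). Caveat: genuinely covarying components in field data can
# trip this check; it is therefore a flag on split_half_validate.
model_is_degenerate <- function(model, threshold = 0.95) {
  if (model$k < 2) return(FALSE)
  sc <- model$scores
  if (any(apply(sc, 2, stats::sd) == 0)) return(TRUE)
  r <- abs(stats::cor(sc))
  any(r[upper.tri(r)] >= threshold)
}

#' Split-half validation of the PARAFAC component number
#'
#' Shuffles the samples with the given seed, splits them into alternating
#' halves, fits each half independently at every k in `k_range`, matches
#' components across halves greedily on the product of emission and
#' excitation congruences, and selects the largest k whose every matched
#' pair exceeds `congruence_threshold` in both modes.
#'
#' @param stack an [eem_stack()] with >= 8 samples.
#' @param k_range candidate component numbers (default 2:7).
#' @param congruence_threshold per-mode validation threshold (default 0.95).
#' @param seed integer seed (shuffle + ALS initialisations).
#' @param n_starts,tol,max_iter ALS settings for the half fits; defaults are
#'   lighter than [parafac_als()]'s because each k is fitted twice per call.
#' @param check_degeneracy reject models containing a split component pair
#'   (score vectors correlated above the congruence threshold); see the
#'   methods vignette for when to disable this.
#' @return list with `selected_k` (NA if no k validates), `validated`
#'   (logical per k), `degenerate` (logical per k: a half contained a
#'   split/duplicated component pair), `congruence` (per-k data.frame of
#'   per-component em/ex congruences), `halves` (sample indices).
#' @export
split_half_validate <- function(stack, k_range = 2:7,
                                congruence_threshold = 0.95, seed,
                                n_starts = 3, tol = 1e-7, max_iter = 500,
                                check_degeneracy = TRUE) {
  stopifnot(inherits(stack, "eem_stack"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  S <- dim(stack$data)[1]
  if (S < 8) stop("need at least 8 samples for split-half validation", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample(S)
  h1 <- sort(idx[seq(1, S, by = 2)])
  h2 <- sort(idx[seq(2, S, by = 2)])
  subset_stack <- function(keep) {
    structure(list(data = stack$data[keep, , , drop = FALSE],
                   ex_grid = stack$ex_grid, em_grid = stack$em_grid,
                   sample_ids = stack$sample_ids[keep]),
              class = "eem_stack")
  }
  s1 <- subset_stack(h1); s2 <- subset_stack(h2)
  validated <- logical(length(k_range))
  degenerate <- logical(length(k_range))
  cong <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    m1 <- parafac_als(s1, k, n_starts = n_starts, tol = tol,
                      max_iter = max_iter, seed = seed + 1000L + k)
    m2 <- parafac_als(s2, k, n_starts = n_starts, tol = tol,
                      max_iter = max_iter, seed = seed + 2000L + k)
    em_c <- abs(crossprod(m1$em_loadings, m2$em_loadings))
    ex_c <- abs(crossprod(m1$ex_loadings, m2$ex_loadings))
    pairs <- greedy_match(em_c * ex_c)
    em_m <- em_c[pairs]
    ex_m <- ex_c[pairs]
    cong[[i]] <- data.frame(k = k, component = seq_len(k),
                            half1 = pairs[, 1], half2 = pairs[, 2],
                            congruence_em = em_m, congruence_ex = ex_m)
    degenerate[i] <- check_degeneracy &&
      (model_is_degenerate(m1, congruence_threshold) ||
         model_is_degenerate(m2, congruence_threshold))
    validated[i] <- !degenerate[i] &&
      all(em_m >= congruence_threshold & ex_m >= congruence_threshold)
  }
  selected <- if (any(validated)) max(k_range[validated]) else NA_integer_
  list(selected_k = selected,
       validated = stats::setNames(validated, k_range),
       degenerate = stats::setNames(degenerate, k_range),
       congruence = do.call(rbind, cong),
       halves = list(h1 = h1, h2 = h2))
}

#' Leverage-based outlier flagging for a fitted PARAFAC model
#'
#' Sample leverage is the diagonal of the hat projection built from the
#' score matrix; samples with leverage above `threshold_factor` times the
#' mean leverage are flagged. Flagging never removes anything: removal is
#' an explicit user step.
#'
#' @param stack the fitted [eem_stack()] (for its sample ids).
#' @param model a [parafac_model()].
#' @param threshold_factor multiplier on the mean leverage (default 3).
#' @return integer vector of flagged sample indices (possibly empty), with
#'   the per-sample leverages as attribute `leverage`.
#' @export
leverage_outliers <- function(stack, model, threshold_factor = 3.0) {
  A <- model$scores
  lev <- diag(A %*% solve(crossprod(A) + 1e-12 * diag(ncol(A)), t(A)))
  flag <- which(lev > threshold_factor * mean(lev))
  structure(as.integer(flag), leverage = lev)
}

#' Reference fluorescent components
#'
#' The default library of five humic/protein-like components with their
#' excitation/emission maxima (nm): C1 330/422; C2 260,360/450;
#' C3 320,390/500; C4 280/400; C5 275/305,340. Multi-peak entries are
#' rendered as equal-weight Gaussian mixtures.
#'
#' @return list of reference components (`name`, `ex_peaks`, `em_peaks`).
#' @export
reference_components <- function() {
  list(
    list(name = "C1", ex_peaks = 330, em_peaks = 422),
    list(name = "C2", ex_peaks = c(260, 360), em_peaks = 450),
    list(name = "C3", ex_peaks = c(320, 390), em_peaks = 500),
    list(name = "C4", ex_peaks = 280, em_peaks = 400),
    list(name = "C5", ex_peaks = 275, em_peaks = c(305, 340))
  )
}

gaussian_profile <- function(grid, peaks, sd) {
  p <- rowSums(vapply(peaks, function(mu) exp(-0.5 * ((grid - mu) / sd)^2),
                      numeric(length(grid))))
  p / sqrt(sum(p^2))
}

#' Render a reference component on model grids
#'
#' Gaussian profiles (sd 15 nm emission, 10 nm excitation; multi-peak
#' components as equal-weight mixtures), unit Euclidean norm.
#'
#' @param ref one element of [reference_components()] (or a list with
#'   `ex_peaks`, `em_peaks`, optionally full `ex_spectrum`/`em_spectrum`).
#' @param ex_grid,em_grid model wavelength grids.
#' @param ex_sd,em_sd Gaussian widths in nm.
#' @return list with unit-norm `em` and `ex` profile vectors.
#' @export
render_reference <- function(ref, ex_grid, em_grid, ex_sd = 10, em_sd = 15) {
  em <- if (!is.null(ref$em_spectrum)) {
    v <- ref$em_spectrum; v / sqrt(sum(v^2))
  } else gaussian_profile(em_grid, ref$em_peaks, em_sd)
  ex <- if (!is.null(ref$ex_spectrum)) {
    v <- ref$ex_spectrum; v / sqrt(sum(v^2))
  } else gaussian_profile(ex_grid, ref$ex_peaks, ex_sd)
  if (length(em) != length(em_grid) || length(ex) != length(ex_grid)) {
    stop("reference spectra do not match the model grids", call. = FALSE)
  }
  list(em = em, ex = ex)
}

#' Match fitted components against reference spectra
#'
#' Greedy one-to-one assignment between model components and references,
#' maximising the geometric mean of the emission and excitation Tucker
#' congruences; pairs whose geometric-mean congruence falls below
#' `threshold` are reported as unmatched.
#'
#' @param model a [parafac_model()].
#' @param references list of reference components (see
#'   [reference_components()]).
#' @param threshold match acceptance threshold (default 0.95).
#' @return data.frame with one row per model component: `component`,
#'   `reference` (NA when unmatched), `congruence_em`, `congruence_ex`,
#'   `congruence` (geometric mean), `matched`.
#' @export
match_components <- function(model, references = reference_components(),
                             threshold = 0.95) {
  rend <- lapply(references, render_reference, ex_grid = model$ex_grid,
                 em_grid = model$em_grid)
  em_ref <- vapply(rend, `[[`, numeric(length(model$em_grid)), "em")
  ex_ref <- vapply(rend, `[[`, numeric(length(model$ex_grid)), "ex")
  em_c <- abs(crossprod(model$em_loadings, em_ref))
  ex_c <- abs(crossprod(model$ex_loadings, ex_ref))
  score <- sqrt(em_c * ex_c)
  pairs <- greedy_match(score)
  out <- data.frame(component = seq_len(model$k),
                    reference = NA_character_,
                    congruence_em = NA_real_, congruence_ex = NA_real_,
                    congruence = NA_real_, matched = FALSE,
                    stringsAsFactors = FALSE)
  ref_names <- vapply(references, `[[`, "", "name")
  for (i in seq_len(nrow(pairs))) {
    comp <- pairs[i, 1]; ref <- pairs[i, 2]
    out$reference[comp] <- ref_names[ref]
    out$congruence_em[comp] <- em_c[comp, ref]
    out$congruence_ex[comp] <- ex_c[comp, ref]
    out$congruence[comp] <- score[comp, ref]
    out$matched[comp] <- score[comp, ref] >= threshold
  }
  out
}

#' Maximum-fluorescence (Fmax) scores
#'
#' With unit-norm spectral loadings, Fmax[i, r] = score[i, r] x
#' max(em loading r) x max(ex loading r); the per-sample total fluorescent
#' DOM (FDOM) is the row sum.
#'
#' @param model a [parafac_model()].
#' @return matrix samples x components with attribute `fdom` (row sums).
#' @export
fmax_scores <- function(model) {
  fm <- sweep(model$scores, 2,
              apply(model$em_loadings, 2, max) *
                apply(model$ex_loadings, 2, max), `*`)
  rownames(fm) <- model$sample_ids
  colnames(fm) <- paste0("comp", seq_len(model$k))
  structure(fm, fdom = rowSums(fm))
}
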