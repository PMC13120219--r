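#' OTU count table
#'
#' Taxa x samples nonnegative integer counts with optional taxonomy strings.
#'
#' @param counts matrix (OTUs in rows, samples in columns) of nonnegative
#'   integer counts; every retained sample must have at least one nonzero
#'   count.
#' @param taxonomy optional character vector, one entry per OTU.
#' @return object of class `otu_table_dl`.
#' @export
otu_table_dl <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("every sample must have at least one nonzero count", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (!is.null(taxonomy) && length(taxonomy) != nrow(counts)) {
    stop("taxonomy must have one entry per OTU", call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "otu_table_dl")
}

#' Shannon diversity of one sample
#'
#' H' = -sum p_i ln p_i over taxa with p_i > 0, in nats.
#'
#' @param counts nonnegative per-taxon counts (or abundances) of one sample.
#' @return H' in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("sample has no counts", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' 1 - 2 sum min(a_i, b_i) / (sum a_i + sum b_i), in [0, 1].
#'
#' @param a,b equal-length nonnegative abundance vectors.
#' @return distance in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tot <- sum(a) + sum(b)
  if (tot <= 0) stop("both samples are empty", call. = FALSE)
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Bray-Curtis distance matrix for an OTU table
#'
#' Computed on per-sample relative abundances.
#'
#' @param otus an [otu_table_dl()].
#' @return symmetric samples x samples matrix.
#' @export
bray_curtis_matrix <- function(otus) {
  stopifnot(inherits(otus, "otu_table_dl"))
  rel <- sweep(otus$counts, 2, colSums(otus$counts), `/`)
  n <- ncol(rel)
  D <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- bray_curtis(rel[, i], rel[, j])
  }
  D
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centres the squared distance matrix, eigendecomposes it, and
#' returns coordinates scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues are reported and their axes dropped.
#' When the input distances are Euclidean-realisable, pairwise distances in
#' the full-rank embedding reproduce the input.
#'
#' @param distances square symmetric matrix with zero diagonal.
#' @param k number of axes to return (default: all positive-eigenvalue axes).
#' @param tol asymmetry tolerance.
#' @return list with `points` (samples x axes), `eigenvalues` (all, sorted),
#'   `explained` (per returned axis, proportions of the positive-eigenvalue
#'   total).
#' @export
pcoa_dl <- function(distances, k = NULL, tol = 1e-8) {
  D <- as.matrix(distances)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(D - t(D))) > tol) stop("distance matrix is asymmetric", call. = FALSE)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-10 & eg$values > 0
  n_pos <- sum(pos)
  if (is.null(k)) k <- n_pos
  k <- min(k, n_pos)
  pts <- if (k > 0) {
    eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(k)]), k)
  } else matrix(0, n, 0)
  rownames(pts) <- rownames(D)
  explained <- if (n_pos > 0) eg$values[seq_len(k)] / sum(eg$values[pos]) else numeric(0)
  list(points = pts, eigenvalues = eg$values, explained = explained)
}

#' Abundance-filtered Spearman screen between DOM features and OTUs
#'
#' Restricts to OTUs whose relative abundance exceeds `min_rel_abundance`
#' (mean across samples by default, maximum when
#' `abundance_stat = "max"`), then computes Spearman's rho and a two-sided
#' p-value (midrank ties) for every (feature, OTU) pair, plus
#' Benjamini-Hochberg adjusted p-values. Constant features or OTUs give NA
#' and are flagged.
#'
#' @param dom_features matrix features x samples (rownames = feature names);
#'   sample columns must align with the OTU table's samples.
#' @param otus an [otu_table_dl()].
#' @param min_rel_abundance relative-abundance filter (default 0.001).
#' @param abundance_stat "mean" or "max" relative abundance across samples.
#' @return object of class `correlation_screen`: list with `rho`, `p`,
#'   `p_adj` (feature x OTU matrices), `significant` (raw p < 0.05),
#'   `otus_kept`, `dropped_constant`, `min_rel_abundance`.
#' @export
spearman_screen <- function(dom_features, otus, min_rel_abundance = 0.001,
                            abundance_stat = c("mean", "max")) {
  stopifnot(inherits(otus, "otu_table_dl"))
  abundance_stat <- match.arg(abundance_stat)
  dom_features <- as.matrix(dom_features)
  if (ncol(dom_features) != ncol(otus$counts)) {
    stop("feature and OTU tables have different sample counts", call. = FALSE)
  }
  if (!is.null(colnames(dom_features)) &&
      !identical(colnames(dom_features), colnames(otus$counts))) {
    stop("feature and OTU sample ids are misaligned", call. = FALSE)
  }
  if (ncol(dom_features) < 4) stop("need at least 4 samples", call. = FALSE)
  rel <- sweep(otus$counts, 2, colSums(otus$counts), `/`)
  ab <- if (abundance_stat == "mean") rowMeans(rel) else apply(rel, 1, max)
  keep <- ab > min_rel_abundance
  if (!any(keep)) stop("no OTU passes the abundance filter", call. = FALSE)
  rel <- rel[keep, , drop = FALSE]
  nf <- nrow(dom_features); no <- nrow(rel)
  rho <- p <- matrix(NA_real_, nf, no,
                     dimnames = list(rownames(dom_features), rownames(rel)))
  dropped <- character(0)
  for (i in seq_len(nf)) {
    if (stats::sd(dom_features[i, ]) == 0) {
      dropped <- c(dropped, rownames(dom_features)[i])
      next
    }
    for (j in seq_len(no)) {
      if (stats::sd(rel[j, ]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(dom_features[i, ], rel[j, ], method = "spearman",
                        exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nf, no,
                  dimnames = dimnames(p))
  structure(list(rho = rho, p = p, p_adj = p_adj,
                 significant = !is.na(p) & p < 0.05,
                 otus_kept = rownames(rel), dropped_constant = dropped,
                 min_rel_abundance = min_rel_abundance),
            class = "correlation_screen")
}
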