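read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s file %s is missing column(s): %s", what, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("%s column '%s' contains non-numeric values", what, cl),
           call. = FALSE)
    }
  }
  df
}

#' Read a peak-list CSV (columns mz, intensity)
#' @param path file path.
#' @return data.frame with columns `mz`, `intensity`.
#' @export
read_peaks_csv <- function(path) {
  df <- read_csv_checked(path, c("mz", "intensity"), "peak list")
  check_numeric(df, c("mz", "intensity"), "peak list")
  df
}

#' Write a peak list CSV
#' @param peaks data.frame with `mz`, `intensity`.
#' @param path output path.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks[, c("mz", "intensity")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a formula-table CSV
#'
#' Accepts either element-count columns `c,h,n,o,s,intensity` or a
#' `formula` string column (e.g. "C16H20O8") with `intensity`. Derived
#' columns present in the file are ignored and recomputed.
#'
#' @param path file path.
#' @param sample_id label (default: file name without extension).
#' @return a [formula_table()].
#' @export
read_formula_csv <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"intensity" %in% names(df)) {
    stop(sprintf("formula file %s is missing column(s): intensity", path), call. = FALSE)
  }
  if (all(ELEMENTS %in% names(df))) {
    recs <- df[, c(ELEMENTS, "intensity")]
  } else if ("formula" %in% names(df)) {
    recs <- parse_formula(df$formula)
    recs$intensity <- df$intensity
  } else {
    stop(sprintf("formula file %s needs either c,h,n,o,s or a formula column", path),
         call. = FALSE)
  }
  extra <- intersect(c("mz_observed", "mass_error_ppm"), names(df))
  for (cl in extra) recs[[cl]] <- df[[cl]]
  formula_table(recs, sample_id = sample_id)
}

#' Write a formula table CSV including all derived columns
#' @param table a [formula_table()].
#' @param path output path.
#' @export
write_formula_csv <- function(table, path) {
  stopifnot_formula_table(table)
  cols <- c("c", "h", "n", "o", "s", "intensity", "formula", "oc", "hc",
            "dbe", "elemental_class", "compound_class", "is_cram")
  cols <- c(cols, intersect(c("mz_observed", "mass_error_ppm"), names(table)))
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read decay series from CSV (columns day, value, quantity, replicate)
#'
#' @param path file path.
#' @return list of [decay_series()], one per (quantity, replicate) group.
#' @export
read_decay_csv <- function(path) {
  df <- read_csv_checked(path, c("day", "value"), "decay series")
  check_numeric(df, c("day", "value"), "decay series")
  if (is.null(df$quantity)) df$quantity <- "DOC"
  if (is.null(df$replicate)) df$replicate <- "rep1"
  groups <- split(df, list(df$quantity, df$replicate), drop = TRUE)
  lapply(groups, function(g) {
    g <- g[order(g$day), ]
    decay_series(g$day, g$value, quantity = g$quantity[1],
                 replicate_id = as.character(g$replicate[1]))
  })
}

#' Write decay series to CSV
#' @param series_list list of [decay_series()].
#' @param path output path.
#' @export
write_decay_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(day = s$times, value = s$values, quantity = s$quantity,
               replicate = s$replicate_id %||% "rep1")
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one EEM from CSV (first row = excitation grid, first column =
#' emission grid, body = intensities)
#'
#' @param path file path.
#' @param sample_id label (default: file name).
#' @return an [eem()].
#' @export
read_eem_csv <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  ex <- as.numeric(raw[1, -1])
  em <- as.numeric(raw[-1, 1])
  body <- matrix(as.numeric(raw[-1, -1]), length(em), length(ex))
  if (any(is.na(ex)) || any(is.na(em)) || any(is.na(body))) {
    stop(sprintf("EEM file %s contains non-numeric cells", path), call. = FALSE)
  }
  if (any(diff(em) <= 0)) {
    stop(sprintf("EEM file %s has a non-monotone emission grid", path), call. = FALSE)
  }
  if (any(diff(ex) <= 0)) {
    stop(sprintf("EEM file %s has a non-monotone excitation grid", path), call. = FALSE)
  }
  eem(body, ex_grid = ex, em_grid = em, sample_id = sample_id)
}

#' Write one EEM to CSV
#' @param x an [eem()].
#' @param path output path.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  out <- rbind(c(0, x$ex_grid), cbind(x$em_grid, x$intensity))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an EEM stack via a manifest CSV (columns sample_id, path)
#'
#' Relative paths in the manifest resolve against the manifest's directory.
#' @param manifest_path manifest file.
#' @return an [eem_stack()].
#' @export
read_eem_manifest <- function(manifest_path) {
  mf <- read_csv_checked(manifest_path, c("sample_id", "path"), "EEM manifest")
  base <- dirname(manifest_path)
  eems <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_eem_csv(p, sample_id = mf$sample_id[i])
  })
  eem_stack(eems)
}

#' Read an OTU table TSV (first column otu_id, then per-sample counts,
#' optional taxonomy column)
#'
#' @param path file path.
#' @return an [otu_table_dl()].
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"otu_id" %in% names(df)) {
    stop(sprintf("OTU file %s is missing column(s): otu_id", path), call. = FALSE)
  }
  if (anyDuplicated(df$otu_id)) {
    stop(sprintf("OTU file %s has duplicated otu_id values", path), call. = FALSE)
  }
  tax <- if ("taxonomy" %in% names(df)) df$taxonomy else NULL
  counts <- as.matrix(df[, setdiff(names(df), c("otu_id", "taxonomy")), drop = FALSE])
  if (!is.numeric(counts)) stop(sprintf("OTU file %s contains non-numeric counts", path), call. = FALSE)
  rownames(counts) <- df$otu_id
  otu_table_dl(counts, taxonomy = tax)
}

#' Write an OTU table TSV
#' @param otus an [otu_table_dl()].
#' @param path output path.
#' @export
write_otu_tsv <- function(otus, path) {
  df <- data.frame(otu_id = rownames(otus$counts), otus$counts,
                   check.names = FALSE)
  if (!is.null(otus$taxonomy)) df$taxonomy <- otus$taxonomy
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
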