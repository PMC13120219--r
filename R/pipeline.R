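#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a JSON file holding one)
#' with a required `out_dir`, a required integer `seed`, and one optional
#' block per stage: `annotate` (peaks, tolerance_ppm), `kinetics` (series,
#' n_starts), `parafac` (manifest, k_range, threshold), `compare` (tables,
#' variant, fold_threshold), `ecology` (otus, dom_features,
#' min_abundance). A stage runs when its block is present and
#' `enabled` is not FALSE. Every referenced input path must exist.
#'
#' @param config named list or path to a JSON config file.
#' @return the normalised config (invisible errors otherwise).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path", call. = FALSE)
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required", call. = FALSE)
  if (is.null(config$seed)) stop("config field 'seed' is required (all random stages are seeded)", call. = FALSE)
  path_fields <- list(
    annotate = "peaks", kinetics = "series", parafac = "manifest",
    compare = "tables", ecology = c("otus", "dom_features"))
  for (stage in names(path_fields)) {
    blk <- config[[stage]]
    if (is.null(blk) || isFALSE(blk$enabled)) next
    for (fld in path_fields[[stage]]) {
      ps <- blk[[fld]]
      if (is.null(ps)) {
        stop(sprintf("config field '%s$%s' is required for the %s stage",
                     stage, fld, stage), call. = FALSE)
      }
      for (p in ps) {
        if (!file.exists(p)) {
          stop(sprintf("config field '%s$%s': path does not exist: %s",
                       stage, fld, p), call. = FALSE)
        }
      }
    }
  }
  config
}

stage_enabled <- function(config, stage) {
  blk <- config[[stage]]
  !is.null(blk) && !isFALSE(blk$enabled)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order - annotate, kinetics,
#' optics/PARAFAC, similarity/fate comparison, ecology - writing tabular
#' outputs under `out_dir` and a machine-readable JSON report
#' (`report.json`). Rerunning with identical config, inputs and seeds
#' reproduces identical outputs (the report carries no timestamps). A
#' failing stage aborts with the stage named; outputs of earlier stages are
#' retained alongside a FAILED marker file.
#'
#' @param config see [pipeline_config()].
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(
    package = "domlake",
    version = as.character(utils::packageVersion("domlake")),
    config = config[setdiff(names(config), "out_dir")],
    stages = list()
  )
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (stage_enabled(config, "annotate")) {
    report$stages$annotate <- run_stage("annotate", function() {
      blk <- config$annotate
      cfg <- assignment_config(tolerance_ppm = blk$tolerance_ppm %||% 1.0)
      res <- lapply(blk$peaks, function(p) {
        tab <- annotate_peaks(read_peaks_csv(p), cfg,
                              sample_id = sub("\\.[^.]*$", "", basename(p)))
        out <- file.path(out_dir, paste0(attr(tab, "sample_id"), "_formulas.csv"))
        write_formula_csv(tab, out)
        list(sample_id = attr(tab, "sample_id"), n_assigned = nrow(tab),
             output = basename(out),
             class_profile_count = as.list(class_profile(tab, "count")),
             class_profile_intensity = as.list(class_profile(tab, "intensity")))
      })
      res
    })
  }

  if (stage_enabled(config, "kinetics")) {
    report$stages$kinetics <- run_stage("kinetics", function() {
      blk <- config$kinetics
      series <- read_decay_csv(blk$series)
      n_starts <- blk$n_starts %||% 16
      lapply(series, function(s) {
        fit <- fit_two_pool(s, n_starts = n_starts, seed = seed)
        list(replicate = s$replicate_id, quantity = s$quantity,
             fa = fit$fa, fb = fit$fb, k1 = fit$k1, k2 = fit$k2,
             fc = fit$fc, t_half_fast = fit$t_half_fast,
             t_half_slow = fit$t_half_slow, r2_adj = fit$r2_adj,
             converged = fit$converged)
      })
    })
  }

  if (stage_enabled(config, "parafac")) {
    report$stages$parafac <- run_stage("parafac", function() {
      blk <- config$parafac
      stack <- preprocess_eem(read_eem_manifest(blk$manifest))
      k_range <- blk$k_range %||% c(2, 7)
      sh <- split_half_validate(stack, k_range = seq(k_range[1], k_range[2]),
                                congruence_threshold = blk$threshold %||% 0.95,
                                seed = seed)
      k <- if (is.na(sh$selected_k)) k_range[1] else sh$selected_k
      model <- parafac_als(stack, k, seed = seed)
      matches <- match_components(model, threshold = blk$threshold %||% 0.95)
      fmax <- fmax_scores(model)
      utils::write.csv(data.frame(sample_id = model$sample_ids, fmax),
                       file.path(out_dir, "fmax.csv"), row.names = FALSE)
      list(selected_k = sh$selected_k, fitted_k = k,
           fit_error = model$fit_error,
           outliers = as.integer(leverage_outliers(stack, model)),
           components = lapply(seq_len(k), function(r) list(
             component = r,
             ex_max = model$ex_grid[which.max(model$ex_loadings[, r])],
             em_max = model$em_grid[which.max(model$em_loadings[, r])],
             reference = matches$reference[r],
             congruence = matches$congruence[r],
             matched = matches$matched[r])))
    })
  }

  if (stage_enabled(config, "compare")) {
    report$stages$compare <- run_stage("compare", function() {
      blk <- config$compare
      tabs <- lapply(blk$tables, read_formula_csv)
      n <- length(tabs)
      variant <- blk$variant %||% "as_printed"
      jac <- matrix(NA_real_, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        jac[i, j] <- jaccard_similarity(tabs[[i]], tabs[[j]], variant = variant)
      }
      ids <- vapply(tabs, attr, "", which = "sample_id")
      dimnames(jac) <- list(ids, ids)
      utils::write.csv(jac, file.path(out_dir, "jaccard.csv"))
      out <- list(variant = variant, sample_ids = ids, jaccard = jac)
      if (n == 2) {
        fate <- molecule_fate(tabs[[1]], tabs[[2]],
                              fold_threshold = blk$fold_threshold %||% 2.0)
        utils::write.csv(as.data.frame(fate),
                         file.path(out_dir, "fate.csv"), row.names = FALSE)
        out$fate_counts <- as.list(table(fate$fate))
        out$class_change_pp <- as.list(attr(fate, "class_change"))
      }
      out
    })
  }

  if (stage_enabled(config, "ecology")) {
    report$stages$ecology <- run_stage("ecology", function() {
      blk <- config$ecology
      otus <- read_otu_tsv(blk$otus)
      sh_div <- apply(otus$counts, 2, shannon)
      D <- bray_curtis_matrix(otus)
      ord <- pcoa_dl(D, k = 2)
      utils::write.csv(data.frame(sample_id = colnames(otus$counts),
                                  shannon = sh_div, ord$points),
                       file.path(out_dir, "ecology_samples.csv"),
                       row.names = FALSE)
      out <- list(shannon = as.list(sh_div),
                  pcoa_explained = ord$explained)
      if (!is.null(blk$dom_features)) {
        feats <- utils::read.csv(blk$dom_features, check.names = FALSE)
        fm <- as.matrix(feats[, -1, drop = FALSE])
        rownames(fm) <- feats[[1]]
        scr <- spearman_screen(fm, otus,
                               min_rel_abundance = blk$min_abundance %||% 0.001)
        utils::write.csv(scr$rho, file.path(out_dir, "spearman_rho.csv"))
        out$n_otus_screened <- length(scr$otus_kept)
        out$n_significant <- sum(scr$significant, na.rm = TRUE)
      }
      out
    })
  }

  write_report_json(report, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Write a run report as deterministic JSON
#' @param report report list.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
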