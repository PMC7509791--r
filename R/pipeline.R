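# End-to-end analysis runs: replication (consistency + ranges), short-set
# validity, and truncation analyses, with tidy CSV + Markdown reports.
#
# All randomness flows from the single root seed in the config, split per
# stage with derive_seed(), so partial reruns are reproducible and two runs
# with the same config produce byte-identical reports.

#' Pipeline run configuration
#'
#' Bundles the data source, filter parameters and analysis settings for
#' [run_replication()], [run_shortset()] and [run_truncation()].
#'
#' The data source is either synthetic (`sim` given: catalog and sessions are
#' generated) or file-based (`fixations_day1`, optionally `fixations_day2`,
#' and `catalog_dir` pointing to the formats of [read_fixation_table()] and
#' [read_scene_catalog()]).
#'
#' @param sim a [sim_config()] for synthetic runs, or `NULL`.
#' @param fixations_day1,fixations_day2 fixation table paths (file mode).
#' @param catalog_dir scene catalog directory (file mode).
#' @param out_dir output directory for reports (`NULL`: no files written).
#' @param seed root seed.
#' @param params a [filter_params()].
#' @param dims_dwell,dims_first tested dimensions.
#' @param n_splits random splits for consistency analyses.
#' @param cutoffs_ms truncation cutoffs.
#' @param subset_sizes exported subset sizes.
#' @param sizes_curve prefix sizes for validity curves (default `10:200`,
#'   clipped to the available ordering).
#' @param threshold validity threshold.
#' @param noise_ceiling named per-dimension noise-ceiling correlations used
#'   for explainable-variance reporting (full-set retest estimates; supply
#'   your own where available).
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       fixations_day1 = NULL, fixations_day2 = NULL,
                       catalog_dir = NULL,
                       out_dir = NULL, seed = 1L,
                       params = filter_params(),
                       dims_dwell = tested_dims("dwell"),
                       dims_first = tested_dims("first_fix"),
                       n_splits = 1000L,
                       cutoffs_ms = seq(100, 3000, by = 100),
                       subset_sizes = c(40, 100, 200),
                       sizes_curve = 10:200,
                       threshold = 0.7,
                       noise_ceiling = c(Faces = 0.80, Text = 0.84,
                                         Touched = 0.70, Taste = 0.70,
                                         Motion = 0.68)) {
  if (is.null(sim) && (is.null(fixations_day1) || is.null(catalog_dir)))
    abort("either `sim` or both `fixations_day1` and `catalog_dir` are required")
  if (n_splits < 1) abort("n_splits must be >= 1")
  structure(list(sim = sim, fixations_day1 = fixations_day1,
                 fixations_day2 = fixations_day2, catalog_dir = catalog_dir,
                 out_dir = out_dir, seed = as.integer(seed), params = params,
                 dims_dwell = dims_dwell, dims_first = dims_first,
                 n_splits = as.integer(n_splits), cutoffs_ms = cutoffs_ms,
                 subset_sizes = subset_sizes, sizes_curve = sizes_curve,
                 threshold = threshold, noise_ceiling = noise_ceiling),
            class = "run_config")
}

# load or simulate both sessions; returns scored data + catalog
load_run_data <- function(cfg, need_day2 = FALSE) {
  if (!is.null(cfg$sim)) {
    catalog <- generate_catalog(cfg$sim, seed = derive_seed(cfg$seed, "catalog"))
    observers <- generate_observers(cfg$sim,
                                    seed = derive_seed(cfg$seed, "observers"))
    fx1 <- simulate_session(observers, catalog, cfg$sim, "day1",
                            seed = derive_seed(cfg$seed, "day1"))
    fx2 <- if (need_day2)
      simulate_session(observers, catalog, cfg$sim, "day2",
                       seed = derive_seed(cfg$seed, "day2"))
  } else {
    catalog <- read_scene_catalog(cfg$catalog_dir)
    fx1 <- read_fixation_table(cfg$fixations_day1)
    fx2 <- if (need_day2) {
      if (is.null(cfg$fixations_day2))
        abort("this analysis needs `fixations_day2`")
      read_fixation_table(cfg$fixations_day2)
    }
  }
  catalog <- prepare_labels(catalog)
  for (d in unique(c(cfg$dims_dwell, cfg$dims_first))) {
    if (!d %in% catalog$vocabulary)
      abort(sprintf("dimension `%s` missing from catalog labels (available: %s)",
                    d, paste(catalog$vocabulary, collapse = ", ")))
  }
  out <- list(catalog = catalog,
              day1 = score_gaze(fx1, catalog, cfg$params))
  if (need_day2) out$day2 <- score_gaze(fx2, catalog, cfg$params)
  out
}

provenance_lines <- function(cfg, stage) {
  c(sprintf("stage: %s", stage),
    sprintf("seed: %d", cfg$seed),
    sprintf("n_splits: %d", cfg$n_splits),
    sprintf("config_hash: %s",
            stable_hash(cfg[setdiff(names(cfg), "out_dir")])))
}

write_report_files <- function(cfg, stage, tables, md_lines) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(cfg$out_dir, paste0(stage, "_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(c(md_lines, "", "```", provenance_lines(cfg, stage), "```"),
             file.path(cfg$out_dir, paste0(stage, "_report.md")))
  invisible(NULL)
}

fmt_tbl_row <- function(dim, ch, rr) {
  sprintf("| %s | %.2f | %s | %.0f-%.0f | %.2f |",
          dim, ch$median_r[ch$dimension == dim],
          format.pval(ch$p_adjusted[ch$dimension == dim], digits = 2,
                      eps = 0.001),
          rr$min_pct, rr$max_pct, rr$maxmin_ratio)
}

#' Replication analysis: consistency and ranges of individual differences
#'
#' Computes, on the day-1 dataset: split-half consistency (median r over
#' random image splits, Bonferroni-adjusted p) for cumulative dwell time on
#' the tested dwell dimensions and for first fixations on the tested
#' first-fixation dimensions, exploration consistency, and the observer range
#' (%) and max/min ratio per dimension — the standard summary table of an
#' individual-differences free-viewing study.
#'
#' @param cfg a [run_config()].
#' @return a report bundle (list) with elements `dwell`, `first_fix`,
#'   `exploration` ([split_half()] results), `summary` (the combined table)
#'   and `exclusions`; written to `cfg$out_dir` when set.
#' @export
run_replication <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dat <- load_run_data(cfg)
  sc <- dat$day1
  ch_dwell <- split_half(sc, dims = cfg$dims_dwell, kind = "dwell",
                         n_splits = cfg$n_splits,
                         seed = derive_seed(cfg$seed, "split-dwell"))
  ch_first <- split_half(sc, dims = cfg$dims_first, kind = "first_fix",
                         n_splits = cfg$n_splits,
                         seed = derive_seed(cfg$seed, "split-first"))
  ch_expl <- split_half(sc, kind = "exploration", n_splits = cfg$n_splits,
                        seed = derive_seed(cfg$seed, "split-expl"))
  m_dwell <- salience_matrix(sc, cfg$dims_dwell, "dwell")
  m_first <- salience_matrix(sc, cfg$dims_first, "first_fix")
  m_expl <- salience_matrix(sc, kind = "exploration")

  summary_rows <- function(ch, m, measure, as_percent) {
    do.call(rbind, lapply(ch$dimension, function(d) {
      rr <- range_and_ratio(m[, d], as_percent = as_percent)
      data.frame(measure = measure, dimension = d,
                 median_r = ch$median_r[ch$dimension == d],
                 p_adjusted = ch$p_adjusted[ch$dimension == d],
                 min_pct = rr$min_pct, max_pct = rr$max_pct,
                 maxmin_ratio = rr$maxmin_ratio, row.names = NULL)
    }))
  }
  summary <- rbind(summary_rows(ch_dwell, m_dwell, "dwell", TRUE),
                   summary_rows(ch_first, m_first, "first_fix", TRUE),
                   summary_rows(ch_expl, m_expl, "exploration", FALSE))

  md <- c("# Replication report: consistency of individual gaze differences", "",
          sprintf("Observers: %d | images: %d | splits: %d",
                  length(sc$observers), length(sc$image_ids), cfg$n_splits), "",
          "| measure / dimension | median r | adj. p | range | max/min |",
          "|---|---|---|---|---|",
          sprintf("| %s: %s | %.2f | %s | %.1f-%.1f | %.2f |",
                  summary$measure, summary$dimension, summary$median_r,
                  format.pval(summary$p_adjusted, digits = 2, eps = 0.001),
                  summary$min_pct, summary$max_pct, summary$maxmin_ratio),
          "",
          sprintf("Exclusions: onset %d, duration %d, unassignable %d of %d fixations.",
                  sc$exclusions[["onset"]], sc$exclusions[["duration"]],
                  sc$exclusions[["unassignable"]], sc$n_input))
  tables <- list(
    summary = summary,
    splits_dwell = cbind(split = seq_len(nrow(attr(ch_dwell, "r_distribution"))),
                         as.data.frame(attr(ch_dwell, "r_distribution"))))
  write_report_files(cfg, "replication", tables, md)
  invisible(list(dwell = ch_dwell, first_fix = ch_first,
                 exploration = ch_expl, summary = summary,
                 matrices = list(dwell = m_dwell, first_fix = m_first,
                                 exploration = m_expl),
                 exclusions = sc$exclusions, scores = sc))
}

#' Short-set analysis: validity of smaller stimulus sets
#'
#' Selects an image ordering on the day-1 data with [greedy_select()] (or
#' uses `ordering` if supplied), then evaluates validity curves of prefix
#' subsets on the day-2 session against the full-set day-1 reference, for
#' dwell, first-fixation and exploration measures; reports threshold
#' crossings and explainable variance relative to the configured noise
#' ceiling.
#'
#' @param cfg a [run_config()] (a day-2 dataset is required).
#' @param ordering optional pre-computed image ordering.
#' @return report bundle with `selection`, `curves` (per measure),
#'   `crossings`, `explainable` and `subsets`.
#' @export
run_shortset <- function(cfg, ordering = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dat <- load_run_data(cfg, need_day2 = TRUE)
  sizes <- cfg$sizes_curve
  sel <- NULL
  if (is.null(ordering)) {
    sel <- greedy_select(dat$day1, dims = cfg$dims_dwell, kind = "dwell",
                         target_size = min(max(cfg$subset_sizes, sizes),
                                           length(dat$day1$image_ids)))
    ordering <- sel$ordering
  }
  sizes <- sizes[sizes <= length(ordering)]
  refs <- list(
    dwell = salience_matrix(dat$day1, cfg$dims_dwell, "dwell"),
    first_fix = salience_matrix(dat$day1, cfg$dims_first, "first_fix"),
    exploration = salience_matrix(dat$day1, kind = "exploration"))
  curves <- lapply(names(refs), function(kind)
    evaluate_ordering(ordering, dat$day2, refs[[kind]], sizes = sizes,
                      kind = kind, threshold = cfg$threshold))
  names(curves) <- names(refs)

  crossings <- do.call(rbind, lapply(names(curves), function(kind) {
    cv <- curves[[kind]]
    do.call(rbind, lapply(unique(cv$dimension), function(d) {
      ok <- cv[cv$dimension == d & cv$above_threshold, ]
      data.frame(measure = kind, dimension = d,
                 first_size_reaching_threshold =
                   if (nrow(ok)) min(ok$size) else NA_integer_,
                 row.names = NULL)
    }))
  }))

  expl <- do.call(rbind, lapply(cfg$subset_sizes[cfg$subset_sizes <= length(ordering)],
                                function(s) {
    cv <- curves$dwell[curves$dwell$size == s, ]
    ceil <- cfg$noise_ceiling[cv$dimension]
    data.frame(size = s, dimension = cv$dimension, r = cv$r,
               noise_ceiling = as.numeric(ceil),
               explainable_variance = suppressWarnings(
                 explainable_variance(cv$r, as.numeric(ceil))),
               row.names = NULL)
  }))

  subsets <- if (!is.null(sel))
    export_subsets(sel, cfg$subset_sizes[cfg$subset_sizes <= length(ordering)])

  md <- c("# Short-set report: validity of smaller stimulus sets", "",
          sprintf("Ordering length: %d | threshold r >= %.2f", length(ordering),
                  cfg$threshold), "",
          "First set size reaching the threshold:",
          sprintf("- %s / %s: %s", crossings$measure, crossings$dimension,
                  ifelse(is.na(crossings$first_size_reaching_threshold),
                         "not reached",
                         crossings$first_size_reaching_threshold)))
  tables <- list(curves = do.call(rbind, lapply(names(curves), function(k)
                   cbind(measure = k, as.data.frame(curves[[k]])))),
                 crossings = crossings, explainable = expl)
  write_report_files(cfg, "shortset", tables, md)
  invisible(list(selection = sel, ordering = ordering, curves = curves,
                 crossings = crossings, explainable = expl, subsets = subsets))
}

#' Truncation analysis: shorter trial durations
#'
#' (i) Correlation of truncated with full-duration estimates per cutoff;
#' (ii) odd/even split-half consistency per cutoff; (iii) when a day-2
#' session is available, validity curves recomputed with both sessions
#' truncated to 1000 and 2000 ms.
#'
#' @param cfg a [run_config()].
#' @param ordering image ordering for part (iii) (required with day-2 data).
#' @return report bundle with `vs_full`, `split_half_by_cutoff` and
#'   optionally `truncated_curves`.
#' @export
run_truncation <- function(cfg, ordering = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  has_day2 <- !is.null(cfg$sim) || !is.null(cfg$fixations_day2)
  dat <- load_run_data(cfg, need_day2 = has_day2)
  vs_full <- truncation_consistency(dat$day1, dims = cfg$dims_dwell,
                                    cutoffs_ms = cfg$cutoffs_ms)
  sh <- truncated_split_half(dat$day1, dims = cfg$dims_dwell,
                             cutoffs_ms = cfg$cutoffs_ms,
                             n_splits = cfg$n_splits,
                             seed = derive_seed(cfg$seed, "trunc-split"),
                             mode = "parity")
  truncated_curves <- NULL
  if (has_day2) {
    if (is.null(ordering))
      ordering <- greedy_select(dat$day1, dims = cfg$dims_dwell,
                                target_size = min(max(cfg$sizes_curve),
                                                  length(dat$day1$image_ids)))$ordering
    sizes <- cfg$sizes_curve[cfg$sizes_curve <= length(ordering)]
    truncated_curves <- do.call(rbind, lapply(c(1000, 2000), function(cut) {
      ref <- salience_matrix(dat$day1, cfg$dims_dwell, "dwell", cutoff_ms = cut)
      cv <- evaluate_ordering(ordering, dat$day2, ref, sizes = sizes,
                              threshold = cfg$threshold, cutoff_ms = cut)
      cbind(cutoff_ms = cut, as.data.frame(cv))
    }))
  }
  md <- c("# Truncation report: shorter trial durations", "",
          sprintf("Cutoffs: %s ms", paste(range(cfg$cutoffs_ms), collapse = "-")),
          "",
          "Correlation with full-duration estimates at the largest cutoff:",
          sprintf("- %s: r = %.3f",
                  vs_full$dimension[vs_full$cutoff_ms == max(cfg$cutoffs_ms)],
                  vs_full$r[vs_full$cutoff_ms == max(cfg$cutoffs_ms)]))
  tables <- list(vs_full = as.data.frame(vs_full), split_half = sh)
  if (!is.null(truncated_curves)) tables$truncated_curves <- truncated_curves
  write_report_files(cfg, "truncation", tables, md)
  invisible(list(vs_full = vs_full, split_half_by_cutoff = sh,
                 truncated_curves = truncated_curves))
}
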