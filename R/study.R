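#' Run the multilayer vs single-layer comparison study
#'
#' For every slice of every patient, solves the inflation problem twice on
#' the same contour data — once with the three-layer wall and layer-specific
#' materials, once with the merged single-layer wall — each after its own
#' circumferential pre-shrink, extracts the 100 lumen and 100 paired
#' out-wall nodal values per slice, pools them per patient, and assembles
#' the six comparison tables (plaque/cap/out-wall x stress/strain) with
#' per-patient maxima and means, cohort Mean +/- SD, relative differences
#' (computed from the cohort averages, single-layer as base) and paired
#' t-test results.
#'
#' Slices whose solve fails are dropped with a warning (for both models, to
#' keep the pairing); a patient is dropped entirely when more than half of
#' their slices fail.
#'
#' @param cohort a `vessel_cohort` from [generate_cohort()], or any list of
#'   patients with `patient_id`, `pressure_mmHg` and `slices`.
#' @param materials a `material_registry` (default [default_materials()]).
#' @param config named list of options: `n_rays` (40), `n_radial_per_layer`
#'   (2), `n_slabs` (1), `axial_stretch` (1.05), `preshrink_tol` (0.005),
#'   `n_per_quarter` (25), `anchor_deg` (0).
#' @param out_dir optional directory; when given, the six tables and a
#'   stats summary are written as CSV/JSON.
#' @return an object of class `comparison_study`: `tables` (named list of
#'   six data frames), `summary` (cohort Mean +/- SD and difference rows),
#'   `stats` (paired t and KS per table column pair), `manifest`, `dropped`.
#' @export
run_comparison_study <- function(cohort, materials = default_materials(),
                                 config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(n_rays = 40, n_radial_per_layer = 2,
                                n_slabs = 1, axial_stretch = 1.05,
                                preshrink_tol = 0.005, n_per_quarter = 25,
                                anchor_deg = 0), config)
  per_patient <- list()
  dropped <- character(0)
  for (pat in cohort) {
    pres <- mmHg_to_kPa(pat$pressure_mmHg)
    pools <- list()
    failed <- 0L
    for (sl in pat$slices) {
      vals <- try(solve_slice_pair(sl, materials, pres, cfg), silent = TRUE)
      if (inherits(vals, "try-error")) {
        failed <- failed + 1L
        warning("dropping slice ", sl$slice_id, " of ", pat$patient_id,
                ": ", attr(vals, "condition")$message, call. = FALSE)
        next
      }
      pools[[length(pools) + 1L]] <- vals
    }
    if (failed > length(pat$slices) / 2) {
      dropped <- c(dropped, pat$patient_id)
      warning("dropping patient ", pat$patient_id, " (", failed, "/",
              length(pat$slices), " slices failed)", call. = FALSE)
      next
    }
    per_patient[[pat$patient_id]] <- summarize_patient(pools)
  }
  if (length(per_patient) < 2L)
    stop("run_comparison_study: fewer than 2 patients solvable",
         call. = FALSE)
  tables <- assemble_tables(per_patient)
  summary <- lapply(tables, summarize_comparison_table)
  stats <- lapply(tables, table_tests)
  out <- structure(list(tables = tables, summary = summary, stats = stats,
                        manifest = cohort_manifest(cohort),
                        dropped = dropped, config = cfg),
                   class = "comparison_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# solve one slice under both wall treatments and return pooled nodal values
solve_slice_pair <- function(slice, materials, pressure_kPa, cfg) {
  out <- list()
  for (mode in c("multi", "single")) {
    sl <- if (mode == "single") merge_to_single_layer(slice) else slice
    ps <- circumferential_preshrink(
      sl, materials, pressure_kPa, axial_stretch = cfg$axial_stretch,
      tol = cfg$preshrink_tol, n_rays = cfg$n_rays,
      n_radial_per_layer = cfg$n_radial_per_layer, n_slabs = cfg$n_slabs)
    out[[mode]] <- extract_slice_values(ps$solution, ps$mesh, ps$shrunk,
                                        n_per_quarter = cfg$n_per_quarter,
                                        anchor_deg = cfg$anchor_deg)
  }
  out
}

# pool slices of one patient into per-region/measure/model value vectors
summarize_patient <- function(pools) {
  pull <- function(mode, field, cap_only = FALSE) {
    unlist(lapply(pools, function(sl) {
      v <- sl[[mode]][[field]]
      if (cap_only) v[sl[[mode]]$cap_idx] else v
    }))
  }
  out <- list()
  for (mode in c("multi", "single")) {
    for (ms in c("stress", "strain")) {
      out[[paste("plaque", ms, mode, sep = ".")]] <-
        pull(mode, paste0("plaque_", ms))
      out[[paste("cap", ms, mode, sep = ".")]] <-
        pull(mode, paste0("plaque_", ms), cap_only = TRUE)
      out[[paste("outwall", ms, mode, sep = ".")]] <-
        pull(mode, paste0("outwall_", ms))
    }
  }
  out
}

assemble_tables <- function(per_patient) {
  tables <- list()
  for (region in c("plaque", "cap", "outwall")) {
    for (ms in c("stress", "strain")) {
      rows <- lapply(names(per_patient), function(pid) {
        pp <- per_patient[[pid]]
        vm <- pp[[paste(region, ms, "multi", sep = ".")]]
        vs <- pp[[paste(region, ms, "single", sep = ".")]]
        if (!length(vm) || !length(vs))
          return(data.frame(patient = pid, multi_max = NA_real_,
                            single_max = NA_real_, diff_max_pct = NA_real_,
                            multi_mean = NA_real_, single_mean = NA_real_,
                            diff_mean_pct = NA_real_))
        data.frame(
          patient = pid,
          multi_max = patient_max(vm), single_max = patient_max(vs),
          diff_max_pct = relative_difference(patient_max(vm),
                                             patient_max(vs)),
          multi_mean = patient_mean(vm), single_mean = patient_mean(vs),
          diff_mean_pct = relative_difference(patient_mean(vm),
                                              patient_mean(vs)))
      })
      tables[[paste(region, ms, sep = "_")]] <- do.call(rbind, rows)
    }
  }
  tables
}

#' Cohort summary of one comparison table
#'
#' Mean and sample SD of each value column across patients, plus the
#' relative difference of the cohort averages (single-layer average as
#' base) for the max and mean columns.
#'
#' @param df a comparison table with columns `multi_max`, `single_max`,
#'   `multi_mean`, `single_mean` (one row per patient; NA rows are dropped).
#' @return list with `mean`, `sd` (named length-4 vectors) and
#'   `diff_max_pct`, `diff_mean_pct` of the averages.
#' @export
summarize_comparison_table <- function(df) {
  df <- df[stats::complete.cases(df[, c("multi_max", "single_max",
                                        "multi_mean", "single_mean")]), ]
  cols <- c("multi_max", "single_max", "multi_mean", "single_mean")
  av <- vapply(df[cols], function(x) cohort_average(x), c(mean = 0, sd = 0))
  list(mean = av["mean", ], sd = av["sd", ],
       diff_max_pct = relative_difference(av["mean", "multi_max"],
                                          av["mean", "single_max"]),
       diff_mean_pct = relative_difference(av["mean", "multi_mean"],
                                           av["mean", "single_mean"]))
}

table_tests <- function(df) {
  df <- df[stats::complete.cases(df[, c("multi_max", "single_max",
                                        "multi_mean", "single_mean")]), ]
  safe_t <- function(a, b) tryCatch(paired_t(a, b), error = function(e)
    structure(list(n = length(a), mean_diff = mean(a - b), t = NA_real_,
                   df = length(a) - 1L, p_value = NA_real_,
                   ks_statistic = NA_real_, ks_p = NA_real_,
                   significant = NA, degenerate = conditionMessage(e)),
              class = "paired_comparison"))
  list(max = safe_t(df$multi_max, df$single_max),
       mean = safe_t(df$multi_mean, df$single_mean))
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$tables))
    utils::write.csv(study$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  stats_flat <- lapply(study$stats, function(s) lapply(s, unclass))
  jsonlite::write_json(list(summary = study$summary, stats = stats_flat,
                            config = study$config,
                            dropped = study$dropped),
                       file.path(out_dir, "study_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(study$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
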