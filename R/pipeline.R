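# End-to-end orchestration: generate cohort -> QC -> complete trees ->
# simulate the breathing cycle -> QCT metrics -> pooled statistics ->
# report tables, with a plain-text config format and seed provenance.

#' Pipeline run configuration
#'
#' Bundles the cohort parameters, breathing-cycle settings, solver
#' settings and PRM thresholds with the output seed.
#'
#' @param cohort A [cohort_params()] list.
#' @param steps_per_cycle Time steps per breathing cycle (default 40).
#' @param tidal_volume_L,period_s Breathing boundary conditions.
#' @param solver A [solver_config()].
#' @param interp_method Geometry schedule smoothing, `"akima"` or
#'   `"linear"`.
#' @param seed Master seed (overrides the cohort seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(), steps_per_cycle = 40L,
                       tidal_volume_L = 1.0, period_s = 4.0,
                       solver = solver_config(),
                       interp_method = c("akima", "linear"), seed = NULL) {
  interp_method <- match.arg(interp_method)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, steps_per_cycle = as.integer(steps_per_cycle),
                 tidal_volume_L = tidal_volume_L, period_s = period_s,
                 solver = solver, interp_method = interp_method),
            class = "run_config")
}

#' Read a run configuration from a plain text file
#'
#' The format is `key = value` lines under `[section]` headers
#' (`[cohort]`, `[breath]`, `[solver]`, `[thresholds]`); unknown keys are
#' an error. Values are parsed as numbers where possible.
#'
#' @param path Path to the config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(parts[1]); val <- trimws(paste(parts[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      kv[[paste(section, key, sep = ".")]] <- if (is.na(num)) val else num
    } else stop("unparseable config line: ", ln, call. = FALSE)
  }
  co <- list(); br <- list(); sv <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    switch(k,
      "cohort.n_a" = { co$n <- c(A = as.integer(v), B = 12L) },
      "cohort.n_b" = { co$n["B"] <- as.integer(v) },
      "cohort.seed" = { co$seed <- as.integer(v) },
      "cohort.voxels_per_lobe" = { co$voxels_per_lobe <- as.integer(v) },
      "cohort.points_per_segment" = { co$points_per_segment <- as.integer(v) },
      "breath.tidal_volume_L" = { br$tidal_volume_L <- v },
      "breath.period_s" = { br$period_s <- v },
      "breath.steps_per_cycle" = { br$steps_per_cycle <- as.integer(v) },
      "breath.interp_method" = { br$interp_method <- v },
      "solver.model" = { sv$model <- v },
      "solver.compliance_LcmH2O" = { sv$compliance_LcmH2O <- v },
      "solver.pedley_coef" = { sv$pedley_coef <- v },
      "thresholds.insp_hu" = { co$insp_threshold <- v },
      "thresholds.exp_hu" = { co$exp_threshold <- v },
      stop("unknown config key: ", k, call. = FALSE))
  }
  if (!is.null(co$n)) {
    # keep the default male fractions when group sizes are overridden
    defaults <- .cohort_defaults()
    frac <- defaults$n_male / defaults$n
    co$n_male <- stats::setNames(as.integer(round(frac * co$n)), names(co$n))
  }
  cohort <- do.call(cohort_params, co)
  run_config(cohort = cohort,
             steps_per_cycle = if (!is.null(br$steps_per_cycle)) br$steps_per_cycle else 40L,
             tidal_volume_L = if (!is.null(br$tidal_volume_L)) br$tidal_volume_L else 1.0,
             period_s = if (!is.null(br$period_s)) br$period_s else 4.0,
             solver = do.call(solver_config, sv),
             interp_method = if (!is.null(br$interp_method)) br$interp_method else "akima")
}

# md5 of the deparsed config, for artifact provenance
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Complete a subject's trees at both volume states
#'
#' Volume-fills the TLC tree into the subject's lobe seeds, then builds
#' the topology-matched FRC tree: resolved branches keep their FRC
#' template values, grown branches are scaled from the TLC completion by
#' the lobe's FRC/TLC mean Dave* ratio (so every branch keeps
#' TLC caliber >= FRC caliber), and grown node coordinates shrink by the
#' lung linear scale factor.
#'
#' @param subject A `subject_record`.
#' @param ... Passed to [complete_tree()] (volume-filling and diameter
#'   parameters).
#' @return The subject with `tree_tlc`/`tree_frc` replaced by completed
#'   trees and a `stats_frc`/`stats_tlc` pair attached.
#' @export
complete_subject <- function(subject, ...) {
  demo <- subject$demographics
  stats_tlc <- lobar_constriction_stats(subject$tree_tlc, demo)
  stats_frc <- lobar_constriction_stats(subject$tree_frc, demo)
  tlc <- complete_tree(subject$tree_tlc, subject$seeds, demo,
                       stats = stats_tlc, ...)
  # FRC completion shares the grown topology
  frc <- subject$tree_frc
  n_res <- nrow(frc$branches)
  new_br <- tlc$branches[-seq_len(n_res), , drop = FALSE]
  new_nd <- tlc$nodes[-seq_len(nrow(frc$nodes)), , drop = FALSE]
  s <- (subject$frc_air_L / subject$tlc_air_L)^(1 / 3)
  new_nd[, c("x", "y", "z")] <- new_nd[, c("x", "y", "z")] * s
  ratio <- stats::setNames(stats_frc$mean / stats_tlc$mean, stats_frc$lobe)
  new_br$diameter_mm <- new_br$diameter_mm * as.numeric(ratio[new_br$lobe])
  new_br$length_mm <- new_br$length_mm * s
  frc$branches <- rbind(frc$branches, new_br)
  frc$nodes <- rbind(frc$nodes, new_nd)
  idx <- match(frc$branches$parent, frc$branches$id)
  for (i in order(frc$branches$generation)) {
    if (frc$branches$resolved[i] || is.na(idx[i])) next
    frc$branches$diameter_mm[i] <- min(frc$branches$diameter_mm[i],
                                       frc$branches$diameter_mm[idx[i]])
  }
  frc <- assign_horsfield_orders(frc)
  validate_airway_tree(frc)
  subject$tree_tlc <- tlc
  subject$tree_frc <- frc
  subject$stats_tlc <- stats_tlc
  subject$stats_frc <- stats_frc
  subject
}

#' Simulate one completed subject over a breathing cycle
#'
#' @param subject A completed `subject_record` (see [complete_subject()]).
#' @param config A [run_config()].
#' @return A `pressure_solution`.
#' @export
simulate_subject <- function(subject, config = run_config()) {
  breath <- breath_config(tidal_volume_L = config$tidal_volume_L,
                          period_s = config$period_s,
                          steps_per_cycle = config$steps_per_cycle,
                          frc_volume_L = subject$frc_air_L,
                          tlc_volume_L = subject$tlc_air_L,
                          interp_method = config$interp_method)
  delta <- stats::setNames(subject$lobar_volumes$tlc_L - subject$lobar_volumes$frc_L,
                           subject$lobar_volumes$lobe)
  # within-lobe flow follows terminal conductance: lobar shares stay
  # registration-derived, but a constricted terminal draws less flow, as a
  # resistive network would impose
  simulate_breath(subject$tree_frc, subject$tree_tlc, breath, config$solver,
                  lobar_delta_L = delta, within_lobe = "conductance")
}

# one row of per-subject derived variables for the statistics family
.subject_variables <- function(subject, sim, params) {
  prm <- lobe_percentages(subject$densities,
                          insp_threshold = params$insp_threshold,
                          exp_threshold = params$exp_threshold)
  dh <- hydraulic_diameter(subject$structure$lumen_area_mm2,
                           subject$structure$lumen_perimeter_mm)
  ns <- normalize_structure(dh, subject$structure$wt_mm, subject$demographics,
                            params$wt_reference_mm)
  br_t <- subject$tree_tlc$branches; br_f <- subject$tree_frc$branches
  rk <- attr(subject$tree_tlc, "region_key")
  seg_ids <- as.integer(names(rk)[rk %in% unlist(.lobe_segments)])
  seg_d <- mean((br_t$diameter_mm[match(seg_ids, br_t$id)] +
                   br_f$diameter_mm[match(seg_ids, br_f$id)]) / 2)
  term <- terminal_branches(subject$tree_tlc)
  term_d <- mean((br_t$diameter_mm[match(term, br_t$id)] +
                    br_f$diameter_mm[match(term, br_f$id)]) / 2)
  dave_frc <- stats::setNames(subject$stats_frc$mean, subject$stats_frc$lobe)
  # pooled-lung Dave*: weighted by resolved branch count
  dave_total <- sum(subject$stats_frc$mean * subject$stats_frc$n) /
    sum(subject$stats_frc$n)
  row <- data.frame(id = subject$id, group = subject$group,
                    sex = subject$demographics$sex,
                    age = subject$demographics$age, bmi = subject$pft$bmi,
                    fev1_pre = subject$pft$fev1_pre,
                    fev1_post = subject$pft$fev1_post,
                    fvc_pre = subject$pft$fvc_pre,
                    fvc_post = subject$pft$fvc_post,
                    fev1_fvc_pre = subject$pft$fev1_fvc_pre,
                    fev1_fvc_post = subject$pft$fev1_fvc_post,
                    seg_diameter_mm = seg_d, term_diameter_mm = term_d,
                    p_alv_PI = sim$at_PI$p_alv_Pa, p_alv_PE = sim$at_PE$p_alv_Pa,
                    neg_p_pl_PI = -sim$at_PI$p_pl_Pa,
                    neg_p_pl_PE = -sim$at_PE$p_pl_Pa,
                    p_tp_PI = sim$at_PI$p_tp_Pa, p_tp_PE = sim$at_PE$p_tp_Pa,
                    workload_J = sim$workload_J, stringsAsFactors = FALSE)
  for (rg in prm$region) {
    row[[paste0("emph_", rg)]] <- prm$emph_pct[prm$region == rg]
    row[[paste0("fsad_", rg)]] <- prm$fsad_pct[prm$region == rg]
  }
  for (i in seq_along(STRUCTURE_REGIONS)) {
    row[[paste0("dh_star_", STRUCTURE_REGIONS[i])]] <- ns$dh_star[i]
    row[[paste0("wt_star_", STRUCTURE_REGIONS[i])]] <- ns$wt_star[i]
  }
  for (lb in names(dave_frc)) row[[paste0("dave_star_frc_", lb)]] <- dave_frc[[lb]]
  row$dave_star_frc_Total <- dave_total
  row
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, applies the expiration QC filter,
#' completes every subject's trees, simulates the breathing cycle,
#' derives QCT metrics, pools every two-group comparison into one
#' Benjamini-Hochberg family, and computes Spearman correlations between
#' lung-function variables and computational outputs. When `out_dir` is
#' given, report tables shaped `variable, region, group means (SD), p, Q`
#' are written as CSV along with the correlation table, the per-subject
#' variable table, and a manifest carrying the seed and a config hash.
#'
#' @param config A [run_config()] (or a path to a config file readable by
#'   [read_run_config()]).
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result`: `subjects` (per-subject
#'   variable data.frame), `report` (a `stat_report`), `excluded`
#'   (ids and reasons), `config_hash`, `seed`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  params <- config$cohort
  cohort <- generate_cohort(params)
  qc <- lapply(cohort, qc_filter)
  inc <- vapply(qc, `[[`, TRUE, "included")
  excluded <- data.frame(id = names(cohort)[!inc],
                         reason = vapply(qc[!inc], `[[`, "", "reason"),
                         stringsAsFactors = FALSE, row.names = NULL)
  cohort <- cohort[inc]
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- tryCatch(complete_subject(cohort[[i]]),
                  error = function(e) stop("tree completion failed for subject ",
                                           cohort[[i]]$id, ": ", conditionMessage(e),
                                           call. = FALSE))
    sim <- tryCatch(simulate_subject(s, config),
                    error = function(e) stop("simulation failed for subject ",
                                             s$id, ": ", conditionMessage(e),
                                             call. = FALSE))
    rows[[i]] <- .subject_variables(s, sim, params)
  }
  subjects <- do.call(rbind, rows)
  a <- subjects[subjects$group == "A", ]
  b <- subjects[subjects$group == "B", ]
  vars <- setdiff(names(subjects), c("id", "group", "sex"))
  comparisons <- do.call(rbind, lapply(vars, function(v) {
    compare_groups(a[[v]], b[[v]], variable = v)
  }))
  pft_vars <- c("fev1_pre", "fev1_post", "fev1_fvc_pre", "fev1_fvc_post")
  comp_vars <- c("p_alv_PI", "p_alv_PE", "neg_p_pl_PI", "neg_p_pl_PE",
                 "p_tp_PI", "p_tp_PE", "workload_J",
                 grep("^(fsad|emph|dave_star)", vars, value = TRUE))
  correlations <- correlation_matrix(subjects[, pft_vars], subjects[, comp_vars])
  report <- build_report(comparisons, correlations)
  result <- structure(list(subjects = subjects, report = report,
                           excluded = excluded,
                           config_hash = .config_hash(config),
                           seed = params$seed),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d subjects (%d excluded), seed %d\n",
              nrow(x$subjects), nrow(x$excluded), x$seed))
  print(x$report)
  invisible(x)
}

# split the pooled comparison table into themed report tables
.report_tables <- function(report) {
  comp <- report$comparisons
  take <- function(pattern) comp[grepl(pattern, comp$variable), ]
  list(demographics = take("^(age|bmi|fev1|fvc)"),
       prm = take("^(emph|fsad)_"),
       structure = take("^(dh_star|wt_star)_"),
       diameters = take("_diameter_mm$"),
       constriction = take("^dave_star_"),
       pressures = take("^(p_alv|neg_p_pl|p_tp|workload)"))
}

#' Write pipeline outputs to a directory
#'
#' Emits six themed report tables (demographics/lung function, PRM
#' percentages, normalized structure, airway diameters, constriction
#' indices, simulated pressures), the correlation table, the per-subject
#' variables, the exclusion list and a manifest with seed and config hash.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- .report_tables(result$report)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$report$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(result$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(result$excluded, file.path(out_dir, "excluded.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = result$seed, config_hash = result$config_hash,
                            n_subjects = nrow(result$subjects)),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
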