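#' Run an end-to-end analysis
#'
#' Orchestrates one cohort (and optionally a control cohort) through the
#' full pipeline for the requested mode, writing per-cell tables, cohort
#' summaries, test results and a run log into `output_dir`. Per-cell
#' failures (no nucleus, no spot, midplane gate) are logged and skipped
#' rather than aborting the cohort; skip counts appear in the summary.
#'
#' Modes:
#' * `"simulate"` - write a synthetic fixture set (`sim` holds
#'   [sim_config()] arguments; `sim_mode` chooses `"spots2d"` or
#'   `"paint3d"`).
#' * `"spots2d"` - segment each cell, select the midplane, partition it
#'   into `K` equal-area shells, detect the spot, apply the midplane gate
#'   (z-stacks only) and score the spot's shell.
#' * `"paint2d"` - midplane intensity profile of the territory channel
#'   across `K` shells.
#' * `"paint3d"` - 3D equal-volume partition, territory binarization and
#'   unique-shell fractions by cumulative colocalization.
#' * `"blot"` - tissue percentages and fold ratios from a band-intensity
#'   CSV.
#'
#' @param config a named list or path to a YAML file. Common fields:
#'   `mode`, `output_dir`, `seed`, `condition` (label), `input_dir`,
#'   `control_dir` (optional second cohort for statistics), mode-specific
#'   fields (`K`, `threshold`, `background`, `midplane_tol`,
#'   `min_component_size`, `sim`, `sim_mode`, `input_csv`, `fold_pairs`).
#' @return list of output artifact paths, invisibly; the main tables are
#'   also returned in `$results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("invalid config")
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("simulate", "spots2d", "paint2d", "paint3d", "blot"))
    stop("config$mode must be one of simulate/spots2d/paint2d/paint3d/blot")
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  paths <- list()
  results <- list()

  if (mode == "simulate") {
    sim_args <- if (is.null(config$sim)) list() else config$sim
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim_mode <- if (is.null(config$sim_mode)) "spots2d" else config$sim_mode
    paths$manifest <- write_fixture_set(cfg, out, mode = sim_mode)
    results$config <- cfg
  } else if (mode == "blot") {
    if (is.null(config$input_csv)) stop("config$input_csv is required")
    tab <- read_band_table(config$input_csv, background = config$background)
    pct <- tissue_percentages(tab)
    paths$percentages <- file.path(out, "tissue_percentages.csv")
    write.csv(round(pct, 6), paths$percentages)
    folds <- NULL
    if (!is.null(config$fold_pairs)) {
      folds <- do.call(rbind, lapply(config$fold_pairs, function(fp) {
        data.frame(protein = rownames(pct),
                   tissue_a = fp[[1]], tissue_b = fp[[2]],
                   fold = apply(pct, 1, tissue_fold_ratio, fp[[1]], fp[[2]]))
      }))
      paths$folds <- file.path(out, "fold_ratios.csv")
      write.csv(folds, paths$folds, row.names = FALSE)
    }
    results$percentages <- pct
    results$folds <- folds
  } else {
    if (is.null(config$input_dir)) stop("config$input_dir is required")
    res <- process_cohort(config$input_dir, mode, config)
    cond <- if (is.null(config$condition)) "test" else config$condition
    res$per_cell$condition <- cond
    paths$per_cell <- file.path(out, "per_cell.csv")
    write.csv(res$per_cell, paths$per_cell, row.names = FALSE)
    results$per_cell <- res$per_cell
    results$skipped <- res$skipped
    summary <- cohort_summary(res$per_cell, mode,
                              K = pipeline_K(mode, config),
                              n_skipped = nrow(res$skipped))
    if (!is.null(config$control_dir)) {
      ctrl <- process_cohort(config$control_dir, mode, config)
      ctrl$per_cell$condition <- "control"
      write.csv(ctrl$per_cell, file.path(out, "per_cell_control.csv"),
                row.names = FALSE)
      paths$per_cell_control <- file.path(out, "per_cell_control.csv")
      results$per_cell_control <- ctrl$per_cell
      summary <- rbind(summary,
                       cohort_summary(ctrl$per_cell, mode,
                                      K = pipeline_K(mode, config),
                                      n_skipped = nrow(ctrl$skipped)))
      test <- compare_cohorts(res$per_cell, ctrl$per_cell, mode,
                              K = pipeline_K(mode, config))
      results$test <- test
      paths$tests <- file.path(out, "tests.json")
      jsonlite::write_json(
        list(test = test$test, statistic = test$statistic,
             p_value = test$p_value, stringency = test$stringency,
             direction = test$direction, n = as.list(test$n)),
        paths$tests, auto_unbox = TRUE, digits = NA)
    }
    paths$summary <- file.path(out, "summary.csv")
    write.csv(summary, paths$summary, row.names = FALSE)
    results$summary <- summary
    if (nrow(res$skipped)) {
      paths$skipped <- file.path(out, "skipped_cells.csv")
      write.csv(res$skipped, paths$skipped, row.names = FALSE)
    }
  }
  paths$log <- write_run_log(out, config, seed)
  invisible(c(paths, list(results = results)))
}

pipeline_K <- function(mode, config) {
  if (!is.null(config$K)) as.integer(config$K)
  else if (mode == "paint3d") 6L else 5L
}

# Process every cell of a fixture directory through one analysis mode.
process_cohort <- function(dir, mode, config) {
  fx <- read_fixture_set(dir)
  K <- pipeline_K(mode, config)
  tol <- if (is.null(config$midplane_tol)) 1 else config$midplane_tol
  rows <- list(); skipped <- list()
  for (i in seq_along(fx$stacks)) {
    id <- fx$manifest$cell_id[i]
    row <- tryCatch(
      process_cell(fx$stacks[[i]], mode, K, tol, config, id),
      error = function(e) conditionMessage(e))
    if (is.character(row))
      skipped[[length(skipped) + 1L]] <- data.frame(cell_id = id,
                                                    reason = row)
    else rows[[length(rows) + 1L]] <- row
  }
  list(per_cell = if (length(rows)) do.call(rbind, rows) else
         data.frame(cell_id = integer()),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(cell_id = integer(), reason = character()))
}

process_cell <- function(stack, mode, K, tol, config, id) {
  nm <- segment_nucleus(stack, threshold = config$nuclear_threshold)
  mz <- select_midplane(nm)
  if (mode == "spots2d") {
    part <- erode_shells_2d(nm, K)
    spot <- detect_spot(stack, nm, threshold = config$spot_threshold)
    if (dim(nm$mask)[3] > 1L && !midplane_gate(spot, mz, tol))
      stop("midplane gate")
    spot <- assign_spot_shell(part, spot)
    mm <- nucleus_morphometrics(nm)
    data.frame(cell_id = id, spot_shell = spot$shell,
               spot_x = spot$x, spot_y = spot$y, spot_z = spot$z,
               midplane_z = mz, area = mm$area, longest = mm$longest,
               shortest = mm$shortest)
  } else if (mode == "paint2d") {
    part <- erode_shells_2d(nm, K)
    plane <- get_channel(stack, "territory")[, , mz + 1L]
    thr <- cell_threshold(config$threshold, plane)
    bg <- if (is.null(config$background)) "auto" else config$background
    prof <- shell_intensity_profile_2d(part, plane, threshold = thr,
                                       background = bg, cell_id = id)
    profile_row(id, prof, mz, thr)
  } else { # paint3d
    part <- erode_shells_3d(nm, K)
    vol <- get_channel(stack, "territory")
    thr <- cell_threshold(config$threshold, vol[nm$mask])
    mcs <- if (is.null(config$min_component_size)) 27L
           else as.integer(config$min_component_size)
    terr <- binarize_territory(vol, nm, threshold = thr,
                               min_component_size = mcs)
    prof <- unique_shell_fractions_3d(part, terr, cell_id = id)
    profile_row(id, prof, mz, thr)
  }
}

# Manual threshold from config, or automatic (Otsu) when "auto"/NULL.
cell_threshold <- function(threshold, values) {
  if (is.null(threshold) || identical(threshold, "auto")) {
    mx <- max(values)
    if (mx <= 0) stop("no signal")
    EBImage::otsu(EBImage::Image(as.numeric(values) / mx),
                  range = c(0, 1)) * mx
  } else as.numeric(threshold)
}

profile_row <- function(id, prof, mz, thr) {
  row <- data.frame(cell_id = id, midplane_z = mz, threshold = thr,
                    peripheral_sum = prof$peripheral_sum,
                    internal_sum = prof$internal_sum)
  for (k in seq_along(prof$fractions))
    row[[paste0("f", k)]] <- prof$fractions[k]
  row
}

cohort_summary <- function(per_cell, mode, K, n_skipped) {
  n <- nrow(per_cell)
  cond <- if (n) per_cell$condition[1] else NA_character_
  if (mode == "spots2d") {
    h <- shell_spot_histogram(per_cell$spot_shell, K)
    out <- data.frame(condition = cond, n = n, n_skipped = n_skipped)
    for (k in seq_len(K)) out[[paste0("shell", k, "_pct")]] <- h$percent[k]
    out
  } else {
    out <- data.frame(condition = cond, n = n, n_skipped = n_skipped,
                      peripheral_mean = mean(per_cell$peripheral_sum),
                      peripheral_sd = sd(per_cell$peripheral_sum),
                      internal_mean = mean(per_cell$internal_sum),
                      internal_sd = sd(per_cell$internal_sum))
    for (k in seq_len(K))
      out[[paste0("f", k, "_mean")]] <- mean(per_cell[[paste0("f", k)]])
    out
  }
}

#' Compare two analyzed cohorts
#'
#' Spot cohorts are compared with the one-tailed chi-squared test on
#' shell-1 vs shells-3+4+5 counts; territory-profile cohorts with the
#' two-sample KS test on per-cell peripheral fractions.
#'
#' @param per_cell_test,per_cell_control per-cell tables as produced by
#'   [run_pipeline()] (columns `spot_shell` or `peripheral_sum`).
#' @param mode `"spots2d"`, `"paint2d"` or `"paint3d"`.
#' @param K shell count (spot mode).
#' @return a `nucshell_test`.
#' @export
compare_cohorts <- function(per_cell_test, per_cell_control,
                            mode = "spots2d", K = 5L) {
  if (mode == "spots2d") {
    ct <- shell_spot_histogram(per_cell_test$spot_shell, K)$counts
    cc <- shell_spot_histogram(per_cell_control$spot_shell, K)$counts
    chi2_shell_test(ct, cc)
  } else {
    ks_peripheral_test(per_cell_test$peripheral_sum,
                       per_cell_control$peripheral_sum)
  }
}

write_run_log <- function(out, config, seed) {
  log <- file.path(out, "run_log.txt")
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  writeLines(c(
    sprintf("nucshell %s", as.character(utils::packageVersion("nucshell"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("mode: %s", config$mode),
    sprintf("seed: %d", seed),
    sprintf("config_md5: %s", hash),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(config), "\n")[[1]])), log)
  log
}

#' Render a human-readable summary of a pipeline run
#'
#' Writes a markdown report with per-condition shell-distribution tables
#' and test results using the conventional asterisk notation (`*` p<0.05,
#' `**` p<0.01).
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return path to `report.md`, invisibly.
#' @export
report_markdown <- function(run_dir) {
  sf <- file.path(run_dir, "summary.csv")
  if (!file.exists(sf)) stop("no pipeline outputs in run_dir")
  summary <- read.csv(sf)
  lines <- c("# Radial position analysis report", "")
  lines <- c(lines, "## Cohort summaries", "", md_table(summary), "")
  tf <- file.path(run_dir, "tests.json")
  if (file.exists(tf)) {
    tst <- jsonlite::read_json(tf)
    star <- if (tst$p_value < 0.01) "**" else if (tst$p_value < 0.05) "*"
            else ""
    lines <- c(lines, "## Statistics", "",
               sprintf("- %s: statistic %.4g, p = %.3g %s (%s, %s)",
                       tst$test, tst$statistic, tst$p_value, star,
                       tst$stringency, tst$direction), "")
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}

md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.4g", x) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
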