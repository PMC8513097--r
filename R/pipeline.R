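# Cohort orchestration: stacks -> masks -> per-cell tables -> group
# summaries, with logged (never silent) exclusions and a QC report.

#' Cohort analysis configuration
#'
#' @param input_dir cohort directory (layout of [generate_cohort()]:
#'   `group_<g>/mouse_<m>/cell_<c>.tif` with `*_soma.json` ROIs).
#' @param out_dir result directory (created).
#' @param seg_params [segmentation_params()].
#' @param rout_q_single ROUT maximum FDR (percent) applied per group and
#'   metric to single-cell values before summarizing (5 in the reproduced
#'   analysis; 10 is used there for expression-style tables).
#' @param seed seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return list of class `mg_cohort_config`.
#' @export
cohort_config <- function(input_dir, out_dir,
                          seg_params = segmentation_params(),
                          rout_q_single = 5, seed = 1L) {
  if (!dir.exists(input_dir))
    mg_stop("input directory does not exist", "mgmorph_bad_path")
  stopifnot(rout_q_single > 0, rout_q_single < 50)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 seg_params = seg_params, rout_q_single = rout_q_single,
                 seed = as.integer(seed)),
            class = "mg_cohort_config")
}

cohort_metrics <- c("volume_um3", "surface_area_um2", "ramification_index",
                    "polarity_index", "mean_intensity", "branch_count",
                    "tree_length_um", "average_branch_length_um",
                    "soma_size_um2", "mean_gray_value")

#' Run the full analysis over a cohort directory
#'
#' For every cell stack: single-cell segmentation ([segment_cell()]),
#' morphometry ([compute_morphometry()]) and soma-ROI metrics
#' ([soma_metrics()] on the maximum projection). Cells are then screened per
#' group and metric with the ROUT outlier test ([rout_outliers()]); flagged
#' cells are excluded from summaries but kept, flagged, in the per-cell
#' table. Per-stack failures are quarantined and logged, and the run
#' continues. Outputs (`per_cell.csv`, `per_mouse.csv`, `group_summary.csv`,
#' `exclusions.csv`, `run_log.json`) are deterministic given the
#' configuration and input files.
#'
#' @param config [cohort_config()].
#' @return invisibly, the result directory path.
#' @export
run_cohort <- function(config) {
  tifs <- sort(list.files(config$input_dir, pattern = "^cell_[0-9]+\\.tif$",
                          recursive = TRUE, full.names = TRUE))
  if (length(tifs) == 0)
    mg_stop("empty cohort: no cell stacks found", "mgmorph_empty_cohort")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); quarantined <- list()
  for (path in tifs) {
    rel <- sub(paste0("^", config$input_dir, "/?"), "", path)
    parts <- strsplit(rel, "/")[[1]]
    group <- sub("^group_", "", parts[1])
    mouse <- sub("^mouse_", "", parts[2])
    res <- tryCatch({
      stk <- read_stack(path)
      vox <- stack_channel(stk, "iba1")
      cm <- segment_cell(vox, stk$cal, config$seg_params)
      rec <- compute_morphometry(vox, cm, cell_id = rel)
      roi_path <- sub("\\.tif$", "_soma.json", path)
      if (file.exists(roi_path)) {
        roi <- read_roi_json(roi_path)
        sm <- soma_metrics(roi, max_project(vox))
        rec$soma_size_um2 <- sm$soma_size_um2
        rec$mean_gray_value <- sm$mean_gray_value
      } else {
        rec$soma_size_um2 <- NA_real_
        rec$mean_gray_value <- NA_real_
      }
      rec$group <- group; rec$mouse <- mouse
      rec$threshold_8bit <- cm$threshold_8bit
      rec$component_count <- cm$component_count
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantined[[length(quarantined) + 1]] <-
        data.frame(path = rel, error = conditionMessage(res))
    } else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0)
    mg_stop("every stack failed; nothing to summarize", "mgmorph_empty_cohort")
  cells <- do.call(rbind, rows)

  # ROUT outlier screen per group x metric; flagged, never silently dropped
  cells$outlier <- FALSE
  excl <- list()
  for (g in unique(cells$group)) {
    sel <- which(cells$group == g)
    for (metric in intersect(cohort_metrics, names(cells))) {
      v <- cells[[metric]][sel]
      if (sum(!is.na(v)) < 3 || sd(v, na.rm = TRUE) == 0) next
      fl <- rout_outliers(v, Q = config$rout_q_single)
      hit <- sel[which(fl)]
      if (length(hit)) {
        cells$outlier[hit] <- TRUE
        excl[[length(excl) + 1]] <- data.frame(
          cell_id = cells$cell_id[hit], group = g, metric = metric,
          value = cells[[metric]][hit],
          reason = sprintf("ROUT Q=%g%%", config$rout_q_single))
      }
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl)
                else data.frame(cell_id = character(), group = character(),
                                metric = character(), value = numeric(),
                                reason = character())

  kept <- cells[!cells$outlier, , drop = FALSE]
  per_mouse <- do.call(rbind, lapply(split(kept, kept[c("group", "mouse")], drop = TRUE),
    function(km) {
      out <- data.frame(group = km$group[1], mouse = km$mouse[1],
                        n_cells = nrow(km))
      for (metric in intersect(cohort_metrics, names(km)))
        out[[metric]] <- mean(km[[metric]], na.rm = TRUE)
      out
    }))
  group_summary <- do.call(rbind, lapply(split(kept, kept$group), function(kg) {
    do.call(rbind, lapply(intersect(cohort_metrics, names(kg)), function(metric) {
      v <- kg[[metric]][!is.na(kg[[metric]])]
      data.frame(group = kg$group[1], metric = metric,
                 n_cells = length(v), n_mice = length(unique(kg$mouse)),
                 mean = mean(v), sem = sd(v) / sqrt(length(v)),
                 median = median(v),
                 q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
    }))
  }))
  rownames(per_mouse) <- rownames(group_summary) <- NULL

  write_records(cells, file.path(config$out_dir, "per_cell.csv"))
  write_records(per_mouse, file.path(config$out_dir, "per_mouse.csv"))
  write_records(group_summary, file.path(config$out_dir, "group_summary.csv"))
  write_records(exclusions, file.path(config$out_dir, "exclusions.csv"))
  quar <- if (length(quarantined)) do.call(rbind, quarantined)
          else data.frame(path = character(), error = character())
  jsonlite::write_json(list(
    package = "mgmorph",
    version = as.character(utils::packageVersion("mgmorph")),
    seed = config$seed,
    rout_q_single = config$rout_q_single,
    seg_params = unclass(config$seg_params),
    n_cells_measured = nrow(cells),
    n_cells_outlier = sum(cells$outlier),
    n_quarantined = nrow(quar),
    quarantined = quar,
    thresholds_8bit = cells$threshold_8bit),
    file.path(config$out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(config$out_dir)
}

#' Quality-control report for a completed run
#'
#' Checks the per-cell table against the workflow expectations (at least 5
#' analyzed cells per mouse, matching the >= 5 microglia per stack design;
#' single surviving component per cell), lists the outlier exclusions and
#' the threshold provenance, and writes a human-readable `qc_report.txt`.
#' Regeneration is idempotent.
#'
#' @param result_dir directory produced by [run_cohort()].
#' @param min_cells_per_mouse expectation used for the flag.
#' @return character vector of flags (empty when clean), invisibly; the
#'   report text is written to `qc_report.txt`.
#' @export
qc_report <- function(result_dir, min_cells_per_mouse = 5L) {
  pc_path <- file.path(result_dir, "per_cell.csv")
  if (!file.exists(pc_path))
    mg_stop("missing per_cell.csv: not a completed run", "mgmorph_bad_path")
  cells <- read_records(pc_path)
  excl <- read_records(file.path(result_dir, "exclusions.csv"))
  flags <- character()
  counts <- table(paste(cells$group, cells$mouse, sep = "/"))
  low <- counts[counts < min_cells_per_mouse]
  if (length(low))
    flags <- c(flags, sprintf("mouse %s has %d cells (< %d expected)",
                              names(low), as.integer(low), min_cells_per_mouse))
  multi <- cells$component_count != 1
  if (any(multi))
    flags <- c(flags, sprintf("cell %s segmented into %d components",
                              cells$cell_id[multi], cells$component_count[multi]))
  lines <- c("mgmorph QC report",
             sprintf("cells measured: %d (%d flagged as outliers)",
                     nrow(cells), sum(cells$outlier)),
             sprintf("8-bit Huang thresholds: %s",
                     paste(sort(unique(cells$threshold_8bit)), collapse = ", ")),
             if (nrow(excl)) sprintf("outlier: %s [%s] %s = %g",
                                     excl$cell_id, excl$reason, excl$metric,
                                     excl$value) else "outliers: none",
             if (length(flags)) paste("FLAG:", flags) else "flags: none")
  writeLines(lines, file.path(result_dir, "qc_report.txt"))
  invisible(flags)
}
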