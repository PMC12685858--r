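#' Write a study report to disk
#'
#' Renders the standard result set of an embolization planning run into a
#' directory: tidy CSV tables (EEI maps per condition, cross-section flows
#' per condition, backflow fractions), a machine-readable `summary.json`
#' (stall pressure, EEI by inlet-path site at the baseline condition, the
#' inflow-invariance verdict) and, optionally, PNG figures.  The file set and
#' the JSON bytes are deterministic for fixed inputs.
#'
#' @param tree The [vascular_tree()] the sweeps were run on.
#' @param pressure_sweep A `sweep_result` from [run_pressure_sweep()].
#' @param inflow_sweep Optional `sweep_result` from [run_inflow_sweep()].
#' @param backflow Optional `backflow_report` from [run_backflow_study()].
#' @param output_dir Directory to write into (created if missing).
#' @param plots Also write PNG figures? (default TRUE).
#' @param stall_rel_threshold Cessation threshold forwarded to
#'   [find_stall_pressure()].
#' @return Invisibly, the character vector of files written.
#' @export
report <- function(tree, pressure_sweep, inflow_sweep = NULL, backflow = NULL,
                   output_dir, plots = TRUE, stall_rel_threshold = 0.01) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (is.null(pressure_sweep) || nrow(pressure_sweep$results) == 0L) {
    abort("`pressure_sweep` is empty; nothing to report.",
          class = "emboflow_precondition_error")
  }
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(sprintf("Cannot create output directory '%s'.", output_dir),
            class = "emboflow_io_error")
    }
  }
  if (file.access(output_dir, mode = 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", output_dir),
          class = "emboflow_io_error")
  }
  files <- character(0)
  emit <- function(name) {
    f <- file.path(output_dir, name)
    files <<- c(files, f)
    f
  }

  eei_tbl <- tidy(pressure_sweep, "eei")
  readr::write_csv(eei_tbl, emit("eei_maps.csv"))
  cs_tbl <- tidy(pressure_sweep, "cross_sections")
  readr::write_csv(cs_tbl, emit("cross_section_flows.csv"))
  if (!is.null(backflow)) {
    readr::write_csv(tibble::as_tibble(backflow),
                     emit("backflow_fractions.csv"))
  }

  bc <- boundary_conditions(pressure_sweep$params$inlet_flow,
                            non_target_pressure = pressure_sweep$params$non_target_pressure)
  stall <- find_stall_pressure(tree, bc, rel_threshold = stall_rel_threshold)

  base_eei <- pressure_sweep$results$eei[[1]]
  path_ids <- path_to_target(tree)
  eei_by_site <- as.list(setNames(
    base_eei$eei[match(path_ids, base_eei$segment_id)], path_ids))

  summary <- list(
    tree_hash = pressure_sweep$tree_hash,
    n_conditions = nrow(pressure_sweep$results),
    target_pressures_pa = pressure_sweep$results$target_pressure,
    stall_pressure_pa = stall,
    stall_rel_threshold = stall_rel_threshold,
    eei_by_site = eei_by_site,
    invariance_verdict = if (is.null(inflow_sweep)) NULL else
      list(max_delta_eei = inflow_sweep$invariance$max_delta_eei,
           pass = inflow_sweep$invariance$pass)
  )
  jsonlite::write_json(summary, emit("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  if (plots) {
    save_plot <- function(p, name, width = 7, height = 4.5) {
      ggplot2::ggsave(emit(name), p, width = width, height = height,
                      dpi = 150)
    }
    save_plot(autoplot(pressure_sweep), "eei_vs_pressure.png")
    cs_df <- cs_tbl
    cs_df$cross_section <- factor(cs_df$cross_section,
                                  levels = unique(cs_df$cross_section))
    p_cs <- ggplot2::ggplot(cs_df,
      ggplot2::aes(x = .data$target_pressure, y = 1e6 * .data$flow,
                   colour = .data$cross_section)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "target total pressure (Pa)",
                    y = expression(flow~(cm^3/s)),
                    colour = "cross-section",
                    title = "Cross-section flows vs target pressure") +
      ggplot2::theme_minimal()
    save_plot(p_cs, "cross_section_flows.png")
    save_plot(autoplot(pressure_sweep$results$eei[[1]], tree = tree),
              "eei_map_baseline.png")
    if (!is.null(inflow_sweep)) {
      save_plot(autoplot(inflow_sweep), "eei_inflow_invariance.png")
    }
    if (!is.null(backflow)) {
      save_plot(autoplot(backflow), "backflow_fractions.png")
      psol <- attr(backflow, "solution")
      tgt_flow <- purrr::map_dbl(psol$solutions, function(s) {
        sum(pmax(s$segments$flow[s$segments$segment_id %in%
                                   target_outlets(tree)], 0))
      })
      wav_df <- tibble::tibble(
        time = rep(psol$times, 2),
        flow_cm3s = 1e6 * c(waveform_flow(psol$waveform, psol$times),
                            tgt_flow),
        curve = rep(c("inlet", "target outlets (forward)"),
                    each = length(psol$times)))
      p_w <- ggplot2::ggplot(wav_df,
        ggplot2::aes(x = .data$time, y = .data$flow_cm3s,
                     colour = .data$curve)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = expression(flow~(cm^3/s)),
                      title = "Inlet and target outlet flow over one cycle") +
        ggplot2::theme_minimal()
      save_plot(p_w, "waveform_overlay.png")
    }
  }
  invisible(files)
}
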