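#' Target-pressure sweep
#'
#' The pressure experiment of an embolization planning study: for each
#' condition the target total pressure is distributed over the target outlets
#' in proportion to their areas (non-target outlets stay at
#' `non_target_pressure`), the steady network is solved, and the EEI map,
#' inlet-to-target cross-section flows and backflow set are recorded.
#' Below flow cessation the target-branch flow decreases strictly (and
#' exactly affinely) with the target pressure.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param pressures Strictly increasing non-negative target total pressures
#'   in Pa; the default enumerates the six standard conditions 0-5000 Pa.
#' @param inlet_flow Steady inlet flow in m^3/s (default 5e-6, i.e. 5
#'   cm^3/s).
#' @param non_target_pressure Non-target outlet pressure in Pa (default 300).
#' @return A `sweep_result` with one bundle (solution, EEI map,
#'   cross-section series, backflow set) per condition.
#' @examples
#' sweep <- run_pressure_sweep(reference_fixture())
#' tidy(sweep, "cross_sections")
#' @export
run_pressure_sweep <- function(tree,
                               pressures = c(0, 1000, 2000, 3000, 4000, 5000),
                               inlet_flow = 5e-6,
                               non_target_pressure = 300) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (any(pressures < 0) || is.unsorted(pressures, strictly = TRUE)) {
    abort("`pressures` must be non-negative and strictly increasing.",
          class = "emboflow_precondition_error")
  }
  bundles <- purrr::map(pressures, function(p) {
    bc <- boundary_conditions(inlet_flow, target_total_pressure = p,
                              non_target_pressure = non_target_pressure)
    sol <- tryCatch(solve_steady(tree, bc, check_laminar = FALSE),
                    error = function(e) {
                      abort(sprintf("Solver failed at condition %g Pa: %s",
                                    p, conditionMessage(e)),
                            class = "emboflow_solver_error")
                    })
    list(bc = bc, solution = sol, eei = compute_eei(tree, sol),
         cross_sections = cross_section_flows(tree, sol),
         backflow = detect_backflow(sol))
  })
  results <- tibble::tibble(
    condition_id = sprintf("p%05.0f", pressures),
    target_pressure = pressures,
    bc = purrr::map(bundles, "bc"),
    solution = purrr::map(bundles, "solution"),
    eei = purrr::map(bundles, "eei"),
    cross_sections = purrr::map(bundles, "cross_sections"),
    backflow = purrr::map(bundles, "backflow")
  )
  new_sweep_result(results, type = "pressure", tree = tree,
                   params = list(inlet_flow = inlet_flow,
                                 non_target_pressure = non_target_pressure))
}

#' Inlet-flow sweep and EEI invariance verdict
#'
#' The inflow experiment: solve the same tree at several multiples of a base
#' inlet flow and compare the EEI maps.  With uniform outlet pressures the
#' flow split of a linear resistance network is independent of the inlet
#' flow, so the maps coincide to numerical precision — the model's exact
#' version of the "EEI does not depend on inlet flow" null result.  Setting
#' `target_total_pressure` breaks the uniformity and the invariance verdict
#' fails, which is the expected behaviour, not an error.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param inlet_scales Dimensionless multipliers applied to `base_flow` (or
#'   to the waveform's mean).
#' @param base_flow Base steady inlet flow in m^3/s (default 5e-6).
#' @param waveform Optional [pulsatile_waveform()]; when given, each scale
#'   solves a full cycle and uses the time-averaged EEI map.
#' @param target_total_pressure Optional target total pressure (Pa); `NULL`
#'   (default) keeps all outlets at `outlet_pressure`, the configuration the
#'   invariance result requires.
#' @param outlet_pressure Uniform outlet pressure in Pa (default 300).
#' @param invariance_tol Maximum |dEEI| (percentage points) for the verdict
#'   to pass (default 1e-6).
#' @param n_steps Time samples per period for the pulsatile case.
#' @return A `sweep_result` with an `invariance` element: list with
#'   `max_delta_eei` and `pass`.
#' @export
run_inflow_sweep <- function(tree, inlet_scales = c(0.5, 1, 2),
                             base_flow = 5e-6, waveform = NULL,
                             target_total_pressure = NULL,
                             outlet_pressure = 300,
                             invariance_tol = 1e-6, n_steps = 64) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (length(inlet_scales) < 1L || any(inlet_scales <= 0)) {
    abort("`inlet_scales` must be positive.",
          class = "emboflow_precondition_error")
  }
  bundles <- purrr::map(inlet_scales, function(s) {
    if (is.null(waveform)) {
      bc <- boundary_conditions(s * base_flow,
                                target_total_pressure = target_total_pressure,
                                non_target_pressure = outlet_pressure)
      sol <- solve_steady(tree, bc, check_laminar = FALSE)
      eei <- compute_eei(tree, sol)
    } else {
      bc <- boundary_conditions(scale_waveform(waveform, s),
                                target_total_pressure = target_total_pressure,
                                non_target_pressure = outlet_pressure)
      sol <- solve_pulsatile(tree, bc, n_steps = n_steps)
      eei <- time_averaged_eei(tree, sol)
    }
    list(bc = bc, solution = sol, eei = eei)
  })
  maps <- purrr::map(bundles, "eei")
  max_delta <- 0
  if (length(maps) > 1L) {
    for (i in seq_len(length(maps) - 1L)) {
      for (j in seq(i + 1L, length(maps))) {
        both <- maps[[i]]$defined & maps[[j]]$defined
        if (any(both)) {
          max_delta <- max(max_delta,
                           max(abs(maps[[i]]$eei[both] - maps[[j]]$eei[both])))
        }
      }
    }
  }
  results <- tibble::tibble(
    condition_id = sprintf("q%g", inlet_scales),
    inlet_scale = inlet_scales,
    bc = purrr::map(bundles, "bc"),
    solution = purrr::map(bundles, "solution"),
    eei = maps
  )
  out <- new_sweep_result(results, type = "inflow", tree = tree,
                          params = list(base_flow = base_flow,
                                        outlet_pressure = outlet_pressure,
                                        target_total_pressure = target_total_pressure))
  out$invariance <- list(max_delta_eei = max_delta,
                         pass = max_delta < invariance_tol)
  out
}

#' Pulsatile backflow study
#'
#' Solves a full pulsatile cycle with the requested target total pressure and
#' reports, for every segment, the fraction of the cycle during which its
#' flow is retrograde.  Retrograde episodes in the target branch appear
#' exactly when the target pressure exceeds the instantaneous stall pressure
#' at the waveform minimum (reported in the attributes as
#' `stall_at_min`/`stall_at_max`, zero-flow convention), the network
#' surrogate for reflux-mediated non-target embolization risk.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param waveform A [pulsatile_waveform()].
#' @param target_pressure Target total pressure in Pa.
#' @param non_target_pressure Non-target outlet pressure in Pa (default 300).
#' @param n_steps,n_periods Time discretisation (defaults 64 x 1).
#' @param tolerance Retrograde flow threshold in m^3/s (default 1e-12).
#' @return A `backflow_report` tibble: `segment_id`, `is_target_member`,
#'   `retrograde_fraction`; attributes carry the instantaneous stall range
#'   and the pulsatile solution.
#' @export
run_backflow_study <- function(tree, waveform, target_pressure,
                               non_target_pressure = 300,
                               n_steps = 64, n_periods = 1,
                               tolerance = 1e-12) {
  stopifnot(inherits(tree, "vascular_tree"),
            inherits(waveform, "pulsatile_waveform"))
  bc <- boundary_conditions(waveform,
                            target_total_pressure = target_pressure,
                            non_target_pressure = non_target_pressure)
  psol <- solve_pulsatile(tree, bc, n_steps = n_steps, n_periods = n_periods)
  q <- waveform_flow(waveform, psol$times)

  stall_at <- function(flow) {
    bcq <- boundary_conditions(flow, non_target_pressure = non_target_pressure)
    analytic_stall_pressure(tree, bcq, rel_threshold = 0)
  }
  flow_mat <- vapply(psol$solutions, function(s) s$segments$flow,
                     numeric(nrow(tree$segments)))
  retro_frac <- rowMeans(flow_mat < -tolerance)

  structure(
    tibble::tibble(segment_id = tree$segments$segment_id,
                   is_target_member = tree$segments$is_target_member,
                   retrograde_fraction = unname(retro_frac)),
    class = c("backflow_report", "tbl_df", "tbl", "data.frame"),
    target_pressure = target_pressure,
    stall_at_min = stall_at(min(q)),
    stall_at_max = stall_at(max(q)),
    solution = psol
  )
}

new_sweep_result <- function(results, type, tree, params) {
  structure(list(results = results, type = type, tree_hash = tree_hash(tree),
                 params = params),
            class = "sweep_result")
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep, %d condition(s)\n", x$type,
              nrow(x$results)))
  if (!is.null(x$invariance)) {
    cat(sprintf("  EEI invariance: max |dEEI| = %.3g pp (%s)\n",
                x$invariance$max_delta_eei,
                if (x$invariance$pass) "pass" else "fail"))
  }
  invisible(x)
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result`.
#' @param what One of `"eei"`, `"cross_sections"` (pressure sweeps only) or
#'   `"flows"`: which per-condition table to unnest.
#' @param ... Unused.
#' @return A long tibble with one row per condition x segment.
#' @export
tidy.sweep_result <- function(x, what = c("eei", "cross_sections", "flows"),
                              ...) {
  what <- match.arg(what)
  cond_cols <- intersect(c("condition_id", "target_pressure", "inlet_scale"),
                         names(x$results))
  pick <- switch(what,
    eei = function(b) tibble::as_tibble(b),
    cross_sections = function(b) tibble::as_tibble(b),
    flows = function(b) {
      if (inherits(b, "pulsatile_solution")) tidy(b) else tidy(b)
    })
  col <- switch(what, eei = "eei", cross_sections = "cross_sections",
                flows = "solution")
  if (!col %in% names(x$results)) {
    abort(sprintf("This sweep has no '%s' component.", what),
          class = "emboflow_precondition_error")
  }
  purrr::map_dfr(seq_len(nrow(x$results)), function(i) {
    dplyr::bind_cols(x$results[i, cond_cols],
                     pick(x$results[[col]][[i]]))
  })
}

#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    n_conditions = nrow(x$results),
    tree_hash = x$tree_hash,
    invariance_max_delta_eei = if (is.null(x$invariance)) NA_real_
                               else x$invariance$max_delta_eei
  )
}

#' @export
autoplot.sweep_result <- function(object, site = NULL, ...) {
  if (identical(object$type, "pressure")) {
    df <- tidy(object, "eei")
    path_ids <- unique(tidy(object, "cross_sections")$segment_id)
    if (is.null(site)) site <- path_ids
    df <- df[df$segment_id %in% site & df$defined, ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$target_pressure,
                                     y = .data$eei,
                                     colour = .data$segment_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "target total pressure (Pa)", y = "EEI (%)",
                    colour = "injection site",
                    title = "EEI vs target outlet pressure") +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object, "eei")
    df <- df[df$defined, ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$segment_id, y = .data$eei,
                                     colour = factor(.data$inlet_scale),
                                     group = factor(.data$inlet_scale))) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "segment", y = "EEI (%)", colour = "inlet scale",
                    title = "EEI map across inlet flow scales") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         size = 6))
  }
}

#' @export
autoplot.cross_section_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cross_section <- factor(df$cross_section, levels = df$cross_section)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cross_section,
                                   y = 1e6 * .data$flow, group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cross-section (inlet to target)",
                  y = expression(flow~(cm^3/s)),
                  title = "Flow along the inlet-to-target path") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.backflow_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$retrograde_fraction > 0 | df$is_target_member, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment_id,
                                   y = .data$retrograde_fraction,
                                   fill = .data$is_target_member)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "segment", y = "fraction of cycle retrograde",
                  fill = "target member",
                  title = sprintf("Backflow under pulsatile inflow (target pressure %g Pa)",
                                  attr(object, "target_pressure"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
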