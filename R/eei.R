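#' Embolization efficiency index per segment
#'
#' The EEI of a candidate injection site is the percentage of the flow
#' passing the site that reaches the designated target outlets:
#' `EEI = 100 * sum(Q_target) / Q_total`, where `Q_target` sums the flows of
#' target outlets downstream of the site (retrograde outlet flows are clamped
#' to zero in the numerator: an embolic agent cannot be delivered against the
#' flow) and `Q_total` is the flow through the site itself.
#'
#' Sites with no forward carrier flow (`Q_total <= tolerance`) are reported
#' as *undefined* (`NA` with `defined = FALSE`), distinct from EEI = 0; this
#' keeps maps clean near flow cessation.  Defined values are clamped to
#' [0, 100].
#'
#' @param tree A [vascular_tree()] with a designated target branch.
#' @param solution A `flow_solution` computed on `tree`.
#' @param tolerance Minimum forward carrier flow in m^3/s for a site to be
#'   evaluable (default 1e-12).
#' @return An `eei_map`: a tibble with `segment_id`, `eei` (percent) and
#'   `defined`.
#' @examples
#' tree <- generate_tree(tree_gen_config(4, 1, 2, random_seed = 1))
#' sol <- solve_steady(tree, boundary_conditions(5e-6))
#' compute_eei(tree, sol)
#' @export
compute_eei <- function(tree, solution, tolerance = 1e-12) {
  check_solution_tree(solution, tree)
  flows <- setNames(solution$segments$flow, solution$segments$segment_id)
  eei_from_flows(tree, flows, tolerance, time_label = "steady")
}

eei_from_flows <- function(tree, flows, tolerance, time_label) {
  if (is.null(tree$target_branch_id)) {
    abort("Tree has no designated target branch; EEI is undefined.",
          class = "emboflow_precondition_error")
  }
  seg <- tree$segments
  tgt_leaves <- target_outlets(tree)
  # accumulate clamped target-outlet flow up the tree (deepest first)
  contrib <- setNames(numeric(nrow(seg)), seg$segment_id)
  contrib[tgt_leaves] <- pmax(flows[tgt_leaves], 0)
  ord <- seg$segment_id[order(seg$depth_level, decreasing = TRUE)]
  parent <- setNames(seg$parent_id, seg$segment_id)
  for (id in ord) {
    p <- parent[id]
    if (!is.na(p)) contrib[p] <- contrib[p] + contrib[id]
  }
  q <- flows[seg$segment_id]
  defined <- q > tolerance
  eei <- ifelse(defined,
                pmin(100, pmax(0, 100 * contrib[seg$segment_id] / q)),
                NA_real_)
  structure(
    tibble::tibble(segment_id = seg$segment_id, eei = unname(eei),
                   defined = unname(defined)),
    class = c("eei_map", "tbl_df", "tbl", "data.frame"),
    time = time_label, tree_hash = tree_hash(tree)
  )
}

#' Time-averaged EEI over a pulsatile cycle
#'
#' EEI computed from period-integrated flows:
#' `100 * integral(Q_target) / integral(Q_total)`, using the mean of the
#' uniformly spaced quasi-steady samples.  With uniform outlet pressures the
#' flow split is constant in time, so the time-averaged map equals the
#' instantaneous map at every step.
#'
#' @param tree A [vascular_tree()].
#' @param pulsatile A `pulsatile_solution` covering at least one full period.
#' @param tolerance As in [compute_eei()].
#' @return An `eei_map`.
#' @export
time_averaged_eei <- function(tree, pulsatile, tolerance = 1e-12) {
  if (!inherits(pulsatile, "pulsatile_solution") ||
      length(pulsatile$solutions) == 0L) {
    abort("`pulsatile` must be a non-empty pulsatile_solution.",
          class = "emboflow_precondition_error")
  }
  check_solution_tree(pulsatile$solutions[[1]], tree)
  flow_mat <- vapply(pulsatile$solutions, function(s) s$segments$flow,
                     numeric(nrow(tree$segments)))
  flows <- setNames(rowMeans(flow_mat),
                    pulsatile$solutions[[1]]$segments$segment_id)
  eei_from_flows(tree, flows, tolerance, time_label = "time-averaged")
}

#' Flows along the inlet-to-target path
#'
#' The monitoring cross-sections of an embolization study sit at the midpoint
#' of each branch on the unique path from the inlet to the target branch; in
#' the 0D network each cross-section's flow is simply its segment's flow.
#' Labels run CS-1 (inlet) to CS-k (target branch) in path order.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param solution A `flow_solution` on `tree`.
#' @return A `cross_section_series` tibble: `cross_section`, `segment_id`,
#'   `flow` (m^3/s).
#' @export
cross_section_flows <- function(tree, solution) {
  check_solution_tree(solution, tree)
  path <- path_to_target(tree)
  flows <- setNames(solution$segments$flow, solution$segments$segment_id)
  structure(
    tibble::tibble(cross_section = sprintf("CS-%d", seq_along(path)),
                   segment_id = path,
                   flow = unname(flows[path])),
    class = c("cross_section_series", "tbl_df", "tbl", "data.frame")
  )
}

#' Linear fit of EEI against target outlet pressure
#'
#' Least-squares line through the (target total pressure, EEI at `site`)
#' points of a pressure sweep.  In the linear network the inlet-site EEI is
#' exactly affine in the target pressure below flow cessation, so residuals
#' there sit at solver tolerance; at sites deeper on the path the carrier
#' flow itself varies with pressure and small curvature appears.  The slope
#' is negative for sites upstream of the target branch.
#'
#' @param sweep A pressure-sweep `sweep_result` from [run_pressure_sweep()].
#' @param site Segment id of the candidate injection site.
#' @return A one-row tibble: `site`, `slope` (percent per Pa), `intercept`
#'   (percent), `max_abs_residual`, `n_conditions`.
#' @export
eei_pressure_fit <- function(sweep, site) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!identical(sweep$type, "pressure")) {
    abort("`sweep` must come from run_pressure_sweep().",
          class = "emboflow_precondition_error")
  }
  df <- purrr::map2_dfr(sweep$results$target_pressure, sweep$results$eei,
                        function(p, m) {
    row <- m[m$segment_id == site, ]
    if (nrow(row) == 0L) {
      abort(sprintf("Site '%s' is not a segment of the sweep's tree.", site),
            class = "emboflow_precondition_error")
    }
    tibble::tibble(pressure = p, eei = row$eei, defined = row$defined)
  })
  df <- df[df$defined, ]
  if (nrow(df) < 3L) {
    abort(sprintf("EEI at site '%s' is defined under %d sweep condition(s); at least 3 below flow cessation are needed for a fit.",
                  site, nrow(df)),
          class = "emboflow_precondition_error")
  }
  fit <- lm(eei ~ pressure, data = df)
  tibble::tibble(site = site,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 max_abs_residual = max(abs(stats::residuals(fit))),
                 n_conditions = nrow(df))
}

#' @export
tidy.eei_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
autoplot.eei_map <- function(object, tree = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(tree)) {
    df <- dplyr::left_join(df,
                           tree$segments[c("segment_id", "depth_level")],
                           by = "segment_id")
    df$segment_id <- factor(df$segment_id,
                            levels = df$segment_id[order(df$depth_level,
                                                         df$segment_id)])
  }
  ggplot2::ggplot(df[df$defined, ],
                  ggplot2::aes(x = .data$segment_id, y = .data$eei,
                               fill = .data$eei)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "EEI (%)") +
    ggplot2::labs(x = "segment (injection site)", y = "EEI (%)",
                  title = "Embolization efficiency index by injection site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
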