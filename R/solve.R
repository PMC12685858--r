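#' Poiseuille resistance of a cylindrical segment
#'
#' Hydraulic resistance of fully developed laminar flow in a rigid cylinder,
#' `R = 8 mu L / (pi r^4)`.  This is the laminar reduced-order closure the
#' whole network model rests on.
#'
#' @param length Segment length in m (> 0); vectorised.
#' @param radius Segment radius in m (> 0); vectorised.
#' @param viscosity Dynamic viscosity in Pa.s (> 0).
#' @return Resistance in Pa.s/m^3.
#' @examples
#' segment_resistance(0.01, 0.001, 0.0035)  # 8.9127e7
#' @export
segment_resistance <- function(length, radius, viscosity) {
  if (any(!is.finite(length) | length <= 0) ||
      any(!is.finite(radius) | radius <= 0) ||
      any(!is.finite(viscosity) | viscosity <= 0)) {
    abort("length, radius and viscosity must all be finite and > 0.",
          class = "emboflow_domain_error")
  }
  8 * viscosity * length / (pi * radius^4)
}

#' Solve steady laminar network flow
#'
#' Solves the linear Poiseuille resistance network exactly: Kirchhoff's
#' current law holds at every junction (mass conservation), each segment
#' carries flow `(P_upstream - P_downstream) / R_segment`, the inlet node
#' receives the prescribed volumetric flow, and outlet (leaf) pressures are
#' Dirichlet conditions.  Junction pressures are continuous with zero
#' junction loss.  The sparse symmetric positive-definite system is solved
#' with a Cholesky factorisation.
#'
#' Per-segment velocity `Q / (pi r^2)` and Reynolds number
#' `4 rho |Q| / (pi mu D)` are attached to the solution; a warning is
#' emitted if any segment exceeds Re = 2300, outside the laminar regime the
#' model is valid for.
#'
#' @param tree A [vascular_tree()].
#' @param bc A [boundary_conditions()] with a steady (scalar) inlet flow;
#'   expanded automatically against `tree`.
#' @param time Time stamp to record on the solution (0 for steady).
#' @param check_laminar Emit the Re > 2300 warning? (default TRUE).
#' @return A `flow_solution`: signed per-segment flows (positive = away from
#'   the inlet), node pressures, velocities and Reynolds numbers.
#' @examples
#' tree <- generate_tree(tree_gen_config(4, 1, 2, random_seed = 1))
#' sol <- solve_steady(tree, boundary_conditions(5e-6))
#' tidy(sol)
#' @export
solve_steady <- function(tree, bc, time = 0, check_laminar = TRUE) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (!inherits(bc, "boundary_conditions")) {
    abort("`bc` must be a boundary_conditions object.",
          class = "emboflow_precondition_error")
  }
  if (inherits(bc$inlet_flow, "pulsatile_waveform")) {
    abort("`bc` has a pulsatile inlet; use solve_pulsatile().",
          class = "emboflow_precondition_error")
  }
  if (!isTRUE(bc$expanded)) bc <- expand_boundary_conditions(bc, tree)

  seg <- tree$segments
  g <- 1 / segment_resistance(seg$length, seg$radius, tree$fluid$viscosity)
  up_node <- ifelse(is.na(seg$parent_id), ".inlet", seg$parent_id)
  down_node <- seg$segment_id
  is_leaf <- !(seg$segment_id %in% seg$parent_id)

  nodes <- c(".inlet", down_node)
  ni <- match(up_node, nodes)
  nj <- match(down_node, nodes)
  nn <- length(nodes)
  lap <- Matrix::sparseMatrix(
    i = c(ni, nj, ni, nj), j = c(ni, nj, nj, ni),
    x = c(g, g, -g, -g), dims = c(nn, nn))

  known <- match(down_node[is_leaf], nodes)
  unknown <- setdiff(seq_len(nn), known)
  p_known <- unname(bc$outlet_pressures[down_node[is_leaf]])
  q <- numeric(nn)
  q[1] <- bc$inlet_flow  # node 1 is .inlet

  rhs <- q[unknown] - as.numeric(lap[unknown, known, drop = FALSE] %*% p_known)
  p_unknown <- tryCatch(
    as.numeric(Matrix::solve(lap[unknown, unknown, drop = FALSE], rhs)),
    error = function(e) {
      abort(sprintf("Singular network system (degenerate geometry): %s",
                    conditionMessage(e)),
            class = "emboflow_solver_error")
    })

  pressures <- numeric(nn)
  pressures[known] <- p_known
  pressures[unknown] <- p_unknown
  names(pressures) <- nodes

  flow <- g * (pressures[ni] - pressures[nj])
  velocity <- flow / (pi * seg$radius^2)
  reynolds <- 4 * tree$fluid$density * abs(flow) /
    (pi * tree$fluid$viscosity * 2 * seg$radius)

  # mass-conservation residual at each internal junction, relative to the
  # inlet flow scale
  resid <- 0
  scale <- max(abs(bc$inlet_flow), max(abs(flow)), 1e-300)
  fl <- setNames(flow, seg$segment_id)
  for (id in seg$segment_id[!is_leaf]) {
    kids <- seg$segment_id[!is.na(seg$parent_id) & seg$parent_id == id]
    resid <- max(resid, abs(fl[id] - sum(fl[kids])) / scale)
  }

  if (check_laminar && any(reynolds > 2300)) {
    warn(sprintf("Maximum segment Reynolds number %.0f exceeds 2300; the laminar network model is outside its validity regime.",
                 max(reynolds)))
  }

  structure(list(
    time = time,
    node_pressures = tibble::tibble(node_id = nodes,
                                    pressure = unname(pressures)),
    segments = tibble::tibble(segment_id = seg$segment_id,
                              flow = unname(flow),
                              velocity = unname(velocity),
                              reynolds = unname(reynolds)),
    inlet_flow = bc$inlet_flow,
    max_mass_residual = resid,
    tree_hash = tree_hash(tree)
  ), class = "flow_solution")
}

#' Solve quasi-steady pulsatile network flow
#'
#' Treats pulsatile inflow quasi-steadily: one steady solve per time sample
#' with the instantaneous inlet flow (no inertance or compliance, consistent
#' with a flow-ratio quantity like the EEI).  Samples are the `n_steps`
#' left endpoints of each period, so harmonic waveforms time-average exactly
#' to their mean.
#'
#' @param tree A [vascular_tree()].
#' @param bc A [boundary_conditions()] whose `inlet_flow` is a
#'   [pulsatile_waveform()].
#' @param n_steps Time samples per period (>= 16).
#' @param n_periods Number of periods to simulate.
#' @return A `pulsatile_solution`: a list of `flow_solution`s plus the sample
#'   times and waveform.
#' @export
solve_pulsatile <- function(tree, bc, n_steps = 64, n_periods = 1) {
  stopifnot(inherits(tree, "vascular_tree"))
  wf <- bc$inlet_flow
  if (!inherits(wf, "pulsatile_waveform")) {
    abort("`bc$inlet_flow` must be a pulsatile_waveform; use solve_steady() for steady inflow.",
          class = "emboflow_precondition_error")
  }
  if (n_steps < 16) {
    abort("n_steps must be >= 16.", class = "emboflow_precondition_error")
  }
  bc <- expand_boundary_conditions(bc, tree)
  times <- (seq_len(n_steps * n_periods) - 1) * wf$period / n_steps
  q <- waveform_flow(wf, times)
  sols <- purrr::map2(times, q, function(t, qq) {
    bct <- bc
    bct$inlet_flow <- qq
    solve_steady(tree, bct, time = t, check_laminar = FALSE)
  })
  max_re <- max(purrr::map_dbl(sols, ~ max(.x$segments$reynolds)))
  if (max_re > 2300) {
    warn(sprintf("Maximum segment Reynolds number %.0f exceeds 2300 during the cycle; the laminar network model is outside its validity regime.",
                 max_re))
  }
  structure(list(solutions = sols, times = times, waveform = wf,
                 n_steps = n_steps, n_periods = n_periods,
                 tree_hash = tree_hash(tree)),
            class = "pulsatile_solution")
}

#' Per-segment Reynolds numbers
#'
#' `Re = 4 rho |Q| / (pi mu D)` with `D = 2 r`; equivalently
#' `rho v D / mu` with the segment mean velocity `v = Q / (pi r^2)`.
#'
#' @param solution A `flow_solution`.
#' @param tree The tree the solution was computed on.
#' @return A tibble with `segment_id` and `reynolds`.
#' @export
reynolds <- function(solution, tree) {
  check_solution_tree(solution, tree)
  r <- setNames(tree$segments$radius, tree$segments$segment_id)
  q <- setNames(solution$segments$flow, solution$segments$segment_id)
  re <- 4 * tree$fluid$density * abs(q) /
    (pi * tree$fluid$viscosity * 2 * r[names(q)])
  tibble::tibble(segment_id = names(q), reynolds = unname(re))
}

check_solution_tree <- function(solution, tree) {
  if (!identical(solution$tree_hash, tree_hash(tree))) {
    abort("Solution was not computed on this tree (hash mismatch).",
          class = "emboflow_precondition_error")
  }
  invisible(TRUE)
}

#' Detect retrograde (backflow) segments
#'
#' Returns every (segment, time) pair whose signed flow is below
#' `-tolerance`, i.e. directed back toward the inlet.  In a passive tree with
#' uniform outlet pressures and positive inflow the set is empty; elevated
#' target outlet pressure can reverse target-branch segments, the network
#' surrogate for embolic reflux risk.
#'
#' @param x A `flow_solution` or `pulsatile_solution`.
#' @param tolerance Absolute flow threshold in m^3/s (default 1e-12).
#' @return A tibble with `segment_id`, `time` and `flow` (m^3/s), one row per
#'   retrograde segment-time pair.
#' @export
detect_backflow <- function(x, tolerance = 1e-12) {
  sols <- if (inherits(x, "pulsatile_solution")) x$solutions
          else if (inherits(x, "flow_solution")) list(x)
          else abort("`x` must be a flow_solution or pulsatile_solution.",
                     class = "emboflow_precondition_error")
  purrr::map_dfr(sols, function(s) {
    retro <- s$segments$flow < -tolerance
    tibble::tibble(segment_id = s$segments$segment_id[retro],
                   time = s$time,
                   flow = s$segments$flow[retro])
  })
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> t = %g s, inlet %.3g cm^3/s, %d segments, max Re %.0f\n",
              x$time, 1e6 * x$inlet_flow, nrow(x$segments),
              max(x$segments$reynolds)))
  invisible(x)
}

#' @export
tidy.flow_solution <- function(x, ...) {
  dplyr::mutate(x$segments, time = x$time, .before = 1)
}

#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    time = x$time,
    inlet_flow = x$inlet_flow,
    n_segments = nrow(x$segments),
    max_reynolds = max(x$segments$reynolds),
    max_mass_residual = x$max_mass_residual,
    n_retrograde = sum(x$segments$flow < -1e-12)
  )
}

#' @exportS3Method base::print
print.pulsatile_solution <- function(x, ...) {
  cat(sprintf("<pulsatile_solution> %d steps x %d period(s) of %g s\n",
              x$n_steps, x$n_periods, x$waveform$period))
  invisible(x)
}

#' @export
tidy.pulsatile_solution <- function(x, ...) {
  purrr::map_dfr(x$solutions, tidy)
}
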