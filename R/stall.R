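#' Target-branch flow under a given target total pressure
#'
#' Convenience wrapper: solves the steady network with
#' `target_total_pressure = pressure` and returns the signed flow through the
#' target branch.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param bc A [boundary_conditions()] providing the inlet flow and
#'   non-target pressure.
#' @param pressure Target total pressure in Pa.
#' @return Flow in m^3/s.
#' @export
target_branch_flow <- function(tree, bc, pressure) {
  bc$target_total_pressure <- pressure
  bc$outlet_pressures <- NULL
  bc$expanded <- FALSE
  sol <- solve_steady(tree, bc, check_laminar = FALSE)
  sol$segments$flow[sol$segments$segment_id == tree$target_branch_id]
}

#' Flow-cessation (stall) pressure by bisection
#'
#' Finds the target outlet total pressure at which the target-branch flow
#' falls to `rel_threshold` times its value at 0 Pa ("flow approaches 0"),
#' by bisection to within `tol` pascals.  The result is cross-checked against
#' the closed-form [analytic_stall_pressure()] (exact by linearity of the
#' network); a discrepancy beyond 2 Pa raises a warning.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param bc A [boundary_conditions()] with a steady inlet flow; its
#'   `target_total_pressure` is ignored (it is the variable being solved
#'   for).
#' @param rel_threshold Fraction of the 0 Pa baseline flow defining
#'   cessation, in [0, 1) (default 0.01).
#' @param tol Bisection tolerance in Pa (default 1).
#' @param max_pressure Upper limit for bracket expansion (default 1e7 Pa).
#' @return Stall pressure in Pa.
#' @examples
#' tree <- reference_fixture()
#' find_stall_pressure(tree, boundary_conditions(5e-6))  # ~5000 Pa
#' @export
find_stall_pressure <- function(tree, bc, rel_threshold = 0.01, tol = 1,
                                max_pressure = 1e7) {
  if (!is.numeric(rel_threshold) || rel_threshold < 0 || rel_threshold >= 1) {
    abort("rel_threshold must lie in [0, 1).",
          class = "emboflow_precondition_error")
  }
  q0 <- target_branch_flow(tree, bc, 0)
  if (q0 <= 0) {
    abort("Baseline (0 Pa) target-branch flow is not positive; stall pressure is undefined.",
          class = "emboflow_precondition_error")
  }
  thr <- rel_threshold * q0
  f <- function(p) target_branch_flow(tree, bc, p) - thr

  lo <- 0
  hi <- min(1000, max_pressure)
  while (f(hi) > 0) {
    if (hi >= max_pressure) {
      abort(sprintf("Stall bracket not found below %g Pa (flow there is still %.3g cm^3/s above threshold).",
                    max_pressure, 1e6 * f(hi)),
            class = "emboflow_solver_error")
    }
    lo <- hi
    hi <- min(hi * 2, max_pressure)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  p_star <- (lo + hi) / 2

  p_analytic <- analytic_stall_pressure(tree, bc, rel_threshold)
  if (abs(p_star - p_analytic) > 2) {
    warn(sprintf("Bisection stall (%.2f Pa) and analytic stall (%.2f Pa) disagree by more than 2 Pa.",
                 p_star, p_analytic))
  }
  p_star
}

#' Closed-form stall pressure from network linearity
#'
#' The target-branch flow is affine in the target total pressure,
#' `Q(P) = Q0 - c P` (superposition in a linear resistance network), so the
#' pressure at which it reaches `rel_threshold * Q0` is
#' `(1 - rel_threshold) * Q0 / c`.  `Q0` and `c` come from two exact linear
#' solves (at 0 Pa and a probe pressure).  With `rel_threshold = 0` this is
#' the true zero-flow stall; for a two-outlet network it reduces to
#' `P_nt + Q_in * R_nt` (non-target outlet pressure plus inlet flow times
#' non-target path resistance).
#'
#' @inheritParams find_stall_pressure
#' @param probe_pressure Second operating point used to measure the slope
#'   (default 1000 Pa).
#' @return Stall pressure in Pa.
#' @export
analytic_stall_pressure <- function(tree, bc, rel_threshold = 0,
                                    probe_pressure = 1000) {
  q0 <- target_branch_flow(tree, bc, 0)
  if (q0 <= 0) {
    abort("Baseline (0 Pa) target-branch flow is not positive; stall pressure is undefined.",
          class = "emboflow_precondition_error")
  }
  q1 <- target_branch_flow(tree, bc, probe_pressure)
  slope <- (q0 - q1) / probe_pressure
  if (slope <= 0) {
    abort("Target-branch flow does not decrease with target pressure; degenerate network.",
          class = "emboflow_solver_error")
  }
  (1 - rel_threshold) * q0 / slope
}

#' Calibrate peripheral resistance to a requested stall pressure
#'
#' Applies one global multiplicative scale to the radii of the *non-target
#' terminal* (outlet) segments — leaving the target subtree and the tree's
#' topology untouched, so the EEI geometry is unchanged — such that the
#' tree's flow-cessation pressure equals `desired_stall`.  The scale is found
#' by one-dimensional root finding on [analytic_stall_pressure()] (exact by
#' network linearity) and verified against the bisection
#' [find_stall_pressure()] to within `tol`.
#'
#' Shrinking peripheral radii raises non-target resistance and hence the
#' junction pressure the target pressure must overcome, so the stall pressure
#' is monotone decreasing in the scale and any stall above the non-target
#' outlet pressure floor is reachable.
#'
#' @param tree A [vascular_tree()] with a target branch.
#' @param bc A [boundary_conditions()] with a steady inlet flow.
#' @param desired_stall Requested stall pressure in Pa (must exceed the
#'   non-target outlet pressure).
#' @param rel_threshold Cessation threshold, as in [find_stall_pressure()].
#' @param tol Verification tolerance in Pa (default 1).
#' @param scale_bracket Initial search interval for the radius scale.
#' @return The calibrated `vascular_tree`, with the applied scale in
#'   attribute `"calibration_scale"`.
#' @export
calibrate_stall_pressure <- function(tree, bc, desired_stall,
                                     rel_threshold = 0.01, tol = 1,
                                     scale_bracket = c(0.01, 100)) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (desired_stall <= bc$non_target_pressure) {
    abort(sprintf("desired_stall (%g Pa) must exceed the non-target outlet pressure (%g Pa).",
                  desired_stall, bc$non_target_pressure),
          class = "emboflow_calibration_error")
  }
  nt_leaves <- setdiff(tree_outlets(tree), target_outlets(tree))
  if (length(nt_leaves) == 0L) {
    abort("Tree has no non-target outlets to calibrate.",
          class = "emboflow_calibration_error")
  }

  scaled <- function(s) {
    tr <- tree
    idx <- tr$segments$segment_id %in% nt_leaves
    tr$segments$radius[idx] <- tr$segments$radius[idx] * s
    # rebuild to re-validate; geometry edits keep topology so this is cheap
    vascular_tree(tr$segments[c("segment_id", "parent_id", "length",
                                "radius", "label")],
                  target_branch_id = tr$target_branch_id, fluid = tr$fluid)
  }
  f <- function(log_s) {
    analytic_stall_pressure(scaled(exp(log_s)), bc, rel_threshold) -
      desired_stall
  }

  lo <- log(scale_bracket[1])
  hi <- log(scale_bracket[2])
  flo <- f(lo)
  fhi <- f(hi)
  if (flo * fhi > 0) {
    abort(sprintf("Requested stall %g Pa is not bracketed by radius scales [%g, %g]: stall(%g) = %.1f Pa, stall(%g) = %.1f Pa.",
                  desired_stall, scale_bracket[1], scale_bracket[2],
                  scale_bracket[1], flo + desired_stall,
                  scale_bracket[2], fhi + desired_stall),
          class = "emboflow_calibration_error")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)
  s_star <- exp(root$root)
  out <- scaled(s_star)

  achieved <- find_stall_pressure(out, bc, rel_threshold, tol = min(tol, 1) / 2)
  if (abs(achieved - desired_stall) > tol) {
    warn(sprintf("Calibration verification: bisection stall %.2f Pa differs from requested %.2f Pa by more than %g Pa.",
                 achieved, desired_stall, tol))
  }
  attr(out, "calibration_scale") <- s_star
  out
}
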