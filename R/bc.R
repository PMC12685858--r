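#' Boundary conditions for a network solve
#'
#' Prescribes the inlet volumetric flow (steady scalar or
#' [pulsatile_waveform()]) and the outlet pressures.  Outlet pressures can be
#' given three ways, mirroring common embolization study designs:
#'
#' * the default: every outlet at `non_target_pressure` (300 Pa);
#' * a *target total pressure*: `target_total_pressure` is distributed over
#'   the target outlets in direct proportion to their cross-sectional areas
#'   (see [distribute_outlet_pressure()]) while non-target outlets stay at
#'   `non_target_pressure`;
#' * an explicit `outlet_pressures` map (named vector, one entry per outlet).
#'
#' The object is tree-agnostic until [expand_boundary_conditions()] resolves
#' it against a specific [vascular_tree()]; solver entry points do this
#' automatically.
#'
#' @param inlet_flow Steady inlet flow in m^3/s (>= 0) or a
#'   [pulsatile_waveform()].
#' @param target_total_pressure Total pressure (Pa) to distribute over the
#'   target outlets, or `NULL`.
#' @param non_target_pressure Pressure (Pa) applied to outlets not covered by
#'   the target distribution (default 300 Pa).
#' @param outlet_pressures Optional named vector of explicit per-outlet
#'   pressures (Pa); overrides the other pressure arguments.
#' @return A `boundary_conditions` object.
#' @examples
#' boundary_conditions(5e-6, target_total_pressure = 2000)
#' @export
boundary_conditions <- function(inlet_flow, target_total_pressure = NULL,
                                non_target_pressure = 300,
                                outlet_pressures = NULL) {
  if (inherits(inlet_flow, "pulsatile_waveform")) {
    # positivity enforced at construction
  } else if (is.numeric(inlet_flow) && length(inlet_flow) == 1L &&
             is.finite(inlet_flow) && inlet_flow >= 0) {
    # ok
  } else {
    abort("`inlet_flow` must be a single finite number >= 0 or a pulsatile_waveform.",
          class = "emboflow_domain_error")
  }
  if (!is.null(target_total_pressure)) {
    if (!is.finite(target_total_pressure) || target_total_pressure < 0) {
      abort("`target_total_pressure` must be finite and >= 0.",
            class = "emboflow_domain_error")
    }
  }
  if (!is.finite(non_target_pressure)) {
    abort("`non_target_pressure` must be finite.",
          class = "emboflow_domain_error")
  }
  if (!is.null(outlet_pressures)) {
    if (is.null(names(outlet_pressures)) || anyNA(names(outlet_pressures)) ||
        any(!is.finite(outlet_pressures))) {
      abort("`outlet_pressures` must be a fully named vector of finite pressures.",
            class = "emboflow_domain_error")
    }
  }
  structure(list(inlet_flow = inlet_flow,
                 target_total_pressure = target_total_pressure,
                 non_target_pressure = non_target_pressure,
                 outlet_pressures = outlet_pressures,
                 expanded = FALSE),
            class = "boundary_conditions")
}

#' Distribute a total pressure over outlets by cross-sectional area
#'
#' Partitions `total_pressure` over the outlets so that each outlet's share
#' is directly proportional to its cross-sectional area:
#' `P_i = total_pressure * A_i / sum(A)`.  The shares sum to `total_pressure`
#' exactly (the last share absorbs the rounding residual).
#'
#' @param total_pressure Total pressure in Pa (>= 0).
#' @param outlet_areas Named vector of outlet cross-sectional areas in m^2
#'   (> 0).
#' @return A named vector of per-outlet pressures in Pa.
#' @examples
#' distribute_outlet_pressure(1000, c(a = 3e-6, b = 1e-6))
#' @export
distribute_outlet_pressure <- function(total_pressure, outlet_areas) {
  if (!is.numeric(total_pressure) || length(total_pressure) != 1L ||
      !is.finite(total_pressure) || total_pressure < 0) {
    abort("`total_pressure` must be a single finite number >= 0.",
          class = "emboflow_domain_error")
  }
  if (length(outlet_areas) == 0L) {
    abort("`outlet_areas` is empty.", class = "emboflow_domain_error")
  }
  if (any(!is.finite(outlet_areas) | outlet_areas <= 0)) {
    abort("All outlet areas must be finite and > 0.",
          class = "emboflow_domain_error")
  }
  p <- total_pressure * outlet_areas / sum(outlet_areas)
  n <- length(p)
  p[n] <- total_pressure - sum(p[-n])  # exact partition
  p
}

#' Resolve boundary conditions against a tree
#'
#' Produces a copy of `bc` whose `outlet_pressures` holds exactly one finite
#' pressure for every outlet of `tree`, applying the target-pressure
#' area-proportional distribution when `target_total_pressure` is set.
#'
#' @param bc A [boundary_conditions()].
#' @param tree A [vascular_tree()].
#' @return An expanded `boundary_conditions`.
#' @export
expand_boundary_conditions <- function(bc, tree) {
  stopifnot(inherits(bc, "boundary_conditions"),
            inherits(tree, "vascular_tree"))
  leaves <- tree_outlets(tree)
  if (!is.null(bc$outlet_pressures)) {
    missing <- setdiff(leaves, names(bc$outlet_pressures))
    extra <- setdiff(names(bc$outlet_pressures), leaves)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf("outlet_pressures do not match the tree's outlets (missing: %s; extra: %s).",
                    paste(missing, collapse = ", "),
                    paste(extra, collapse = ", ")),
            class = "emboflow_domain_error")
    }
    p <- bc$outlet_pressures[leaves]
  } else {
    p <- setNames(rep(bc$non_target_pressure, length(leaves)), leaves)
    if (!is.null(bc$target_total_pressure)) {
      tgt <- target_outlets(tree)
      if (length(tgt) == 0L) {
        abort("target_total_pressure set but the tree has no target outlets.",
              class = "emboflow_domain_error")
      }
      p[tgt] <- distribute_outlet_pressure(bc$target_total_pressure,
                                           outlet_areas(tree)[tgt])
    }
  }
  bc$outlet_pressures <- p
  bc$expanded <- TRUE
  bc
}

#' Read boundary conditions from a config file
#'
#' Reads a YAML or JSON boundary-condition file.  Flows are given in cm^3/s
#' at the file interface (converted to SI internally) and pressures in Pa.
#' Recognised fields: `inlet_flow_cm3s` *or* a `waveform` block
#' (`mean_flow_cm3s`, `period_s`, `harmonic_amplitudes`, `harmonic_phases`,
#' `pulsatility_index`), plus optional `target_total_pressure_pa` and
#' `non_target_pressure_pa`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [boundary_conditions()].
#' @export
read_boundary_conditions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  inlet <- if (!is.null(cfg$waveform)) {
    w <- cfg$waveform
    pulsatile_waveform(
      mean_flow = w$mean_flow_cm3s * 1e-6,
      period = w$period_s %||% 0.8,
      harmonic_amplitudes = w$harmonic_amplitudes %||% c(0.45, 0.12),
      harmonic_phases = w$harmonic_phases %||% c(0, -pi / 2),
      pulsatility_index = w$pulsatility_index %||% 1)
  } else if (!is.null(cfg$inlet_flow_cm3s)) {
    cfg$inlet_flow_cm3s * 1e-6
  } else {
    abort("Config must provide `inlet_flow_cm3s` or a `waveform` block.",
          class = "emboflow_domain_error")
  }
  boundary_conditions(inlet,
                      target_total_pressure = cfg$target_total_pressure_pa,
                      non_target_pressure = cfg$non_target_pressure_pa %||% 300)
}

#' @exportS3Method base::print
print.boundary_conditions <- function(x, ...) {
  inflow <- if (inherits(x$inlet_flow, "pulsatile_waveform")) {
    sprintf("pulsatile, mean %.3g cm^3/s", 1e6 * x$inlet_flow$mean_flow)
  } else sprintf("steady %.3g cm^3/s", 1e6 * x$inlet_flow)
  cat(sprintf("<boundary_conditions> inlet: %s\n", inflow))
  if (!is.null(x$target_total_pressure)) {
    cat(sprintf("  target total pressure: %g Pa (area-distributed)\n",
                x$target_total_pressure))
  }
  cat(sprintf("  non-target outlet pressure: %g Pa%s\n",
              x$non_target_pressure,
              if (x$expanded) sprintf(" [expanded over %d outlets]",
                                      length(x$outlet_pressures)) else ""))
  invisible(x)
}
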