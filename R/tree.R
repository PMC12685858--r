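#' Blood fluid properties
#'
#' Newtonian, incompressible blood model used throughout the network solver.
#' Defaults are the standard hepatic-arterial values: density 1060 kg/m^3 and
#' dynamic viscosity 0.0035 Pa.s.
#'
#' @param density Blood density in kg/m^3 (> 0).
#' @param viscosity Dynamic viscosity in Pa.s (> 0).
#' @return A `fluid_properties` object (a named list).
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.0035) {
  check_positive_scalar(density, "density")
  check_positive_scalar(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite number > 0.", name),
          class = "emboflow_domain_error")
  }
  invisible(x)
}

#' Construct a vascular tree
#'
#' A vascular tree is a directed rooted tree of cylindrical vessel segments.
#' Each segment runs from its parent's downstream junction to its own
#' downstream junction; leaf segments end in outlets.  Depth level follows the
#' branch-counting convention: the inlet (root) segment is level 1 and every
#' bifurcation increments the level by one.  One segment may be designated the
#' *target branch*: the vessel whose downstream outlets are the intended
#' destination of embolic material.
#'
#' @param segments A data frame with columns `segment_id`, `parent_id`
#'   (`NA` for the root), `length` (m, > 0), `radius` (m, > 0) and optionally
#'   `label`.
#' @param target_branch_id Identifier of the designated target branch, or
#'   `NULL` for a tree without a target (EEI and path operations then error).
#' @param fluid A [fluid_properties()] object.
#' @return A `vascular_tree` object: a list with the validated `segments`
#'   tibble (augmented with derived `depth_level` and `is_target_member`
#'   columns), `inlet_id`, `target_branch_id` and `fluid`.
#' @examples
#' seg <- tibble::tibble(
#'   segment_id = c("a", "b", "c"),
#'   parent_id  = c(NA, "a", "a"),
#'   length     = c(0.02, 0.015, 0.015),
#'   radius     = c(2e-3, 1.6e-3, 1.6e-3)
#' )
#' vascular_tree(seg, target_branch_id = "b")
#' @export
vascular_tree <- function(segments, target_branch_id = NULL,
                          fluid = fluid_properties()) {
  if (!inherits(fluid, "fluid_properties")) {
    abort("`fluid` must be created with fluid_properties().",
          class = "emboflow_domain_error")
  }
  segments <- tibble::as_tibble(segments)
  required <- c("segment_id", "parent_id", "length", "radius")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    abort(paste0("`segments` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "emboflow_validation_error")
  }
  segments$segment_id <- as.character(segments$segment_id)
  segments$parent_id <- as.character(segments$parent_id)
  if (!"label" %in% names(segments)) segments$label <- NA_character_
  segments <- segments[, c("segment_id", "parent_id", "length", "radius",
                           "label")]

  validate_segment_table(segments)
  root_id <- segments$segment_id[is.na(segments$parent_id)]

  depth <- compute_depth_levels(segments, root_id)
  segments$depth_level <- unname(depth[segments$segment_id])

  if (!is.null(target_branch_id)) {
    target_branch_id <- as.character(target_branch_id)
    if (!target_branch_id %in% segments$segment_id) {
      abort(sprintf("target_branch_id '%s' is not a segment of the tree.",
                    target_branch_id),
            class = "emboflow_validation_error")
    }
    in_target <- segments$segment_id %in% subtree_ids_impl(segments, target_branch_id)
  } else {
    in_target <- rep(FALSE, nrow(segments))
  }
  segments$is_target_member <- in_target

  structure(
    list(segments = segments, inlet_id = root_id,
         target_branch_id = target_branch_id, fluid = fluid),
    class = "vascular_tree"
  )
}

validate_segment_table <- function(segments) {
  ids <- segments$segment_id
  if (anyNA(ids) || any(ids == "")) {
    abort("Every segment needs a non-empty segment_id.",
          class = "emboflow_validation_error")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate segment id(s): %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "emboflow_validation_error")
  }
  for (col in c("length", "radius")) {
    bad <- !is.finite(segments[[col]]) | segments[[col]] <= 0
    if (any(bad)) {
      abort(sprintf("Segment(s) %s: `%s` must be finite and > 0.",
                    paste(ids[bad], collapse = ", "), col),
            class = "emboflow_validation_error")
    }
  }
  is_root <- is.na(segments$parent_id)
  if (sum(is_root) == 0L) {
    abort("No root segment found (exactly one segment must have parent NA); the graph may contain a cycle.",
          class = "emboflow_validation_error")
  }
  if (sum(is_root) > 1L) {
    abort(sprintf("Multiple root segments: %s. A vascular tree has exactly one inlet.",
                  paste(ids[is_root], collapse = ", ")),
          class = "emboflow_validation_error")
  }
  unknown <- setdiff(segments$parent_id[!is_root], ids)
  if (length(unknown) > 0) {
    abort(sprintf("parent_id(s) %s do not name any segment.",
                  paste(unknown, collapse = ", ")),
          class = "emboflow_validation_error")
  }
  # connectivity / acyclicity: BFS from root must reach every segment
  reached <- bfs_order(segments)
  if (length(reached) != nrow(segments)) {
    stranded <- setdiff(ids, reached)
    abort(sprintf("Segment(s) %s are not reachable from the root (cycle or disconnected component).",
                  paste(stranded, collapse = ", ")),
          class = "emboflow_validation_error")
  }
  invisible(segments)
}

# breadth-first order of segment ids from the root
bfs_order <- function(segments) {
  kids <- split(segments$segment_id, factor(segments$parent_id,
                                            levels = segments$segment_id))
  out <- segments$segment_id[is.na(segments$parent_id)]
  frontier <- out
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

compute_depth_levels <- function(segments, root_id) {
  depth <- setNames(rep(NA_integer_, nrow(segments)), segments$segment_id)
  parent <- setNames(segments$parent_id, segments$segment_id)
  for (id in bfs_order(segments)) {
    depth[id] <- if (is.na(parent[id])) 1L else depth[parent[id]] + 1L
  }
  depth
}

subtree_ids_impl <- function(segments, id) {
  kids <- split(segments$segment_id, factor(segments$parent_id,
                                            levels = segments$segment_id))
  out <- id
  frontier <- id
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Tree accessors
#'
#' Small helpers for interrogating a [vascular_tree()]: outlet (leaf) segment
#' ids, target-outlet ids, outlet cross-sectional areas (pi r^2), the ids of a
#' segment's subtree, and the unique path from the inlet to the target branch.
#'
#' @param tree A `vascular_tree`.
#' @param id A segment id.
#' @return Character vectors of segment ids, except `outlet_areas()` which
#'   returns a named numeric vector in m^2.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
tree_outlets <- function(tree) {
  seg <- tree$segments
  seg$segment_id[!(seg$segment_id %in% seg$parent_id)]
}

#' @rdname tree-accessors
#' @export
target_outlets <- function(tree) {
  intersect(tree_outlets(tree),
            tree$segments$segment_id[tree$segments$is_target_member])
}

#' @rdname tree-accessors
#' @export
outlet_areas <- function(tree) {
  leaves <- tree_outlets(tree)
  r <- setNames(tree$segments$radius, tree$segments$segment_id)[leaves]
  pi * r^2
}

#' @rdname tree-accessors
#' @export
subtree_ids <- function(tree, id) {
  if (!id %in% tree$segments$segment_id) {
    abort(sprintf("Segment '%s' not in tree.", id),
          class = "emboflow_validation_error")
  }
  subtree_ids_impl(tree$segments, id)
}

#' @rdname tree-accessors
#' @export
path_to_target <- function(tree) {
  if (is.null(tree$target_branch_id)) {
    abort("Tree has no designated target branch.",
          class = "emboflow_validation_error")
  }
  parent <- setNames(tree$segments$parent_id, tree$segments$segment_id)
  path <- tree$target_branch_id
  while (!is.na(parent[path[1]])) path <- c(unname(parent[path[1]]), path)
  path
}

# stable content hash used to pair solutions with the tree they came from
tree_hash <- function(tree) {
  rlang::hash(list(tree$segments[c("segment_id", "parent_id", "length",
                                   "radius")],
                   tree$target_branch_id, tree$fluid))
}

#' @exportS3Method base::print
print.vascular_tree <- function(x, ...) {
  n_out <- length(tree_outlets(x))
  n_tgt <- length(target_outlets(x))
  cat(sprintf("<vascular_tree> %d segments, %d outlets (max depth %d)\n",
              nrow(x$segments), n_out, max(x$segments$depth_level)))
  cat(sprintf("  inlet: %s (radius %.3g mm)\n", x$inlet_id,
              1e3 * x$segments$radius[x$segments$segment_id == x$inlet_id]))
  if (!is.null(x$target_branch_id)) {
    cat(sprintf("  target branch: %s (depth %d, %d target outlets)\n",
                x$target_branch_id,
                x$segments$depth_level[x$segments$segment_id == x$target_branch_id],
                n_tgt))
  }
  cat(sprintf("  fluid: rho = %g kg/m^3, mu = %g Pa.s\n",
              x$fluid$density, x$fluid$viscosity))
  invisible(x)
}

#' @export
tidy.vascular_tree <- function(x, ...) {
  x$segments
}

#' @export
glance.vascular_tree <- function(x, ...) {
  tgt_depth <- if (is.null(x$target_branch_id)) NA_integer_ else
    x$segments$depth_level[x$segments$segment_id == x$target_branch_id]
  tibble::tibble(
    n_segments = nrow(x$segments),
    n_outlets = length(tree_outlets(x)),
    n_target_outlets = length(target_outlets(x)),
    target_branch_depth = tgt_depth,
    max_depth = max(x$segments$depth_level),
    inlet_radius = x$segments$radius[x$segments$segment_id == x$inlet_id]
  )
}

#' Murray's-law closure residuals
#'
#' For every internal segment, the relative residual
#' `|r_parent^k - sum(r_child^k)| / r_parent^k` of Murray's bifurcation rule.
#' Trees built by [generate_tree()] satisfy this to floating-point precision;
#' calibrated trees ([calibrate_stall_pressure()]) intentionally break it at
#' the parents of rescaled peripheral outlets.
#'
#' @param tree A `vascular_tree`.
#' @param exponent Murray exponent k (default 3).
#' @return A tibble with `segment_id` and `murray_residual` for each internal
#'   segment.
#' @export
murray_closure <- function(tree, exponent = 3) {
  seg <- tree$segments
  internal <- seg$segment_id[seg$segment_id %in% seg$parent_id]
  r <- setNames(seg$radius, seg$segment_id)
  res <- vapply(internal, function(id) {
    kids <- seg$segment_id[!is.na(seg$parent_id) & seg$parent_id == id]
    abs(r[id]^exponent - sum(r[kids]^exponent)) / r[id]^exponent
  }, numeric(1))
  tibble::tibble(segment_id = internal, murray_residual = unname(res))
}
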