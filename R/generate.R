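#' Configuration for the synthetic tree generator
#'
#' Parameters of the seeded stochastic binary-branching generator.  The
#' generator stands in for patient-specific angiographic geometry: it
#' reproduces the hierarchy statistics the downstream analysis depends on
#' (depth levels, outlet counts and areas, Murray-law radii) without imaging
#' data.
#'
#' @param total_outlet_count Total number of outlets (leaves) in the tree.
#' @param target_outlet_count Number of outlets below the target branch
#'   (< `total_outlet_count`).
#' @param target_depth Depth level of the target branch (inlet = 1, so >= 2).
#' @param inlet_radius Radius of the inlet segment in metres.  The default
#'   2.31e-3 m (4.62 mm diameter) puts the inlet Reynolds number at ~417 for
#'   a 5 cm^3/s inflow of standard blood.
#' @param murray_exponent Exponent k of Murray's law: parent_r^k =
#'   sum(child_r^k) at every bifurcation (default 3).
#' @param length_to_radius_ratio Segment length as a multiple of its radius
#'   (default 20).
#' @param branching_asymmetry Width of the log-uniform jitter applied to the
#'   leaf-count-proportional flow split at each bifurcation, in (0, 1).
#'   0 gives strictly leaf-count-proportional radii.
#' @param random_seed Integer seed; the generator is deterministic for a
#'   fixed seed.
#' @return A `tree_gen_config` object.
#' @export
tree_gen_config <- function(total_outlet_count, target_outlet_count,
                            target_depth, inlet_radius = 2.31e-3,
                            murray_exponent = 3, length_to_radius_ratio = 20,
                            branching_asymmetry = 0.3, random_seed = 1L) {
  bad <- function(msg) abort(msg, class = "emboflow_config_error")
  if (target_outlet_count < 1) bad("target_outlet_count must be >= 1.")
  if (target_outlet_count >= total_outlet_count) {
    bad("target_outlet_count must be < total_outlet_count.")
  }
  if (target_depth < 2) bad("target_depth must be >= 2 (inlet is level 1).")
  if (murray_exponent <= 0) bad("murray_exponent must be > 0.")
  if (branching_asymmetry < 0 || branching_asymmetry >= 1) {
    bad("branching_asymmetry must lie in [0, 1).")
  }
  check_positive_scalar(inlet_radius, "inlet_radius")
  check_positive_scalar(length_to_radius_ratio, "length_to_radius_ratio")
  # one side branch leaves the inlet->target path at each of the
  # target_depth - 1 path bifurcations, and each needs at least one outlet
  if (total_outlet_count - target_outlet_count < target_depth - 1) {
    bad(sprintf(paste0(
      "Infeasible config: %d non-target outlets cannot populate the %d side ",
      "branches required to place the target branch at depth %d."),
      total_outlet_count - target_outlet_count, target_depth - 1, target_depth))
  }
  structure(list(
    total_outlet_count = as.integer(total_outlet_count),
    target_outlet_count = as.integer(target_outlet_count),
    target_depth = as.integer(target_depth),
    inlet_radius = inlet_radius,
    murray_exponent = murray_exponent,
    length_to_radius_ratio = length_to_radius_ratio,
    branching_asymmetry = branching_asymmetry,
    random_seed = as.integer(random_seed)
  ), class = "tree_gen_config")
}

#' Generate a synthetic branching arterial tree
#'
#' Builds a rooted binary tree with `total_outlet_count` outlets in which a
#' designated target branch at depth `target_depth` subtends exactly
#' `target_outlet_count` outlets.  The inlet->target path is laid down first;
#' one side branch leaves the path at each bifurcation and receives a random
#' share of the remaining outlets.  At every bifurcation the parent radius is
#' divided by Murray's law, `parent_r^k = sum(child_r^k)`, with each child's
#' share proportional to its outlet count times a log-uniform jitter
#' `exp(U(-a, a))` where `a = branching_asymmetry`.  Segment lengths are
#' `length_to_radius_ratio * radius`.
#'
#' The generator is deterministic for a fixed `random_seed` (the caller's RNG
#' state is left untouched).
#'
#' @param config A [tree_gen_config()].
#' @return A [vascular_tree()] with the depth-`target_depth` path segment as
#'   its target branch.
#' @examples
#' tree <- generate_tree(tree_gen_config(43, 10, 5, random_seed = 1))
#' glance(tree)
#' @export
generate_tree <- function(config) {
  if (!inherits(config, "tree_gen_config")) {
    abort("`config` must be created with tree_gen_config().",
          class = "emboflow_config_error")
  }
  withr::with_seed(config$random_seed, generate_tree_impl(config))
}

generate_tree_impl <- function(config) {
  k <- config$murray_exponent
  a <- config$branching_asymmetry
  lr <- config$length_to_radius_ratio

  rows <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("s%03d", counter)
  }
  add_segment <- function(id, parent, radius, label = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(segment_id = id, parent_id = parent,
                                       length = lr * radius, radius = radius,
                                       label = label)
  }
  # Murray split of `radius` between children subtending n1 and n2 outlets
  split_radius <- function(radius, n1, n2) {
    w1 <- n1 * exp(stats::runif(1, -a, a))
    w2 <- n2 * exp(stats::runif(1, -a, a))
    f1 <- w1 / (w1 + w2)
    c(radius * f1^(1 / k), radius * (1 - f1)^(1 / k))
  }
  # random binary subtree with n outlets rooted at a freshly created segment
  grow <- function(parent_id, radius, n, label = NA_character_) {
    id <- new_id()
    add_segment(id, parent_id, radius, label)
    if (n > 1L) {
      n1 <- sample.int(n - 1L, 1L)
      r12 <- split_radius(radius, n1, n - n1)
      grow(id, r12[1], n1)
      grow(id, r12[2], n - n1)
    }
    id
  }

  n_side_total <- config$total_outlet_count - config$target_outlet_count
  n_levels <- config$target_depth - 1L
  # random composition of the non-target outlets over the side branches
  side_counts <- if (n_levels == 1L) n_side_total else {
    cuts <- sort(sample.int(n_side_total - 1L, n_levels - 1L))
    diff(c(0L, cuts, n_side_total))
  }

  # inlet -> target path
  path_radius <- config$inlet_radius
  parent <- NA_character_
  for (d in seq_len(n_levels)) {
    id <- new_id()
    add_segment(id, parent, path_radius,
                label = if (d == 1L) "inlet" else sprintf("CS-%d host", d))
    n_below_path <- config$target_outlet_count +
      if (d < n_levels) sum(side_counts[(d + 1L):n_levels]) else 0L
    r12 <- split_radius(path_radius, n_below_path, side_counts[d])
    grow(id, r12[2], side_counts[d])
    path_radius <- r12[1]
    parent <- id
  }
  target_id <- grow(parent, path_radius, config$target_outlet_count,
                    label = "target branch")

  segments <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  vascular_tree(segments, target_branch_id = target_id)
}
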