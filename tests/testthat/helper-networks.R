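# Hand-built analytic networks and an independent dense reference solver.

MU <- 0.0035

# length giving a prescribed Poiseuille resistance at a chosen radius
length_for_resistance <- function(R, radius, viscosity = MU) {
  R * pi * radius^4 / (8 * viscosity)
}

# inlet segment of resistance R0 feeding two outlet segments of resistance
# R1 (the target) and R2
make_two_outlet <- function(R0 = 1e7, R1 = 5e7, R2 = 2e7) {
  r <- c(2e-3, 1.5e-3, 1.5e-3)
  seg <- tibble::tibble(
    segment_id = c("root", "tgt", "nt"),
    parent_id = c(NA, "root", "root"),
    length = length_for_resistance(c(R0, R1, R2), r),
    radius = r
  )
  vascular_tree(seg, target_branch_id = "tgt")
}

# symmetric bifurcation: two identical children, child 1 is the target
make_y_tree <- function(r_root = 2e-3) {
  r_child <- r_root / 2^(1 / 3)
  seg <- tibble::tibble(
    segment_id = c("root", "left", "right"),
    parent_id = c(NA, "root", "root"),
    length = 20 * c(r_root, r_child, r_child),
    radius = c(r_root, r_child, r_child)
  )
  vascular_tree(seg, target_branch_id = "left")
}

# closed-form Kirchhoff solution of the two-outlet network
closed_form_two_outlet <- function(Q, R1, R2, P1, P2) {
  Q1 <- (Q * R2 + (P2 - P1)) / (R1 + R2)
  list(Q1 = Q1, Q2 = Q - Q1, P_junction = P1 + Q1 * R1)
}

# Independent brute-force reference: dense row-by-row assembly (Dirichlet
# rows for outlets, KCL rows elsewhere) solved with base::solve.  Shares no
# code with the package's sparse Laplacian path.
oracle_solve <- function(tree, bc) {
  bc <- expand_boundary_conditions(bc, tree)
  seg <- as.data.frame(tree$segments)
  R <- 8 * tree$fluid$viscosity * seg$length / (pi * seg$radius^4)
  names(R) <- seg$segment_id
  nodes <- c(".inlet", seg$segment_id)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  b <- rep(0, n)
  up_of <- function(id) {
    p <- seg$parent_id[seg$segment_id == id]
    if (is.na(p)) ".inlet" else p
  }
  is_leaf <- !(seg$segment_id %in% seg$parent_id)
  for (i in seq_len(n)) {
    node <- nodes[i]
    if (node != ".inlet" && is_leaf[seg$segment_id == node]) {
      A[i, node] <- 1
      b[i] <- bc$outlet_pressures[[node]]
      next
    }
    # KCL: sum over incident segments of (P_node - P_other)/R = injection
    for (s in seg$segment_id) {
      u <- up_of(s)
      if (u == node) {
        A[i, node] <- A[i, node] + 1 / R[s]
        A[i, s] <- A[i, s] - 1 / R[s]
      } else if (s == node) {
        A[i, node] <- A[i, node] + 1 / R[s]
        A[i, u] <- A[i, u] - 1 / R[s]
      }
    }
    if (node == ".inlet") b[i] <- bc$inlet_flow
  }
  p <- solve(A, b)
  flows <- vapply(seg$segment_id,
                  function(s) (p[up_of(s)] - p[s]) / R[s], numeric(1))
  list(pressures = p, flows = flows)
}

fixture_bc <- function() boundary_conditions(5e-6, non_target_pressure = 300)

# small generated trees used in the seeded property batteries
battery_tree <- function(seed, total = 20, target = 5, depth = 4) {
  generate_tree(tree_gen_config(total_outlet_count = total,
                                target_outlet_count = target,
                                target_depth = depth, random_seed = seed))
}
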