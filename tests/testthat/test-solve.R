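test_that("Poiseuille resistance matches hand evaluation and scaling laws", {
  expect_equal(segment_resistance(0.01, 0.001, 0.0035), 8.9127e7,
               tolerance = 1e-4)
  R <- segment_resistance(0.02, 1.3e-3, 0.0035)
  expect_equal(segment_resistance(0.02, 2.6e-3, 0.0035), R / 16)
  expect_equal(segment_resistance(0.04, 1.3e-3, 0.0035), 2 * R)
  expect_error(segment_resistance(-0.01, 0.001, 0.0035),
               class = "emboflow_domain_error")
  expect_error(segment_resistance(0.01, 0, 0.0035),
               class = "emboflow_domain_error")
})

test_that("symmetric bifurcation splits the inlet flow evenly", {
  tree <- make_y_tree()
  sol <- solve_steady(tree, boundary_conditions(4e-6))
  flows <- setNames(sol$segments$flow, sol$segments$segment_id)
  expect_equal(unname(flows[c("left", "right")]), c(2e-6, 2e-6),
               tolerance = 1e-12)
  expect_equal(unname(flows["root"]), 4e-6, tolerance = 1e-12)
})

test_that("two-outlet network matches the closed-form Kirchhoff solution", {
  R0 <- 1.2e7; R1 <- 6.5e7; R2 <- 2.8e7
  tree <- make_two_outlet(R0, R1, R2)
  for (case in list(c(5e-6, 0, 300), c(5e-6, 2000, 300), c(2e-6, 4000, 100))) {
    Q <- case[1]; P1 <- case[2]; P2 <- case[3]
    bc <- boundary_conditions(Q, outlet_pressures = c(tgt = P1, nt = P2))
    sol <- solve_steady(tree, bc, check_laminar = FALSE)
    ref <- closed_form_two_outlet(Q, R1, R2, P1, P2)
    flows <- setNames(sol$segments$flow, sol$segments$segment_id)
    expect_equal(unname(flows["tgt"]), ref$Q1, tolerance = 1e-10)
    expect_equal(unname(flows["nt"]), ref$Q2, tolerance = 1e-10)
    pj <- sol$node_pressures$pressure[sol$node_pressures$node_id == "root"]
    expect_equal(pj, ref$P_junction, tolerance = 1e-10)
  }
})

test_that("sparse solver agrees with the brute-force dense reference on small trees", {
  for (seed in 1:5) {
    tree <- generate_tree(tree_gen_config(4, 1, 2, random_seed = seed))
    expect_lte(nrow(tree$segments), 8L)
    bc <- boundary_conditions(5e-6, target_total_pressure = 700 * seed,
                              non_target_pressure = 300)
    sol <- solve_steady(tree, bc, check_laminar = FALSE)
    ref <- oracle_solve(tree, bc)
    flows <- setNames(sol$segments$flow, sol$segments$segment_id)
    expect_equal(unname(flows[names(ref$flows)]), unname(ref$flows),
                 tolerance = 1e-9)
  }
})

test_that("mass is conserved at every junction and at the outlets", {
  tree <- reference_fixture()
  for (p in c(0, 2500)) {
    bc <- boundary_conditions(5e-6, target_total_pressure = p)
    sol <- solve_steady(tree, bc, check_laminar = FALSE)
    expect_lt(sol$max_mass_residual, 1e-10)
    leaf_flows <- sol$segments$flow[sol$segments$segment_id %in%
                                      tree_outlets(tree)]
    expect_equal(sum(leaf_flows), 5e-6, tolerance = 1e-10)
  }
})

test_that("segment flows are affine in the inlet flow and target pressure", {
  tree <- reference_fixture()
  get_flows <- function(q, p) {
    bc <- boundary_conditions(q, target_total_pressure = p)
    solve_steady(tree, bc, check_laminar = FALSE)$segments$flow
  }
  # second difference along each input vanishes, and there is no interaction
  f11 <- get_flows(3e-6, 1000); f12 <- get_flows(3e-6, 3000)
  f21 <- get_flows(7e-6, 1000); f22 <- get_flows(7e-6, 3000)
  fmid <- get_flows(5e-6, 2000)
  expect_equal((f11 + f12 + f21 + f22) / 4, fmid, tolerance = 1e-9)
  expect_equal(f11 + f22 - f12 - f21, rep(0, length(f11)),
               tolerance = 1e-9 * max(abs(f11)))
})

test_that("Reynolds numbers follow 4 rho |Q| / (pi mu D) and the laminar guard fires", {
  tree <- reference_fixture()
  bc <- fixture_bc()
  sol <- solve_steady(tree, bc)
  re <- reynolds(sol, tree)
  inlet_re <- re$reynolds[re$segment_id == tree$inlet_id]
  expect_equal(inlet_re, 4 * 1060 * 5e-6 / (pi * 0.0035 * 4.62e-3),
               tolerance = 1e-12)
  # linearity and the zero-flow case
  sol2 <- solve_steady(tree, boundary_conditions(1e-5), check_laminar = FALSE)
  expect_equal(reynolds(sol2, tree)$reynolds, 2 * re$reynolds,
               tolerance = 1e-9)
  sol0 <- solve_steady(tree, boundary_conditions(0, non_target_pressure = 300),
                       check_laminar = FALSE)
  expect_lt(max(abs(reynolds(sol0, tree)$reynolds)), 1e-9)
  # turbulent-regime warning
  expect_warning(solve_steady(make_y_tree(), boundary_conditions(5e-5)),
                 regexp = "2300")
})

test_that("solver preconditions are enforced", {
  tree <- make_y_tree()
  wf <- pulsatile_waveform(5e-6)
  expect_error(solve_steady(tree, boundary_conditions(wf)),
               class = "emboflow_precondition_error")
  expect_error(solve_steady(tree, list(inlet_flow = 1)),
               class = "emboflow_precondition_error")
  expect_error(
    solve_steady(tree, boundary_conditions(
      5e-6, outlet_pressures = c(left = 300))),
    class = "emboflow_domain_error")
  # solution/tree pairing is checked
  other <- make_two_outlet()
  sol <- solve_steady(tree, boundary_conditions(5e-6), check_laminar = FALSE)
  expect_error(reynolds(sol, other), class = "emboflow_precondition_error")
})

test_that("backflow detection is empty for uniform pressures and flags reversed targets", {
  tree <- make_two_outlet()
  bc_even <- boundary_conditions(5e-6, outlet_pressures = c(tgt = 300, nt = 300))
  expect_equal(nrow(detect_backflow(solve_steady(tree, bc_even,
                                                 check_laminar = FALSE))), 0L)
  # drive the target outlet above its stall pressure -> retrograde target
  stall <- analytic_stall_pressure(tree, fixture_bc(), rel_threshold = 0)
  bc_hi <- boundary_conditions(5e-6, target_total_pressure = 1.5 * stall)
  bf <- detect_backflow(solve_steady(tree, bc_hi, check_laminar = FALSE))
  expect_true("tgt" %in% bf$segment_id)
  expect_true(all(bf$flow < 0))
})
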