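test_that("EEI is 100% at the target branch and follows the flow split upstream", {
  # symmetric bifurcation, one target outlet: inlet site delivers 50%
  ytree <- make_y_tree()
  sol <- solve_steady(ytree, boundary_conditions(5e-6), check_laminar = FALSE)
  eei <- compute_eei(ytree, sol)
  val <- setNames(eei$eei, eei$segment_id)
  expect_equal(unname(val["left"]), 100)
  expect_equal(unname(val["root"]), 50)
  expect_equal(unname(val["right"]), 0)

  # two-outlet network: inlet EEI equals 100 Q1/Q from the closed form
  # zero-flow stall here is 300 + Q R2 = 450 Pa, so 350 Pa keeps forward flow
  R0 <- 1e7; R1 <- 6e7; R2 <- 3e7
  tree <- make_two_outlet(R0, R1, R2)
  bc <- boundary_conditions(5e-6, target_total_pressure = 350)
  sol2 <- solve_steady(tree, bc, check_laminar = FALSE)
  ref <- closed_form_two_outlet(5e-6, R1, R2, 350, 300)
  eei2 <- compute_eei(tree, sol2)
  expect_equal(eei2$eei[eei2$segment_id == "root"],
               100 * ref$Q1 / 5e-6, tolerance = 1e-10)
})

test_that("sites without forward carrier flow are undefined, not zero, and defined values stay in [0, 100]", {
  tree <- make_two_outlet()
  stall0 <- analytic_stall_pressure(tree, fixture_bc(), rel_threshold = 0)
  # exactly at zero-flow stall the target branch carries ~no flow
  bc <- boundary_conditions(5e-6, target_total_pressure = stall0)
  eei <- compute_eei(tree, solve_steady(tree, bc, check_laminar = FALSE))
  expect_false(eei$defined[eei$segment_id == "tgt"])
  expect_true(is.na(eei$eei[eei$segment_id == "tgt"]))
  # above stall the target flow is retrograde: clamped out of the numerator
  bc_hi <- boundary_conditions(5e-6, target_total_pressure = 2 * stall0)
  eei_hi <- compute_eei(tree, solve_steady(tree, bc_hi, check_laminar = FALSE))
  expect_equal(eei_hi$eei[eei_hi$segment_id == "root"], 0)
  # range property over the standard sweep of the packaged tree
  sweep <- run_pressure_sweep(reference_fixture())
  all_eei <- tidy(sweep, "eei")
  defined <- all_eei[all_eei$defined, ]
  expect_true(all(defined$eei >= 0 & defined$eei <= 100))
})

test_that("EEI map is invariant under inlet-flow rescaling with uniform outlet pressures", {
  tree <- reference_fixture()
  maps <- lapply(c(0.5, 1, 2), function(s) {
    sol <- solve_steady(tree, boundary_conditions(s * 5e-6),
                        check_laminar = FALSE)
    compute_eei(tree, sol)$eei
  })
  expect_equal(maps[[1]], maps[[2]], tolerance = 1e-10)
  expect_equal(maps[[3]], maps[[2]], tolerance = 1e-10)
})

test_that("time-averaged EEI equals steady EEI under uniform pressures and detects flow dependence otherwise", {
  tree <- reference_fixture()
  wf <- pulsatile_waveform(5e-6)
  psol <- solve_pulsatile(tree, boundary_conditions(wf), n_steps = 32)
  tavg <- time_averaged_eei(tree, psol)
  steady <- compute_eei(tree, solve_steady(tree, boundary_conditions(5e-6),
                                           check_laminar = FALSE))
  expect_equal(tavg$eei, steady$eei, tolerance = 1e-9)
  # doubling the whole waveform leaves the map unchanged
  psol2 <- solve_pulsatile(tree, boundary_conditions(scale_waveform(wf, 2)),
                           n_steps = 32)
  expect_equal(time_averaged_eei(tree, psol2)$eei, tavg$eei,
               tolerance = 1e-9)
  # with unequal outlet pressures the split depends on the mean flow
  two <- make_two_outlet()  # zero-flow stall ~400 Pa at 5 cm^3/s
  eei_at <- function(q) {
    bc <- boundary_conditions(q, target_total_pressure = 350)
    m <- compute_eei(two, solve_steady(two, bc, check_laminar = FALSE))
    m$eei[m$segment_id == "root"]
  }
  expect_gt(abs(eei_at(5e-6) - eei_at(1e-5)), 1)
  expect_error(time_averaged_eei(tree, list()),
               class = "emboflow_precondition_error")
})

test_that("cross-section series follows the inlet-to-target path and conserves target flow", {
  ytree <- make_y_tree()
  soly <- solve_steady(ytree, boundary_conditions(5e-6), check_laminar = FALSE)
  csy <- cross_section_flows(ytree, soly)
  expect_equal(csy$cross_section, c("CS-1", "CS-2"))
  expect_equal(csy$segment_id, c("root", "left"))

  tree <- reference_fixture()
  sol <- solve_steady(tree, fixture_bc())
  cs <- cross_section_flows(tree, sol)
  expect_equal(cs$cross_section, sprintf("CS-%d", 1:5))
  expect_equal(cs$segment_id[1], tree$inlet_id)
  expect_equal(cs$segment_id[5], tree$target_branch_id)
  tgt_sum <- sum(sol$segments$flow[sol$segments$segment_id %in%
                                     target_outlets(tree)])
  expect_equal(cs$flow[5], tgt_sum, tolerance = 1e-10)

  no_target <- vascular_tree(ytree$segments[, 1:5])
  sol_nt <- solve_steady(no_target, boundary_conditions(5e-6),
                         check_laminar = FALSE)
  expect_error(cross_section_flows(no_target, sol_nt),
               class = "emboflow_validation_error")
})

test_that("EEI is non-decreasing along the inlet-to-target path (proximity effect)", {
  for (seed in 1:5) {
    tree <- battery_tree(seed)
    bc <- boundary_conditions(5e-6, target_total_pressure = 500)
    eei <- compute_eei(tree, solve_steady(tree, bc, check_laminar = FALSE))
    path_eei <- eei$eei[match(path_to_target(tree), eei$segment_id)]
    expect_true(all(diff(path_eei) >= -1e-9))
    expect_equal(path_eei[length(path_eei)], 100, tolerance = 1e-9)
  }
})

test_that("EEI-pressure fit recovers the analytic slope of the two-outlet network", {
  R0 <- 1e7; R1 <- 6e7; R2 <- 3e7
  tree <- make_two_outlet(R0, R1, R2)
  stall0 <- analytic_stall_pressure(tree, fixture_bc(), rel_threshold = 0)
  pressures <- seq(0, 0.8 * stall0, length.out = 5)
  sweep <- run_pressure_sweep(tree, pressures = pressures)
  fit <- eei_pressure_fit(sweep, "root")
  # d(EEI)/dP1 = -100 / (Q (R1 + R2)) from the closed-form flow split
  expect_equal(fit$slope, -100 / (5e-6 * (R1 + R2)), tolerance = 1e-9)
  expect_lt(fit$max_abs_residual, 1e-8)
  expect_lt(fit$slope, 0)

  expect_error(eei_pressure_fit(sweep, "nope"),
               class = "emboflow_precondition_error")
  # fewer than 3 defined conditions is rejected
  sweep2 <- run_pressure_sweep(tree, pressures = c(0, 1000))
  expect_error(eei_pressure_fit(sweep2, "root"),
               class = "emboflow_precondition_error")
})
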