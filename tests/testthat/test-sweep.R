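test_that("default pressure sweep enumerates six conditions with monotone target flow", {
  tree <- reference_fixture()
  sweep <- run_pressure_sweep(tree)
  expect_equal(nrow(sweep$results), 6L)
  expect_equal(sweep$results$target_pressure,
               c(0, 1000, 2000, 3000, 4000, 5000))
  tgt_flow <- vapply(sweep$results$solution, function(s) {
    s$segments$flow[s$segments$segment_id == tree$target_branch_id]
  }, numeric(1))
  # 0 Pa carries the sweep maximum; flow decreases strictly with pressure
  expect_equal(which.max(tgt_flow), 1L)
  expect_true(all(diff(tgt_flow) < 0))
  # at the calibrated 5000 Pa condition the target flow has fallen to ~1%
  expect_lte(tgt_flow[6], 0.011 * tgt_flow[1])
  expect_error(run_pressure_sweep(tree, pressures = c(2000, 1000)),
               class = "emboflow_precondition_error")
})

test_that("tidy and glance expose sweep results as long tibbles", {
  sweep <- run_pressure_sweep(reference_fixture(),
                              pressures = c(0, 2000, 4000))
  eei <- tidy(sweep, "eei")
  expect_s3_class(eei, "tbl_df")
  expect_equal(nrow(eei), 3L * 85L)
  cs <- tidy(sweep, "cross_sections")
  expect_equal(nrow(cs), 3L * 5L)
  expect_true(all(c("condition_id", "target_pressure") %in% names(cs)))
  g <- glance(sweep)
  expect_equal(g$n_conditions, 3L)
  expect_equal(g$type, "pressure")
})

test_that("inflow sweep verdict: invariant under uniform pressures, broken by a target pressure", {
  tree <- reference_fixture()
  sweep <- run_inflow_sweep(tree, inlet_scales = c(0.5, 1, 2))
  expect_true(sweep$invariance$pass)
  expect_lt(sweep$invariance$max_delta_eei, 1e-6)

  skewed <- run_inflow_sweep(tree, inlet_scales = c(0.5, 1, 2),
                             target_total_pressure = 2000)
  expect_false(skewed$invariance$pass)
  expect_gt(skewed$invariance$max_delta_eei, 1)

  single <- run_inflow_sweep(tree, inlet_scales = 1)
  expect_true(single$invariance$pass)
  expect_equal(single$invariance$max_delta_eei, 0)

  # pulsatile variant with time-averaged maps
  puls <- run_inflow_sweep(tree, inlet_scales = c(1, 2),
                           waveform = pulsatile_waveform(5e-6), n_steps = 16)
  expect_true(puls$invariance$pass)
})

test_that("backflow study fractions bracket the instantaneous stall window", {
  tree <- reference_fixture()
  wf <- pulsatile_waveform(5e-6)
  bc300 <- fixture_bc()

  quiet <- run_backflow_study(tree, wf, target_pressure = 0, n_steps = 16)
  expect_equal(max(quiet$retrograde_fraction), 0)

  stall_min <- attr(quiet, "stall_at_min")
  stall_max <- attr(quiet, "stall_at_max")
  expect_lt(stall_min, stall_max)

  # above the systolic (max-flow) stall: target branch retrograde all cycle
  always <- run_backflow_study(tree, wf, target_pressure = 1.1 * stall_max,
                               n_steps = 16)
  expect_equal(
    always$retrograde_fraction[always$segment_id == tree$target_branch_id], 1)

  # between diastolic and systolic stall: episodes for part of the cycle
  mid <- run_backflow_study(tree, wf,
                            target_pressure = (stall_min + stall_max) / 2,
                            n_steps = 32)
  frac <- mid$retrograde_fraction[mid$segment_id == tree$target_branch_id]
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("report writes a deterministic file set with the promised summary fields", {
  tree <- reference_fixture()
  sweep <- run_pressure_sweep(tree, pressures = c(0, 2000, 4000))
  inflow <- run_inflow_sweep(tree, inlet_scales = c(0.5, 1))
  dir1 <- file.path(tempdir(), "emboflow-report-1")
  files <- report(tree, sweep, inflow_sweep = inflow, output_dir = dir1,
                  plots = FALSE)
  expect_true(all(file.exists(files)))
  summ <- jsonlite::fromJSON(file.path(dir1, "summary.json"))
  expect_true(all(c("stall_pressure_pa", "eei_by_site",
                    "invariance_verdict") %in% names(summ)))
  expect_equal(summ$stall_pressure_pa, 5000, tolerance = 1e-3)
  expect_true(summ$invariance_verdict$pass)

  # rerun -> byte-identical summary
  dir2 <- file.path(tempdir(), "emboflow-report-2")
  report(tree, sweep, inflow_sweep = inflow, output_dir = dir2, plots = FALSE)
  f1 <- file.path(dir1, "summary.json")
  f2 <- file.path(dir2, "summary.json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  empty <- run_pressure_sweep(tree, pressures = numeric(0))
  expect_error(report(tree, empty, output_dir = dir1),
               class = "emboflow_precondition_error")
})

test_that("report renders the figure set", {
  tree <- reference_fixture()
  sweep <- run_pressure_sweep(tree, pressures = c(0, 2000, 4000))
  bf <- run_backflow_study(tree, pulsatile_waveform(5e-6),
                           target_pressure = 4000, n_steps = 16)
  dir3 <- file.path(tempdir(), "emboflow-report-3")
  files <- report(tree, sweep, backflow = bf, output_dir = dir3, plots = TRUE)
  expect_true(any(grepl("eei_vs_pressure[.]png$", files)))
  expect_true(any(grepl("waveform_overlay[.]png$", files)))
  expect_true(all(file.exists(files)))
})
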