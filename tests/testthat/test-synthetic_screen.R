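test_that("configuration validation rejects out-of-range parameters", {
  expect_error(screen_config(baseline_pos = -0.1), "\\[0,1\\]")
  expect_error(screen_config(ir_pos = 1.2), "\\[0,1\\]")
  expect_error(screen_config(planted_hits = data.frame(
    target_id = "T", hit_class = "strong", effect_size = 1.5)), "\\[0,1\\]")
  expect_error(screen_config(ir_pos = 0.04), "exceed")
  expect_error(viability_model(survival = list(bad = c(1, 1.5, 0.5))),
               "survival fractions")
  expect_error(viability_model(survival = list(bad = c(0.9, 0.5, 0.2))),
               "dose-0")
})

test_that("effect sizes map to true fold reductions in closed form", {
  b <- 0.05; ir <- 0.45
  for (f in c(1, 1.5, 1.8, 2.5, 9)) {
    e <- effect_for_fold(f, b, ir)
    expect_equal(ir / (b + (ir - b) * (1 - e)), f)
  }
  expect_error(effect_for_fold(10, b, ir), "dynamic range")
})

test_that("a fixed seed reproduces the screen bit-identically; seeds differ", {
  cfg <- small_screen_config(seed = 3, n_targets = 5)
  a <- simulate_screen(cfg, level = "cell")
  b <- simulate_screen(cfg, level = "cell")
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  d <- simulate_screen(cfg, level = "cell", seed = 4)
  expect_false(identical(a$cells$ch_marker, d$cells$ch_marker))
})

test_that("plate layout carries triplicate controls and every well has cells", {
  lay <- plate_layout(sprintf("T%02d", 1:87))
  expect_equal(sum(lay$role == "pos_control"), 3)
  expect_equal(sum(lay$role == "mock"), 3)
  expect_equal(sum(lay$role == "nt"), 3)
  expect_equal(nrow(lay), 96)
  expect_error(plate_layout(sprintf("T%02d", 1:88)), "at most 87")

  sim <- simulate_screen(small_screen_config(n_targets = 10), level = "cell")
  counts <- table(paste(sim$cells$plate_id, sim$cells$well))
  expect_equal(length(counts), nrow(sim$plate_map))
  expect_true(all(counts >= 1))
  # both treatment runs present
  expect_setequal(unique(sim$plate_map$treatment_gy), c(0, 5))
})

test_that("positive-control wells are fully suppressed to baseline", {
  cfg <- screen_config(n_targets = 10, pos_control_effect = 1,
                       well_noise_sd = 0, seed = 2)
  sim <- simulate_screen(cfg, level = "well")
  tr <- sim$truth
  pc_ir <- tr$true_fraction[tr$role == "pos_control" & tr$treatment_gy > 0]
  expect_equal(pc_ir, rep(cfg$baseline_pos, length(pc_ir)))
  nt_ir <- tr$true_fraction[tr$role == "nt" & tr$treatment_gy > 0]
  expect_equal(nt_ir, rep(cfg$ir_pos, length(nt_ir)))
})

test_that("empirical well fractions converge to the truth table", {
  cfg <- screen_config(n_targets = 10, cells_per_well = 20000, seed = 9)
  sim <- simulate_screen(cfg, level = "cell")
  ir_map <- sim$plate_map[sim$plate_map$treatment_gy > 0, ]
  g <- gate_plate(sim$cells[sim$cells$plate_id == ir_map$plate_id[1], ],
                  ir_map[ir_map$plate_id == ir_map$plate_id[1], ])
  m <- merge(g$wells, sim$truth, by = c("plate_id", "well"))
  expect_true(all(abs(m$pos_fraction - 100 * m$true_fraction) <= 2))
})

test_that("well-level and cell-level generators agree statistically", {
  cfg <- screen_config(n_targets = 60, seed = 21)
  wl <- simulate_screen(cfg, level = "well")
  cl <- simulate_screen(cfg, level = "cell", seed = 22)
  gated <- lapply(split(cl$plate_map, cl$plate_map$plate_id), function(pm) {
    if (pm$treatment_gy[1] == 0) return(NULL)  # gates need an assay window
    gate_plate(cl$cells[cl$cells$plate_id == pm$plate_id[1], ], pm)$wells
  })
  wells_cl <- do.call(rbind, gated)
  ir_ids <- unique(cl$plate_map$plate_id[cl$plate_map$treatment_gy > 0])
  mw <- mean(wl$wells$pos_fraction[wl$wells$plate_id %in% ir_ids])
  mc <- mean(wells_cl$pos_fraction)
  expect_lt(abs(mw - mc), 1.5)
})

test_that("viability arms reproduce configured survival and reject unknown arms", {
  cfg <- screen_config(n_targets = 10, seed = 5)
  expect_error(simulate_viability_arms(cfg, arms = "nonsense"), "unknown")
  obs <- simulate_viability_arms(cfg, tech_reps = 200)
  expect_true(all(obs$value > 0))
  sc <- survival_curves(obs)
  mock <- sc$curves[sc$curves$target == "mock" & sc$curves$co_kd == "NT", ]
  expect_equal(mock$survival[mock$dose_gy == 0], 1)
  expect_equal(mock$survival[mock$dose_gy == 2],
               cfg$viability$survival$mock_nt[2], tolerance = 0.03)
  expect_equal(mock$survival[mock$dose_gy == 5],
               cfg$viability$survival$mock_nt[3], tolerance = 0.03)
})

test_that("an identity arm keeps normalized survival at 1 across doses", {
  vm <- viability_model(survival = list(mock_nt = c(1, 0.7, 0.4),
                                        target_nt = c(1, 1, 1)))
  cfg <- screen_config(n_targets = 10, viability = vm, seed = 6)
  sc <- survival_curves(simulate_viability_arms(cfg, tech_reps = 300))
  tgt <- sc$curves[sc$curves$target == "target", ]
  expect_equal(tgt$survival, rep(1, 3), tolerance = 0.03)
})

test_that("profile matrices carry the planted group structure", {
  m0 <- simulate_profile_matrix(default_groups, noise_sd = 0, seed = 1)
  expect_equal(nrow(m0), 8)
  expect_identical(m0["PRPK", ], m0["STK4", ])
  expect_false(identical(m0["PRPK", ], m0["DYRK1A", ]))
  # duplicated rows of a single group are at zero distance
  expect_equal(max(dist(m0[group_II, ])), 0)
  expect_error(simulate_profile_matrix(c(A = "I")), "at least 2")
  expect_error(simulate_profile_matrix(c(A = "X", B = "X")), "no profile")
})
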