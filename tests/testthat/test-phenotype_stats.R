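test_that("relative normalization maps the reference to 1", {
  expect_equal(normalize_relative(c(60, 60), c(60, 60)), c(1, 1))
  expect_equal(normalize_relative(30, c(55, 65)), 0.5)
  expect_error(normalize_relative(1, c(-2, 2)), "positive")
})

test_that("technical replicates collapse before pairing", {
  v <- c(10, 12, 14, 20, 22, 24)
  b <- rep(c("b1", "b2"), each = 3)
  expect_equal(unname(bio_rep_means(v, b)), c(12, 22))
})

test_that("paired t matches the closed-form oracle and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(0, 0, 0)   # differences 1,2,3
  r <- paired_t(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)))           # = 2*sqrt(3) ~ 3.464
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2)) # ~ 0.0742
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  same <- paired_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  const <- paired_t(c(5, 6, 7), c(4, 5, 6))       # constant nonzero diffs
  expect_equal(const$p, 0)

  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t tracks the exact sign-flip permutation distribution", {
  perm_p <- function(d) {
    n <- length(d)
    tobs <- abs(mean(d) / (sd(d) / sqrt(n)))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    ts <- apply(signs, 1, function(s) {
      ds <- d * s
      abs(mean(ds) / (sd(ds) / sqrt(n)))
    })
    mean(ts >= tobs - 1e-12)
  }
  set.seed(401)
  devs <- replicate(10, {
    d <- rnorm(8, 0.4, 1)
    abs(paired_t(d, rep(0, 8))$p - perm_p(d))
  })
  expect_lt(max(devs), 0.06)
})

test_that("paired t holds its nominal type-I error under the null", {
  set.seed(402)
  rej <- mean(replicate(4000, paired_t(rnorm(3), rnorm(3))$p < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("interaction index follows the multiplicative-expectation rule", {
  r0 <- interaction_index(100, 50, 40, 20, direction = "decreases")
  expect_equal(r0$expected, 0.2)
  expect_equal(r0$index, 0)
  expect_equal(r0$classification, "none")

  syn <- interaction_index(100, 50, 40, 10, direction = "decreases")
  expect_equal(syn$index, 0.1)
  expect_equal(syn$classification, "synergistic")

  ant <- interaction_index(100, 50, 40, 30, direction = "decreases")
  expect_equal(ant$index, -0.1)
  expect_equal(ant$classification, "antagonistic")

  expect_error(interaction_index(0, 1, 1, 1), "positive")
})

test_that("blunted induction is antagonistic for IR-increasing readouts", {
  # p21 positivity: IR triples the mock readout; knockdown halves the
  # baseline and the combined response falls below expectation
  r <- interaction_index(1, 0.6, 3, 1.2, direction = "increases")
  expect_gt(r$index, 0)
  expect_equal(r$classification, "antagonistic")
  # knockdown that amplifies the induction is synergistic
  r2 <- interaction_index(1, 0.6, 3, 2.5, direction = "increases")
  expect_equal(r2$classification, "synergistic")
})

test_that("the index is scale-invariant and obeys the multiplicative-null identity", {
  set.seed(403)
  for (i in 1:200) {
    q <- runif(4, 0.1, 200)
    a <- runif(1, 0.01, 100)
    i1 <- interaction_index(q[1], q[2], q[3], q[4])
    i2 <- interaction_index(a * q[1], a * q[2], a * q[3], a * q[4])
    expect_equal(i1$index, i2$index, tolerance = 1e-9)
    # null identity: R_IR = Rc * C_IR / Cc gives index exactly 0
    null <- interaction_index(q[1], q[2], q[3], q[2] * q[3] / q[1])
    expect_equal(null$index, 0, tolerance = 1e-12)
  }
})

test_that("survival curves normalize per arm and localize synergy by background", {
  cfg <- screen_config(n_targets = 10, seed = 404)
  obs <- simulate_viability_arms(cfg, tech_reps = 100)
  sc <- survival_curves(obs)
  expect_true(all(sc$curves$survival[sc$curves$dose_gy == 0] == 1))
  nt <- sc$indices[sc$indices$co_kd == "NT", ]
  ck <- sc$indices[sc$indices$co_kd == "coKD", ]
  expect_true(all(abs(nt$index) < 0.05))          # multiplicative null arm
  expect_true(all(ck$index > 0.1))                # sensitizes only under co-KD
  expect_true(all(ck$classification == "synergistic"))

  # configured synergy of half the multiplicative expectation:
  # index = expected / 2 in closed form
  vm <- viability_model(survival = list(mock_cokd = c(1, 0.7, 0.4),
                                        target_cokd = c(1, 0.35, 0.2)))
  cfg2 <- screen_config(n_targets = 10, viability = vm, seed = 405)
  sc2 <- survival_curves(simulate_viability_arms(cfg2, tech_reps = 400))
  expect_equal(sc2$indices$index[sc2$indices$dose_gy == 2], 0.7 / 2,
               tolerance = 0.05)
  expect_equal(sc2$indices$index[sc2$indices$dose_gy == 5], 0.4 / 2,
               tolerance = 0.05)

  expect_error(survival_curves(obs[obs$dose_gy > 0, ]), "dose-0")
})
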