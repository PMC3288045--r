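test_that("equal-spread controls gate at the geometric midpoint of medians", {
  set.seed(101)
  neg <- lognormal_cells(5000, 100, 0.1)
  pos <- lognormal_cells(5000, 40, 0.1)
  g <- derive_gate(neg, pos, "ch_marker", direction = "below")
  expect_s3_class(g, "gate_spec")
  expect_equal(g$threshold, sqrt(100 * 40), tolerance = 0.05)
  # provenance recorded
  expect_equal(g$derivation$n_neg, 5000)
  expect_true(g$threshold < g$derivation$median_neg &&
                g$threshold > g$derivation$median_pos)
})

test_that("indistinguishable or undersized controls are rejected", {
  set.seed(102)
  x <- lognormal_cells(2000, 80, 0.2)
  y <- lognormal_cells(2000, 80, 0.2)
  expect_error(derive_gate(x, y, "ch_marker"), "no separation")
  expect_error(derive_gate(x[1:100, ], y, "ch_marker"), "at least 500")
  expect_error(derive_gate(x, y, "ch_nonexistent"), "not found")
})

test_that("unequal-spread crossing matches a brute-force KDE grid scan", {
  set.seed(103)
  xn <- rlnorm(6000, log(100), 0.1)
  xp <- rlnorm(6000, log(40), 0.3)
  g <- derive_gate(xn, xp, "ch_marker")
  # oracle: scan |f_neg - f_pos| on a 0.1-AFU grid between the medians,
  # with the same common-bandwidth convention
  grid <- seq(median(xp), median(xn), by = 0.1)
  bw <- (bw.nrd0(log(xn)) + bw.nrd0(log(xp))) / 2
  dn <- density(log(xn), bw = bw, n = 4096,
                from = log(min(grid)), to = log(max(grid)))
  f_n <- approx(dn$x, dn$y, xout = log(grid))$y
  dp <- density(log(xp), bw = bw, n = 4096,
                from = log(min(grid)), to = log(max(grid)))
  f_p <- approx(dp$x, dp$y, xout = log(grid))$y
  oracle <- grid[which.min(abs(f_n - f_p))]
  expect_equal(g$threshold, oracle, tolerance = 0.02)
})

test_that("mixture-weight controls gate at the component crossing", {
  # realistic screen controls: same two components, different weights
  set.seed(104)
  im <- intensity_model()
  neg <- mixture_intensities(7500, 0.45, im)
  pos <- mixture_intensities(7500, 0.05, im)
  g <- derive_gate(neg, pos, "ch_marker")
  midpoint <- exp((im$lo_meanlog + im$hi_meanlog) / 2)
  expect_equal(g$threshold, midpoint, tolerance = 0.06)
})

test_that("gates are equivariant under common intensity rescaling", {
  set.seed(105)
  xn <- rlnorm(3000, log(100), 0.15)
  xp <- rlnorm(3000, log(30), 0.15)
  g1 <- derive_gate(xn, xp, "ch_marker")
  for (a in c(0.1, 7, 250)) {
    g2 <- derive_gate(a * xn, a * xp, "ch_marker")
    expect_equal(g2$threshold / g1$threshold, a, tolerance = 1e-6)
  }
})

test_that("pos_fraction counts responders and flags low-cell wells", {
  gate <- structure(list(channel = "ch_marker", threshold = 50,
                         direction = "below", method = "fixed",
                         derivation = list()), class = "gate_spec")
  cells <- lognormal_cells(2000, 100, 0.001)
  cells$ch_marker[1:300] <- 10          # 300 of 2000 below the gate
  ws <- pos_fraction(cells, gate)
  expect_equal(ws$pos_fraction, 15.0)
  expect_equal(ws$n_cells, 2000)
  expect_false(ws$flag_low_cells)

  none_below <- lognormal_cells(2000, 100, 0.001)
  expect_equal(pos_fraction(none_below, gate)$pos_fraction, 0)

  small <- lognormal_cells(1200, 100, 0.1)
  expect_true(pos_fraction(small, gate)$flag_low_cells)

  expect_error(pos_fraction(cells[0, ], gate), "no cells")
  bad <- cells; bad$ch_marker <- NA_real_
  expect_error(pos_fraction(bad, gate), "empty")
})

test_that("responder and non-responder fractions are complementary", {
  set.seed(106)
  below <- structure(list(channel = "ch_marker", threshold = 70,
                          direction = "below"), class = "gate_spec")
  above <- structure(list(channel = "ch_marker", threshold = 70,
                          direction = "above"), class = "gate_spec")
  cells <- lognormal_cells(5000, 70, 0.4)  # continuous: no ties at the gate
  expect_equal(pos_fraction(cells, below)$pos_fraction +
                 pos_fraction(cells, above)$pos_fraction, 100)
})

test_that("estimated responder fractions are unbiased on simulated wells", {
  set.seed(107)
  im <- intensity_model()
  g <- derive_gate(mixture_intensities(7500, 0.45, im),
                   mixture_intensities(7500, 0.05, im), "ch_marker")
  errs <- replicate(100, {
    p <- runif(1, 0.05, 0.6)
    n <- 2500
    resp <- rbinom(n, 1, p) == 1
    cells <- data.frame(plate_id = "P", well = "B01",
                        ch_marker = rlnorm(n, ifelse(resp, im$lo_meanlog,
                                                     im$hi_meanlog), im$sdlog))
    pos_fraction(cells, g)$pos_fraction - 100 * mean(resp)
  })
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(100))
})

test_that("G1 fractions follow the nuclear/cytoplasmic ratio gate", {
  base <- data.frame(plate_id = "P", well = "C01", cell_id = 1:2,
                     ch_dna = 1000, ch_marker = 500,
                     ch_gfp_nuc = c(50, 38), ch_gfp_cyto = c(20, 20))
  ws <- g1_fraction(base, min_cells = 1)
  expect_equal(ws$pos_fraction, 50)   # ratio 2.5 counted, 1.9 not

  # inclusive boundary: ratio exactly 2 is G1
  at2 <- base; at2$ch_gfp_nuc <- c(40, 40)
  expect_equal(g1_fraction(at2, min_cells = 1)$pos_fraction, 100)

  no_rep <- base; no_rep$ch_gfp_nuc <- NA_real_
  expect_error(g1_fraction(no_rep), "absent")

  # non-positive cytoplasm dropped and counted
  dropped <- base; dropped$ch_gfp_cyto[2] <- 0
  ws2 <- g1_fraction(dropped, min_cells = 1)
  expect_equal(ws2$n_cells, 1)
  expect_equal(attr(ws2, "n_dropped"), 1)
})

test_that("simulated reporter wells recover the planted G1 fraction", {
  set.seed(108)
  cells <- simulate_reporter_well(2000, 0.55)
  truth <- 100 * mean(cells$ch_gfp_nuc > cells$ch_gfp_cyto)  # planted states
  ws <- g1_fraction(cells)
  expect_equal(ws$pos_fraction, 55, tolerance = 1.5 / 55)
  expect_equal(ws$pos_fraction, truth, tolerance = 0.02)
})
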