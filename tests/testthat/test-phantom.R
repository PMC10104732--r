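test_that("vessel geometry obeys its closed-form radius profile", {
  # no stenosis: uniform tube
  g0 <- vessel_geometry(L = 30, R0 = 2, d = 0)
  expect_equal(vessel_radius(g0, c(0, 7.3, 15, 30)), rep(2, 4))

  # throat radius is R0 * (1 - d) by definition
  g5 <- vessel_geometry(L = 30, R0 = 2, d = 0.5)
  expect_equal(vessel_radius(g5, g5$s0), 1.0)

  # Gaussian bump evaluated one width away from the throat
  g3 <- vessel_geometry(L = 40, R0 = 1.8, d = 0.3, s0 = 20, w = 5)
  expect_equal(
    vessel_radius(g3, c(20 - 5, 20 + 5)),
    rep(1.8 * (1 - 0.3 * exp(-0.5)), 2)
  )

  expect_error(vessel_geometry(L = 30, R0 = 2, d = 1), "\\[0, 1\\)")
  expect_error(vessel_geometry(L = -1, R0 = 2, d = 0.2), "L")
  expect_error(vessel_geometry(L = 30, R0 = 0, d = 0.2), "R0")
})

test_that("noise-free rasterization is the analytic cylinder, converging with spacing", {
  geom <- vessel_geometry(L = 20, R0 = 2, d = 0)
  err <- vapply(c(0.8, 0.4), function(sp) {
    vol <- rasterize_ct(geom, spacing = sp, lumen = 1, background = 0, noise_sd = 0)
    count <- sum(vol$data > 0.5)
    # cylinder volume pi R0^2 L; z grid has one extra voxel-center plane at L
    analytic <- pi * geom$R0^2 * (geom$L + sp) / sp^3
    abs(count - analytic) / analytic
  }, numeric(1))
  expect_lt(err[1], 0.08) # partial-volume tolerance at 0.8 mm
  expect_lt(err[2], err[1] / 2 + 1e-12) # error halves or better as spacing halves

  # every axial slice's foreground is a centered disk of the expected radius
  vol <- rasterize_ct(geom, spacing = 0.5, lumen = 1, background = 0, noise_sd = 0)
  slice <- vol$data[, , 10] > 0.5
  nx <- dim(slice)[1]
  cx <- (nx + 1) / 2
  rows <- which(slice, arr.ind = TRUE)
  expect_true(all(sqrt((rows[, 1] - cx)^2 + (rows[, 2] - cx)^2) * 0.5 <= geom$R0 + 0.25))
})

test_that("rasterization is deterministic per seed and validates extent", {
  geom <- vessel_geometry(L = 10, R0 = 1.5, d = 0.4)
  a <- rasterize_ct(geom, spacing = 0.5, noise_sd = 15, seed = 42)
  b <- rasterize_ct(geom, spacing = 0.5, noise_sd = 15, seed = 42)
  c <- rasterize_ct(geom, spacing = 0.5, noise_sd = 15, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  expect_error(rasterize_ct(geom, spacing = 0.5, dims = c(4, 4, 4)), "too small")
})

test_that("supersampled occupancy yields graded partial-volume intensities", {
  geom <- vessel_geometry(L = 6, R0 = 1.2, d = 0)
  hard <- rasterize_ct(geom, spacing = 0.6, lumen = 1, background = 0, noise_sd = 0)
  soft <- rasterize_ct(geom,
    spacing = 0.6, lumen = 1, background = 0, noise_sd = 0, supersample = 4L
  )
  expect_setequal(unique(as.vector(hard$data)), c(0, 1))
  frac <- soft$data[soft$data > 0 & soft$data < 1]
  expect_gt(length(frac), 0) # boundary voxels are fractional
  # total occupancy mass approximates the exact cylinder volume; the
  # voxel-center count instead carries an extra half-voxel plane at each end
  vol_exact <- pi * geom$R0^2 * geom$L / 0.6^3
  expect_lt(abs(sum(soft$data) - vol_exact) / vol_exact, 0.05)
})

test_that("pressure waveforms average to their mean over whole cycles", {
  flat <- pressure_waveform(mean = 95, amplitude = 0, period = 0.8)
  expect_true(all(flat$pressure == 95))

  sine <- pressure_waveform(mean = 90, amplitude = 20, period = 0.8, n_cycles = 4)
  expect_equal(mean_pressure(sine), 90, tolerance = 1e-10)

  pulse <- pressure_waveform(mean = 100, amplitude = 25, period = 0.9, n_cycles = 3, shape = "pulse")
  expect_equal(mean_pressure(pulse), oracle_trapz_mean(pulse$time, pulse$pressure))
  expect_equal(mean_pressure(pulse), 100, tolerance = 1e-6)

  expect_error(pressure_waveform(period = 0), "period")
  expect_error(pressure_waveform(dt = -0.1), "dt")
})

test_that("cohort generator reproduces its requested correlation structure", {
  # independence limit
  c0 <- simulate_cohort(n = 10000, r_target = c(tc = 0, tg = 0, ldl = 0, apo = 0), seed = 11)
  for (v in c("total_cholesterol", "triglyceride", "ldl_c", "apob_apoa1")) {
    expect_lt(abs(cor(c0$syntax_score, c0[[v]])), 0.05)
  }

  # requested correlation recovered at n = 5000
  c3 <- simulate_cohort(n = 5000, r_target = c(tc = 0.3, tg = 0.3, ldl = 0.3, apo = 0.3), seed = 5)
  for (v in c("total_cholesterol", "triglyceride", "ldl_c", "apob_apoa1")) {
    expect_lt(abs(cor(c3$syntax_score, c3[[v]]) - 0.3), 0.05)
  }

  # marginal structure: non-negative integer scores, positive ratio
  expect_true(all(c3$syntax_score >= 0))
  expect_true(all(c3$syntax_score == round(c3$syntax_score)))
  expect_true(all(c3$apob_apoa1 > 0))
  expect_lt(abs(mean(c3$total_cholesterol) - 4.6), 0.1)
  expect_lt(abs(sd(c3$total_cholesterol) - 1.0), 0.1)
})

test_that("cohort generator is seed-deterministic and validates its spec", {
  a <- simulate_cohort(n = 50, seed = 9)
  b <- simulate_cohort(n = 50, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_cohort(n = 10, r_target = c(1, 0, 0, 0)), "strictly inside")
  bad_sigma <- matrix(0.99, 5, 5)
  diag(bad_sigma) <- 1
  bad_sigma[1, 2] <- bad_sigma[2, 1] <- -0.99 # wildly inconsistent
  expect_error(simulate_cohort(n = 10, sigma = bad_sigma), "positive definite")
})

test_that("group event rates follow the prescribed probabilities", {
  coh <- simulate_cohort(n = 3000, event_prob = c(low = 0.1, medium = 0.1, high = 0.4), seed = 21)
  rates <- group_event_rates(coh)$rates
  # binomial 99% bounds around each group's target probability
  p_tgt <- c(low = 0.1, medium = 0.1, high = 0.4)
  for (i in seq_len(3)) {
    p <- p_tgt[[rates$group[i]]]
    half <- qnorm(0.995) * sqrt(p * (1 - p) / rates$n[i])
    expect_lt(abs(rates$rate[i] - p), half + 1e-9)
  }
})
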