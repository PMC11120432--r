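presets <- load_sequence_presets()

test_that("two-point fit inverts exact exponentials and flags degeneracy", {
  expect_equal(fit_t2_two_point(100, 100 * exp(-1), 50)$t_ms, 50)
  expect_equal(fit_t2_two_point(100, 100 * exp(-1.25), 50)$t_ms, 40)
  flat <- fit_t2_two_point(100, 100, 50)
  expect_false(flat$valid)
  expect_true(is.na(flat$t_ms))
  expect_false(fit_t2_two_point(100, 2, 50, floor = 3)$valid)
  expect_error(fit_t2_two_point(100, 50, 0), "tau_ms")
})

test_that("log-linear fit recovers exact exponentials and rejects flat signals", {
  s <- 100 * exp(-c(0, 25, 50) / 45)
  fit <- fit_monoexp_loglinear(s, c(0, 25, 50))
  expect_equal(fit$t_ms, 45, tolerance = 1e-12)
  expect_equal(fit$s0, 100, tolerance = 1e-9)
  expect_equal(fit$rsq, 1)
  expect_true(fit$valid)

  flat <- fit_monoexp_loglinear(c(80, 80, 80), c(0, 25, 50))
  expect_false(flat$valid)
  expect_error(fit_monoexp_loglinear(100, 0), "pairs")
  expect_error(fit_monoexp_loglinear(c(1, 2), c(5, 5)), "duplicated")
})

test_that("log-linear fit matches the brute-force grid+refine SSE minimizer", {
  set.seed(42)
  times <- c(0, 25, 50)
  for (i in seq_len(100)) {
    truth <- runif(1, 20, 100)
    s <- exp(-times / truth) * (1 + rnorm(3, 0, 0.02))
    fit <- fit_monoexp_loglinear(s, times)
    oracle <- oracle_monoexp_t(s, times)
    expect_equal(fit$t_ms, oracle, tolerance = 1e-6)
  }
})

test_that("two-point and log-linear fits agree exactly on two points", {
  set.seed(7)
  for (i in seq_len(20)) {
    s <- c(1, runif(1, 0.1, 0.9))
    two <- fit_t2_two_point(s[1], s[2], 50)
    ll <- fit_monoexp_loglinear(s, c(0, 50))
    expect_equal(two$t_ms, ll$t_ms, tolerance = 1e-12)
  }
})

test_that("fitted times are invariant under global signal scaling", {
  set.seed(8)
  times <- c(0, 25, 50)
  s <- exp(-times / 45) * (1 + rnorm(3, 0, 0.05))
  base <- fit_monoexp_loglinear(s, times)$t_ms
  for (c_scale in c(0.1, 3, 1e4)) {
    expect_equal(fit_monoexp_loglinear(c_scale * s, times)$t_ms, base,
                 tolerance = 1e-12)
  }
})

test_that("noiseless map reconstruction equals truth in water voxels", {
  ph <- build_knee_phantom(small_config(), seed = 3)
  water <- water_voxels(ph)

  m_t2 <- reconstruct_map(simulate_stack(ph, presets[["MIX1"]], 0, 1), "T2",
                          floor = 0)
  expect_true(all(m_t2$valid[water]))
  expect_equal(m_t2$values_ms[water], ph$truth_t2_ms[water],
               tolerance = 1e-9)

  m_rho <- reconstruct_map(simulate_stack(ph, presets[["MIX2"]], 0, 1),
                           "T1rho", floor = 0)
  expect_true(all(m_rho$valid[water]))
  expect_equal(m_rho$values_ms[water], ph$truth_t1rho_ms[water],
               tolerance = 1e-9)
})

test_that("map reconstruction rejects mismatched prep families", {
  ph <- build_knee_phantom(small_config(), seed = 3)
  st1 <- simulate_stack(ph, presets[["MIX1"]], 0, 1)
  expect_error(reconstruct_map(st1, "T1rho"), "prep family mismatch")
  st_ref <- simulate_stack(ph, presets[["2D TSE PD-w FS"]], 0, 1)
  expect_error(reconstruct_map(st_ref, "T2"), "prep family mismatch")
})

test_that("fat-dominated voxels are flagged invalid, by diagnostics or truth mask", {
  ph <- build_knee_phantom(small_config(), seed = 3)
  fat <- ph$labels %in% c(4L, 5L)

  # MIX1: fat is saturated in the unprepared block only, so its signal rises
  m1 <- reconstruct_map(simulate_stack(ph, presets[["MIX1"]], 0.005, 2), "T2")
  expect_gt(mean(!m1$valid[fat]), 0.99)

  # MIX2: the suppressed/unsuppressed block inconsistency trips diagnostics
  m2 <- reconstruct_map(simulate_stack(ph, presets[["MIX2"]], 0.005, 2),
                        "T1rho")
  expect_gt(mean(!m2$valid[fat]), 0.99)

  # ground-truth masking mode gives exactly the fat-fraction mask
  mask <- fat_mask_from_phantom(ph)
  expect_identical(as.vector(mask), fat)
  m3 <- reconstruct_map(simulate_stack(ph, presets[["MIX2"]], 0.005, 2),
                        "T1rho", fat_mask = mask)
  expect_true(all(!m3$valid[fat]))
})

test_that("noisy two- and three-point recovery stays within 3% at SNR 50", {
  n <- 1e4
  sigma <- 1 / 50
  # two-point, truth 40 ms, tau 50 ms
  s1 <- add_rician_noise(array(1, n), sigma, seed = 21)
  s2 <- add_rician_noise(array(exp(-50 / 40), n), sigma, seed = 22)
  fit <- fit_t2_two_point(s1, s2, 50, floor = 3 * sigma)
  expect_gt(mean(fit$valid), 0.99)
  expect_lt(abs(mean(fit$t_ms[fit$valid]) - 40) / 40, 0.03)

  # three-point, truth 45 ms, TSL 0/25/50 ms
  times <- c(0, 25, 50)
  S <- vapply(seq_along(times), function(j) {
    as.vector(add_rician_noise(array(exp(-times[j] / 45), n), sigma,
                               seed = 30 + j))
  }, numeric(n))
  fits <- qmixture:::monoexp_loglinear_matrix(S, times, floor = 3 * sigma)
  ok <- fits$valid
  expect_gt(mean(ok), 0.99)
  expect_lt(abs(mean(fits$t_ms[ok]) - 45) / 45, 0.03)
})

test_that("region summaries aggregate valid voxels only", {
  ph <- build_knee_phantom(small_config(), seed = 4)
  m <- reconstruct_map(simulate_stack(ph, presets[["MIX1"]], 0, 1), "T2",
                       floor = 0)
  sm <- summarize_region(m, ph, c("femoral_cartilage", "tibial_cartilage",
                                  "synovial_fluid"))
  expect_equal(nrow(sm), 3)
  # noiseless: summary equals the truth-map mean over the same voxels
  fem <- ph$labels == 1L & m$valid
  expect_equal(sm$mean_ms[sm$region == "femoral_cartilage"],
               mean(ph$truth_t2_ms[fem]), tolerance = 1e-9)
  expect_equal(sm$sd_ms[sm$region == "synovial_fluid"], 0, tolerance = 1e-9)
  expect_equal(sm$n_voxels[sm$region == "femoral_cartilage"], sum(fem))

  # a fully invalid region errors
  m_masked <- m
  m_masked$valid[ph$labels == 6L] <- FALSE
  expect_error(summarize_region(m_masked, ph, "meniscus"), "no valid voxels")
})

test_that("constant region summarizes to its value with zero SD", {
  ph <- build_knee_phantom(small_config(), seed = 4)
  m <- reconstruct_map(simulate_stack(ph, presets[["MIX1"]], 0, 1), "T2",
                       floor = 0)
  # muscle truth is constant 32 ms
  sm <- summarize_region(m, ph, "muscle")
  expect_equal(sm$mean_ms, 32, tolerance = 1e-9)
  expect_equal(sm$sd_ms, 0, tolerance = 1e-9)
})
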