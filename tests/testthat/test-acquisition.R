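presets <- load_sequence_presets()

test_that("presets reproduce the published acquisition parameters", {
  expect_setequal(names(presets),
                  c("MIX1", "2D TSE PD-w FS", "3D TSE PD-w FS", "MIX2",
                    "2D TSE T1-w", "3D TSE T1-w"))
  mix1 <- presets[["MIX1"]]
  expect_equal(mix1$tr_ms, 1200)
  expect_length(mix1$blocks, 2)
  expect_equal(vapply(mix1$blocks, `[[`, 0, "prep_time_ms"), c(0, 50))
  expect_equal(vapply(mix1$blocks, `[[`, TRUE, "fat_sat"), c(TRUE, FALSE))

  mix2 <- presets[["MIX2"]]
  expect_equal(mix2$tr_ms, 600)
  expect_length(mix2$blocks, 3)
  expect_equal(vapply(mix2$blocks, `[[`, 0, "prep_time_ms"), c(0, 25, 50))
  expect_equal(vapply(mix2$blocks, `[[`, TRUE, "fat_sat"),
               c(FALSE, TRUE, TRUE))
  expect_equal(mix2$spinlock_freq_hz, 500)

  trs <- vapply(presets, `[[`, 0, "tr_ms")
  expect_equal(unname(trs[c("2D TSE PD-w FS", "3D TSE PD-w FS",
                            "2D TSE T1-w", "3D TSE T1-w")]),
               c(3000, 1100, 582, 400))
  tes <- vapply(presets, `[[`, 0, "te_equiv_ms")
  expect_equal(unname(tes), c(46, 40, 46, 13, 15, 21)[match(names(presets),
    c("MIX1", "2D TSE PD-w FS", "3D TSE PD-w FS", "MIX2", "2D TSE T1-w",
      "3D TSE T1-w"))])
})

test_that("steady-state signal obeys its defining identities", {
  tis <- tissue_params("cartilage", 0.8, 1200, 40, 45, 0)
  seq <- presets[["MIX1"]]
  b_none <- prep_block("none", 0, fat_sat = FALSE)
  b_zero <- prep_block("t2prep", 0, fat_sat = FALSE)
  s_none <- steady_state_signal(tis, 40, 45, b_none, seq)
  s_zero <- steady_state_signal(tis, 40, 45, b_zero, seq)
  expect_equal(s_none, s_zero)   # exp(0) = 1

  tis2 <- tis
  tis2$proton_density <- 2 * tis$proton_density
  expect_equal(steady_state_signal(tis2, 40, 45, b_none, seq), 2 * s_none)

  fat <- tissue_params("pure_fat", 1, 380, 130, 130, fat_fraction = 1)
  b_fs <- prep_block("none", 0, fat_sat = TRUE)
  s_sat <- steady_state_signal(fat, 130, 130, b_fs, seq, fs_residual = 0.05)
  s_unsat <- steady_state_signal(fat, 130, 130, b_none, seq)
  expect_equal(s_sat, 0.05 * s_unsat)
  # fat_fraction 1 with zero residual leaves no water contribution
  expect_equal(steady_state_signal(fat, 130, 130, b_fs, seq, fs_residual = 0),
               0)
  expect_error(steady_state_signal(tis, -1, 45, b_none, seq),
               "non-positive")
})

test_that("prep-ratio isolation holds: prepared/unprepared = exp(-tau/T)", {
  ph <- build_knee_phantom(small_config(), seed = 2)
  st <- simulate_stack(ph, presets[["MIX1"]], noise_sigma = 0, seed = 1)
  water <- water_voxels(ph)
  ratio <- st$volumes[[2]][water] / st$volumes[[1]][water]
  expect_equal(ratio, exp(-50 / ph$truth_t2_ms[water]), tolerance = 1e-12)

  st2 <- simulate_stack(ph, presets[["MIX2"]], noise_sigma = 0, seed = 1)
  ratio2 <- st2$volumes[[3]][water] / st2$volumes[[1]][water]
  # blocks 2-3 are fat saturated, but water-only voxels are unaffected
  expect_equal(ratio2, exp(-50 / ph$truth_t1rho_ms[water]), tolerance = 1e-12)
})

test_that("simulated stacks have one volume per block and are deterministic", {
  ph <- build_knee_phantom(small_config(), seed = 2)
  expect_length(simulate_stack(ph, presets[["MIX1"]], 0.01, seed = 3)$volumes, 2)
  expect_length(simulate_stack(ph, presets[["MIX2"]], 0.01, seed = 3)$volumes, 3)

  a <- simulate_stack(ph, presets[["MIX2"]], 0.01, seed = 3)
  b <- simulate_stack(ph, presets[["MIX2"]], 0.01, seed = 3)
  expect_identical(a$volumes, b$volumes)
  d <- simulate_stack(ph, presets[["MIX2"]], 0.01, seed = 4)
  expect_false(identical(a$volumes, d$volumes))
  # blocks use independent substreams: noise differs between blocks
  n1 <- a$volumes[[2]] - simulate_stack(ph, presets[["MIX2"]], 0, 3)$volumes[[2]]
  n2 <- a$volumes[[3]] - simulate_stack(ph, presets[["MIX2"]], 0, 3)$volumes[[3]]
  expect_false(identical(n1, n2))
  expect_true(all(vapply(a$volumes, function(v) all(v >= 0), TRUE)))
})

test_that("zero-sigma noise is the identity and magnitudes stay non-negative", {
  v <- array(runif(1000), c(10, 10, 10))
  expect_identical(add_rician_noise(v, 0, seed = 1), v)
  out <- add_rician_noise(v, 0.5, seed = 1)
  expect_true(all(out >= 0))
  expect_error(add_rician_noise(v, -1, seed = 1), ">= 0")
})

test_that("Rician noise matches the analytic Rayleigh and Rice means", {
  n <- 1e6
  zero <- add_rician_noise(array(0, n), 1, seed = 11)
  expect_equal(mean(zero), sqrt(pi / 2), tolerance = 0.01)
  hi <- add_rician_noise(array(100, n), 1, seed = 12)
  expect_equal(mean(hi), rice_mean(100, 1), tolerance = 0.001)
  # intermediate SNR against the closed-form Rice mean
  mid <- add_rician_noise(array(2, n), 1, seed = 13)
  expect_equal(mean(mid), rice_mean(2, 1), tolerance = 0.005)
})
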