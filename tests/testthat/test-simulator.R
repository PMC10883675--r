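test_that("session initialization is deterministic and validates its inputs", {
  cfg <- test_cfg()
  map <- make_grid_layout(5, 5, 0.4, origin = c(20, 0), cfg)
  s1 <- sim_init(map, cfg, seed = 4)
  s2 <- sim_init(map, cfg, seed = 4)
  expect_identical(s1$Athr, s2$Athr)
  expect_true(all(s1$A == 0) && all(s1$B == 0))
  expect_true(all(s1$Athr > 0))

  s3 <- sim_init(map, test_cfg(sigma = 0), seed = 4)
  expect_equal(s3$Athr, rep(cfg$theta50, 25))

  expect_error(sim_init(map[0, ], cfg), "empty")
})

test_that("thresholds stay fixed until explicitly re-initialized", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  before <- s$Athr
  s <- sim_step(s, list(amplitude_uA = 100, pulse_width_us = 170,
                        frequency_hz = 300))
  expect_identical(s$Athr, before)
  s2 <- sim_reset_thresholds(s, seed = 99)
  expect_false(identical(s2$Athr, before))
})

test_that("a large phosphene map over a 16 degree field initializes cleanly", {
  cfg <- phosim_config(resolution = c(64, 64), fov_deg = 16)
  map <- make_grid_layout(32, 32, 0.12, origin = c(25, 0), cfg)
  s <- sim_init(map, cfg, seed = 1)
  expect_equal(length(s$A), 1024)
})

test_that("zero stimulation from quiescence leaves a black frame and zero state", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  s <- sim_step(s, list(amplitude_uA = 0, pulse_width_us = 0,
                        frequency_hz = 0))
  expect_true(all(s$percept$image == 0))
  expect_equal(s$A, 0)
  expect_equal(s$B, 0)
  expect_equal(s$frame_count, 1L)
  expect_equal(s$clock, cfg$dt)
})

test_that("a 166 ms train at 20 uA produces no phosphenes at all", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  tr <- build_train_sequence(1, 20, 166, 170, 300, 1, 1, cfg$dt)
  out <- run_sequence(s, tr$stim, n_frames = tr$n_frames, trace = TRUE)
  expect_true(all(out$trace$Ieff == 0))
  expect_true(all(vapply(out$frames, function(f) all(f$image == 0), logical(1))))
})

test_that("brightness decays smoothly after stimulation offset", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  tr <- build_train_sequence(1, 500, 166, 170, 300, 1, 1, cfg$dt)
  out <- run_sequence(s, tr$stim, n_frames = tr$n_frames + 10, trace = TRUE)
  sums <- vapply(out$frames, function(f) sum(f$image), numeric(1))
  on_frames <- tr$n_frames
  expect_gt(sums[on_frames], 0)
  # after offset the percept persists and fades rather than vanishing
  expect_gt(sums[on_frames + 1], 0)
  expect_gt(sums[on_frames + 2], 0)
  post <- sums[(on_frames + 1):(on_frames + 10)]
  expect_true(all(diff(post) <= 0))
  expect_lt(post[10], post[1])
  # activation follows the exponential decay of the leaky integrator
  tail_A <- out$trace$A[(on_frames + 1):(on_frames + 10)]
  expect_equal(tail_A[-1] / tail_A[-10],
               rep(1 - cfg$dt / cfg$tau_act, 9), tolerance = 1e-9)
})

test_that("identical seeds give bit-identical frame sequences", {
  cfg <- test_cfg()
  map <- make_grid_layout(3, 3, 0.4, origin = c(20, 0), cfg)
  tr <- build_train_sequence(1:9, c(60, 120), 100, 170, 300, 0.5, 3, cfg$dt)
  run <- function() {
    s <- sim_init(map, cfg, seed = 21)
    run_sequence(s, tr$stim, n_frames = tr$n_frames)
  }
  o1 <- run()
  o2 <- run()
  for (i in seq_along(o1$frames)) {
    expect_identical(o1$frames[[i]]$image, o2$frames[[i]]$image)
  }
})

test_that("resuming from exported state reproduces the unsplit run exactly", {
  cfg <- test_cfg()
  map <- make_grid_layout(2, 2, 0.4, origin = c(20, 0), cfg)
  tr <- build_train_sequence(1:4, 300, 100, 170, 300, 0.4, 6, cfg$dt)
  full <- run_sequence(sim_init(map, cfg, seed = 5), tr$stim,
                       n_frames = tr$n_frames)

  half <- floor(tr$n_frames / 2)
  first <- tr$stim[tr$stim$frame <= half, ]
  second <- tr$stim[tr$stim$frame > half, ]
  second$frame <- second$frame - half
  s <- sim_init(map, cfg, seed = 5)
  part1 <- run_sequence(s, first, n_frames = half)
  state <- sim_state(part1$session)
  s2 <- sim_restore(sim_init(map, cfg, seed = 99), state)
  part2 <- run_sequence(s2, second, n_frames = tr$n_frames - half)

  rejoined <- c(part1$frames, part2$frames)
  for (i in seq_along(full$frames)) {
    expect_identical(full$frames[[i]]$image, rejoined[[i]]$image)
  }
})

test_that("the composed frame is the sum of single-electrode simulations", {
  cfg <- test_cfg(clip_mode = "none")
  map <- make_grid_layout(2, 2, 0.8, origin = c(18, 0), cfg)
  stim <- list(amplitude_uA = c(300, 420, 500, 350),
               pulse_width_us = 170, frequency_hz = 300)
  s_all <- sim_init(map, cfg, seed = 13)
  for (i in 1:3) s_all <- sim_step(s_all, stim)
  singles <- matrix(0, cfg$resolution[1], cfg$resolution[2])
  for (e in 1:4) {
    solo <- stim
    solo$amplitude_uA <- ifelse(seq_len(4) == e, stim$amplitude_uA, 0)
    s_e <- sim_init(map, cfg, seed = 13) # same seed: same thresholds
    for (i in 1:3) s_e <- sim_step(s_e, solo)
    singles <- singles + s_e$percept$image
  }
  expect_equal(s_all$percept$image, singles, tolerance = 1e-12)
})

test_that("dropped electrodes contribute nothing", {
  cfg <- test_cfg()
  map <- make_grid_layout(2, 2, 0.8, origin = c(18, 0), cfg)
  map_dropped <- map
  map_dropped$active <- c(TRUE, FALSE, FALSE, TRUE)
  stim <- list(amplitude_uA = 400, pulse_width_us = 170, frequency_hz = 300)
  s <- sim_init(map_dropped, cfg, seed = 2)
  s <- sim_step(s, stim)
  expect_equal(s$last_specs$brightness[c(2, 3)], c(0, 0))
  expect_equal(s$last_specs$Ieff[c(2, 3)], c(0, 0))
  # the same layout with all electrodes alive is strictly brighter
  s_full <- sim_init(map, cfg, seed = 2)
  s_full <- sim_step(s_full, stim)
  expect_gt(sum(s_full$percept$image), sum(s$percept$image))
})

test_that("a small amplitude increase raises both brightness and size", {
  cfg <- test_cfg(sigma = 0) # deterministic threshold at theta50
  map <- single_electrode_map(cfg)
  probe <- function(amp) {
    s <- sim_init(map, cfg, seed = 1)
    tr <- build_train_sequence(1, amp, 166, 170, 300, 1, 1, cfg$dt)
    out <- run_sequence(s, tr$stim, n_frames = tr$n_frames, trace = TRUE)
    i <- which.max(out$trace$brightness)
    c(brightness = out$trace$brightness[i],
      size = phosphene_size(amp, map$eccentricity_deg, cfg))
  }
  lo <- probe(260)
  hi <- probe(280)
  expect_gt(hi["brightness"], lo["brightness"])
  expect_gt(hi["size"], lo["size"])
})

test_that("malformed stimulation input is rejected with electrode context", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  expect_error(sim_step(s, list(amplitude_uA = NaN, pulse_width_us = 170,
                                frequency_hz = 300)),
               "amplitude_uA.*electrode")
  expect_error(sim_step(s, list(amplitude_uA = -5, pulse_width_us = 170,
                                frequency_hz = 300)), "non-negative")
  expect_error(run_sequence(s, tibble::tibble(frame = 1, electrode_id = 7,
                                              amplitude_uA = 10,
                                              pulse_width_us = 170,
                                              frequency_hz = 300)),
               "absent from the map")
})

test_that("an empty stimulation sequence produces no frames", {
  cfg <- test_cfg()
  s <- sim_init(single_electrode_map(cfg), cfg, seed = 1)
  out <- run_sequence(s, tibble::tibble(frame = integer(),
                                        electrode_id = integer(),
                                        amplitude_uA = numeric(),
                                        pulse_width_us = numeric(),
                                        frequency_hz = numeric()))
  expect_equal(length(out$frames), 0)
  expect_equal(out$session$frame_count, 0L)
})

test_that("amplitude quantization snaps to the ten-level safety grid", {
  expect_equal(quantize_amplitude(0), 0)
  expect_equal(quantize_amplitude(128), 128)
  expect_equal(quantize_amplitude(20), 128 / 9, tolerance = 1e-12)
  levels <- quantize_amplitude(seq(0, 128, length.out = 1000))
  expect_equal(sort(unique(levels)), seq(0, 128, length.out = 10),
               tolerance = 1e-12)
  # the smooth staircase tracks the hard quantizer away from the jumps
  x <- seq(2, 126, by = 1)
  hard <- quantize_amplitude(x)
  soft <- smooth_staircase(x, sharpness = 60)
  mid <- abs((x / (128 / 9)) - round(x / (128 / 9))) < 0.3
  expect_lt(max(abs(hard[mid] - soft[mid])), 1)
})
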