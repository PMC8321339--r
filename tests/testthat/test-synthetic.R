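test_that("generation is deterministic from the seed", {
  spec <- synthetic_spec(T = 40, bursts = list(list(20, 24, 1)), noise_std = 2,
                         seed = 77)
  a <- generate_sequence(spec)
  b <- generate_sequence(spec)
  expect_identical(a$stack$frames, b$stack$frames)
  # and a different seed changes the clip
  spec2 <- synthetic_spec(T = 40, bursts = list(list(20, 24, 1)), noise_std = 2,
                          seed = 78)
  expect_false(identical(generate_sequence(spec2)$stack$frames, a$stack$frames))
})

test_that("the generator refuses malformed specs", {
  expect_error(synthetic_spec(T = 60, bursts = list(list(20, 25)),
                              plateaus = list(c(23, 30)), seed = 1),
               "overlaps")
  expect_error(synthetic_spec(T = 60, plateaus = list(c(10, 20), c(15, 30)),
                              seed = 1), "disjoint")
  expect_error(synthetic_spec(T = 60, bursts = list(list(55, 70)), seed = 1),
               "outside")
  expect_error(synthetic_spec(T = 60, seed = 1, noise_std = -1), "noise_std")
  expect_error(synthetic_spec(T = 60), "seed")
})

test_that("noise-free plateau frames are bit-identical", {
  cl <- generate_sequence(synthetic_spec(T = 60, plateaus = list(c(20, 30)),
                                         noise_std = 0, seed = 5))
  for (t in 21:30) {
    expect_identical(cl$stack$frames[, , t], cl$stack$frames[, , 20])
  }
  # neighbours outside the plateau differ (micro-motion is on)
  expect_false(identical(cl$stack$frames[, , 19], cl$stack$frames[, , 20]))
  expect_true(all(cl$truth$still[20:30]))
  expect_false(any(cl$truth$still[c(19, 31)]))
})

test_that("exact-freeze mode keeps plateaus frozen under noise", {
  cl <- generate_sequence(synthetic_spec(T = 60, plateaus = list(c(20, 30)),
                                         noise_std = 2, exact_freeze = TRUE,
                                         seed = 6))
  expect_identical(cl$stack$frames[, , 25], cl$stack$frames[, , 20])
  expect_false(identical(cl$stack$frames[, , 40], cl$stack$frames[, , 41]))
})

test_that("bursts produce motion energy inside their interval", {
  cl <- generate_sequence(synthetic_spec(T = 60, bursts = list(list(25, 30, 1.2)),
                                         noise_std = 0, jitter_amp = 0,
                                         seed = 9))
  lh <- st_filter(rho_std = 2, phi_size = 2, mode = "LH")
  sigG <- spatial_std_signal(apply_separable(cl$stack, lh), "sigma_G")
  expect_gt(max(sigG$values[25:30]), 1e-3)
  # without jitter or noise the stretch far from the burst is exactly still
  expect_lt(max(sigG$values[40:55]), 1e-9)
})

test_that("benchmark clips carry adjacent frozen flanks and annotations", {
  bench <- make_benchmark(8, seed = 123)
  expect_length(bench$clips, 8)
  expect_true(all(bench$annotations$N == 8L))
  for (id in names(bench$clips)) {
    tr <- bench$clips[[id]]$truth
    expect_gte(nrow(tr$plateaus), 1)
    for (i in seq_len(nrow(tr$bursts))) {
      edges <- c(tr$bursts$onset[i] - 1L, tr$bursts$offset[i] + 1L)
      adjacent <- any(tr$plateaus$end %in% edges | tr$plateaus$start %in% edges)
      expect_true(adjacent)
    }
    # plateaus never overlap bursts
    for (i in seq_len(nrow(tr$plateaus))) {
      expect_false(any(tr$plateaus$start[i] <= tr$bursts$offset &
                         tr$bursts$onset <= tr$plateaus$end[i]))
    }
  }
  ann200 <- make_benchmark(1, seed = 4, fps = 200)$annotations
  expect_equal(unique(ann200$N), 64L)
})

test_that("noise-free recovery puts the global sigma_F minimum in a plateau", {
  cfg <- run_config(25, rho_std = 3)
  bench <- make_benchmark(6, seed = 31, noise_std = 0)
  for (id in names(bench$clips)) {
    cl <- bench$clips[[id]]
    res <- spot_frozen_frames(cl$stack, config = cfg)
    sF <- res$energy[["1"]]
    t_min <- sF$t_index[which.min(sF$values)]
    expect_true(any(cl$truth$plateaus$start <= t_min &
                      t_min <= cl$truth$plateaus$end))
  }
})

test_that("detection degrades monotonically with noise", {
  recovery <- function(noise) {
    bench <- make_benchmark(10, seed = 55, noise_std = noise)
    cfg <- run_config(25, rho_std = 3)
    hits <- 0
    for (id in names(bench$clips)) {
      cl <- bench$clips[[id]]
      sel <- head(spot_frozen_frames(cl$stack, config = cfg)$ranked$t, 3)
      tb <- cl$truth$bursts
      d <- vapply(sel, function(t) min(abs(t - c(tb$onset, tb$offset))), numeric(1))
      if (any(d < 4)) hits <- hits + 1
    }
    hits / 10
  }
  r2 <- recovery(2); r8 <- recovery(8)
  expect_gte(r2, r8)
  expect_gte(r2, 0.9)
})

test_that("luminance drift does not move the detected minima", {
  cfg <- run_config(25, rho_std = 3)
  base <- synthetic_spec(T = 80, bursts = list(list(40, 44, 1.2)),
                         plateaus = list(c(36, 39), c(45, 48)),
                         noise_std = 0, drift_rate = 0, seed = 202)
  drift <- base; drift$drift_rate <- -0.5
  m0 <- spot_frozen_frames(generate_sequence(base)$stack, config = cfg)$ranked
  m1 <- spot_frozen_frames(generate_sequence(drift)$stack, config = cfg)$ranked
  expect_true(all(abs(sort(m0$t) - sort(m1$t)) <= 1))
})

test_that("clips round-trip to disk in the package formats", {
  cl <- generate_sequence(synthetic_spec(T = 20, bursts = list(list(8, 11, 1)),
                                         noise_std = 0, seed = 12))
  dir <- withr::local_tempdir()
  write_synthetic_clip(cl, dir, "demo")
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  ann <- load_annotations(file.path(dir, "annotations.csv"))
  expect_equal(ann$onset, 8L)
  back <- load_frames(file.path(dir, "frames"), "image_dir", fps = 25)
  expect_equal(dim(back$frames), dim(cl$stack$frames))
  # 8-bit PNG quantization allows up to half a grey level of error
  expect_lt(max(abs(back$frames - cl$stack$frames)), 0.51)
})
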