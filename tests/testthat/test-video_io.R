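test_that("PNG image directories round-trip through write_frames/load_frames", {
  stk <- make_integer_stack(1, H = 8L, W = 8L, T = 4L)
  dir <- withr::local_tempdir()
  write_frames(stk, dir)
  back <- load_frames(dir, "image_dir", fps = 25)
  expect_equal(back$frames, stk$frames)
  expect_equal(back$fps, 25)
  # deterministic re-read
  again <- load_frames(dir, "image_dir", fps = 25)
  expect_identical(back$frames, again$frames)
})

test_that("identical frames load as an identical stack", {
  dir <- withr::local_tempdir()
  img <- matrix(0.5, 8, 8)
  for (i in 1:3) png::writePNG(img, file.path(dir, sprintf("f%02d.png", i)))
  stk <- load_frames(dir, "image_dir", fps = 25)
  expect_equal(dim(stk$frames), c(8, 8, 3))
  expect_true(all(stk$frames[, , 1] == stk$frames[, , 2]))
  expect_true(all(stk$frames[, , 2] == stk$frames[, , 3]))
})

test_that("multi-page TIFF acts as a video container", {
  stk <- make_integer_stack(2, T = 5L)
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(seq_len(5), function(t) stk$frames[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  back <- load_frames(path, "video_file", fps = 30)
  expect_equal(dim(back$frames), dim(stk$frames))
  expect_equal(back$frames, stk$frames, tolerance = 1e-4)
})

test_that("loader rejects bad sources", {
  expect_error(load_frames(tempfile("nope"), "image_dir", fps = 25), "exist")
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.1, 4, 4), file.path(dir, "a.png"))
  expect_error(load_frames(dir, "image_dir", fps = 25), "at least 2")
  png::writePNG(matrix(0.1, 4, 4), file.path(dir, "b.png"))
  png::writePNG(matrix(0.1, 6, 6), file.path(dir, "c.png"))
  expect_error(load_frames(dir, "image_dir", fps = 25), "inconsistent")
  dir2 <- withr::local_tempdir()
  png::writePNG(matrix(0.1, 4, 4), file.path(dir2, "a.png"))
  png::writePNG(matrix(0.2, 4, 4), file.path(dir2, "b.png"))
  expect_error(load_frames(dir2, "image_dir"), "fps")
})

test_that("color frames are converted with Rec.601 luma weights", {
  dir <- withr::local_tempdir()
  rgb <- array(0, dim = c(4, 4, 3)); rgb[, , 1] <- 1  # pure red
  png::writePNG(rgb, file.path(dir, "a.png"))
  png::writePNG(rgb, file.path(dir, "b.png"))
  stk <- load_frames(dir, "image_dir", fps = 25)
  expect_equal(stk$frames[1, 1, 1], 0.299 * 255, tolerance = 1e-6)
})

test_that("crop_roi restricts space, keeps time, and composes", {
  stk <- make_integer_stack(3, H = 20L, W = 30L, T = 4L)
  expect_equal(crop_roi(stk, roi_spec(0, 0, 30, 20))$frames, stk$frames)
  small <- crop_roi(stk, roi_spec(5, 3, 10, 8))
  expect_equal(dim(small$frames), c(8, 10, 4))
  expect_equal(mean(small$frames[, , 2]), mean(stk$frames[4:11, 6:15, 2]))
  # nested crops equal one composed crop
  ab <- crop_roi(crop_roi(stk, roi_spec(5, 3, 12, 10)), roi_spec(2, 4, 6, 5))
  once <- crop_roi(stk, roi_spec(7, 7, 6, 5))
  expect_equal(ab$frames, once$frames)
  expect_error(crop_roi(stk, roi_spec(25, 0, 10, 5)), "bounds")
})

test_that("scene partition covers the stack and honors cuts", {
  static <- frame_stack(array(10, dim = c(6, 6, 50)), fps = 25)
  expect_equal(partition_scenes(static, 0.1),
               data.frame(start = 1L, end = 50L))
  two <- frame_stack(array(c(rep(0, 6 * 6 * 25), rep(200, 6 * 6 * 25)),
                           dim = c(6, 6, 50)), fps = 25)
  expect_equal(partition_scenes(two, 0.1),
               data.frame(start = c(1L, 26L), end = c(25L, 50L)))
  sixty <- frame_stack(array(10, dim = c(4, 4, 60)), fps = 25)
  expect_equal(partition_scenes(sixty, user_cuts = 30),
               data.frame(start = c(1L, 30L), end = c(29L, 60L)))
  # property: any random stack partitions [1, T] disjointly
  set.seed(42)
  for (i in 1:5) {
    stk <- make_integer_stack(100 + i, T = 12L)
    sc <- partition_scenes(stk, cut_threshold = runif(1, 0.05, 0.5))
    expect_equal(sc$start[1], 1L)
    expect_equal(sc$end[nrow(sc)], 12L)
    if (nrow(sc) > 1) expect_true(all(sc$start[-1] == head(sc$end, -1) + 1L))
  }
})

test_that("annotation tables parse, default N from fps, and validate rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence_id,onset,apex,offset,fps",
               "1.1,49,,62,25",
               "casme_x,100,120,140,200"), path)
  ann <- load_annotations(path)
  expect_equal(ann$onset, c(49L, 100L))
  expect_equal(ann$N, c(8L, 64L))
  expect_true(is.na(ann$apex[1]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence_id,onset,apex,offset,fps", "s,10,12,11,25"), bad)
  expect_error(load_annotations(bad), "row 1")

  # explicit N column wins over the fps rule
  withN <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence_id,onset,apex,offset,fps,N", "a,5,,9,25,20"), withN)
  expect_equal(load_annotations(withN)$N, 20L)
})
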