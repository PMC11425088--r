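test_that("channel segregation labels a clean synthetic movie perfectly and flags planted dropouts", {
  gen <- generate_movie(shape = c(300, 24, 24), outlier_frac = 0, seed = 5)
  labs <- segregate_channels(gen$movie)
  expect_identical(labs, gen$truth$labels)
  # zero one frame: LED dropout, must come back as an outlier
  movie2 <- gen$movie
  movie2$frames[17, , ] <- 0
  labs2 <- segregate_channels(movie2)
  expect_equal(labs2[17], "outlier")
  expect_identical(labs2[-17], gen$truth$labels[-17])
  # constant movie is degenerate
  flat <- dual_channel_movie(array(7, c(10, 4, 4)))
  expect_error(segregate_channels(flat), "separability")
})

test_that("motion correction recovers planted integer shifts exactly against a reference frame", {
  gen <- generate_movie(shape = c(100, 48, 48), max_shift_px = 3,
                        hemo_amp = 0, outlier_frac = 0, seed = 6)
  bi <- which(gen$truth$labels == "blue")
  mc <- rigid_motion_correct(gen$movie$frames[bi, , ], template = 1)
  expect_identical(mc$shifts, gen$truth$shifts[bi, ])
  # already-aligned stack: zero shifts, untouched frames
  gen0 <- generate_movie(shape = c(40, 32, 32), max_shift_px = 0, seed = 6)
  b0 <- gen0$movie$frames[gen0$truth$labels == "blue", , ]
  mc0 <- rigid_motion_correct(b0, template = 1)
  expect_true(all(mc0$shifts == 0))
  expect_identical(mc0$corrected, b0)
  # constant stack: zero shifts; all-zero frame warns
  cst <- array(5, c(4, 8, 8))
  expect_true(all(rigid_motion_correct(cst)$shifts == 0))
  z <- cst; z[2, , ] <- 0
  expect_warning(rigid_motion_correct(z), "all-zero")
})

test_that("bilinear area binning preserves frame means and is the identity at fraction 1", {
  fr <- matrix(3.7, 10, 10)
  out <- spatial_bin(array(fr, c(1, 10, 10)), 0.8)
  expect_equal(dim(out), c(1, 8, 8))
  expect_equal(as.vector(out), rep(3.7, 64), tolerance = 1e-12)
  chk <- matrix(c(0, 1), 10, 10)  # checkerboard columns
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  out2 <- spatial_bin(array(chk, c(1, 10, 10)), 0.8)
  expect_equal(mean(out2), mean(chk), tolerance = 0.005 * mean(chk) + 1e-9)
  expect_identical(spatial_bin(array(chk, c(1, 10, 10)), 1),
                   array(chk, c(1, 10, 10)))
})

test_that("mask averaging is a vote: majority by default, intersection at vote 1", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  m3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_identical(average_masks(list(m1, m1, m1)), m1)
  avg <- average_masks(list(m1, m2, m3), vote = 0.5)
  expect_identical(as.vector(avg), c(TRUE, TRUE, TRUE, FALSE))  # 2-of-3 pixels in
  expect_identical(average_masks(list(m1, m2, m3), vote = 1), m1 & m2 & m3)
  expect_error(average_masks(list(m1, matrix(TRUE, 3, 3))), "mismatch")
})

test_that("ratiometric DF/F cancels a shared artifact; constant inputs give zero", {
  mask <- matrix(TRUE, 4, 4)
  cb <- array(100, c(50, 4, 4)); cg <- array(40, c(50, 4, 4))
  d0 <- compute_dff(cb, cg, mask)
  expect_equal(max(abs(d0$corrected)), 0)
  # green constant: corrected equals uncorrected
  h <- 1 + 0.1 * sin(seq_len(50) / 4)
  vb <- array(rep(100 * h, 16), c(50, 4, 4))
  d1 <- compute_dff(vb, cg, mask)
  expect_equal(d1$corrected, d1$uncorrected, tolerance = 1e-12)
  # shared multiplicative artifact cancels exactly in the ratio
  vg <- array(rep(40 * h, 16), c(50, 4, 4))
  d2 <- compute_dff(vb, vg, mask)
  expect_lt(max(abs(d2$corrected)), 1e-12)
  expect_gt(max(abs(d2$uncorrected)), 0.05)
  # F0 <= 0 in the mask is a baseline error
  bad <- cb; bad[, 1, 1] <- -1
  expect_error(compute_dff(bad, cg, mask), "baseline")
})

test_that("correction beats no correction at recovering ground-truth calcium", {
  gen <- generate_movie(shape = c(800, 24, 24), n_cells = 4, hemo_amp = 0.06,
                        outlier_frac = 0, max_shift_px = 0, seed = 12)
  blue <- gen$movie$frames[gen$truth$labels == "blue", , ]
  green <- gen$movie$frames[gen$truth$labels == "green", , ]
  dd <- compute_dff(blue, green, gen$truth$mask)
  sel <- as.vector(matrix(rowSums(gen$truth$cell_footprints) > 0.3, 24, 24) &
                     gen$truth$mask)
  truth_tr <- rowMeans(t(gen$truth$cell_footprints[sel, , drop = FALSE] %*%
                           t(gen$truth$cell_traces)))
  Tn <- dim(blue)[1]
  ctr <- rowMeans(matrix(dd$corrected, Tn)[, sel])
  utr <- rowMeans(matrix(dd$uncorrected, Tn)[, sel])
  expect_gt(cor(ctr, truth_tr), cor(utr, truth_tr))
  expect_gt(cor(ctr, truth_tr), 0.8)
  # the regression variant also helps
  dr <- compute_dff(blue, green, gen$truth$mask, method = "regression")
  rtr <- rowMeans(matrix(dr$corrected, Tn)[, sel])
  expect_gt(cor(rtr, truth_tr), cor(utr, truth_tr))
})

test_that("the band-pass filter rejects DC, passes 1 Hz, and is zero-phase", {
  const <- rep(4.2, 600)
  out <- temporal_bandpass(const, fps = 15)
  expect_lt(max(abs(out)), 1e-6 * 4.2)
  tt <- (0:899) / 15
  x <- sin(2 * pi * 1 * tt)
  y <- temporal_bandpass(x, fps = 15)
  amp <- diff(range(y[200:700])) / 2
  expect_gte(amp, 0.9); expect_lte(amp, 1.0 + 1e-6)
  # zero phase: peak cross-correlation at lag 0
  cc <- ccf(x[100:800], y[100:800], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(temporal_bandpass(x, fps = 8), "parameter error")
})

test_that("mask-aware smoothing spreads an impulse over the in-mask window only", {
  mask <- matrix(TRUE, 21, 21)
  fr <- matrix(0, 21, 21); fr[11, 11] <- 1
  sm <- spatial_smooth(fr, mask, size_px = 7)
  expect_equal(sum(sm > 0), 49)
  expect_equal(max(sm), 1 / 49)
  # constant frames are unchanged inside the mask, zero outside
  mask2 <- matrix(FALSE, 21, 21); mask2[5:15, 5:15] <- TRUE
  cm <- spatial_smooth(matrix(2, 21, 21), mask2)
  expect_equal(cm[mask2], rep(2, sum(mask2)))
  expect_equal(cm[!mask2], rep(0, sum(!mask2)))
  # an edge pixel averages over its in-mask neighbors only: still exact
  fr2 <- matrix(3, 21, 21)
  expect_equal(spatial_smooth(fr2, mask2)[5, 5], 3)
})

test_that("z-scoring gives per-pixel mean 0 / population SD 1, affine-invariantly", {
  set.seed(8)
  x <- array(rnorm(60 * 5 * 5, 10, 3), c(60, 5, 5))
  mask <- matrix(TRUE, 5, 5)
  z <- zscore_pixels(x, mask)
  m <- matrix(z, 60)
  expect_lt(max(abs(colMeans(m))), 1e-6)
  sds <- sqrt(colMeans(m^2))
  expect_lt(max(abs(sds - 1)), 1e-6)
  z2 <- zscore_pixels(5 * x + 3, mask)
  expect_equal(z2, z, tolerance = 1e-9)
  flat <- x; flat[, 2, 2] <- 7
  zf <- zscore_pixels(flat, mask)
  expect_equal(zf[, 2, 2], rep(0, 60))
  expect_equal(attr(zf, "n_flat"), 1L)
})

test_that("the pipeline runner enforces the canonical stage order end to end", {
  gen <- generate_movie(shape = c(240, 20, 20), outlier_frac = 0.0125,
                        max_shift_px = 1, seed = 13)
  expect_error(run_calcium_pipeline(gen$movie, stages = c("zscore", "dff")),
               "out-of-order")
  expect_error(run_calcium_pipeline(gen$movie, stages = c("segregate", "foo")),
               "unknown")
  res <- run_calcium_pipeline(gen$movie, mask = gen$truth$mask)
  expect_s3_class(res, "dff_movie")
  expect_equal(res$qc$n_outliers, 3)
  expect_equal(dim(res$dff)[2:3], c(16, 16))
  # z-scored in-mask pixels
  m <- matrix(res$dff, dim(res$dff)[1])
  inm <- as.vector(res$mask)
  expect_lt(max(abs(colMeans(m[, inm]))), 1e-6)
})

test_that("movies round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  gen <- generate_movie(shape = c(10, 8, 8), seed = 14)
  f <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(gen$movie, f)
  back <- read_movie_tiff(f)
  expect_equal(dim(back$frames), dim(gen$movie$frames))
  expect_lt(max(abs(back$frames - round(gen$movie$frames / 65535 * 65535))), 1.1)
})
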