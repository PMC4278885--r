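# Synthetic spot image generator: expectation identities, invariances,
# determinism, and the array-level experiment.

test_that("constructors validate their ranges", {
  expect_error(ground_truth(-0.1, 0.5), "q_ref_break")
  expect_error(ground_truth(0.5, 1.2), "coupling_efficiency")
  expect_error(ground_truth(0.5, 0.5, 0), "probe_density")
  expect_error(optical_model(gain_red = 0), "gains")
  expect_error(optical_model(fret_factor = 1.5), "fret_factor")
  expect_error(noise_model(background_offset = -1), "background_offset")
  expect_error(simulate_spot_imageset(ground_truth(0.5, 0.5), optical_model(),
                                      noise_model(), shape = c(8, 8)),
               "16 x 16")
})

test_that("noise-free expectations obey the ratio identities exactly", {
  # E[Ratio_RED] = (1-CE) + CE*q and E[Ratio_FRET] = 1-CE, pixel by pixel
  for (q in c(0, 0.353, 0.5, 1)) {
    for (ce in c(0.3, 0.8, 1)) {
      im <- small_spot(q, ce, optical = optical_model(illumination = "uniform"),
                       noise = noise_model(background_offset = 0),
                       sampling = FALSE)
      msk <- im$spot_mask
      rr <- (im$red_final / im$red_start)[msk]
      rf <- (im$fret_final / im$fret_start)[msk]
      expect_equal(rr, rep((1 - ce) + ce * q, sum(msk)), tolerance = 1e-12)
      if (ce < 1) {
        expect_equal(rf, rep(1 - ce, sum(msk)), tolerance = 1e-12)
      } else {
        expect_true(all(rf == 0))
      }
    }
  }
})

test_that("expected ratios are invariant to illumination and channel gains", {
  base <- small_spot(0.4, 0.7, optical = optical_model(illumination = "uniform"),
                     noise = noise_model(background_offset = 0), sampling = FALSE)
  # strong Gaussian illumination gradient and rescaled gains
  warped <- small_spot(0.4, 0.7,
                       optical = optical_model(gain_red = 300, gain_fret = 40,
                                               fret_factor = 0.5,
                                               illumination = "gaussian",
                                               illum_sigma = 20),
                       noise = noise_model(background_offset = 0), sampling = FALSE)
  msk <- base$spot_mask
  expect_equal((warped$red_final / warped$red_start)[msk],
               (base$red_final / base$red_start)[msk], tolerance = 1e-10)
  expect_equal((warped$fret_final / warped$fret_start)[msk],
               (base$fret_final / base$fret_start)[msk], tolerance = 1e-10)
  # the illumination field itself is non-uniform: start image varies
  expect_gt(stats::sd(warped$red_start[msk]), 0)
})

test_that("sampled realizations match expectations within sampling error", {
  im <- small_spot(0.5, 0.8, seed = 31,
                   optical = optical_model(illumination = "uniform"),
                   noise = noise_model(background_offset = 0))
  msk <- im$spot_mask
  rr <- (im$red_final / im$red_start)[msk]
  rf <- (im$fret_final / im$fret_start)[msk]
  n <- sum(msk)
  expect_lt(abs(mean(rr) - 0.6), 4 * stats::sd(rr) / sqrt(n))
  expect_lt(abs(mean(rf) - 0.2), 4 * stats::sd(rf) / sqrt(n))
})

test_that("q = 0, CE = 1 leaves only background in RED Final", {
  im <- small_spot(0, 1, noise = noise_model(background_offset = 40,
                                             read_noise_sd = 0,
                                             shot_noise = FALSE))
  expect_true(all(im$red_final == 40))
  # while RED Start carries signal inside the spot
  expect_gt(mean(im$red_start[im$spot_mask]), 100)
})

test_that("generation is deterministic per seed and restores the caller RNG", {
  a <- small_spot(0.3, 0.6, seed = 77)
  set.seed(123); x1 <- runif(1)
  b <- small_spot(0.3, 0.6, seed = 77)
  expect_identical(a$red_start, b$red_start)
  expect_identical(a$fret_final, b$fret_final)
  c <- small_spot(0.3, 0.6, seed = 78)
  expect_false(identical(a$red_start, c$red_start))
  set.seed(123); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulate_array_experiment writes a consistent, reproducible run", {
  ramp <- default_ramp()
  conds <- list(
    even = list(probe = make_probe(65, 65), ce = 0.8),
    strong = list(probe = make_probe(75, 65), ce = 0.6))
  layout <- matrix(NA_character_, 4, 4)
  layout[1, ] <- "even"
  layout[2, 1:2] <- "strong"
  dir1 <- tempfile("arr1_"); dir2 <- tempfile("arr2_")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  res1 <- simulate_array_experiment(layout, conds, ramp, out_dir = dir1,
                                    seed = 5, shape = c(64, 64))
  expect_equal(nrow(res1$manifest), 6)
  expect_setequal(list.files(dir1, pattern = "\\.tif$"),
                  unlist(res1$manifest[, c("red_start", "fret_start",
                                           "red_final", "fret_final")]))
  # ground truth q comes from the competition model
  expect_equal(unique(res1$truth$q_true[res1$truth$condition == "even"]), 0.5,
               tolerance = 1e-9)
  # rerun with the same seed: bit-identical images and identical tables
  res2 <- simulate_array_experiment(layout, conds, ramp, out_dir = dir2,
                                    seed = 5, shape = c(64, 64))
  expect_identical(res1$truth, res2$truth)
  f <- res1$manifest$red_start[1]
  expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                   readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))))
  # undefined condition is named in the error
  bad <- layout; bad[4, 4] <- "ghost"
  expect_error(simulate_array_experiment(bad, conds, ramp, out_dir = dir1, seed = 1),
               "ghost")
  # manifest round trip through read_spot_imageset
  spot <- read_spot_imageset(res1$manifest[1, ], dir1)
  expect_s3_class(spot, "spot_imageset")
  expect_equal(dim(spot$red_start), c(64, 64))
})

test_that("replicate spots of one condition differ only by noise", {
  ramp <- default_ramp()
  conds <- list(rep = list(probe = make_probe(67, 65), ce = 0.8))
  layout <- matrix(NA_character_, 4, 4)
  layout[1, ] <- "rep"
  dir <- tempfile("arrrep_")
  on.exit(unlink(dir, recursive = TRUE))
  res <- simulate_array_experiment(layout, conds, ramp, out_dir = dir,
                                   seed = 21, shape = c(128, 128))
  nfs <- vapply(seq_len(4), function(i) {
    quantify_spot(read_spot_imageset(res$manifest[i, ], dir))$nf
  }, numeric(1))
  q <- res$truth$q_true[1]
  # all four replicates recover the common ground truth closely
  expect_true(all(abs(nfs - q) < 0.02))
  expect_lt(stats::sd(nfs), 0.01)
})
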