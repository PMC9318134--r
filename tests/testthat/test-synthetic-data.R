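test_that("generated fields hit the requested fraction exactly, including edge cases", {
  f0 <- make_field(target = 0)
  expect_identical(sum(f0$mask), 0L)
  expect_equal(f0$true_fraction, 0)

  f100 <- make_field(target = 100)
  expect_true(all(f100$mask == 1L))
  expect_equal(f100$true_fraction, 100)

  for (target in c(3, 15, 28)) {
    f <- make_field(target = target, seed = target)
    # ground-truth conservation: fraction recomputed from pixels
    expect_equal(f$true_fraction, 100 * sum(f$mask) / prod(dim(f$mask)))
    expect_lt(abs(f$true_fraction - target), 0.5)
  }
})

test_that("field generation is bit-identical under a fixed seed", {
  a <- make_field(seed = 7L)
  b <- make_field(seed = 7L)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- make_field(seed = 8L)
  expect_false(identical(a$image, c$image))
})

test_that("an unreachable target fraction fails with a named constraint", {
  # sub-pixel blobs cannot cover 60% of the raster within the blob budget
  expect_error(
    generate_field(field_gen_params(extent = c(32, 32),
                                    target_fraction = 60,
                                    blob_axes = c(0.05, 0.06), seed = 1)),
    "blob_axes"
  )
})

test_that("GOOD fields have no brown-family pixels outside the truth mask", {
  f <- make_field(target = 20, seed = 3)
  sel <- color_range_select(f, color_range_spec(f$stain_color, 100))
  expect_identical(sel$weights == 1, f$mask == 1L)
})

test_that("background noise never alters ground truth and leaves zero-noise images unchanged", {
  f <- make_field(target = 12, seed = 4)

  z <- add_background_noise(f, 0, seed = 9)
  expect_identical(z$image, f$image)
  expect_equal(z$regime, "NOISE")

  n <- add_background_noise(f, 0.5, seed = 9)
  expect_identical(n$mask, f$mask)
  expect_equal(n$true_fraction, f$true_fraction)
  # stained pixels untouched; only background shifts toward the stain color
  changed <- apply(n$image != f$image, c(1, 2), any)
  expect_true(all(!changed[f$mask == 1L]))
  background <- sum(f$mask == 0L)
  expect_gte(sum(changed) / background, 0.01)

  expect_error(add_background_noise(f, 1.5), "noise_intensity")
  expect_error(add_background_noise(n, 0.5), "GOOD")
})

test_that("study fixtures match the requested design and are seed-stable", {
  expect_identical(generate_study_fixtures(0, 0), list())

  fx <- generate_study_fixtures(4, 3, seed = 11, extent = c(64, 64))
  expect_length(fx, 7)
  expect_equal(sum(vapply(fx, `[[`, "", "regime") == "GOOD"), 4)
  expect_equal(sum(vapply(fx, `[[`, "", "regime") == "NOISE"), 3)

  fx2 <- generate_study_fixtures(4, 3, seed = 11, extent = c(64, 64))
  expect_identical(
    vapply(fx, `[[`, 0, "true_fraction"),
    vapply(fx2, `[[`, 0, "true_fraction")
  )
  expect_identical(fx[[2]]$image, fx2[[2]]$image)
})

test_that("fixture fractions follow the declared uniform target distribution", {
  fx <- generate_study_fixtures(1000, 0, seed = 5, extent = c(32, 32),
                                fraction_range = c(1, 30))
  fr <- vapply(fx, `[[`, 0, "true_fraction")
  expect_true(all(fr >= 0.5 & fr <= 30.5))
  # mean of U(1, 30) is 15.5, sd is 29/sqrt(12)
  se <- (29 / sqrt(12)) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 15.5), 3 * se)
})

test_that("paired-difference simulation has the requested bias structure", {
  a <- generate_paired_differences(10, bias = 0, sd = 0, seed = 1)
  expect_equal(a$value_a, a$value_b)

  b <- generate_paired_differences(10, bias = 2, sd = 0, seed = 1)
  expect_equal(b$value_b - b$value_a, rep(2, 10))

  big <- generate_paired_differences(1e4, bias = -0.44, sd = 1, seed = 2,
                                     base = function(n) runif(n, 30, 70))
  d <- big$value_b - big$value_a
  expect_lt(abs(mean(d) - (-0.44)), 3 * 1 / sqrt(1e4))
  expect_identical(attr(big, "n_clipped"), 0L)

  clipped <- generate_paired_differences(500, bias = -5, sd = 1, seed = 3,
                                         base = function(n) runif(n, 0, 2))
  expect_gt(attr(clipped, "n_clipped"), 0)
  expect_true(all(clipped$value_b >= 0))
})

test_that("field round-trip through PNG + manifest preserves pixels and truth", {
  dir <- withr::local_tempdir()
  fx <- generate_study_fixtures(2, 1, seed = 2, extent = c(48, 48))
  manifest <- write_fields(fx, dir)
  expect_setequal(
    list.files(dir),
    c("manifest.csv", paste0(manifest$field_id, "_img.png"),
      paste0(manifest$field_id, "_mask.png"))
  )
  img <- read_ihc_image(file.path(dir, paste0(fx[[1]]$field_id, "_img.png")))
  expect_identical(img, fx[[1]]$image)
  m <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(m$true_fraction, vapply(fx, `[[`, 0, "true_fraction"))
})

test_that("simulated cohorts follow the two-group design", {
  co <- generate_cohort(n_per_group = 11, seed = 1)
  expect_s3_class(co, "cohort_data")
  expect_length(unique(co$patient_id), 22)
  expect_equal(length(unique(co$patient_id[co$group == "PI"])), 11)
  expect_equal(length(unique(co$patient_id[co$group == "PD"])), 11)
  expect_length(unique(co$marker), 7)
  # 4 fields per patient per marker per method
  counts <- table(co$patient_id, co$marker, co$method)
  expect_true(all(counts == 4))
  expect_identical(co, generate_cohort(n_per_group = 11, seed = 1))
})

test_that("a cohort without injected effects has equal group means in expectation", {
  vals <- replicate(40, {
    co <- generate_cohort(n_per_group = 6, marker_effects = numeric(0),
                          seed = sample.int(1e6, 1))
    mean(co$value[co$group == "PI"]) - mean(co$value[co$group == "PD"])
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.2)
})
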