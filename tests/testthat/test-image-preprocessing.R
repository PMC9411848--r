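# Scale conversion, augmentation and class equalization.

flat_image <- function(value, h = 20, w = 20) {
  image_sample(array(value, dim = c(h, w, 3)), class_label = "x")
}

test_that("the four scaler formulas meet their range contracts", {
  expect_equal(scale_image(flat_image(255), "normalize255"),
               array(1, dim = c(20, 20, 3)))

  two <- flat_image(0)
  two$pixels[1:10, , ] <- 200
  mm <- scale_image(two, "minmax")
  expect_setequal(unique(as.numeric(mm)), c(0, 1))

  withr::with_seed(1, {
    img <- image_sample(array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3)))
    st <- scale_image(img, "standard")
    expect_lt(abs(mean(st)), 1e-6)
    expect_lt(abs(sd(st) - 1), 1e-6)
    ma <- scale_image(img, "maxabs")
    expect_true(all(ma >= -1 & ma <= 1))
    expect_equal(max(abs(ma)), 1)
  })
})

test_that("degenerate images return zeros with a warning, not an error", {
  const <- flat_image(7)
  expect_warning(out <- scale_image(const, "minmax"), "constant")
  expect_true(all(out == 0))
  expect_warning(out2 <- scale_image(const, "standard"), "constant")
  expect_true(all(out2 == 0))
  expect_true(all(scale_image(flat_image(0), "maxabs") == 0))
})

test_that("minmax and maxabs are idempotent on already-scaled input", {
  withr::with_seed(2, {
    img <- image_sample(array(runif(300, 0, 255), c(10, 10, 3)))
    once <- scale_image(img, "minmax")
    twice <- scale_image(image_sample(once), "minmax")
    expect_equal(once, twice, tolerance = 1e-12)
    ma1 <- scale_image(img, "maxabs")
    ma2 <- scale_image(image_sample(ma1 * 255) , "maxabs") * 255
    expect_equal(as.numeric(ma1 * 255), as.numeric(ma2), tolerance = 1e-9)
  })
})

test_that("identity augmentation config reproduces the input", {
  img <- make_synthetic_drawing("spiral", 1, seed = 3)
  cfg <- augmentation_config(rotation_deg = 0, width_shift = 0, height_shift = 0,
                             shear = 0, zoom = 0, horizontal_flip = FALSE,
                             vertical_flip = FALSE, brightness_range = c(1, 1))
  out <- augment_image(img, cfg, seed = 1)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-9)
  expect_identical(out$provenance, "augmented")
})

test_that("brightness multiplies and clips pixel values", {
  img <- flat_image(100)
  cfg <- augmentation_config(rotation_deg = 0, width_shift = 0, height_shift = 0,
                             shear = 0, zoom = 0, horizontal_flip = FALSE,
                             vertical_flip = FALSE, brightness_range = c(2, 2))
  out <- augment_image(img, cfg, seed = 1)
  expect_true(all(abs(out$pixels - 200) < 1e-9))
  bright <- flat_image(200)
  out2 <- augment_image(bright, cfg, seed = 1)
  expect_true(all(out2$pixels == 255))  # clipped
})

test_that("augmentation is seed-deterministic and shape-preserving", {
  img <- make_synthetic_drawing("meander", 2, seed = 4)
  a <- augment_image(img, seed = 99)
  b <- augment_image(img, seed = 99)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), dim(img$pixels))
  c_ <- augment_image(img, seed = 100)
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("equalization lifts every class to the maximum original count", {
  ds <- c(lapply(1:3, function(i) make_synthetic_drawing("circle", 0, class_label = "A",
                                                         seed = i)),
          lapply(1, function(i) make_synthetic_drawing("spiral", 1, class_label = "B",
                                                       seed = 50)))
  eq <- equalize_classes(ds, seed = 5)
  counts <- table(vapply(eq, `[[`, "", "class_label"))
  expect_equal(as.numeric(counts), c(3, 3))
  # originals retained, additions marked augmented
  prov <- vapply(eq, `[[`, "", "provenance")
  expect_equal(sum(prov == "original"), 4)
  expect_equal(sum(prov == "augmented"), 2)

  # already-equal classes unchanged
  balanced <- ds[1:2]
  balanced[[2]]$class_label <- "B"
  expect_identical(equalize_classes(balanced, seed = 1), balanced)
})

test_that("image folders round-trip with aug_ prefixes", {
  ds <- c(lapply(1:2, function(i) make_synthetic_drawing("circle", 0, class_label = "HealthyCircle",
                                                         seed = i)),
          lapply(1, function(i) make_synthetic_drawing("spiral", 2, class_label = "PatientSpiral",
                                                       seed = 9)))
  eq <- equalize_classes(ds, seed = 6)
  dir <- withr::local_tempdir()
  write_image_folder(eq, dir)
  files <- list.files(dir, recursive = TRUE)
  expect_length(files, 4)
  expect_true(any(grepl("^PatientSpiral/aug_", files)))
  back <- load_image_folder(dir)
  expect_length(back, 4)
  expect_setequal(unique(vapply(back, `[[`, "", "class_label")),
                  c("HealthyCircle", "PatientSpiral"))
})
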