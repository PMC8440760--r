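test_that("PNG, TIFF and DICOM round trips preserve 8-bit pixels exactly", {
  px <- matrix(sample(0:255, 24 * 20, replace = TRUE), 24, 20)
  img <- mammo_image(px, patient_id = "P1", pixel_spacing = 0.07)
  for (ext in c("png", "tiff", "dcm")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_identical(unname(back$pixels), unname(px * 1.0))
  }
  # DICOM additionally carries pixel spacing
  path <- withr::local_tempfile(fileext = ".dcm")
  write_image(img, path)
  expect_equal(read_image(path)$pixel_spacing, 0.07)
})

test_that("reading preserves dynamic range and trivial images", {
  zero_path <- withr::local_tempfile(fileext = ".png")
  write_image(matrix(0, 16, 16), zero_path)
  z <- read_image(zero_path)
  expect_true(all(z$pixels == 0))
  expect_identical(dim(z$pixels), c(16L, 16L))

  ramp <- matrix(rep(0:255, length.out = 16 * 16), 16, 16)
  ramp_path <- withr::local_tempfile(fileext = ".png")
  write_image(ramp, ramp_path)
  expect_equal(max(read_image(ramp_path)$pixels), 255)
})

test_that("colour and missing inputs are rejected with clear errors", {
  rgb_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 8 * 3), dim = c(8, 8, 3)), rgb_path)
  expect_error(read_image(rgb_path), "channels")
  expect_error(read_image("nope.png"), "does not exist")
  expect_error(read_image(withr::local_tempfile(fileext = ".xyz")), "exist")
})

test_that("annotation CSVs are validated row by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- "patient_id,view,round,x,y,label"
  writeLines(header, path)
  expect_equal(nrow(read_annotations(path)), 0)

  writeLines(c(header,
               "P1,CC,recent,10,20,benign",
               "P1,CC,recent,30,40,suspicious",
               "P2,MLO,recent,5,6,benign"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$x, c(10, 30, 5))  # file order

  writeLines(c(header,
               "P1,CC,recent,1,1,benign",
               "P1,CC,recent,2,2,malignant"), path)
  expect_error(read_annotations(path), "malignant.*2|2.*malignant")
})

test_that("annotations survive a write/read round trip", {
  ann <- tibble::tibble(patient_id = "P9", view = "MLO", round = "recent",
                        x = c(3, 7), y = c(4, 8),
                        label = c("benign", "suspicious"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(as.data.frame(read_annotations(path)), as.data.frame(ann))
})

test_that("manifest loading is validated and order-stable", {
  dir <- withr::local_tempdir()
  for (f in c("r1.png", "p1.png", "r2.png", "p2.png")) {
    write_image(matrix(1:100 %% 256, 10, 10), file.path(dir, f))
  }
  for (f in c("a1.csv", "a2.csv")) {
    writeLines("patient_id,view,round,x,y,label", file.path(dir, f))
  }
  man <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(records = list(
    list(patient_id = "P1", view = "CC", recent_path = "r1.png",
         prior_path = "p1.png", annotation_path = "a1.csv",
         population = "normal"),
    list(patient_id = "P2", view = "CC", recent_path = "r2.png",
         prior_path = "p2.png", annotation_path = "a2.csv",
         population = "suspicious"))), man)
  recs <- read_manifest(man)
  expect_equal(recs$patient_id, c("P1", "P2"))
  expect_identical(recs, read_manifest(man))  # deterministic

  yaml::write_yaml(list(records = list(
    list(patient_id = "P1", view = "CC", recent_path = "r1.png",
         prior_path = "p1.png", annotation_path = "a1.csv",
         population = "normal"),
    list(patient_id = "P1", view = "CC", recent_path = "r2.png",
         prior_path = "p2.png", annotation_path = "a2.csv",
         population = "normal"))), man)
  expect_error(read_manifest(man), "more than once")

  yaml::write_yaml(list(records = list(
    list(patient_id = "P1", view = "CC", recent_path = "gone.png",
         prior_path = "p1.png", annotation_path = "a1.csv",
         population = "normal"))), man)
  expect_error(read_manifest(man), "missing file")
})

test_that("mammo_image enforces its invariants", {
  expect_error(mammo_image(matrix(-1, 2, 2)), "255")
  expect_error(mammo_image(matrix(NA_real_, 2, 2)), "finite")
  expect_s3_class(mammo_image(matrix(0.5, 3, 4)), "mammo_image")
})
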