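test_that("SpectrumSet enforces its invariants", {
  m <- matrix(1:6, 2, 3)
  s <- makeSet(m, wn = c(1000, 1004, 1008))
  expect_s4_class(s, "SpectrumSet")
  expect_equal(wavenumbers(s), c(1000, 1004, 1008))
  expect_equal(unname(intensities(s)), matrix(as.numeric(1:6), 2, 3))
  expect_equal(axisDirection(s), "ascending")
  # descending axes are legal and recorded
  expect_equal(axisDirection(makeSet(m, wn = c(1008, 1004, 1000))), "descending")
  # non-monotone axis rejected
  expect_error(makeSet(m, wn = c(1000, 1008, 1004)), "monotone")
  # duplicate ids rejected, naming the id
  expect_error(makeSet(m, wn = c(1000, 1004, 1008), ids = c("a", "a")), "a")
  # metadata consistency: pure <=> concentration 0 <=> adulterant none
  bad <- data.frame(class_label = "pure", adulterant = "apricot",
                    concentration = 10, variety = 1, set_role = "calibration")
  expect_error(makeSet(m[1, , drop = FALSE], wn = c(1000, 1004, 1008),
                       ids = "x", meta = bad), "pure")
})

test_that("CSV round trip is exact and metadata pairing survives", {
  set.seed(42)
  m <- matrix(rnorm(10 * 50), 10, 50)
  meta <- data.frame(class_label = rep(c("pure", "adulterated"), 5),
                     adulterant = rep(c("none", "apricot"), 5),
                     concentration = rep(c(0, 12.5), 5),
                     variety = rep(1:2, 5),
                     set_role = "validation1")
  s <- makeSet(m, wn = seq(650, by = 4, length.out = 50),
               ids = sprintf("v%02d", 1:10), meta = meta)
  path <- tempfile(fileext = ".csv")
  writeSpectraCSV(s, path)
  s2 <- readSpectraCSV(path)
  expect_identical(colnames(s2), colnames(s))
  expect_equal(max(abs(intensities(s2) - intensities(s))), 0)
  expect_equal(wavenumbers(s2), wavenumbers(s))
  expect_equal(sampleMeta(s2)$concentration, sampleMeta(s)$concentration)
  expect_equal(sampleMeta(s2)$class_label, sampleMeta(s)$class_label)
  # byte stability: writing twice gives identical files
  path2 <- tempfile(fileext = ".csv")
  writeSpectraCSV(s, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degenerate CSV shapes round trip", {
  wn <- c(1000, 1010)
  empty <- makeSet(matrix(numeric(0), 0, 2), wn = wn)
  p <- tempfile(fileext = ".csv")
  writeSpectraCSV(empty, p)
  expect_length(readLines(p), 1)          # header only
  back <- readSpectraCSV(p)
  expect_equal(ncol(back), 0)
  expect_equal(wavenumbers(back), wn)
  one <- makeSet(matrix(c(1.5, 2.5), 1, 2), wn = wn, ids = "only")
  writeSpectraCSV(one, p)
  expect_length(readLines(p), 2)
  expect_equal(unname(intensities(readSpectraCSV(p))), matrix(c(1.5, 2.5), 1, 2))
})

test_that("readSpectraCSV reports malformed input precisely", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,class_label,adulterant,concentration,variety,set_role,1000,1004",
               "a,pure,none,0,1,calibration,1.0,2.0",
               "a,pure,none,0,1,calibration,1.5,2.5"), p)
  expect_error(readSpectraCSV(p), "duplicate sample id.*a")
  writeLines(c("sample_id,class_label,adulterant,concentration,variety,set_role,1000,1004",
               "a,pure,none,0,1,calibration,1.0,oops"), p)
  expect_error(readSpectraCSV(p), "non-numeric intensity.*row 1.*1004")
  writeLines(c("sample_id,class_label,adulterant,concentration,variety,set_role,1000,banana",
               "a,pure,none,0,1,calibration,1.0,2.0"), p)
  expect_error(readSpectraCSV(p), "non-numeric wavenumber")
})

test_that("selectRegion keeps closed-interval columns and is idempotent", {
  grid <- seq(650, 4000, by = 4)
  set.seed(7)
  s <- makeSet(matrix(rnorm(3 * length(grid)), 3), wn = grid)
  # full-range bounds are the identity
  full <- selectRegion(s, 650, 4000)
  expect_equal(intensities(full), intensities(s))
  # analysis cut used for MIR modeling
  cut <- selectRegion(s, 650, 3700)
  expect_true(all(wavenumbers(cut) <= 3700))
  # closed interval: 1000..1100 on a step-4 grid through 1000 has 26 points
  s4 <- makeSet(matrix(rnorm(838), 1), wn = seq(648, by = 4, length.out = 838))
  expect_equal(nrow(selectRegion(s4, 1000, 1100)), 26)
  twice <- selectRegion(cut, 650, 3700)
  expect_equal(intensities(twice), intensities(cut))
  expect_error(selectRegion(s, 4100, 4200), "overlap")
  expect_error(selectRegion(s, 2000, 1000), "smaller")
  # row/metadata pairing is preserved under subsetting
  expect_identical(rownames(intensities(cut)), rownames(intensities(s)))
})

test_that("a synthetic calibration file reproduces the expected dimensions", {
  std <- generateStudy(studyDesign("mir", "apricot", "separable", seed = 3))
  p <- tempfile(fileext = ".csv")
  writeSpectraCSV(std$calibration, p)
  back <- readSpectraCSV(p)
  expect_equal(ncol(back), 100)     # samples
  expect_equal(nrow(back), 838)     # wavenumbers: 650..3998 by 4
  expect_equal(max(abs(intensities(back) - intensities(std$calibration))), 0)
})
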