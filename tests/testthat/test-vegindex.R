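test_that("index library has the 35 canonical names in stable order", {
  nm <- vi_names()
  expect_length(nm, 35)
  expect_identical(nm[1], "NDVI")
  expect_identical(nm[35], "MRVI")
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(nm, vi_names())
})

test_that("hand-evaluated formulas match", {
  expect_equal(compute_index("NDVI", nir = 0.5, red = 0.1), 0.4 / 0.6)
  expect_equal(compute_index("NDVI", nir = 0.3, red = 0.3), 0)
  expect_equal(compute_index("GCI", nir = 0.6, green = 0.2), 2.0)
  expect_equal(compute_index("SAVI", nir = 0.5, red = 0.1),
               1.5 * 0.4 / (0.5 + 0.1 + 0.16))
  expect_equal(compute_index("CVI", nir = 0.4, red = 0.1, green = 0.2),
               0.4 * 0.1 / 0.04)
  expect_error(compute_index("NOPE", nir = 0.5), class = "viselect_name_error")
})

test_that("duplicate printed formulas are numerically identical", {
  b <- random_bands(1000, seed = 42)
  expect_identical(compute_index("GCI", b), compute_index("CIg", b))
  expect_identical(compute_index("RECI", b), compute_index("CIre", b))
})

test_that("normalized-difference indices stay in [-1, 1] for positive bands", {
  b <- random_bands(500, seed = 7)
  for (nm in c("NDVI", "NDRE", "GNDVI", "NGRDI", "RI", "MRVI",
               "NormG", "NormR", "NormNIR")) {
    v <- compute_index(nm, b)
    expect_true(all(v >= -1 & v <= 1), label = nm)
  }
})

test_that("pure-ratio indices are invariant to common band scaling", {
  b <- random_bands(200, seed = 11)
  b2 <- as.data.frame(lapply(b, function(x) 3.7 * x))
  for (nm in c("RVI", "GRVI", "RGR", "RRI1", "RRI2", "CIg", "CIre",
               "NDVI", "NDRE", "GNDVI")) {
    expect_equal(compute_index(nm, b2), compute_index(nm, b),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("zero denominators become missing values, never sentinels", {
  expect_true(is.na(compute_index("RVI", nir = 0.5, red = 0)))
  expect_true(is.na(compute_index("CVI", nir = 0.5, red = 0.1, green = 0)))
  expect_true(is.na(compute_index("NDVI", nir = 0.2, red = -0.2)))
  # CCCI as printed divides by (NIR+RE)(NIR-R)(NIR+R)
  expect_true(is.na(compute_index("CCCI", nir = 0.3, red = 0.3, red_edge = 0.2)))
})

test_that("corrected dialect changes only the known typographic variants", {
  b <- random_bands(100, seed = 3)
  ndvi <- compute_index("NDVI", b)
  expect_equal(compute_index("TVI", b), ndvi + 0.5)
  tvi_expected <- suppressWarnings(sqrt(ndvi + 0.5))
  tvi_expected[is.nan(tvi_expected)] <- NA_real_
  expect_equal(compute_index("TVI", b, dialect = "corrected"), tvi_expected)
  ndre <- compute_index("NDRE", b)
  expect_equal(compute_index("CCCI", b, dialect = "corrected"), ndre / ndvi)
  for (nm in setdiff(vi_names(), c("TVI", "CCCI"))) {
    expect_identical(compute_index(nm, b, dialect = "corrected"),
                     compute_index(nm, b), label = nm)
  }
})

test_that("compute_all matches cell-wise compute_index and is deterministic", {
  tr <- simulate_experiment(sim_config(seed = 5))
  vit <- compute_all(tr$plots)
  expect_identical(dim(as.data.frame(vit)), c(120L, 36L))
  for (nm in c("NDVI", "CCCI", "ATSAVI", "TCARI", "MNLI", "MRVI")) {
    expect_identical(vit[[nm]], compute_index(nm, tr$plots), label = nm)
  }
  expect_identical(as.data.frame(compute_all(tr$plots)), as.data.frame(vit))
})

test_that("compute_all flags rows with zero-denominator indices", {
  pt <- data.frame(plot_id = c("a", "b"), blue = 0.05, green = c(0, 0.1),
                   red = 0.06, red_edge = 0.25, nir = 0.4)
  vit <- compute_all(pt)
  expect_identical(attr(vit, "incomplete"), c(TRUE, FALSE))
  expect_true(is.na(vit$CVI[1]) && is.na(vit$GRVI[1]))
  expect_false(is.na(vit$NDVI[1]))
  expect_gt(attr(vit, "missing_report")[["CVI"]], 0)
})

test_that("missing band columns raise a schema error naming the column", {
  pt <- random_bands(5)
  pt$red_edge <- NULL
  expect_error(compute_all(pt), "red_edge", class = "viselect_schema_error")
})

test_that("band validation warns but does not fail outside [0, 1]", {
  expect_warning(validate_bands(nir = c(0.5, 1.2), red = 0.1), "nir")
  expect_silent(validate_bands(nir = 0.5, red = 0.1))
})
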