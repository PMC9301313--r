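# feature tables here are built directly (a named 36-column matrix), since
# fitting only needs the named columns
fake_features <- function(x, key = "LAB_1_mean") {
  keys <- as.vector(outer(outer(c("RGB", "XYZ", "LAB", "HSV"), 0:2,
                                paste, sep = "_"),
                          c("mean", "median", "mode"), paste, sep = "_"))
  m <- matrix(0, nrow = length(x), ncol = length(keys),
              dimnames = list(NULL, keys))
  m[, key] <- x
  m
}

test_that("r_squared matches hand arithmetic and rejects degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1.0)
  obs <- c(2, 4, 9)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0.0)
  # SSres = 1, SStot = 2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(r_squared(1, 1), "n >= 2")
})

test_that("fitting an exact linear feature map recovers it perfectly", {
  conc <- c(0.5, 1, 2, 3, 5, 7)
  x <- 200 - 12 * conc            # feature = affine in concentration
  m <- fit_model(fake_features(x), conc, "LAB_1_mean", order = 1)
  expect_equal(m$training_r_squared, 1.0, tolerance = 1e-12)
  # inverting the map: conc = (200 - x)/12
  expect_equal(unname(m$coefficients), c(200 / 12, -1 / 12), tolerance = 1e-8)
  expect_error(fit_model(fake_features(x[1:2]), conc[1:2], "LAB_1_mean",
                         order = 1), "training points")
  expect_error(fit_model(fake_features(x), conc, "LAB_1_mean", order = 4),
               "order")
  expect_error(fit_model(fake_features(x), conc,
                         c("LAB_1_mean", "RGB_0_mean")), "single space")
})

test_that("quadratic ground truth needs the quadratic term", {
  x <- seq(1, 4, length.out = 10)
  y <- 0.3 + 0.8 * x + 0.25 * x^2
  m2 <- fit_model(fake_features(x, "XYZ_0_mean"), y, "XYZ_0_mean", order = 2)
  expect_equal(unname(m2$coefficients), c(0.3, 0.8, 0.25), tolerance = 1e-8)
  pred2 <- predict(m2, fake_features(x, "XYZ_0_mean"))
  expect_lt(max(abs(pred2 - y)), 1e-8)
  m1 <- fit_model(fake_features(x, "XYZ_0_mean"), y, "XYZ_0_mean", order = 1)
  expect_lt(m1$training_r_squared, 1)
})

test_that("prediction floors at zero and validates its inputs", {
  model <- structure(list(space = "RGB", feature_keys = "RGB_0_mean",
                          order = 1L,
                          coefficients = c(`(Intercept)` = 1.5,
                                           `RGB_0_mean^1` = 0),
                          quantifiable_range = c(0.5, 7)),
                     class = "calibration_model")
  expect_equal(as.vector(predict(model, fake_features(c(10, 200)))),
               c(1.5, 1.5))
  model$coefficients <- c(`(Intercept)` = -0.2, `RGB_0_mean^1` = 0)
  expect_equal(as.vector(predict(model, fake_features(0))), 0.0)
  bad <- fake_features(1)[, -1, drop = FALSE]
  expect_error(predict(model, bad), "missing model key")
})

test_that("predictions outside the quantifiable range are flagged, not clipped", {
  conc <- c(0.5, 1, 2, 3, 5, 7, 9)
  m <- fit_model(fake_features(10 * conc, "LAB_0_mean"), conc, "LAB_0_mean", order = 1)
  pr <- predict(m, fake_features(10 * c(0.2, 3, 9), "LAB_0_mean"))
  expect_equal(as.vector(pr), c(0.2, 3, 9), tolerance = 1e-8)
  expect_equal(as.vector(attr(pr, "outside_range")), c(TRUE, FALSE, TRUE))
})

test_that("model selection maximises validation R^2 with the stated tie-breaks", {
  conc_t <- c(0.5, 1, 2, 3, 4, 5, 6, 7)
  conc_v <- c(0.8, 1.5, 2.5, 4.5, 6.5)
  lin <- function(c) 150 + 10 * c
  ft <- fake_features(lin(conc_t)); fv <- fake_features(lin(conc_v))

  one <- select_model(ft, conc_t, fv, conc_v, feature_keys = "LAB_1_mean",
                      orders = 2)
  expect_equal(one$order, 2L)
  expect_equal(one$validation_r_squared, 1.0, tolerance = 1e-10)

  # exact linear data: orders 1 and 2 tie at R^2 = 1; the lower order wins
  tie <- select_model(ft, conc_t, fv, conc_v, feature_keys = "LAB_1_mean",
                      orders = 1:2)
  expect_equal(tie$order, 1L)

  # equally perfect features in two spaces: the earlier space wins
  ft2 <- fake_features(lin(conc_t), key = "HSV_2_mean")
  ft2[, "XYZ_0_mean"] <- lin(conc_t)
  fv2 <- fake_features(lin(conc_v), key = "HSV_2_mean")
  fv2[, "XYZ_0_mean"] <- lin(conc_v)
  both <- select_model(ft2, conc_t, fv2, conc_v,
                       feature_keys = c("HSV_2_mean", "XYZ_0_mean"))
  expect_equal(both$space, "XYZ")

  expect_error(select_model(ft, conc_t, fv, conc_v,
                            feature_keys = character(0)), "empty candidate")
})

test_that("fit-then-predict is the identity on noiseless training data", {
  conc <- seq(0.5, 7, length.out = 9)
  x <- 240 - 15 * conc                    # exactly invertible at any order
  for (ord in 1:3) {
    m <- fit_model(fake_features(x, "RGB_1_median"), conc, "RGB_1_median",
                   order = ord)
    expect_lt(max(abs(predict(m, fake_features(x, "RGB_1_median")) - conc)),
              1e-6)
  }
})

test_that("stratified splitting keeps every level in both halves", {
  conc <- rep(c(0.5, 2, 4, 7), each = 5)
  sp <- stratified_split(conc, 0.6, seed = 3)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_along(conc))
  expect_setequal(unique(conc[sp$train]), unique(conc))
  expect_setequal(unique(conc[sp$validation]), unique(conc))
})

test_that("model JSON round-trips", {
  conc <- c(0.5, 1, 2, 3, 5, 7)
  m <- fit_model(fake_features(200 - 12 * conc), conc, "LAB_1_mean",
                 order = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m2$order, m$order)
  expect_equal(predict(m2, fake_features(150)), predict(m, fake_features(150)))
})
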