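# The estimation oracle is the simulator's own forward model:
# observed = gain * scene + offset (+ seeded Poisson-Gaussian noise).

calibration_stack <- function(gain, n = 60, photons = 2000, offset = 0.01,
                              seed = 1) {
  # flat-field exposures at varying levels, plus a few near-dark frames,
  # pushed through the same forward model the renderer uses
  rbscreen:::with_seed(seed, {
    levels <- c(stats::runif(n - 6, 0.1, 0.8), rep(0.02, 6))
    lapply(levels, function(cl)
      matrix(stats::rpois(length(gain), photons * as.numeric(gain * cl)) /
               photons, nrow(gain), ncol(gain)) + offset)
  })
}

test_that("a constant stack yields unit gain and a near-level offset", {
  stack <- replicate(50, matrix(5, 48, 48), simplify = FALSE)
  mod <- estimate_illumination(stack)
  expect_equal(as.numeric(mod$gain), rep(1, 48 * 48), tolerance = 1e-6)
  expect_equal(mean(mod$offset), 5, tolerance = 1e-6)
})

test_that("a known radial gain field is recovered from a calibration stack", {
  g <- vignette_gain(site_optics(field_px = 128L))
  stack <- calibration_stack(g, seed = 2)
  mod <- estimate_illumination(stack)
  expect_gt(stats::cor(as.numeric(mod$gain), as.numeric(g)), 0.95)
  # correcting the very stack used for estimation flattens it >= 5x
  cv <- function(m) stats::sd(as.numeric(m)) / mean(as.numeric(m))
  before <- Reduce(`+`, stack) / length(stack)
  after <- Reduce(`+`, lapply(stack, correct_image, model = mod)) /
    length(stack)
  expect_gte(cv(before) / cv(after), 5)
  # relative flatness restored to < 2% RMS of the (unit) flat scene
  expect_lt(sqrt(mean((after / mean(after) - 1)^2)), 0.02)
})

test_that("estimation rejects undersized or degenerate stacks", {
  stack10 <- replicate(10, matrix(1, 16, 16), simplify = FALSE)
  expect_error(estimate_illumination(stack10), "at least 50.*got 10")
  zeros <- replicate(50, matrix(0, 16, 16), simplify = FALSE)
  expect_error(estimate_illumination(zeros), "degenerate")
  mixed <- c(replicate(25, matrix(1, 16, 16), simplify = FALSE),
             replicate(25, matrix(1, 8, 8), simplify = FALSE))
  expect_error(estimate_illumination(mixed), "shape")
})

test_that("correction inverts the forward model and clips at zero", {
  g <- vignette_gain(site_optics(field_px = 64L))
  truth <- matrix(stats::runif(64^2, 0.1, 1), 64, 64)
  model <- structure(list(gain = g, offset = matrix(0.05, 64, 64),
                          n_images = 1L, params = list()),
                     class = "illumination_model")
  img <- g * truth + 0.05
  expect_equal(correct_image(img, model), truth, tolerance = 1e-10)
  # identity model
  id <- structure(list(gain = matrix(1, 64, 64),
                       offset = matrix(0, 64, 64), n_images = 1L,
                       params = list()), class = "illumination_model")
  expect_identical(correct_image(img, id), img)
  # negative intermediates clip to zero
  dark <- matrix(0.01, 64, 64)
  expect_true(all(correct_image(dark, model) == 0))
  expect_error(correct_image(matrix(1, 32, 32), model), "shape")
})

test_that("illumination model persists through TIFF + JSON roundtrip", {
  g <- vignette_gain(site_optics(field_px = 32L))
  stack <- calibration_stack(g, n = 50, seed = 4)
  mod <- estimate_illumination(stack)
  stem <- tempfile()
  write_illumination_model(mod, stem)
  rd <- read_illumination_model(stem)
  expect_equal(rd$gain, mod$gain, tolerance = 1e-5)
  expect_equal(rd$offset, mod$offset, tolerance = 1e-5)
  expect_equal(rd$n_images, mod$n_images)
})

test_that("focus filter rejects blurred copies but keeps sharp images", {
  fx <- screen_sites_fixture()
  sharp <- lapply(fx$sites[1:6], `[[`, "hoechst")
  blurred <- lapply(sharp[1:3], function(m)
    as.matrix(EBImage::gblur(EBImage::Image(m), sigma = 8)))
  names(sharp) <- paste0("sharp", 1:6)
  names(blurred) <- paste0("blur", 1:3)
  res <- focus_filter(c(sharp, blurred))
  expect_setequal(names(res$retained), names(sharp))
  expect_true(all(!res$log$retained[res$log$name %in% names(blurred)]))
  # sharpness scores order as the oracle predicts
  expect_gt(min(res$log$score[1:6]), max(res$log$score[7:9]))
  # all-sharp set: everything retained
  res2 <- focus_filter(sharp)
  expect_length(res2$retained, 6)
  # single image: retained, no population to compare
  res3 <- focus_filter(sharp[1])
  expect_length(res3$retained, 1)
})
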