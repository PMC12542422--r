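# Retrospective illumination (flat-field) correction. The model has two
# per-pixel terms, matching the standard vignetting forward model
# observed = gain * true + offset: an additive offset (camera/dark term)
# estimated as a smoothed low quantile of the stack, and a multiplicative
# gain (optical term) estimated as a smoothed robust per-pixel average of
# the offset-subtracted stack, normalized to mean 1.

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Estimate an illumination model from a stack of site images
#'
#' @param stack list of equally-sized matrices (one channel), or a 3-D array
#'   with the image index last.
#' @param min_images minimum stack size (default 50); fewer is an error.
#' @param quantile_q low quantile defining the additive offset.
#' @param sigma_frac Gaussian smoothing sigma as a fraction of image width.
#' @param trim trimming proportion of the per-pixel robust mean defining
#'   the gain (robust against sparse bright foreground objects).
#' @return object of class `illumination_model`: `gain` (mean 1, strictly
#'   positive), `offset`, `n_images`, and the parameters used.
#' @export
#' @examples
#' stack <- replicate(50, matrix(1, 32, 32), simplify = FALSE)
#' mod <- estimate_illumination(stack)
#' range(mod$gain)
estimate_illumination <- function(stack, min_images = 50L,
                                  quantile_q = 0.05, sigma_frac = 0.02,
                                  trim = 0.2) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  n <- length(stack)
  if (n < min_images)
    stopf("need at least %d images to estimate illumination, got %d",
          min_images, n)
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1) stopf("stack images differ in shape")
  arr <- array(unlist(stack, use.names = FALSE), c(dims[[1]], n))
  if (max(abs(arr)) == 0) stopf("degenerate stack: all pixels zero")
  sigma <- sigma_frac * dims[[1]][2]
  offset <- gaussian_smooth(apply(arr, c(1, 2), stats::quantile,
                                  probs = quantile_q, names = FALSE), sigma)
  resid <- sweep(arr, c(1, 2), offset)
  gain <- gaussian_smooth(apply(resid, c(1, 2), mean, trim = trim), sigma)
  if (mean(gain) <= 1e-10 * max(abs(arr))) {
    # no structure above the offset (e.g. a constant stack): unit gain
    gain <- matrix(1, dims[[1]][1], dims[[1]][2])
  } else {
    gain <- gain / mean(gain)
    gain <- pmax(gain, 1e-3)  # strictly positive by construction
  }
  structure(list(gain = gain, offset = offset, n_images = n,
                 params = list(min_images = min_images,
                               quantile_q = quantile_q,
                               sigma_frac = sigma_frac, trim = trim)),
            class = "illumination_model")
}

#' @export
print.illumination_model <- function(x, ...) {
  cat(sprintf("Illumination model: %dx%d, from %d images; gain range [%.3f, %.3f]\n",
              nrow(x$gain), ncol(x$gain), x$n_images,
              min(x$gain), max(x$gain)))
  invisible(x)
}

#' Correct an image with an illumination model
#'
#' Applies `corrected = (img - offset) / gain`, clipped at zero.
#'
#' @param img matrix.
#' @param model an `illumination_model` (shapes must match).
#' @return corrected matrix.
#' @export
correct_image <- function(img, model) {
  if (!all(dim(img) == dim(model$gain)))
    stopf("image shape %s does not match model shape %s",
          paste(dim(img), collapse = "x"),
          paste(dim(model$gain), collapse = "x"))
  pmax((img - model$offset) / model$gain, 0)
}

#' Persist / load an illumination model
#'
#' The model is stored as a two-page float TIFF (gain, offset) with a JSON
#' sidecar holding the parameters.
#'
#' @param model an `illumination_model`.
#' @param path file stem; writes `<stem>.tif` and `<stem>.json`.
#' @return `path` (write) or the model (read).
#' @export
write_illumination_model <- function(model, path) {
  # TIFF pixel data live in [0, 1]; persist both fields divided by a common
  # scale recorded in the sidecar
  scale <- max(model$gain, model$offset, 1e-12)
  EBImage::writeImage(EBImage::Image(abind_2(model$gain / scale,
                                             model$offset / scale)),
                      paste0(path, ".tif"), type = "tiff",
                      bits.per.sample = 32L)
  jsonlite::write_json(c(model$params, list(n_images = model$n_images,
                                            scale = scale)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_illumination_model
#' @export
read_illumination_model <- function(path) {
  img <- EBImage::readImage(paste0(path, ".tif"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- EBImage::imageData(img)
  as_plain <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  structure(list(gain = as_plain(arr[, , 1]) * meta$scale,
                 offset = as_plain(arr[, , 2]) * meta$scale,
                 n_images = meta$n_images,
                 params = meta[setdiff(names(meta), c("n_images", "scale"))]),
            class = "illumination_model")
}

laplacian_variance <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  f <- as.matrix(EBImage::filter2(EBImage::Image(img), k))
  stats::var(as.numeric(f))
}

#' Exclude out-of-focus images by relative sharpness
#'
#' Sharpness is the variance of the Laplacian. An image is rejected when its
#' score falls below `fraction` times the batch median score, which makes
#' the rule exposure-invariant. A single image is always retained (no
#' population to compare against).
#'
#' @param images named list of matrices.
#' @param fraction rejection fraction of the median score (default 0.2).
#' @return list with `retained` (list of images), `log` (data.frame of
#'   name, score, retained flag). Warns if everything is rejected.
#' @export
focus_filter <- function(images, fraction = 0.2) {
  if (!length(images)) stopf("need at least one image")
  if (is.null(names(images)))
    names(images) <- sprintf("img%03d", seq_along(images))
  score <- vapply(images, laplacian_variance, numeric(1))
  keep <- if (length(images) == 1L) TRUE
          else score >= stats::median(score) * fraction
  if (!any(keep)) warning("focus filter rejected every image")
  list(retained = images[keep],
       log = data.frame(name = names(images), score = unname(score),
                        retained = unname(keep), stringsAsFactors = FALSE))
}
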