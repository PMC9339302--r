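# Synthetic DAPI-field generator.
#
# Each nucleus is rendered as an isotropic 2-D Gaussian intensity blob.
# Intensities are scaled so that at the default segmentation threshold
# (half the blob amplitude) the blob's full width equals
# compaction * mask_diameter_px: compaction 1 reproduces a wildtype-sized
# mass that exactly fills the circular ROI mask, compaction < 1 a
# hypercondensed (smaller) mass. A fraction of masses carries a thin
# bright protrusion emulating the rDNA loop that emanates from the
# genomic mass.

BLOB_AMPLITUDE <- 0.8

#' Specify a synthetic DAPI field
#'
#' @param width,height Field size in pixels.
#' @param n_nuclei Number of nuclear masses (>= 0).
#' @param compaction Mass-size scale factor in `(0, 1]`; the rendered
#'   full width at the segmentation threshold is
#'   `compaction * mask_diameter_px`.
#' @param loop_probability Fraction of masses carrying a thin protrusion.
#' @param loop_length_px,loop_width_px Protrusion geometry in pixels;
#'   `loop_width_px` must stay below a quarter of the mask diameter.
#' @param noise_sd Additive Gaussian intensity noise (image intensities
#'   live in `[0, 1]`).
#' @param mask_diameter_px Reference ROI mask diameter (default 62).
#' @param min_separation_px Minimum centre-to-centre distance between
#'   nuclei; colliding draws are re-placed up to a retry cap.
#' @param seed Optional integer seed.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(width = 512, height = 512, n_nuclei = 12,
                       compaction = 1, loop_probability = 0.3,
                       loop_length_px = 20, loop_width_px = 3,
                       noise_sd = 0.02, mask_diameter_px = 62,
                       min_separation_px = 80, seed = NULL) {
  if (!is.numeric(compaction) || compaction <= 0 || compaction > 1) {
    stop_usage("compaction must lie in (0, 1]")
  }
  if (loop_width_px >= mask_diameter_px / 4) {
    stop_usage("loop_width_px must be below mask_diameter_px / 4")
  }
  if (mask_diameter_px >= min(width, height)) {
    stop_usage("nucleus diameter must be smaller than the field")
  }
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_nuclei = check_count(n_nuclei, "n_nuclei", min = 0),
               compaction = compaction, loop_probability = loop_probability,
               loop_length_px = loop_length_px, loop_width_px = loop_width_px,
               noise_sd = noise_sd, mask_diameter_px = mask_diameter_px,
               min_separation_px = min_separation_px, seed = seed)
  class(spec) <- "field_spec"
  spec
}

# sigma such that amplitude/2 is reached at radius theta * D / 2
blob_sigma <- function(theta, diameter_px) {
  theta * diameter_px / (2 * sqrt(2 * log(2)))
}

#' Render a synthetic DAPI field with ground truth
#'
#' Places `n_nuclei` Gaussian masses uniformly inside the field (keeping a
#' border margin and a minimum separation; a draw violating either is
#' re-placed, and the function errors after `max_retries` failures), adds
#' optional thin loop protrusions and Gaussian noise. Deterministic for a
#' fixed seed.
#'
#' @param spec A [field_spec()].
#' @param field_id Label recorded in the ground truth.
#' @param max_retries Placement retry cap per nucleus.
#' @return A list of class `nucleus_field`: `image` (height x width
#'   matrix in `[0, 1]`), `truth` (tibble `nucleus_id`, `x`, `y`,
#'   `compaction`, `has_loop`), `spec`, `field_id`.
#' @export
render_field <- function(spec = field_spec(), field_id = "field1",
                         max_retries = 200) {
  D <- spec$mask_diameter_px
  margin <- D / 2 + spec$loop_length_px + 2
  if (spec$width - 2 * margin <= 0 || spec$height - 2 * margin <= 0) {
    stop_usage("field too small for nucleus diameter plus loop margin")
  }
  with_seed_if(spec$seed, {
    centers <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        x <- runif(1, margin, spec$width - margin)
        y <- runif(1, margin, spec$height - margin)
        ok <- nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) >=
                spec$min_separation_px)
        if (ok) {
          centers <- rbind(centers, c(x, y))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_usage("could not place nucleus %d after %d retries", i,
                   max_retries)
      }
    }
    img <- matrix(0, nrow = spec$height, ncol = spec$width)
    xs <- matrix(rep(seq_len(spec$width), each = spec$height),
                 nrow = spec$height)
    ys <- matrix(rep(seq_len(spec$height), times = spec$width),
                 nrow = spec$height)
    has_loop <- logical(spec$n_nuclei)
    sigma <- blob_sigma(spec$compaction, D)
    for (i in seq_len(spec$n_nuclei)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      r2 <- (xs - cx)^2 + (ys - cy)^2
      img <- pmax(img, BLOB_AMPLITUDE * exp(-r2 / (2 * sigma^2)))
      if (runif(1) < spec$loop_probability) {
        has_loop[i] <- TRUE
        phi <- runif(1, 0, 2 * pi)
        r0 <- spec$compaction * D / 2
        p0 <- c(cx + r0 * cos(phi), cy + r0 * sin(phi))
        p1 <- p0 + spec$loop_length_px * c(cos(phi), sin(phi))
        img <- pmax(img, draw_segment(xs, ys, p0, p1,
                                      spec$loop_width_px / 2,
                                      BLOB_AMPLITUDE * 0.9))
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
    }
    img <- pmin(pmax(img, 0), 1)
    truth <- tibble(
      nucleus_id = seq_len(spec$n_nuclei),
      x = if (spec$n_nuclei > 0) centers[, 1] else numeric(0),
      y = if (spec$n_nuclei > 0) centers[, 2] else numeric(0),
      compaction = rep(spec$compaction, spec$n_nuclei),
      has_loop = has_loop
    )
    out <- list(image = img, truth = truth, spec = spec, field_id = field_id)
    class(out) <- "nucleus_field"
    out
  })
}

# intensity map of a capsule (segment p0-p1 with half-width hw)
draw_segment <- function(xs, ys, p0, p1, hw, amplitude) {
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- ((xs - p0[1]) * d[1] + (ys - p0[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- p0[1] + t * d[1]
  py <- p0[2] + t * d[2]
  dist <- sqrt((xs - px)^2 + (ys - py)^2)
  ifelse(dist <= hw, amplitude, 0)
}

#' @export
print.nucleus_field <- function(x, ...) {
  cat(sprintf("<nucleus_field> %s: %dx%d px, %d nuclei (compaction %.2f, %d loops)\n",
              x$field_id, ncol(x$image), nrow(x$image), nrow(x$truth),
              x$spec$compaction, sum(x$truth$has_loop)))
  invisible(x)
}

#' Write a rendered field as 16-bit TIFF plus JSON ground truth
#'
#' @param field A `nucleus_field` from [render_field()].
#' @param tiff_path Output TIFF path.
#' @param json_path Optional ground-truth sidecar path (defaults to the
#'   TIFF path with a `.json` extension).
#' @return `tiff_path`, invisibly.
#' @export
write_field <- function(field, tiff_path, json_path = NULL) {
  tiff::writeTIFF(field$image, tiff_path, bits.per.sample = 16L)
  json_path <- json_path %||% sub("\\.tiff?$", ".json", tiff_path)
  jsonlite::write_json(
    list(field_id = field$field_id,
         spec = field$spec[setdiff(names(field$spec), "seed")],
         truth = field$truth),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a grayscale field image
#'
#' Reads 8/16-bit grayscale TIFF or PNG into a numeric matrix in
#' `[0, 1]`; multi-channel images are averaged to grayscale.
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @return Numeric matrix (rows = image rows).
#' @export
read_field_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop_usage("reading PNG requires the png package")
    }
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}
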