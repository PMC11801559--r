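#' Specification for a synthetic radiograph phantom
#'
#' The phantom emulates the degradations the enhancement pipeline targets:
#' bright elongated "bone" ridges over a smooth soft-tissue background, then
#' global range compression (low contrast), mild Gaussian blur, and additive
#' Gaussian noise. It is a stand-in for clinical radiographs in tests, not an
#' anatomical simulation.
#'
#' @param height,width image size in pixels (default 256 x 256).
#' @param n_ridges number of bone-like line segments (default 4).
#' @param ridge_intensity intensity range (low, high) of ridges on `[0, 1]`
#'   (default 0.65-0.9).
#' @param background_blobs number of broad Gaussian soft-tissue blobs
#'   (default 6).
#' @param blob_intensity blob amplitude range (default 0.25-0.5).
#' @param contrast_factor global range compression b in (0, 1] (default 0.55).
#' @param offset additive pedestal a >= 0 (default 0.15);
#'   `offset + contrast_factor <= 1` so degradation never clips by design.
#' @param noise_sigma additive Gaussian noise s.d. on the `[0, 1]` scale
#'   (default 0.02).
#' @param blur_sigma Gaussian blur s.d. in pixels (default 1.0).
#' @param seed integer RNG seed (default 1).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_ridges = 4L,
                         ridge_intensity = c(0.65, 0.9),
                         background_blobs = 6L,
                         blob_intensity = c(0.25, 0.5),
                         contrast_factor = 0.55, offset = 0.15,
                         noise_sigma = 0.02, blur_sigma = 1.0, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_ridges = as.integer(n_ridges),
               ridge_intensity = ridge_intensity,
               background_blobs = as.integer(background_blobs),
               blob_intensity = blob_intensity,
               contrast_factor = contrast_factor, offset = offset,
               noise_sigma = noise_sigma, blur_sigma = blur_sigma,
               seed = as.integer(seed))
  if (spec$height < 2L || spec$width < 2L) stop("phantom must be >= 2x2")
  if (spec$offset < 0 || spec$contrast_factor <= 0 || spec$contrast_factor > 1)
    stop("need offset >= 0 and contrast_factor in (0, 1]", call. = FALSE)
  if (spec$offset + spec$contrast_factor > 1)
    stop("offset + contrast_factor must be <= 1 (no clipping by construction)",
         call. = FALSE)
  for (p in list(ridge_intensity, blob_intensity))
    if (length(p) != 2L || p[1] > p[2] || any(p < 0) || any(p > 1))
      stop("intensity pairs must be ordered and within [0, 1]", call. = FALSE)
  if (spec$noise_sigma < 0 || spec$blur_sigma < 0)
    stop("noise_sigma and blur_sigma must be >= 0", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# separable Gaussian blur with replicate padding; kernel truncated at 3 sigma
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_rows <- function(m) {
    n <- nrow(m)
    acc <- m * k[half + 1L]
    for (j in seq_len(half)) {
      up <- m[pmax(seq_len(n) - j, 1L), , drop = FALSE]
      dn <- m[pmin(seq_len(n) + j, n), , drop = FALSE]
      acc <- acc + k[half + 1L - j] * up + k[half + 1L + j] * dn
    }
    acc
  }
  t(blur_rows(t(blur_rows(x))))
}

# anti-aliased intensity profile of a thick segment: distance from each pixel
# to the segment, mapped through a half-pixel linear edge ramp
segment_profile <- function(height, width, p0, p1, halfwidth) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  tt <- ((rows - p0[1]) * v[1] + (cols - p0[2]) * v[2]) / max(len2, 1e-12)
  tt <- clamp(tt, 0, 1)
  d <- sqrt((rows - (p0[1] + tt * v[1]))^2 + (cols - (p0[2] + tt * v[2]))^2)
  clamp(halfwidth + 0.5 - d, 0, 1)   # 1 inside, linear ramp over 1 px at edge
}

#' Generate a synthetic radiograph phantom
#'
#' Builds `clean` (background blobs + ridges, clipped to `[0, 1]`), then
#' degrades: `image = quantize(clip(offset + contrast_factor * blur(clean)
#' + noise))`. Bit-exactly reproducible from the spec's seed: all sampling is
#' driven by R's default Mersenne-Twister/Inversion generator seeded locally
#' (the caller's RNG state is restored on exit).
#'
#' @param spec a [phantom_spec()].
#' @return List of class `phantom_result` with `image` (8-bit [raw_image()]),
#'   `bone_mask` (logical matrix of ridge pixels), `clean` (matrix in `[0,1]`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  background <- matrix(0, h, w)
  for (i in seq_len(spec$background_blobs)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    sy <- stats::runif(1, 0.15, 0.4) * h
    sx <- stats::runif(1, 0.15, 0.4) * w
    amp <- stats::runif(1, spec$blob_intensity[1], spec$blob_intensity[2])
    background <- background +
      amp * exp(-((rows - cy)^2 / (2 * sy^2) + (cols - cx)^2 / (2 * sx^2)))
  }
  background <- background / max(max(background), 1e-12) *
    spec$blob_intensity[2]

  ridges <- matrix(0, h, w)
  bone_mask <- matrix(FALSE, h, w)
  for (i in seq_len(spec$n_ridges)) {
    p0 <- c(stats::runif(1, 0.1 * h, 0.9 * h), stats::runif(1, 0.1 * w, 0.9 * w))
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.4, 0.9) * min(h, w)
    p1 <- p0 + len * c(sin(ang), cos(ang))
    halfwidth <- stats::runif(1, 2, 5)
    amp <- stats::runif(1, spec$ridge_intensity[1], spec$ridge_intensity[2])
    prof <- segment_profile(h, w, p0, p1, halfwidth)
    ridges <- pmax(ridges, amp * prof)
    bone_mask <- bone_mask | (prof >= 0.999)
  }

  clean <- clamp(pmax(background, ridges), 0, 1)
  degraded <- spec$offset + spec$contrast_factor * gaussian_blur(clean, spec$blur_sigma)
  if (spec$noise_sigma > 0)
    degraded <- degraded + stats::rnorm(h * w, 0, spec$noise_sigma)
  structure(
    list(image = to_octet(clamp(degraded, 0, 1)),
         bone_mask = bone_mask, clean = clean, spec = spec),
    class = "phantom_result"
  )
}

#' Generate a batch of phantoms with consecutive seeds
#'
#' @param n number of phantoms (>= 1).
#' @param base_seed seed of the first phantom; phantom i uses
#'   `base_seed + i - 1`.
#' @param spec template [phantom_spec()] whose seed is overridden.
#' @return List of `phantom_result`.
#' @export
make_fixture_batch <- function(n, base_seed = 1L, spec = phantom_spec()) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    spec$seed <- as.integer(base_seed + i - 1L)
    generate_phantom(spec)
  })
}
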