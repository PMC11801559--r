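#' Parameters for the tissue-attenuation contrast stage
#'
#' @param window odd side length of the square neighborhood over which the
#'   local maximum G and local minimum T are taken. Default 15: large enough
#'   to span soft-tissue structure at typical radiograph resolutions while
#'   staying local.
#' @param eps guard for quotients and logarithms (default 1e-6). Clamps are
#'   always applied after, never before, the governing formula.
#' @param degenerate_policy what a pixel does when the stretch denominator is
#'   degenerate (constant neighborhoods): `"pass_through"` keeps the input
#'   value, `"zero"` writes 0.
#' @return A list of class `contrast_params`.
#' @export
contrast_params <- function(window = 15L, eps = 1e-6,
                            degenerate_policy = c("pass_through", "zero")) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  structure(
    list(window = window, eps = eps,
         degenerate_policy = match.arg(degenerate_policy)),
    class = "contrast_params"
  )
}

# One-dimensional running extremum along rows via shifted pmin/pmax with
# replicate (edge-clamp) padding; applied to rows then columns this gives the
# separable window x window min/max filter.
running_extremum_rows <- function(x, half, fun) {
  n <- nrow(x)
  acc <- x
  for (k in seq_len(half)) {
    up <- x[pmax(seq_len(n) - k, 1L), , drop = FALSE]
    dn <- x[pmin(seq_len(n) + k, n), , drop = FALSE]
    acc <- fun(acc, up, dn)
  }
  acc
}

window_filter <- function(x, window, fun) {
  half <- (window - 1L) %/% 2L
  if (half == 0L) return(x)
  t(running_extremum_rows(t(running_extremum_rows(x, half, fun)), half, fun))
}

#' Local extrema over a sliding window
#'
#' Per-pixel maximum G and minimum T over the `window x window` neighborhood
#' centered at each pixel (grayscale dilation/erosion with a square structuring
#' element), with replicate padding at the borders so edges do not acquire
#' artificial zero minima.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params a [contrast_params()].
#' @return List of class `local_extrema` with matrices `local_max`, `local_min`.
#' @export
compute_local_extrema <- function(image, params = contrast_params()) {
  assert_norm(image)
  if (params$window > min(dim(image)))
    warning("window exceeds image extent; extrema become global")
  structure(
    list(local_max = window_filter(image, params$window, pmax),
         local_min = window_filter(image, params$window, pmin)),
    class = "local_extrema"
  )
}

#' Removable factor from local extrema
#'
#' The proportion of the local-minimum (highest-attenuation tissue) map judged
#' safe to subtract: `beta = exp(-G * var(T) / T)`, where `var(T)` is the
#' scalar sample variance (n-1 denominator) of the whole local-minimum map.
#' No manual tuning is involved; flat images (zero variance) give beta = 1.
#'
#' @param extrema a `local_extrema`.
#' @param params a [contrast_params()]; `eps` guards the division.
#' @return List of class `attenuation_maps` with `beta` and `t_variance`.
#' @export
removable_factor <- function(extrema, params = contrast_params()) {
  t_var <- stats::var(as.vector(extrema$local_min))
  beta <- exp(-extrema$local_max * t_var / pmax(extrema$local_min, params$eps))
  structure(
    list(beta = beta, t_variance = t_var, removable = NULL, psi = NULL),
    class = "attenuation_maps"
  )
}

#' Removable tissue component
#'
#' `R = beta * T`: the scaled part of the local-minimum map that the stretch
#' subtracts, leaving the detail component.
#'
#' @param maps an `attenuation_maps` with `beta` populated.
#' @param extrema the matching `local_extrema`.
#' @return `maps` with `removable` populated.
#' @export
removable_component <- function(maps, extrema) {
  maps$removable <- maps$beta * extrema$local_min
  maps
}

#' Brightness-consistency exponent
#'
#' Per-pixel exponent `psi = log(1 - R * (1/G - 1)) / log(G)` applied to the
#' local maximum so the stretched image keeps consistent overall brightness.
#' This parse makes psi a dimensionless non-negative exponent with psi = 0
#' when R = 0 (identity enhancement) and gives the stretch a fixed point at
#' local maxima. Where G >= 1 - eps the exponent is 1 by convention; the log
#' argument is clamped to `[eps, 1]`.
#'
#' @param maps an `attenuation_maps` with `removable` populated.
#' @param extrema the matching `local_extrema`.
#' @param params a [contrast_params()].
#' @return `maps` with `psi` populated.
#' @export
brightness_exponent <- function(maps, extrema, params = contrast_params()) {
  G <- extrema$local_max
  arg <- clamp(1 - maps$removable * (1 / pmax(G, params$eps) - 1), params$eps, 1)
  psi <- log(arg) / log(pmax(pmin(G, 1 - params$eps), params$eps))
  psi[G >= 1 - params$eps] <- 1
  maps$psi <- pmax(psi, 0)
  maps
}

#' Apply the contrast-enhancing dynamic-range stretch
#'
#' `E = (I - R) / (G^psi - R)` per pixel: subtract the removable component and
#' stretch what remains against the brightness-adjusted local maximum. The
#' numerator is clamped to >= 0, the denominator to >= eps, and the result to
#' `[0, 1]`; degenerate denominators (< eps) follow `degenerate_policy`.
#'
#' @param image numeric matrix in `[0, 1]` (the normalized input).
#' @param extrema,maps stage intermediates.
#' @param params a [contrast_params()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
apply_contrast_enhancement <- function(image, extrema, maps,
                                       params = contrast_params()) {
  denom <- extrema$local_max^maps$psi - maps$removable
  degenerate <- denom < params$eps
  e <- pmax(image - maps$removable, 0) / pmax(denom, params$eps)
  e <- clamp(e, 0, 1)
  if (any(degenerate)) {
    e[degenerate] <- switch(params$degenerate_policy,
      pass_through = image[degenerate],
      zero = 0
    )
  }
  e
}

#' Run the full tissue-attenuation contrast stage
#'
#' Composes local extrema, removable factor, removable component, brightness
#' exponent, and the stretch, returning all intermediates for inspection.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params a [contrast_params()].
#' @return List with `enhanced` (matrix), `extrema`, `maps`.
#' @export
run_contrast_stage <- function(image, params = contrast_params()) {
  extrema <- compute_local_extrema(image, params)
  maps <- removable_factor(extrema, params)
  maps <- removable_component(maps, extrema)
  maps <- brightness_exponent(maps, extrema, params)
  list(
    enhanced = apply_contrast_enhancement(image, extrema, maps, params),
    extrema = extrema,
    maps = maps
  )
}
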