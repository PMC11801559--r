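#' Parameters for the type-II fuzzy sharpening stage
#'
#' @param alpha enhancement strength in (0, 1); above about 0.6 the sharpening
#'   becomes pronounced. Default 0.7.
#' @param gamma positive exponent of the final max-preserving gamma
#'   correction. Default 1.2 (mild darkening of mid-tones; 1 = identity).
#' @param eps guard for the t-conorm denominator (default 1e-6).
#' @return A list of class `sharpness_params`.
#' @export
sharpness_params <- function(alpha = 0.7, gamma = 1.2, eps = 1e-6) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma, eps = eps),
            class = "sharpness_params")
}

#' Fuzzify an image onto [0, 1] membership grades
#'
#' Min-max stretch `f = (E - min E) / (max E - min E)`. A constant input has
#' no spread to stretch: it returns all zeros with attribute
#' `degenerate = TRUE` so callers can pass the image through unchanged.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @return Matrix spanning exactly `[0, 1]` (unless degenerate).
#' @export
fuzzify <- function(image) {
  assert_norm(image)
  lo <- min(image); hi <- max(image)
  if (hi - lo <= 0) {
    out <- array(0, dim(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (image - lo) / (hi - lo)
}

#' Global mean and standard deviation of the fuzzified image
#'
#' `mu` is the mean over all n pixels; `sigma` the sample standard deviation
#' with the n-1 denominator. Both are global (not windowed) and parameterise
#' the membership bounds and the Hamacher t-conorm.
#'
#' @param f fuzzified matrix.
#' @return List of class `global_stats` with `mu`, `sigma`, `n`.
#' @export
global_stats <- function(f) {
  n <- length(f)
  if (n < 2L) stop("need at least 2 pixels", call. = FALSE)
  structure(list(mu = mean(f), sigma = stats::sd(as.vector(f)), n = n),
            class = "global_stats")
}

#' Upper membership bound
#'
#' `u = f^alpha + (1 - f^alpha) * sigma^(2*alpha)`: a gamma-style brightening
#' of the membership grade, floored at `sigma^(2*alpha)` and reaching 1 at
#' f = 1, monotone increasing in f.
#'
#' @param f fuzzified matrix.
#' @param stats a [global_stats()] computed from `f`.
#' @param params a [sharpness_params()].
#' @export
upper_membership <- function(f, stats, params = sharpness_params()) {
  fa <- f^params$alpha
  fa + (1 - fa) * stats$sigma^(2 * params$alpha)
}

#' Lower membership bound
#'
#' Linear contrast stretch around the anchor `alpha * mu`:
#' `w_raw = (alpha * mu / (sigma + alpha)) * (f - alpha * mu)`, clamped to
#' `[0, u]` because interval type-II semantics require lower <= upper.
#'
#' @param f fuzzified matrix.
#' @param stats a [global_stats()].
#' @param params a [sharpness_params()].
#' @param upper matching upper bound (for the clamp); if `NULL` it is computed.
#' @export
lower_membership <- function(f, stats, params = sharpness_params(),
                             upper = NULL) {
  if (is.null(upper)) upper <- upper_membership(f, stats, params)
  anchor <- params$alpha * stats$mu
  w <- (anchor / (stats$sigma + params$alpha)) * (f - anchor)
  clamp(w, 0, upper)
}

#' Hamacher t-conorm fusion of the membership bounds
#'
#' The parametric Hamacher sum with parameter `lambda = sigma^2`:
#' `S(u, w) = (u + w + (sigma^2 - 2) u w) / (1 - (1 - sigma^2) u w)`.
#' Satisfies the t-conorm axioms (commutative, S(a,0)=a, S(a,1)=1, monotone).
#' A denominator below `eps` yields 1.
#'
#' @param upper,lower membership matrices in `[0, 1]`.
#' @param stats a [global_stats()] (supplies sigma).
#' @param params a [sharpness_params()].
#' @export
hamacher_tconorm <- function(upper, lower, stats, params = sharpness_params()) {
  s2 <- stats$sigma^2
  uw <- upper * lower
  denom <- 1 - (1 - s2) * uw
  t <- (upper + lower + (s2 - 2) * uw) / pmax(denom, params$eps)
  t[denom < params$eps] <- 1
  clamp(t, 0, 1)
}

#' Max-preserving gamma correction
#'
#' `L = max(t) * (t / max(t))^gamma`: a power law anchored at the map's own
#' maximum, so `max(L) = max(t)` exactly and ordering is preserved. An
#' all-zero map returns all zeros.
#'
#' @param t matrix in `[0, 1]`.
#' @param params a [sharpness_params()].
#' @export
gamma_correction <- function(t, params = sharpness_params()) {
  m <- max(t)
  if (m <= 0) return(array(0, dim(t)))
  m * (t / m)^params$gamma
}

#' Run the full type-II fuzzy sharpening stage
#'
#' Composes fuzzify, global stats, upper/lower membership, Hamacher t-conorm,
#' and gamma correction. A constant input is returned unchanged with
#' `degenerate = TRUE` in the result.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params a [sharpness_params()].
#' @return List with `enhanced`, `stats`, `maps` (upper/lower/tconorm/output),
#'   and `degenerate` flag.
#' @export
run_sharpness_stage <- function(image, params = sharpness_params()) {
  f <- fuzzify(image)
  if (isTRUE(attr(f, "degenerate"))) {
    return(list(enhanced = image, stats = NULL, maps = NULL, degenerate = TRUE))
  }
  stats <- global_stats(f)
  u <- upper_membership(f, stats, params)
  w <- lower_membership(f, stats, params, upper = u)
  t <- hamacher_tconorm(u, w, stats, params)
  L <- gamma_correction(t, params)
  list(
    enhanced = L,
    stats = stats,
    maps = list(fuzzified = f, upper = u, lower = w, tconorm = t, output = L),
    degenerate = FALSE
  )
}
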