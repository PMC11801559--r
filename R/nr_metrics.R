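#' Average gradient (AG)
#'
#' Mean local gradient magnitude on the 0-255 intensity scale, the standard
#' detail-contrast proxy: over the (M-1) x (N-1) interior grid,
#' `AG = mean( sqrt((dx^2 + dy^2) / 2) )` with dx, dy forward differences.
#' Higher values mean more visible detail. Normalized `[0,1]` matrices are
#' mapped to 0-255 first; 16-bit rasters are rescaled to the 8-bit range so
#' scores are comparable across depths.
#'
#' @param image a [raw_image()] or a numeric matrix in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
average_gradient <- function(image) {
  x <- as_octet_scale(image)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L || n < 2L) stop("image must be at least 2x2", call. = FALSE)
  dx <- x[-1, -n, drop = FALSE] - x[-m, -n, drop = FALSE]
  dy <- x[-m, -1, drop = FALSE] - x[-m, -n, drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Information entropy (IE)
#'
#' Shannon entropy in bits of the 256-bin gray-level histogram
#' (`-sum p_k log2 p_k`, with 0 log 0 := 0); bounded by 8 bits. Normalized
#' inputs are quantized to 256 levels first.
#'
#' @param image a [raw_image()] or a numeric matrix in `[0, 1]`.
#' @return Scalar in `[0, 8]`.
#' @export
information_entropy <- function(image) {
  x <- as_octet_scale(image)
  lev <- floor(x + 0.5)           # quantize to 0..255 (half away from zero)
  counts <- tabulate(lev + 1L, nbins = 256L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Create a metric registry
#'
#' Learned no-reference metrics (e.g. BIQME, FADE, MA) need externally trained
#' models that this package does not ship; a registry lets users plug such
#' scorers in as callables taking a `raw_image`/matrix and returning a scalar.
#'
#' @param ... named functions.
#' @return Named list of class `metric_registry`.
#' @export
metric_registry <- function(...) {
  reg <- list(...)
  if (length(reg) && (is.null(names(reg)) || any(names(reg) == "")))
    stop("all registered metrics must be named", call. = FALSE)
  if (!all(vapply(reg, is.function, logical(1))))
    stop("registered metrics must be functions", call. = FALSE)
  structure(reg, class = "metric_registry")
}

#' Score an image with the built-in and registered metrics
#'
#' Always computes AG and IE; registered external metrics are run with
#' failures recorded as `NA` plus a warning rather than aborting a batch.
#'
#' @param image a [raw_image()] or numeric matrix in `[0, 1]`.
#' @param registry a [metric_registry()] (default: empty).
#' @return List with `ag`, `ie`, and `extras` (named numeric, possibly empty).
#' @export
score_image <- function(image, registry = metric_registry()) {
  extras <- vapply(names(registry), function(nm) {
    tryCatch(as.numeric(registry[[nm]](image)), error = function(e) {
      warning(sprintf("metric '%s' failed: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  list(ag = average_gradient(image), ie = information_entropy(image),
       extras = extras)
}

#' Score table comparing enhancement methods on one source image
#'
#' One row per metric, one column per method, plus a per-metric `mean` column;
#' the layout used for method-comparison tables. Writable as CSV.
#'
#' @param images named list of images (same source radiograph, different
#'   methods).
#' @param registry a [metric_registry()].
#' @return `data.frame` with a `metric` column, one column per method, `mean`.
#' @export
compare_methods <- function(images, registry = metric_registry()) {
  if (!length(images)) stop("empty image collection", call. = FALSE)
  if (is.null(names(images)) || any(names(images) == ""))
    stop("images must be named by method", call. = FALSE)
  scores <- lapply(images, score_image, registry = registry)
  metric_names <- c("ag", "ie", names(registry))
  rows <- lapply(metric_names, function(mn) {
    vals <- vapply(scores, function(s) {
      if (mn %in% c("ag", "ie")) s[[mn]] else unname(s$extras[mn])
    }, numeric(1))
    c(list(metric = mn), as.list(vals), list(mean = mean(vals)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
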