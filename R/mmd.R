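#' Gaussian kernel configuration for MMD scoring
#'
#' @param bandwidth_policy `"median_heuristic"` (default): per comparison,
#'   sigma is the median of the nonzero pairwise absolute differences of
#'   the pooled two-group values; `"fixed"`: use `sigma` as given.
#' @param sigma Positive bandwidth, required when `bandwidth_policy` is
#'   `"fixed"`, ignored otherwise.
#' @param scale_mode `"raw"` (default) reports the unbiased MMD^2
#'   estimate itself (bounded above by 2 for the Gaussian kernel);
#'   `"m_scaled"` multiplies it by the first group size m, the
#'   convention behind sample-size-scaled test statistics.  Within one
#'   comparison all genes share group sizes, so gene ranking is
#'   unaffected by the choice.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(bandwidth_policy = c("median_heuristic", "fixed"),
                          sigma = NULL,
                          scale_mode = c("raw", "m_scaled")) {
  bandwidth_policy <- match.arg(bandwidth_policy)
  scale_mode <- match.arg(scale_mode)
  if (bandwidth_policy == "fixed") {
    if (is.null(sigma) || !is.numeric(sigma) || length(sigma) != 1L ||
        !is.finite(sigma) || sigma <= 0) {
      stop("fixed bandwidth policy requires a single positive sigma",
           call. = FALSE)
    }
  }
  structure(list(bandwidth_policy = bandwidth_policy,
                 sigma = if (bandwidth_policy == "fixed") sigma else NULL,
                 scale_mode = scale_mode),
            class = "kernel_config")
}

#' Gaussian (RBF) kernel between scalar expression values
#'
#' k(a, b) = exp(-(a - b)^2 / (2 sigma^2)); symmetric, in (0, 1], and
#' equal to 1 iff a = b.
#'
#' @param a,b Numeric vectors (recycled pairwise).
#' @param sigma Positive bandwidth.
#' @return Kernel values in (0, 1].
#' @export
gaussian_kernel <- function(a, b, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  exp(-(a - b)^2 / (2 * sigma^2))
}

#' Median-heuristic kernel bandwidth
#'
#' sigma = median of the nonzero pairwise absolute differences over the
#' pooled sample - the standard data-driven bandwidth for Gaussian-kernel
#' two-sample statistics.  Zero differences (ties, ubiquitous for
#' zero-expressed genes) are excluded so the bandwidth stays positive.
#'
#' @param x,y Numeric vectors; pooled before taking differences.
#' @return Positive bandwidth; error if all pooled values are identical.
#' @export
median_heuristic_bandwidth <- function(x, y = numeric(0)) {
  z <- c(x, y)
  if (any(!is.finite(z))) stop("values must be finite", call. = FALSE)
  if (length(z) < 2L || length(unique(z)) < 2L) {
    stop("median-heuristic bandwidth undefined: fewer than two distinct values",
         call. = FALSE)
  }
  d <- abs(outer(z, z, "-"))
  d <- d[lower.tri(d)]
  stats::median(d[d > 0])
}

# Resolve the bandwidth a config implies for one two-sample instance.
resolve_bandwidth <- function(config, x, y) {
  if (config$bandwidth_policy == "fixed") config$sigma
  else median_heuristic_bandwidth(x, y)
}

#' Unbiased squared maximum mean discrepancy between two samples
#'
#' The U-statistic (minimum-variance unbiased) estimator of MMD^2 with a
#' Gaussian kernel:
#' \deqn{\widehat{MMD}^2_u = \frac{1}{m(m-1)}\sum_{i \ne j} k(x_i, x_j)
#'   + \frac{1}{n(n-1)}\sum_{i \ne j} k(y_i, y_j)
#'   - \frac{2}{mn}\sum_{i,j} k(x_i, y_j)}
#' Diagonal terms are excluded from the within-group sums, so the
#' estimate can be negative on finite samples; negative values are
#' reported as-is.  A larger score means a larger distributional
#' difference; for the Gaussian kernel the raw-scale score is at most 2.
#' Cost is O((m + n)^2) kernel evaluations.
#'
#' @param x,y Numeric vectors of length >= 2 (the two groups' values for
#'   one gene).
#' @param config A [kernel_config()].
#' @return The scalar score (multiplied by m when
#'   `scale_mode = "m_scaled"`).
#' @export
mmd2_unbiased <- function(x, y, config = kernel_config()) {
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) {
    stop("both groups need >= 2 samples (got m=", m, ", n=", n, ")",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  sigma <- resolve_bandwidth(config, x, y)
  kxx <- gaussian_kernel(rep(x, times = m), rep(x, each = m), sigma)
  kyy <- gaussian_kernel(rep(y, times = n), rep(y, each = n), sigma)
  kxy <- gaussian_kernel(rep(x, times = n), rep(y, each = m), sigma)
  score <- (sum(kxx) - m) / (m * (m - 1)) +
    (sum(kyy) - n) / (n * (n - 1)) -
    2 * sum(kxy) / (m * n)
  if (config$scale_mode == "m_scaled") score <- m * score
  score
}
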