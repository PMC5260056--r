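#' Default cutoff grid for threshold scans
#'
#' The canonical scan runs cutoffs from 0 to 1 in steps of 0.02 (51 points).
#' When the largest observed weight exceeds 1 — mutual information in nats
#' is unbounded — the grid is rescaled to `[0, max_weight]` with the same
#' number of points.
#'
#' @param max_weight Largest pair weight the grid must cover.
#' @return Strictly ascending numeric grid of 51 cutoffs.
#' @export
default_grid <- function(max_weight = 1) {
  if (!is.finite(max_weight) || max_weight <= 1) seq(0, 1, by = 0.02)
  else seq(0, max_weight, length.out = 51L)
}

#' Edge counts over a cutoff grid
#'
#' Counts, for each cutoff, the pairs whose weight is strictly above it.
#' The counts are non-increasing along the grid by construction.
#'
#' @param weights Numeric vector of pair weights (non-empty).
#' @param grid Strictly ascending cutoff grid.
#' @return A `threshold_scan` with fields `cutoffs`, `counts`, `grid_min`,
#'   `grid_max`.
#' @export
scan_counts <- function(weights, grid = default_grid(max(weights))) {
  weights <- as.numeric(weights)
  if (length(weights) == 0L) stop("weights must be non-empty", call. = FALSE)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly ascending with >= 2 points", call. = FALSE)
  }
  sw <- sort(weights)
  # pairs strictly above cutoff t: n - (count of weights <= t)
  counts <- length(sw) - findInterval(grid, sw)
  structure(list(cutoffs = grid, counts = as.integer(counts),
                 grid_min = grid[1L], grid_max = grid[length(grid)]),
            class = "threshold_scan")
}

#' Fit an exponential decay to a threshold scan
#'
#' Least-squares fit of `count = a * exp(-b * cutoff) + c` on the raw count
#' scale, with bounds `a > 0`, `b > 0`, `c >= 0`. Initial values: `c0` is
#' the final count, `a0` the first count minus `c0`, and `b0` comes from a
#' log-linear regression of `max(count - c0, eps)` on the cutoff.
#'
#' @param scan A `threshold_scan`.
#' @return An `exponential_fit` with fields `a`, `b`, `c`, `rmse`,
#'   `converged`.
#' @export
fit_exponential <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  x <- scan$cutoffs
  y <- as.numeric(scan$counts)
  if (length(x) < 4L) stop("need at least 4 grid points", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("degenerate scan: all counts are equal, no decay to fit",
         call. = FALSE)
  }
  c0 <- y[length(y)]
  a0 <- max(y[1L] - c0, 1e-8)
  eps <- max(a0 * 1e-6, 1e-9)
  # initial decay rate from a log-linear regression over the points still
  # above the floor; a half-decay estimate serves as an alternative start
  pos <- which(y - c0 > eps)
  b_cands <- numeric(0)
  if (length(pos) >= 2L) {
    lf <- stats::lm(log(y[pos] - c0) ~ x[pos])
    b_cands <- max(-stats::coef(lf)[[2L]], 1e-3)
  }
  half <- which(y <= c0 + a0 / 2)[1L]
  if (!is.na(half) && x[half] > x[1L]) {
    b_cands <- c(b_cands, log(2) / (x[half] - x[1L]))
  }
  if (length(b_cands) == 0L) b_cands <- 1
  fit <- NULL
  for (b0 in b_cands) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-b * x) + c,
        start = list(a = a0, b = b0, c = max(c0, 0)),
        lower = c(a = 1e-12, b = 1e-12, c = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8,
                                             ptol = 1e-8, maxfev = 10000)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          rmse = NA_real_, converged = FALSE),
                     class = "exponential_fit"))
  }
  p <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(a = p[["a"]], b = p[["b"]], c = p[["c"]], rmse = rmse,
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "exponential_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interaction cutoff from the tangent intersection of a fitted decay
#'
#' The automatic cutoff is the x-coordinate where the tangent line to the
#' fitted curve at the start of the grid meets the tangent at the end — the
#' inflection point separating the steep initial decay (mass of weak,
#' mostly indirect pairs) from the flat tail (strong direct interactions).
#' The result is clamped into `[x_start, x_end]`.
#'
#' @param fit A converged `exponential_fit`.
#' @param x_start,x_end Grid endpoints at which the tangents are taken.
#' @return The cutoff (scalar).
#' @examples
#' fit <- structure(list(a = 100, b = 5, c = 3, rmse = 0, converged = TRUE),
#'                  class = "exponential_fit")
#' determine_threshold(fit, 0, 1)  # 0.19322
#' @export
determine_threshold <- function(fit, x_start, x_end) {
  stopifnot(inherits(fit, "exponential_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (x_start >= x_end) stop("x_start must be < x_end", call. = FALSE)
  f <- function(x) fit$a * exp(-fit$b * x) + fit$c
  fp <- function(x) -fit$a * fit$b * exp(-fit$b * x)
  s0 <- fp(x_start); s1 <- fp(x_end)
  if (abs(s0 - s1) < 1e-12) {
    stop("degenerate fit: start and end tangents are parallel", call. = FALSE)
  }
  # intercepts of the two tangent lines y = s*x + q
  q0 <- f(x_start) - s0 * x_start
  q1 <- f(x_end) - s1 * x_end
  xint <- (q1 - q0) / (s0 - s1)
  min(max(xint, x_start), x_end)
}

#' Automatic interaction cutoff from a pair-weight distribution
#'
#' Composes [scan_counts()], [fit_exponential()] and
#' [determine_threshold()]. When the exponential fit is degenerate or fails
#' to converge, falls back to the maximum-chord-distance elbow of the scan:
#' the grid point whose count lies farthest from the straight line joining
#' the scan's endpoints. The returned cutoff always lies within the grid.
#'
#' @param weights Numeric vector of pair weights (non-empty).
#' @param grid Cutoff grid; `NULL` selects [default_grid()] for the observed
#'   maximum weight.
#' @return The cutoff (scalar).
#' @export
auto_threshold <- function(weights, grid = NULL) {
  weights <- as.numeric(weights)
  if (length(weights) == 0L) stop("weights must be non-empty", call. = FALSE)
  if (is.null(grid)) grid <- default_grid(max(weights))
  scan <- scan_counts(weights, grid)
  fit <- tryCatch(fit_exponential(scan), error = function(e) NULL)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    th <- tryCatch(
      determine_threshold(fit, scan$grid_min, scan$grid_max),
      error = function(e) NULL)
    if (!is.null(th)) return(th)
  }
  elbow_threshold(scan)
}

# Max-chord-distance elbow: deterministic fallback when no exponential
# decay can be fitted. A decay curve is convex, so the knee is the grid
# point lying farthest BELOW the chord joining the scan's endpoints; the
# distance is signed accordingly and the first maximizer wins.
elbow_threshold <- function(scan) {
  x <- scan$cutoffs
  y <- as.numeric(scan$counts)
  x1 <- x[1L]; y1 <- y[1L]
  x2 <- x[length(x)]; y2 <- y[length(y)]
  chord <- y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  x[which.max(chord - y)]
}
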