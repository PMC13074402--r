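# Averaging-pattern construction, budget projection, and integer rounding.
#
# The scan-time budget is the TR count of the reference experiment,
# w0 * N0 (uniform w0-fold averaging of all N0 lines). In effective averages
# the budget becomes sum(w) = w0 * N0^2 / N for a grid of size N.

#' Construct an averaging pattern
#'
#' @param N grid size (even)
#' @param w positive effective averages, length `N`
#' @param N0 reference grid size
#' @param w0 reference uniform actual averages (integer in the physical
#'   experiment; stored as given)
#' @return object of class `averaging_pattern`
#' @export
averaging_pattern <- function(N, w, N0, w0) {
  if (length(w) != N) stop("w must have length N")
  if (any(w <= 0)) stop("effective averages must be positive")
  structure(list(N = N, w = as.numeric(w), N0 = N0, w0 = w0),
            class = "averaging_pattern")
}

#' Scan-time budget in effective averages for grid size N
#' @param N,N0,w0 see [averaging_pattern()]
#' @export
budget_effective <- function(N, N0, w0) w0 * N0^2 / N

#' Check budget feasibility of a pattern
#'
#' @param pattern an [averaging_pattern()]
#' @param tol relative tolerance on the budget residual
#' @return logical
#' @export
is_feasible <- function(pattern, tol = 1e-9) {
  b <- budget_effective(pattern$N, pattern$N0, pattern$w0)
  abs(sum(pattern$w) - b) <= tol * b
}

#' Uniform averaging pattern at grid size N
#'
#' Spends the whole scan-time budget uniformly: `w_m = w0 * N0^2 / N^2` for
#' every line. This is both the uniform-averaging design and the
#' initialization of the nonuniform optimization.
#'
#' @inheritParams averaging_pattern
#' @return an [averaging_pattern()], feasible by construction
#' @export
uniform_pattern <- function(N, N0, w0) {
  if (N %% 2L != 0L) stop("N must be even")
  if (N > N0) stop("N must not exceed N0")
  averaging_pattern(N, rep(w0 * N0^2 / N^2, N), N0, w0)
}

#' Euclidean projection of an averaging vector onto the scan-time budget
#'
#' Projects onto the hyperplane `sum(w) = budget` by the shift
#' `w + beta / N` with `beta = budget - sum(w)`, which is the closed-form
#' Euclidean projection. Entries that would fall to or below a positivity
#' floor `eps` are clipped at `eps` and the remaining deficit redistributed
#' over the free entries (iterated), so the result stays strictly positive.
#'
#' @param w numeric vector of length `N`
#' @param budget target sum (positive)
#' @param eps positivity floor in effective averages
#' @return numeric vector with `sum == budget` (to machine precision) and all
#'   entries `>= eps`
#' @export
project_to_budget <- function(w, budget, eps = 1e-3) {
  if (budget <= 0) stop("budget must be positive")
  n <- length(w)
  if (budget < n * eps) stop("budget too small for the positivity floor")
  free <- rep(TRUE, n)
  out <- w
  repeat {
    beta <- budget - sum(out[free]) - sum(out[!free])
    out[free] <- out[free] + beta / sum(free)
    low <- free & (out < eps)
    if (!any(low)) break
    out[low] <- eps
    free <- free & !low
    if (!any(free)) break
  }
  out
}

#' Normalize a gradient vector to unit Euclidean norm
#'
#' Used to stabilize the projected stochastic gradient updates of the
#' averaging pattern across SNRs and reconstruction methods. A zero gradient
#' is returned unchanged.
#'
#' @param g numeric vector
#' @return vector with `l2` norm one (or the zero vector)
#' @export
normalize_gradient <- function(g) {
  nrm <- sqrt(sum(g^2))
  if (nrm > 0) g / nrm else g
}

#' Centered phase-encode coordinates for a grid of size N
#'
#' Returns `m = -N/2, ..., N/2 - 1` matching array rows `1..N`.
#' @param N even grid size
#' @export
line_coords <- function(N) seq.int(-N / 2, N / 2 - 1)

# Distance of each line from the k-space center. For even grids the two
# central lines (m = -1, 0) are equidistant under |m + 1/2|.
center_distance <- function(N) abs(line_coords(N) + 0.5)

#' Round an averaging pattern to integer actual averages
#'
#' Solves `argmin_q ||q - (N/N0) w||_1  s.t.  sum(q) = w0 * N0, q >= 0
#' integer` exactly: each entry of the actual-average target `(N/N0) w` is
#' rounded to the nearest integer; if the sum constraint is violated, single
#' averages are added or removed greedily, always at the position whose unit
#' change least increases the l1 cost. By separability and piecewise
#' linearity of the objective the greedy procedure is globally optimal. Ties
#' are broken by preferentially preserving averages nearest the center of
#' k-space (distance `|m + 1/2|`, then smaller row index).
#'
#' @param pattern an [averaging_pattern()] (feasible)
#' @param no_undersampling if `TRUE`, require at least one average per line
#'   and error if the budget cannot supply that
#' @return object of class `integer_pattern` with fields `q` (integer
#'   averages per line), `N`, `N0`, `w0`
#' @export
round_to_integer_averages <- function(pattern, no_undersampling = TRUE) {
  N <- pattern$N; N0 <- pattern$N0; w0 <- pattern$w0
  target <- actual_averages(pattern$w, N, N0)   # (N/N0) w
  total <- round(w0 * N0)
  if (no_undersampling && total < N)
    stop("scan-time budget cannot give every line at least one average")
  q <- round(target)
  qmin <- if (no_undersampling) 1L else 0L
  q <- pmax(q, qmin)
  dist <- center_distance(N)
  while (sum(q) != total) {
    if (sum(q) > total) {
      # removing one from line i changes cost by |q_i - 1 - t_i| - |q_i - t_i|
      delta <- abs(q - 1 - target) - abs(q - target)
      delta[q <= qmin] <- Inf
      best <- which(delta == min(delta))
      # preserve central lines: among minimal-cost candidates remove the one
      # farthest from the center
      pick <- best[order(-dist[best], -seq_len(N)[best])][1]
      q[pick] <- q[pick] - 1
    } else {
      delta <- abs(q + 1 - target) - abs(q - target)
      best <- which(delta == min(delta))
      pick <- best[order(dist[best], seq_len(N)[best])][1]
      q[pick] <- q[pick] + 1
    }
  }
  structure(list(q = as.integer(q), N = N, N0 = N0, w0 = w0),
            class = "integer_pattern")
}

#' Convert an integer pattern back to a frozen effective-average pattern
#'
#' After rounding, the integer actual averages are fixed and converted back to
#' exact effective averages `q * N0 / N` for the refinement phase.
#'
#' @param qpat an `integer_pattern`
#' @return an [averaging_pattern()]
#' @export
pattern_from_integer <- function(qpat) {
  averaging_pattern(qpat$N, effective_averages(qpat$q, qpat$N, qpat$N0),
                    qpat$N0, qpat$w0)
}

#' Write an integer averaging pattern as a two-column text table
#'
#' @param qpat an `integer_pattern`
#' @param path output file
#' @export
write_pattern <- function(qpat, path) {
  utils::write.table(
    data.frame(m = line_coords(qpat$N), averages = qpat$q),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read an integer averaging pattern written by [write_pattern()]
#' @param path input file
#' @param N0,w0 reference grid size and averages
#' @export
read_pattern <- function(path, N0, w0) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(q = as.integer(tab$averages), N = nrow(tab), N0 = N0, w0 = w0),
            class = "integer_pattern")
}

#' Plot an averaging pattern as bars over phase-encode index
#'
#' Bar-style layout: one bar per phase-encode line at its centered index m,
#' height equal to the integer (or effective) number of averages.
#'
#' @param pattern an `integer_pattern` or [averaging_pattern()]
#' @param main plot title
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, the bar midpoints
#' @export
plot_pattern <- function(pattern, main = NULL, ...) {
  vals <- if (inherits(pattern, "integer_pattern")) pattern$q else pattern$w
  ylab <- if (inherits(pattern, "integer_pattern")) "averages"
          else "effective averages"
  if (is.null(main))
    main <- sprintf("N = %d (budget %g TRs)", pattern$N,
                    round(pattern$w0 * pattern$N0))
  mids <- graphics::barplot(vals, names.arg = line_coords(pattern$N),
                            xlab = "phase-encode index m", ylab = ylab,
                            main = main, border = NA, space = 0, ...)
  invisible(mids)
}
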