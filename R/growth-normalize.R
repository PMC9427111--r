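#' Build a spatial control surface from interleaved control colonies
#'
#' Colony phenotyping plates carry systematic spatial gradients (temperature,
#' moisture, nutrient access). Interleaved wild-type control colonies on a
#' regular subgrid measure that gradient directly; this function interpolates
#' their log2 doubling times across the whole plate so every experimental
#' position can be normalized against the control value it would have had.
#'
#' Interpolation is bilinear on the regular grid formed by the control rows
#' and columns, which reproduces any plane exactly, is bounded by the control
#' values, and equals the measured value at each control position. Positions
#' outside the convex hull of the control grid (plate edges) are clamped to
#' the nearest control row/column, i.e. nearest-neighbour extrapolation.
#'
#' @param estimates Data frame with columns `row`, `col`, `log2_D` holding
#'   the measured control values (non-control rows are ignored if a logical
#'   `is_control` column is present).
#' @return An object of class `control_surface`; evaluate it with
#'   [predict_surface()].
#' @export
build_control_surface <- function(estimates) {
  stopifnot(all(c("row", "col", "log2_D") %in% names(estimates)))
  if ("is_control" %in% names(estimates)) {
    estimates <- estimates[estimates$is_control, , drop = FALSE]
  }
  if (nrow(estimates) < 4L) stop("need at least 4 control positions")
  rows <- sort(unique(estimates$row))
  cols <- sort(unique(estimates$col))
  grid <- matrix(NA_real_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  grid[cbind(match(estimates$row, rows), match(estimates$col, cols))] <-
    estimates$log2_D
  if (anyNA(grid)) {
    stop("control positions must form a complete regular subgrid")
  }
  structure(list(rows = rows, cols = cols, values = grid),
            class = "control_surface")
}

#' Evaluate a control surface at arbitrary plate positions
#'
#' @param surface A `control_surface` from [build_control_surface()].
#' @param row,col Numeric vectors of positions (recycled to common length).
#' @return Interpolated control log2 doubling times.
#' @export
predict_surface <- function(surface, row, col) {
  stopifnot(inherits(surface, "control_surface"))
  n <- max(length(row), length(col))
  row <- rep_len(row, n); col <- rep_len(col, n)
  # clamp -> nearest-neighbour extrapolation at plate edges
  r <- pmin(pmax(row, min(surface$rows)), max(surface$rows))
  c <- pmin(pmax(col, min(surface$cols)), max(surface$cols))
  ri <- findInterval(r, surface$rows, rightmost.closed = TRUE)
  ci <- findInterval(c, surface$cols, rightmost.closed = TRUE)
  ri2 <- pmin(ri + 1L, length(surface$rows))
  ci2 <- pmin(ci + 1L, length(surface$cols))
  r1 <- surface$rows[ri]; r2 <- surface$rows[ri2]
  c1 <- surface$cols[ci]; c2 <- surface$cols[ci2]
  fr <- ifelse(r2 > r1, (r - r1) / (r2 - r1), 0)
  fc <- ifelse(c2 > c1, (c - c1) / (c2 - c1), 0)
  v11 <- surface$values[cbind(ri, ci)]
  v12 <- surface$values[cbind(ri, ci2)]
  v21 <- surface$values[cbind(ri2, ci)]
  v22 <- surface$values[cbind(ri2, ci2)]
  (1 - fr) * ((1 - fc) * v11 + fc * v12) + fr * ((1 - fc) * v21 + fc * v22)
}

#' @export
print.control_surface <- function(x, ...) {
  cat(sprintf("Control surface on a %d x %d control grid (rows %s..%s, cols %s..%s)\n",
              length(x$rows), length(x$cols), min(x$rows), max(x$rows),
              min(x$cols), max(x$cols)))
  invisible(x)
}

#' Normalize a log2 doubling time against the local spatial control
#'
#' Subtracts the interpolated control log2 doubling time at the colony's
#' position, yielding a relative log2 doubling time that is free of the
#' plate's spatial gradient: 0 means "grows exactly like a control would
#' here".
#'
#' @param log2_D Measured log2 doubling time(s).
#' @param surface A `control_surface`.
#' @param row,col Position(s) on the plate.
#' @return Normalized log2 doubling time(s).
#' @export
normalize_doubling <- function(log2_D, surface, row, col) {
  log2_D - predict_surface(surface, row, col)
}

#' Adjust a normalized doubling time for pre-cultivation bias
#'
#' Controls and evolving populations can differ slightly in pre-cultivation
#' history; subtracting the cycle-0 normalized value removes that constant
#' offset.
#'
#' @param log2_D_norm_t Normalized log2 doubling time at cycle t.
#' @param log2_D_norm_0 Normalized log2 doubling time at cycle 0.
#' @return Adjusted log2 doubling time.
#' @export
adjust_doubling <- function(log2_D_norm_t, log2_D_norm_0) {
  log2_D_norm_t - log2_D_norm_0
}

#' Convert a normalized log2 doubling time back to hours
#'
#' Rescales by the grand mean of the raw control doubling times so the
#' normalized values can be read as doubling times in hours while retaining
#' the spatial normalization.
#'
#' @param log2_D_norm Normalized log2 doubling time(s).
#' @param D_control_grand Grand mean of the raw control doubling times of
#'   the experimental series, in hours.
#' @return Doubling time(s) in hours.
#' @export
doubling_to_hours <- function(log2_D_norm, D_control_grand) {
  stopifnot(D_control_grand > 0)
  2^log2_D_norm * D_control_grand
}

#' Count cell generations across serial growth cycles
#'
#' Each growth cycle contributes `log2(N_final / N_initial)` generations
#' (population doublings). Cycles with missing counts are filled with the
#' mean of the two adjacent observed cycles; a run of consecutive missing
#' cycles all receive the mean of its two flanking observed cycles. Missing
#' cycles at either end cannot be interpolated and are an error.
#'
#' @param n_initial,n_final Numeric vectors, one entry per cycle, of the
#'   population size at the start and end of the cycle. Use `NA` in both for
#'   a missing cycle.
#' @return A tibble with columns `cycle`, `generations`, `interpolated`,
#'   `cumulative`.
#' @examples
#' count_generations(c(5e4, NA, 5e4), c(1.6e6, NA, 1.6e6))
#' @export
count_generations <- function(n_initial, n_final) {
  stopifnot(length(n_initial) == length(n_final), length(n_initial) >= 1L)
  miss <- is.na(n_initial) | is.na(n_final)
  if (any(!miss & (n_initial <= 0 | n_final <= 0))) {
    stop("population counts must be positive")
  }
  if (miss[1L] || miss[length(miss)]) {
    stop("missing cycles at either end cannot be interpolated")
  }
  gens <- ifelse(miss, NA_real_, log2(n_final / n_initial))
  if (any(miss)) {
    obs <- which(!miss)
    for (i in which(miss)) {
      lo <- max(obs[obs < i]); hi <- min(obs[obs > i])
      gens[i] <- (gens[lo] + gens[hi]) / 2
    }
  }
  tibble::tibble(cycle = seq_along(gens), generations = gens,
                 interpolated = miss, cumulative = cumsum(gens))
}

#' Percent of the maximum possible doubling-time reduction realized
#'
#' Expresses an adapting population's doubling time as the fraction of the
#' maximum physiologically possible reduction it has realized, taking the
#' founder's unstressed doubling time as the lower boundary of what is
#' achievable and its initial stressed doubling time as the starting point.
#'
#' @param D_t_h Current doubling time(s) under stress, hours.
#' @param D_init_stress_h Founder doubling time under stress at the start of
#'   the experiment, hours.
#' @param D_floor_h Founder doubling time without stress (the physiological
#'   floor), hours.
#' @return Percentage(s) in \[0, 100\]; values outside the range (D_t above
#'   the initial value or below the floor) are clipped with a warning.
#' @examples
#' percent_max_adaptation(202, 308, 93) # about 49.5
#' @export
percent_max_adaptation <- function(D_t_h, D_init_stress_h, D_floor_h) {
  if (D_init_stress_h <= D_floor_h) {
    stop("D_init_stress_h must exceed D_floor_h")
  }
  p <- 100 * (D_init_stress_h - D_t_h) / (D_init_stress_h - D_floor_h)
  if (any(p < 0 | p > 100, na.rm = TRUE)) {
    warning("doubling time outside [floor, initial]; percentage clipped")
    p <- pmin(pmax(p, 0), 100)
  }
  p
}

#' Combine doubling-time reductions additively
#'
#' The attribution arithmetic for multi-locus effects: assuming additive
#' phenotypic effects, the joint reduction in doubling time is the sum of
#' the individual reductions.
#'
#' @param reductions Non-empty numeric vector of reductions (any consistent
#'   time unit).
#' @return Their sum.
#' @examples
#' additive_combination(c(31, 38)) # 69
#' @export
additive_combination <- function(reductions) {
  if (length(reductions) == 0L) stop("`reductions` must be non-empty")
  stopifnot(is.numeric(reductions), !anyNA(reductions))
  sum(reductions)
}

#' Adjust a growth curve for display
#'
#' Rescales a curve in log space so it starts at a common initial population
#' size, removing visual offsets caused by inoculum-size differences while
#' preserving the curve's log-scale shape:
#' `N_adj(t) = 2^( log2(N_t) * log2(median_N0) / log2(N_0) )`.
#'
#' @param counts Cell counts over time (> 1).
#' @param median_N0 Common initial population size to map all curves onto
#'   (> 1).
#' @param N0 The curve's own initial population size; defaults to
#'   `counts[1]`.
#' @return Adjusted counts, same length as `counts`.
#' @export
adjust_curve_for_display <- function(counts, median_N0, N0 = counts[1L]) {
  if (N0 <= 1) stop("initial population size must exceed 1")
  stopifnot(median_N0 > 1, all(counts > 0))
  2^(log2(counts) * log2(median_N0) / log2(N0))
}
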