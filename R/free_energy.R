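#' @name free_energy
#' @title Free-energy profiles from repeated non-equilibrium pulling work
#'
#' @description
#' Repeated steered pulls of the same system give a set of work curves
#' W_i(x) along the reaction coordinate. The Jarzynski equality relates
#' their exponential average to the equilibrium free-energy difference,
#' `exp(-beta dF) = < exp(-beta W) >`; with few repeats (the protocol here
#' uses M = 10) the exponential average is biased toward the smallest
#' sampled work, so the second-order cumulant expansion
#' `dF = <W> - (beta/2) Var(W)` -- exact for Gaussian work distributions --
#' is the default estimator.
NULL

#' Aligned set of work curves
#'
#' @param coordinate_nm common, strictly increasing reaction-coordinate
#'   grid (nm).
#' @param works matrix of work values in kBT, one column per repeat,
#'   `length(coordinate_nm)` rows. Each curve is referenced to zero at the
#'   first grid point (enforced by subtracting its first value).
#' @param temperature_K temperature (default 310 K).
#' @return a `WorkTraceSet` with fields `coordinate_nm`, `works_kBT`,
#'   `beta` (1 / pN nm), `temperature_K` and `M`.
#' @export
work_trace_set <- function(coordinate_nm, works, temperature_K = 310) {
  works <- as.matrix(works)
  if (length(coordinate_nm) != nrow(works))
    stop("grid length must equal number of work rows")
  if (ncol(works) < 1) stop("need at least one work curve")
  if (length(coordinate_nm) > 1 && any(diff(coordinate_nm) <= 0))
    stop("coordinate grid must be strictly increasing")
  if (!all(is.finite(works))) stop("non-finite work values")
  works <- sweep(works, 2, works[1, ])
  structure(list(coordinate_nm = as.numeric(coordinate_nm),
                 works_kBT = unname(works),
                 beta = 1 / kbt_pN_nm(temperature_K),
                 temperature_K = temperature_K, M = ncol(works)),
            class = "WorkTraceSet")
}

#' @export
print.WorkTraceSet <- function(x, ...) {
  cat(sprintf("WorkTraceSet: M = %d repeats, %d grid points, %g..%g nm, T = %g K\n",
              x$M, length(x$coordinate_nm), min(x$coordinate_nm),
              max(x$coordinate_nm), x$temperature_K))
  invisible(x)
}

#' Work curves in pN nm
#' @param w a `WorkTraceSet`.
#' @export
works_pN_nm <- function(w) w$works_kBT * kbt_pN_nm(w$temperature_K)

free_energy_profile <- function(coordinate_nm, delta_F_kBT, estimator, M,
                                temperature_K, ref_index = 1) {
  out <- data.frame(coordinate_nm = coordinate_nm,
                    delta_F_kBT = delta_F_kBT - delta_F_kBT[ref_index])
  attr(out, "estimator") <- estimator
  attr(out, "M") <- M
  attr(out, "temperature_K") <- temperature_K
  class(out) <- c("FreeEnergyProfile", "data.frame")
  out
}

# log of mean of exp(v), guarded against overflow
log_mean_exp <- function(v) {
  mx <- max(v)
  mx + log(mean(exp(v - mx)))
}

#' Jarzynski exponential-average free-energy estimate
#'
#' `dF(x) = -(1/beta) log( (1/M) sum_i exp(-beta W_i(x)) )`, computed with a
#' log-sum-exp guard. Works and the returned profile are in kBT, so beta
#' enters as unity on that scale. By Jensen's inequality the estimate never
#' exceeds the mean work.
#'
#' @param w a [work_trace_set()].
#' @return a `FreeEnergyProfile` (data.frame `coordinate_nm`,
#'   `delta_F_kBT`, zero at the first grid point).
#' @export
jarzynski_exact <- function(w) {
  stopifnot(inherits(w, "WorkTraceSet"))
  dF <- -apply(-w$works_kBT, 1, log_mean_exp)
  free_energy_profile(w$coordinate_nm, dF, "exact", w$M, w$temperature_K)
}

#' Second-order cumulant free-energy estimate
#'
#' `dF(x) = mean_i W_i(x) - (beta/2) var_i W_i(x)` with the unbiased
#' (M - 1) sample variance; exact when the work distribution is Gaussian,
#' and far less biased than the exponential average at small M.
#'
#' @param w a [work_trace_set()] with `M >= 2`.
#' @param unbiased use the (M - 1) variance divisor (default `TRUE`); set
#'   `FALSE` for the population (M) divisor.
#' @return a `FreeEnergyProfile`.
#' @export
jarzynski_second_order <- function(w, unbiased = TRUE) {
  stopifnot(inherits(w, "WorkTraceSet"))
  if (w$M < 2) stop("insufficient samples: second-order estimator needs M >= 2")
  mu <- rowMeans(w$works_kBT)
  v <- apply(w$works_kBT, 1, stats::var)
  if (!unbiased) v <- v * (w$M - 1) / w$M
  free_energy_profile(w$coordinate_nm, mu - v / 2, "second_order", w$M,
                      w$temperature_K)
}

#' Mean-work profile (no fluctuation correction)
#' @param w a [work_trace_set()].
#' @return a `FreeEnergyProfile`.
#' @export
mean_work_profile <- function(w) {
  stopifnot(inherits(w, "WorkTraceSet"))
  free_energy_profile(w$coordinate_nm, rowMeans(w$works_kBT), "mean_work",
                      w$M, w$temperature_K)
}

#' Barrier height of a free-energy profile
#'
#' Finds the activation barrier as the largest rise from a preceding valley
#' to a local peak along the pulling direction (grid order): for every
#' interior local maximum, the candidate barrier is its height above the
#' deepest minimum at earlier grid points, and the largest candidate wins.
#' Monotone profiles carry no barrier.
#'
#' @param p a `FreeEnergyProfile` (or data.frame with `coordinate_nm` and
#'   `delta_F_kBT`).
#' @return list with `has_barrier`, `peak_nm`, `valley_nm` and
#'   `barrier_kBT` (`NA`s when no barrier exists). Adding a constant to the
#'   profile leaves the result unchanged.
#' @export
barrier_height <- function(p) {
  f <- p$delta_F_kBT
  x <- p$coordinate_nm
  n <- length(f)
  none <- list(has_barrier = FALSE, peak_nm = NA_real_,
               valley_nm = NA_real_, barrier_kBT = NA_real_)
  if (n < 3) return(none)
  d <- diff(f)
  if (all(d >= 0) || all(d <= 0)) return(none)
  best <- none
  for (i in 2:(n - 1)) {
    if (f[i] >= f[i - 1] && f[i] >= f[i + 1] &&
        (f[i] > f[i - 1] || f[i] > f[i + 1])) {
      j <- which.min(f[1:i])
      h <- f[i] - f[j]
      if (h > 0 && (!best$has_barrier || h > best$barrier_kBT)) {
        best <- list(has_barrier = TRUE, peak_nm = x[i], valley_nm = x[j],
                     barrier_kBT = h)
      }
    }
  }
  best
}

#' Estimate a PMF from raw pulling force traces
#'
#' Pipeline composition: integrate the work of each trace along its guide
#' coordinate ([integrate_work()]), resample the work curves onto a common
#' grid by linear interpolation, and apply the chosen estimator. The grid
#' defaults to `n_grid` points over the coordinate range covered by every
#' trace; with a user grid extending beyond some traces, each grid point
#' uses only the traces that reach it (counts in the `n_traces` attribute).
#'
#' @param traces list of [force_trace()] objects (the steering protocol
#'   default is M = 10 repeats).
#' @param temperature_K temperature (default 310 K).
#' @param estimator one of `"second_order"` (default), `"exact"`,
#'   `"mean_work"`.
#' @param grid optional explicit coordinate grid (nm).
#' @param n_grid number of grid points when `grid` is absent (default 200).
#' @return a `FreeEnergyProfile`.
#' @export
estimate_pmf <- function(traces, temperature_K = 310,
                         estimator = c("second_order", "exact", "mean_work"),
                         grid = NULL, n_grid = 200) {
  estimator <- match.arg(estimator)
  if (length(traces) < 1) stop("need at least one trace")
  if (estimator == "second_order" && length(traces) < 2)
    stop("insufficient samples: second-order estimator needs M >= 2")
  works <- lapply(traces, integrate_work, temperature_K = temperature_K)
  los <- vapply(works, function(w) min(w$guide_nm), numeric(1))
  his <- vapply(works, function(w) max(w$guide_nm), numeric(1))
  if (is.null(grid)) {
    lo <- max(los); hi <- min(his)
    if (lo >= hi) stop("traces have non-overlapping coordinate ranges")
    grid <- seq(lo, hi, length.out = n_grid)
  }
  W <- vapply(works, function(w) {
    stats::approx(w$guide_nm, w$work_kBT, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  W <- as.matrix(W)
  n_traces <- rowSums(is.finite(W))
  if (all(n_traces == 0)) stop("traces have non-overlapping coordinate ranges")
  # reference every covering trace to the first fully-covered grid point
  full <- which(n_traces == ncol(W))
  if (length(full) == 0) stop("no grid point is covered by every trace")
  W <- sweep(W, 2, W[full[1], ])
  est <- switch(estimator,
    second_order = {
      mu <- rowMeans(W, na.rm = TRUE)
      v <- apply(W, 1, stats::var, na.rm = TRUE)
      mu - v / 2
    },
    exact = apply(W, 1, function(r) -log_mean_exp(-r[is.finite(r)])),
    mean_work = rowMeans(W, na.rm = TRUE))
  # zero at the first grid point covered by every trace, not a ragged edge
  out <- free_energy_profile(grid, est, estimator, length(traces),
                             temperature_K, ref_index = full[1])
  attr(out, "n_traces") <- n_traces
  out
}

#' Read / write a work-trace matrix as TSV
#'
#' First column is the coordinate (nm), remaining columns one work curve
#' (kBT) per repeat.
#'
#' @param file path.
#' @param temperature_K temperature recorded on the set.
#' @return a [work_trace_set()].
#' @export
read_work_set <- function(file, temperature_K = 310) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  if (ncol(d) < 2) stop("work set must have a coordinate and >= 1 work column")
  work_trace_set(d[[1]], as.matrix(d[, -1, drop = FALSE]),
                 temperature_K = temperature_K)
}

#' @rdname read_work_set
#' @param w a `WorkTraceSet`.
#' @export
write_work_set <- function(w, file) {
  d <- data.frame(coordinate_nm = w$coordinate_nm, w$works_kBT)
  names(d)[-1] <- paste0("W", seq_len(w$M), "_kBT")
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
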