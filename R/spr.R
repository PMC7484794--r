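#' Sequential-injection SPR schedule
#'
#' Defaults follow the analyte titration used for APOH on corona-coated
#' particles: five concentrations (20, 100, 300, 1000, 3000 nM), injection
#' from 0 to 800 s, dissociation followed to 2400 s, association fitted on
#' 2-798 s and dissociation on 1400-2400 s (data around the rinse are
#' omitted).
#'
#' @param concentrations_nM Strictly increasing analyte concentrations (nM).
#' @param t_inject_start,t_inject_end,t_dissoc_end Cycle phase boundaries (s).
#' @param assoc_window,dissoc_window Two-element fit windows (s).
#' @return An `spr_schedule` list.
#' @export
spr_schedule <- function(concentrations_nM = c(20, 100, 300, 1000, 3000),
                         t_inject_start = 0, t_inject_end = 800,
                         t_dissoc_end = 2400,
                         assoc_window = c(2, 798),
                         dissoc_window = c(1400, 2400)) {
  if (any(concentrations_nM <= 0) || is.unsorted(concentrations_nM, strictly = TRUE))
    stop("invalid-input: concentrations must be positive and strictly increasing")
  if (!(t_inject_start <= assoc_window[1] && assoc_window[1] < assoc_window[2] &&
        assoc_window[2] <= t_inject_end))
    stop("invalid-input: association window must lie inside the injection")
  if (!(t_inject_end < dissoc_window[1] && dissoc_window[1] < dissoc_window[2] &&
        dissoc_window[2] <= t_dissoc_end))
    stop("invalid-input: dissociation window must lie after the injection")
  structure(list(concentrations_M = concentrations_nM * 1e-9,
                 concentrations_nM = concentrations_nM,
                 t_inject_start = t_inject_start,
                 t_inject_end = t_inject_end,
                 t_dissoc_end = t_dissoc_end,
                 assoc_window = assoc_window,
                 dissoc_window = dissoc_window),
            class = "spr_schedule")
}

#' Logarithmic (K_D, k_off) grid for affinity-distribution fitting
#'
#' 21 log-spaced dissociation constants in \[1e-9, 1e-3\] M crossed with 21
#' log-spaced off-rates in \[1e-5, 1\] s^-1 by default; the association rate
#' at each node is `k_on = k_off / K_D`.
#'
#' @param kd_range,koff_range Two-element bounds (M, s^-1).
#' @param n_kd,n_koff Grid points per axis. Default 21 each.
#' @return A `kinetic_grid` list with `kd`, `koff` node vectors and a
#'   `nodes` data frame of all combinations (kd varies fastest).
#' @export
kinetic_grid <- function(kd_range = c(1e-9, 1e-3), koff_range = c(1e-5, 1),
                         n_kd = 21, n_koff = 21) {
  stopifnot(all(kd_range > 0), all(koff_range > 0), n_kd >= 2, n_koff >= 2)
  kd <- 10^seq(log10(kd_range[1]), log10(kd_range[2]), length.out = n_kd)
  koff <- 10^seq(log10(koff_range[1]), log10(koff_range[2]), length.out = n_koff)
  nodes <- expand.grid(kd = kd, koff = koff, KEEP.OUT.ATTRS = FALSE)
  nodes$kon <- nodes$koff / nodes$kd
  structure(list(kd = kd, koff = koff, nodes = nodes,
                 n_kd = n_kd, n_koff = n_koff),
            class = "kinetic_grid")
}

#' Unit-amplitude 1:1 Langmuir occupancy trace for one schedule
#'
#' Association follows
#' `theta(t) = theta_eq + (theta0 - theta_eq) * exp(-(kon*C + koff)(t - t0))`
#' with `theta_eq = C / (C + K_D)`; dissociation decays as
#' `theta(t_off) * exp(-koff (t - t_off))`. In `independent_cycles` mode
#' every concentration cycle starts from zero occupancy; in
#' `sequential_titration` mode the occupancy left at the end of one cycle
#' seeds the next.
#'
#' @param kd Dissociation constant (M, > 0).
#' @param koff Off-rate (s^-1, > 0).
#' @param schedule An [spr_schedule()].
#' @param times Numeric vector of within-cycle times (s), shared by all
#'   cycles.
#' @param mode `"independent_cycles"` (default) or `"sequential_titration"`.
#' @return Matrix `length(times) x n_concentrations` of occupancies in
#'   \[0, 1\].
#' @export
langmuir_basis <- function(kd, koff, schedule, times,
                           mode = c("independent_cycles", "sequential_titration")) {
  mode <- match.arg(mode)
  if (kd <= 0 || koff <= 0) stop("invalid-input: rates must be positive")
  kon <- koff / kd
  t0 <- schedule$t_inject_start
  t_off <- schedule$t_inject_end
  out <- matrix(0, length(times), length(schedule$concentrations_M))
  theta_carry <- 0
  for (ci in seq_along(schedule$concentrations_M)) {
    C <- schedule$concentrations_M[ci]
    theta_eq <- C / (C + kd)
    kobs <- kon * C + koff
    assoc <- times <= t_off
    th <- numeric(length(times))
    th[assoc] <- theta_eq + (theta_carry - theta_eq) *
      exp(-kobs * (times[assoc] - t0))
    theta_at_off <- theta_eq + (theta_carry - theta_eq) * exp(-kobs * (t_off - t0))
    th[!assoc] <- theta_at_off * exp(-koff * (times[!assoc] - t_off))
    out[, ci] <- th
    theta_carry <- if (mode == "sequential_titration")
      theta_at_off * exp(-koff * (schedule$t_dissoc_end - t_off)) else 0
  }
  out
}

#' Within-cycle time points retained for fitting
#'
#' Regular `dt`-spaced samples restricted to the association and
#' dissociation fit windows of the schedule (the rinse gap between them is
#' excluded).
#'
#' @param schedule An [spr_schedule()].
#' @param dt Sampling interval (s). Default 4.
#' @return Sorted numeric vector of times (s).
#' @export
retained_times <- function(schedule, dt = 4) {
  full <- seq(schedule$t_inject_start, schedule$t_dissoc_end, by = dt)
  keep <- (full >= schedule$assoc_window[1] & full <= schedule$assoc_window[2]) |
    (full >= schedule$dissoc_window[1] & full <= schedule$dissoc_window[2])
  full[keep]
}

#' Design matrix of Langmuir basis traces over a kinetic grid
#'
#' Column j holds the unit-amplitude occupancy of grid node j evaluated at
#' the retained time points of every concentration cycle, stacked cycle by
#' cycle. Fitting weights against this matrix discretizes the
#' affinity-distribution integral.
#'
#' @param grid A [kinetic_grid()].
#' @param schedule An [spr_schedule()].
#' @param times Within-cycle retained times; default [retained_times()].
#' @param mode Cycle handling, see [langmuir_basis()].
#' @return Matrix `(length(times) * n_conc) x (n_kd * n_koff)`; attribute
#'   `times` / `cycle` give the row layout.
#' @export
build_design_matrix <- function(grid, schedule, times = retained_times(schedule),
                                mode = c("independent_cycles", "sequential_titration")) {
  mode <- match.arg(mode)
  if (length(times) == 0)
    stop("configuration error: no retained time points")
  n_conc <- length(schedule$concentrations_M)
  A <- matrix(0, length(times) * n_conc, nrow(grid$nodes))
  for (j in seq_len(nrow(grid$nodes))) {
    A[, j] <- as.vector(langmuir_basis(grid$nodes$kd[j], grid$nodes$koff[j],
                                       schedule, times, mode))
  }
  attr(A, "times") <- rep(times, times = n_conc)
  attr(A, "cycle") <- rep(seq_len(n_conc), each = length(times))
  A
}

#' Linear drift correction of a sensorgram
#'
#' Estimates the baseline slope before and after the injection (ordinary
#' least squares within each window), subtracts the line with the mean of
#' the two slopes anchored at the start of the pre-injection window.
#'
#' @param time,response Numeric vectors of equal length.
#' @param pre_window,post_window Two-element time windows (s) containing
#'   baseline-only data (>= 2 points each).
#' @return List with `time`, `response` (corrected), `slope` (RU s^-1),
#'   `drift_corrected = TRUE`.
#' @export
drift_correct <- function(time, response, pre_window, post_window) {
  stopifnot(length(time) == length(response))
  pre <- time >= pre_window[1] & time <= pre_window[2]
  post <- time >= post_window[1] & time <= post_window[2]
  if (sum(pre) < 2 || sum(post) < 2)
    stop("insufficient-baseline: each window needs >= 2 points")
  slope_pre <- stats::coef(stats::lm(response[pre] ~ time[pre]))[2]
  slope_post <- stats::coef(stats::lm(response[post] ~ time[post]))[2]
  slope <- unname((slope_pre + slope_post) / 2)
  list(time = time,
       response = response - slope * (time - pre_window[1]),
       slope = slope, drift_corrected = TRUE)
}

#' Fit a regularized 2-D affinity distribution to sensorgrams
#'
#' Solves `min_{P >= 0} ||A P - r||^2 + alpha ||P||^2` (zeroth-order
#' Tikhonov with non-negativity) over a log-spaced scan of regularization
#' strengths, then selects the most parsimonious solution: the largest
#' `alpha` whose data misfit `S(alpha)` stays statistically consistent with
#' the best attainable fit at the requested confidence,
#' `S(alpha) <= S_min * qf(conf, n - q, n - q)` with `n` retained points
#' and `q` grid nodes (the F-ratio convention of the sedimentation/affinity
#' distribution literature). Since `S(alpha)` is non-decreasing in `alpha`,
#' the scan is resolved by bisection.
#'
#' @param response Numeric vector of stacked drift-corrected responses (RU)
#'   matching the rows of the design matrix.
#' @param grid A [kinetic_grid()].
#' @param schedule An [spr_schedule()].
#' @param times Within-cycle retained times; default [retained_times()].
#' @param mode Cycle handling, see [langmuir_basis()].
#' @param reg_confidence Confidence level of the parsimony criterion.
#'   Default 0.95.
#' @param alphas Optional increasing vector of regularization strengths to
#'   scan; by default 25 log-spaced values auto-scaled to the design.
#' @param design Optional precomputed design matrix (columns must match
#'   `grid$nodes`); avoids rebuilding it across fits.
#' @return A `kinetic_fit` list: `P` (n_kd x n_koff weight matrix, RU),
#'   `weights` (vector form), `grid`, `alpha`, `rss`, `rss_min`,
#'   `threshold`, `parsimony_ok`, `fitted`, `mode`.
#' @export
fit_distribution <- function(response, grid, schedule,
                             times = retained_times(schedule),
                             mode = c("independent_cycles", "sequential_titration"),
                             reg_confidence = 0.95, alphas = NULL,
                             design = NULL) {
  mode <- match.arg(mode)
  A <- if (is.null(design)) build_design_matrix(grid, schedule, times, mode) else design
  if (length(response) != nrow(A))
    stop("invalid-input: response length does not match design matrix rows")
  n <- length(response)
  q <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, response))
  btb <- sum(response^2)
  scale <- mean(diag(AtA))
  if (is.null(alphas))
    alphas <- scale * 10^seq(-8, 3, length.out = 25)
  alphas <- sort(alphas)

  solve_at <- function(alpha) {
    x <- fnnls(AtA + diag(alpha, q), Atb)
    # residual computed directly: the cross-product form loses ~1e-9 RU^2
    # to cancellation, which matters in the noiseless limit
    list(x = x, rss = sum((drop(A %*% x) - response)^2))
  }

  base <- solve_at(scale * 1e-14)  # effectively unregularized
  rss_min <- base$rss
  if (n <= q) {
    threshold <- Inf
  } else {
    threshold <- rss_min * stats::qf(reg_confidence, n - q, n - q)
  }

  chosen <- base; chosen_alpha <- 0; parsimony_ok <- TRUE
  if (sum(Atb > 0) > 0 && btb > 0) {
    lo <- 0L; hi <- length(alphas) + 1L  # invariant: alphas[lo] feasible index
    cache <- vector("list", length(alphas))
    while (hi - lo > 1L) {
      midi <- (lo + hi) %/% 2L
      cache[[midi]] <- solve_at(alphas[midi])
      if (cache[[midi]]$rss <= threshold) lo <- midi else hi <- midi
    }
    if (lo >= 1L) {
      chosen <- cache[[lo]]
      chosen_alpha <- alphas[lo]
    } else {
      parsimony_ok <- FALSE  # even the smallest scanned alpha fails
      chosen <- base
      chosen_alpha <- 0
    }
  }

  P <- matrix(chosen$x, grid$n_kd, grid$n_koff,
              dimnames = list(signif(grid$kd, 4), signif(grid$koff, 4)))
  structure(list(P = P, weights = chosen$x, grid = grid,
                 alpha = chosen_alpha, rss = chosen$rss, rss_min = rss_min,
                 threshold = threshold, parsimony_ok = parsimony_ok,
                 fitted = drop(A %*% chosen$x), response = response,
                 n_points = n, mode = mode,
                 reg_confidence = reg_confidence),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("kinetic_fit:", x$grid$n_kd, "x", x$grid$n_koff, "grid;",
      "total signal", sprintf("%.2f RU", sum(x$weights)), "\n")
  cat("  alpha =", format(x$alpha, digits = 3),
      " rss =", format(x$rss, digits = 4),
      " (min", format(x$rss_min, digits = 4), ")",
      if (!x$parsimony_ok) " [parsimony-failure]" else "", "\n")
  invisible(x)
}

#' Signal fractions of kinetic populations
#'
#' Sums the fitted weight distribution over rectangular (K_D, k_off)
#' regions and reports each region's share of the total signal; mass in no
#' region is reported as `unassigned`.
#'
#' @param fit A `kinetic_fit` (or a `kinetic_grid` plus `P` weight matrix).
#' @param regions Named list of regions, each
#'   `list(kd = c(lo, hi), koff = c(lo, hi))` in M and s^-1; regions must be
#'   pairwise disjoint on the grid nodes.
#' @param P Weight matrix when `fit` is a `kinetic_grid`.
#' @return Named numeric vector of fractions (summing to 1 with
#'   `unassigned`).
#' @export
population_fractions <- function(fit, regions, P = NULL) {
  if (inherits(fit, "kinetic_fit")) {
    grid <- fit$grid; P <- fit$P
  } else {
    grid <- fit
    stopifnot(!is.null(P))
  }
  total <- sum(P)
  if (total <= 0) stop("empty-distribution: total fitted signal is zero")
  assigned <- matrix(FALSE, grid$n_kd, grid$n_koff)
  out <- numeric(0)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    sel <- outer(grid$kd >= r$kd[1] & grid$kd <= r$kd[2],
                 grid$koff >= r$koff[1] & grid$koff <= r$koff[2], "&")
    if (any(sel & assigned))
      stop("invalid-input: regions overlap on grid nodes")
    assigned <- assigned | sel
    out[nm] <- sum(P[sel]) / total
  }
  out["unassigned"] <- sum(P[!assigned]) / total
  out
}

#' Mass-weighted centroid of a fitted distribution
#'
#' Centroid in (log10 K_D, log10 k_off) space, the summary used to score
#' recovery of planted single-site truths.
#'
#' @param fit A `kinetic_fit`.
#' @return Named vector `c(log10_kd =, log10_koff =)`.
#' @export
distribution_centroid <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  P <- fit$P
  total <- sum(P)
  if (total <= 0) stop("empty-distribution: total fitted signal is zero")
  lkd <- log10(fit$grid$kd)
  lkoff <- log10(fit$grid$koff)
  c(log10_kd = sum(rowSums(P) * lkd) / total,
    log10_koff = sum(colSums(P) * lkoff) / total)
}
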