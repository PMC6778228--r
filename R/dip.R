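#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function.
#' It is computed from a band-feasibility characterization: a unimodal cdf
#' within distance `t` of the ECDF exists iff for some support point `s`
#' (the mode, possibly carrying an atom) a convex nondecreasing function
#' fits the ECDF band over the points up to `s`, a concave one fits from
#' `s` on, and the two pieces can be joined monotonically at `s`. A mode
#' interior to a gap between data points is dominated by one of the
#' adjacent point-mode solutions, so scanning support points is exhaustive.
#' Every condition is linear in `t`; the dip is the smallest feasible `t`
#' over all splits. Values are bounded below by `1/(2n)` (attained by
#' evenly spaced samples) and above by 1/4 (balanced two-point samples).
#'
#' @param x numeric sample (ties allowed).
#' @return the dip statistic, a value in `[0, 0.25]`.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 2) return(0)
  tab <- table(x)
  w <- as.numeric(names(tab))
  m <- length(w)
  if (m == 1) return(0)
  f <- cumsum(as.integer(tab)) / n # upper ECDF corners
  flow <- c(0, f[-m]) # lower ECDF corners

  lo <- prefix_convex_thresholds(w, f, flow)
  hi_rev <- prefix_convex_thresholds(-rev(w), 1 - rev(flow), 1 - rev(f))
  hi <- rev(hi_rev) # hi[s]: threshold for the concave fit on s..m
  base <- pmax(lo, hi) # per-split lower bound before the junction condition

  ord <- order(base)
  best <- Inf
  for (s in ord) {
    if (base[s] >= best) break
    ts <- if (s <= 1 || s >= m) {
      base[s]
    } else {
      max(base[s], junction_threshold(s, w, f, flow, m, t0 = base[s]))
    }
    if (ts < best) best <- ts
  }
  best
}

# Minimal band half-width t such that a convex nondecreasing function fits
# within [f_i - t, flow_i + t] over points 1..s, ending at the s-th point's
# lower-corner window [flow_s - t, flow_s + t] (the mode may carry an atom
# at s, so the upper-corner constraint does not apply there). Feasibility
# for given t is equivalent to the greatest convex minorant of the lower
# corners staying within 2t of the upper corners at the interior points;
# the returned threshold is half the largest such deviation. Vector over s.
prefix_convex_thresholds <- function(w, f, flow) {
  m <- length(w)
  out <- numeric(m)
  hull <- integer(0)
  for (j in seq_len(m)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # pop b when slope(a,b) >= slope(b,j) (lower convex hull)
      if ((flow[b] - flow[a]) * (w[j] - w[b]) <
            (flow[j] - flow[b]) * (w[b] - w[a])) break
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, j)
    if (j == 1L) {
      out[j] <- 0
      next
    }
    ii <- seq_len(j - 1L)
    g <- if (length(hull) == 1L) {
      rep(flow[hull], length(ii))
    } else {
      stats::approx(w[hull], flow[hull], xout = w[ii], rule = 2)$y
    }
    out[j] <- max(f[ii] - g) / 2
  }
  out
}

# Smallest t at which the convex part (points 1..s, ending at the mode's
# left limit) and the concave part (points s..m) join monotonically. The
# minimal reachable left-limit value at w[s] is a maximum of linear,
# decreasing functions of t (chords through an upper corner and a later
# lower corner, extended to w[s], plus the window floor); the maximal
# reachable start of the concave part is a minimum of linear, increasing
# functions. Their crossing is found by Newton steps on the active lines
# (exact for piecewise-linear monotone functions).
junction_threshold <- function(s, w, f, flow, m, t0) {
  aL <- flow[s]; bL <- 1 # left-limit window floor flow_s - t
  if (s >= 3) {
    p <- rep(seq_len(s - 2L), times = (s - 2L):1L)
    i <- unlist(lapply(seq_len(s - 2L), function(pp) seq(pp + 1L, s - 1L)))
    r <- (w[s] - w[i]) / (w[i] - w[p])
    aL <- c(aL, f[i] + (f[i] - flow[p]) * r)
    bL <- c(bL, 1 + 2 * r)
  }
  cR <- f[s]; dR <- 1 # start window ceiling f_s + t
  if (s <= m - 2L) {
    i2 <- rep(seq(s + 1L, m - 1L), times = (m - 1L):(s + 1L) - s)
    q2 <- unlist(lapply(seq(s + 1L, m - 1L), function(ii) seq(ii + 1L, m)))
    r2 <- (w[i2] - w[s]) / (w[q2] - w[i2])
    cR <- c(cR, flow[i2] - (f[q2] - flow[i2]) * r2)
    dR <- c(dR, 1 + 2 * r2)
  }
  t <- t0
  for (it in 1:200) {
    vL <- aL - bL * t
    vR <- cR + dR * t
    iL <- which.max(vL)
    iR <- which.min(vR)
    if (vL[iL] <= vR[iR] + 1e-12) return(t)
    t_new <- (aL[iL] - cR[iR]) / (bL[iL] + dR[iR])
    if (t_new <= t + 1e-14) return(t_new)
    t <- t_new
  }
  t
}

#' Calibrated dip test of unimodality
#'
#' Bootstrap calibration of the dip statistic against samples of equal size
#' drawn from the uniform distribution, the standard reference null for the
#' dip test. The p value is the fraction of null dips at or above the
#' observed dip (with the +1 continuity correction).
#'
#' @param x numeric sample (at least 10 values to be testable).
#' @param n_boot number of null draws (default 2000).
#' @param seed integer seed for the null draws.
#' @return list with `dip`, `p_value`, `n`, `n_boot`, and `testable`.
#' @export
dip_test_calibrated <- function(x, n_boot = 2000, seed = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10) {
    return(list(dip = NA_real_, p_value = NA_real_, n = n, n_boot = n_boot,
                testable = FALSE))
  }
  obs <- dip_statistic(x)
  null_dips <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) dip_statistic(stats::runif(n)),
           numeric(1))
  })
  list(
    dip = obs,
    p_value = (1 + sum(null_dips >= obs)) / (n_boot + 1),
    n = n,
    n_boot = n_boot,
    testable = TRUE
  )
}
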