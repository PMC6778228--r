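# Independent oracles used to validate the implementation.

# Exact dip statistic as a minimax program: for each candidate mode point s
# (which may carry an atom), minimize the band half-width t such that a
# nondecreasing function, convex up to s and concave from s on, fits within
# [ECDF - t, ECDF + t]. Solved as a ridge-regularized LP with the dual-method
# QP solver (quadprog), which is numerically robust; the 1e-8 ridge perturbs
# the optimum far below the comparison tolerance. The mode's left limit is a
# separate variable u constrained to the lower-corner window at s.
dip_lp_oracle <- function(x) {
  x <- sort(x)
  if (diff(range(x)) > 0) x <- (x - min(x)) / diff(range(x))
  tab <- table(x)
  w <- as.numeric(names(tab))
  m <- length(w)
  n <- length(x)
  if (m == 1) return(0)
  f <- cumsum(as.integer(tab)) / n
  flow <- c(0, f[-m])
  nv <- m + 2 # v_1..v_m, u (mode left limit), t
  iu <- m + 1
  it <- m + 2
  best <- Inf
  for (s in 1:m) {
    rows <- list() # constraints as  row %*% x >= rhs
    rhs <- c()
    add <- function(idx, coef, b) {
      r <- numeric(nv); r[idx] <- coef
      rows[[length(rows) + 1L]] <<- r
      rhs <<- c(rhs, b)
    }
    for (i in 1:m) {
      up <- if (i == s) f[i] else flow[i] # atom allowed at the mode point
      add(c(i, it), c(-1, 1), -up)        # v_i - t <= up
      add(c(i, it), c(1, 1), f[i])        # v_i + t >= f_i
    }
    for (i in 1:(m - 1)) add(c(i, i + 1), c(-1, 1), 0) # monotone
    if (s > 1) {
      add(c(iu, it), c(-1, 1), -flow[s])
      add(c(iu, it), c(1, 1), flow[s])
      add(c(s - 1, iu), c(-1, 1), 0) # v_{s-1} <= u
      add(c(iu, s), c(-1, 1), 0)     # u <= v_s
    }
    if (s >= 3) for (i in 2:(s - 1)) { # convex kinks, last point is u at w_s
      ids <- c(i - 1, i, if (i + 1 == s) iu else i + 1)
      dx1 <- w[i] - w[i - 1]; dx2 <- w[i + 1] - w[i]
      add(ids, c(dx2, -(dx1 + dx2), dx1), 0)
    }
    if (s <= m - 2) for (i in (s + 1):(m - 1)) { # concave kinks
      dx1 <- w[i] - w[i - 1]; dx2 <- w[i + 1] - w[i]
      add(c(i - 1, i, i + 1), -c(dx2, -(dx1 + dx2), dx1), 0)
    }
    Amat <- t(do.call(rbind, rows))
    dvec <- numeric(nv); dvec[it] <- -1 # minimize t
    sol <- try(quadprog::solve.QP(Dmat = diag(1e-8, nv), dvec = dvec,
                                  Amat = Amat, bvec = rhs), silent = TRUE)
    if (!inherits(sol, "try-error")) best <- min(best, sol$solution[it])
  }
  best
}

# Type-II sums-of-squares F statistics by brute-force model comparison:
# each effect is tested against the model containing every term that does
# not involve it, with the residual from the full factorial model.
anova_type2_oracle <- function(data, response, factors) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  all_terms <- attr(stats::terms(
    stats::reformulate(paste(factors, collapse = " * "))
  ), "term.labels")
  full <- stats::lm(stats::reformulate(all_terms, response), data = data)
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  out <- list()
  contains <- function(term, target) {
    all(strsplit(target, ":")[[1]] %in% strsplit(term, ":")[[1]])
  }
  for (target in all_terms) {
    base_terms <- all_terms[!vapply(all_terms, contains, TRUE, target = target)]
    with_terms <- c(base_terms, target)
    fit0 <- if (length(base_terms)) {
      stats::lm(stats::reformulate(base_terms, response), data = data)
    } else {
      stats::lm(stats::reformulate("1", response), data = data)
    }
    fit1 <- stats::lm(stats::reformulate(with_terms, response), data = data)
    rss0 <- sum(stats::residuals(fit0)^2)
    rss1 <- sum(stats::residuals(fit1)^2)
    df_eff <- fit0$df.residual - fit1$df.residual
    out[[target]] <- c(
      df = df_eff,
      statistic = ((rss0 - rss1) / df_eff) / (rss_full / df_res)
    )
  }
  out
}

# Dense profile grid over the gain variance for the NB fit (lambda at the
# sample mean, its closed-form MLE in this parameterization).
nb_grid_oracle <- function(counts, s2_max = 3, n_grid = 30001) {
  m <- mean(counts)
  grid <- seq(0, s2_max, length.out = n_grid)
  ll <- vapply(grid, function(s2) {
    if (s2 < 1e-10) sum(stats::dpois(counts, m, log = TRUE))
    else sum(stats::dnbinom(counts, size = 1 / s2, mu = m, log = TRUE))
  }, numeric(1))
  list(gain_var = grid[which.max(ll)], loglik = max(ll),
       step = grid[2] - grid[1])
}

# Gamma-renewal ISI sample (operational time, unit rate).
gamma_isis <- function(n, shape) stats::rgamma(n, shape = shape, rate = shape)

# A quick null cell: flat rates, no gains, Poisson-like spiking.
null_archetype <- function(rate = 10) {
  cell_archetype("null", p2t_mean_us = 400, p2t_sd_us = 0,
                 base_rate_hz = rate, attention_gain = 1, drug_gain = 1,
                 gain_var = 0, isi_shape = 1)
}
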