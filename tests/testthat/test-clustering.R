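# Synthetic per-cell metrics table with planted Gaussian feature clusters,
# bypassing the spike simulator (fast path for clustering unit tests).
planted_metrics <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    m <- matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                      sd = sd), nrow = n_per)
    colnames(m) <- colnames(centers)
    tibble::as_tibble(m)
  })
  out <- dplyr::bind_rows(rows)
  out$cell_id <- sprintf("c%03d", seq_len(nrow(out)))
  out$truth <- rep(seq_len(nrow(centers)), each = n_per)
  out
}

test_that("feature screening drops a duplicated feature", {
  set.seed(18)
  n <- 120
  base <- matrix(rnorm(3 * n), n, 3)
  met <- tibble::tibble(
    cell_id = sprintf("c%d", 1:n),
    f1 = base[, 1],
    f1_copy = base[, 1] + rnorm(n, sd = 1e-3),
    f2 = base[, 2],
    f3 = base[, 3]
  )
  fm <- build_feature_matrix(met, features = c("f1", "f1_copy", "f2", "f3"))
  sc <- screen_parameters(fm, threshold = 0.95)
  expect_lte(sum(c("f1", "f1_copy") %in% sc$selected), 1)
  expect_gte(sc$explained, 0.95 - 1e-9)
})

test_that("threshold 1 with independent features selects everything", {
  set.seed(19)
  met <- tibble::tibble(cell_id = sprintf("c%d", 1:80),
                        a = rnorm(80), b = rnorm(80), c = rnorm(80))
  fm <- build_feature_matrix(met, features = c("a", "b", "c"))
  sc <- screen_parameters(fm, threshold = 1)
  expect_setequal(sc$selected, c("a", "b", "c"))
  expect_error(screen_parameters(fm, threshold = 1.2))
  expect_error(screen_parameters(fm, threshold = 0))
})

test_that("missing features drop cells from the matrix, listed by id", {
  met <- tibble::tibble(cell_id = c("a", "b", "c"),
                        f1 = c(1, NA, 3), f2 = c(1, 2, 3))
  fm <- build_feature_matrix(met, features = c("f1", "f2"))
  expect_equal(rownames(fm$z), c("a", "c"))
  expect_equal(fm$dropped_cells, "b")
  expect_equal(unname(colMeans(fm$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(fm$z, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("mixture sweep recovers three well-separated planted components", {
  centers <- matrix(c(0, 0, 0, 4, 4, 0, 0, 4, 4), 3, 3, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y", "w")))
  met <- planted_metrics(centers, 30, sd = 0.4, seed = 20)
  fm <- build_feature_matrix(met, features = c("x", "y", "w"))
  sweep <- fit_mixture_sweep(fm$z, k_range = 2:6, restarts = 30, seed = 2)
  tab <- sweep$table
  # BIC's consistent penalty lands on the planted count; AIC is liberal on
  # mixtures, so the recovery guarantee runs through the selection rule
  expect_equal(tab$k[which.min(tab$bic)], 3)
  cls <- setNames(rep(c("narrow", "broad", "broad"), each = 30), met$cell_id)
  # AIC's argmin may sit at the sweep boundary here; that warning is expected
  sel <- suppressWarnings(select_k(sweep, cell_class = cls))
  expect_equal(sel$k, 3)
  ari <- mclust::adjustedRandIndex(sweep$assignments[["3"]], met$truth)
  expect_gt(ari, 0.95)
})

test_that("a single Gaussian cloud is not split", {
  met <- planted_metrics(matrix(c(0, 0), 1, 2,
                                dimnames = list(NULL, c("x", "y"))),
                         80, sd = 1, seed = 21)
  fm <- build_feature_matrix(met, features = c("x", "y"))
  sweep <- fit_mixture_sweep(fm$z, k_range = 2:8, restarts = 20, seed = 2)
  tab <- sweep$table
  expect_equal(tab$k[which.min(tab$bic)], 2) # lowest k on offer
  expect_gt(min(diff(tab$bic)), 0) # BIC strictly increasing in k
})

test_that("identical seeds give bit-identical sweeps", {
  centers <- matrix(c(0, 0, 3, 3), 2, 2, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y")))
  met <- planted_metrics(centers, 20, seed = 22)
  fm <- build_feature_matrix(met, features = c("x", "y"))
  s1 <- fit_mixture_sweep(fm$z, k_range = 2:4, restarts = 10, seed = 9)
  s2 <- fit_mixture_sweep(fm$z, k_range = 2:4, restarts = 10, seed = 9)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$assignments, s2$assignments)
})

test_that("clustering is invariant to row order up to label permutation", {
  centers <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y")))
  met <- planted_metrics(centers, 25, seed = 23)
  fm1 <- build_feature_matrix(met, features = c("x", "y"))
  perm <- sample(nrow(met))
  fm2 <- build_feature_matrix(met[perm, ], features = c("x", "y"))
  a1 <- fit_mixture_sweep(fm1$z, k_range = 3, restarts = 20, seed = 4)$assignments[["3"]]
  a2 <- fit_mixture_sweep(fm2$z, k_range = 3, restarts = 20, seed = 4)$assignments[["3"]]
  common <- intersect(names(a1), names(a2))
  expect_equal(mclust::adjustedRandIndex(a1[common], a2[common]), 1)
})

test_that("AIC and BIC use the diagonal-mixture parameter count", {
  set.seed(24)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(sprintf("c%d", 1:30), c("x", "y")))
  sweep <- fit_mixture_sweep(x, k_range = 1, restarts = 5, seed = 1)
  # one component: closed-form Gaussian MLE log-likelihood
  ll <- sum(vapply(1:2, function(j) {
    mu <- mean(x[, j]); s2 <- mean((x[, j] - mu)^2)
    sum(dnorm(x[, j], mu, sqrt(s2), log = TRUE))
  }, numeric(1)))
  p <- 2 * 1 * 2 + 0
  expect_equal(sweep$table$loglik, ll, tolerance = 1e-6)
  expect_equal(sweep$table$aic, 2 * p - 2 * ll, tolerance = 1e-6)
  expect_equal(sweep$table$bic, p * log(30) - 2 * ll, tolerance = 1e-6)
})

test_that("k selection applies the width-mixing tiebreak", {
  tab <- tibble::tibble(k = c(2, 3), loglik = c(-10, -5), df = c(9, 14),
                        aic = c(38.5, 38), bic = c(40, 41),
                        best_start = "hierarchical")
  cls <- c(a = "narrow", b = "narrow", c = "broad", d = "broad")
  sweep <- structure(list(
    table = tab,
    assignments = list(
      # k=2 mixes classes; k=3 separates them cleanly
      "2" = c(a = 1, b = 2, c = 1, d = 2),
      "3" = c(a = 1, b = 1, c = 2, d = 3)
    )
  ), class = "mixture_sweep")
  sel <- suppressWarnings(select_k(sweep, cell_class = cls))
  expect_equal(sel$k, 3)
  expect_match(sel$criterion_used, "tiebreak")
  # when both criteria agree the tiebreak is bypassed
  tab2 <- tab; tab2$aic <- c(10, 20); tab2$bic <- c(10, 25)
  sel2 <- select_k(structure(list(table = tab2, assignments = sweep$assignments),
                             class = "mixture_sweep"), cell_class = cls)
  expect_equal(sel2$k, 2)
})

test_that("cluster summaries label width composition and test bimodality", {
  set.seed(25)
  metrics <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:120),
    p2t_us = c(rnorm(40, 450, 15), rnorm(40, 200, 10),
               c(rnorm(20, 180, 10), rnorm(20, 420, 15))), # mixed cluster
    cell_class = classify_cell_width(p2t_us),
    fr = rnorm(120, 10), lv = rnorm(120, 1, 0.1), auroc = runif(120, 0.4, 0.9)
  )
  assign <- setNames(rep(1:3, each = 40), metrics$cell_id)
  sum3 <- summarize_clusters(assign, metrics, dip_n_boot = 500, seed = 2)
  comp <- sum3$composition
  expect_equal(nrow(comp), 3)
  # the balanced mixed cluster counts as broad-dominated (ties go to B)
  expect_equal(sort(comp$label), c("B1", "B2", "N1"))
  expect_equal(comp$minority_fraction[1], 0)
  # the planted half-narrow/half-broad cluster is the one flagged bimodal
  mixed <- which.max(comp$minority_fraction)
  expect_true(comp$dip_testable[mixed])
  expect_lt(comp$dip_p_adj[mixed], 0.05)
  expect_equal(length(sum3$labels), 120)
})
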