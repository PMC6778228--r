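#' Build the cell-feature matrix for clustering
#'
#' Assembles the candidate features (P2T, CV, CV2, Lv, FR, FF, AUROC by
#' default) from a per-cell metrics table, drops cells with any missing
#' feature (they are listed in the result), and z-scores each column.
#'
#' @param metrics per-cell tibble from [population_metrics()].
#' @param features character vector of feature column names.
#' @return a `feature_matrix`: list with `raw` and `z` matrices (rownames =
#'   cell ids), `features`, `dropped_cells`, and the cells' width classes.
#' @export
build_feature_matrix <- function(metrics,
                                 features = c("p2t_us", "cv", "cv2", "lv",
                                              "fr", "fano", "auroc")) {
  stopifnot(all(features %in% names(metrics)), "cell_id" %in% names(metrics))
  raw <- as.matrix(metrics[, features])
  rownames(raw) <- metrics$cell_id
  complete <- stats::complete.cases(raw)
  dropped <- metrics$cell_id[!complete]
  raw <- raw[complete, , drop = FALSE]
  z <- scale(raw)
  structure(
    list(
      raw = raw,
      z = z,
      features = features,
      dropped_cells = dropped,
      cell_class = if ("cell_class" %in% names(metrics)) {
        stats::setNames(metrics$cell_class, metrics$cell_id)[complete]
      } else NULL
    ),
    class = "feature_matrix"
  )
}

#' Screen clustering features by explained variance
#'
#' Ranks the z-scored candidate features by their PCA importance (total
#' squared loading weighted by component explained variance) and greedily
#' selects features until the span of the selected subset explains at least
#' `threshold` of the total variance. At each step the feature with the
#' largest marginal gain in explained span is added (ranking score breaks
#' ties), so a feature nearly collinear with an already selected one is
#' passed over -- of two duplicated features only one survives.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param threshold fraction of total variance the selected subset must
#'   explain, in `(0, 1]` (default 0.90).
#' @return list with `selected` (feature names), `explained` (fraction
#'   attained), `ranking` (PCA importance scores), and `path` (per-step
#'   explained fractions).
#' @export
screen_parameters <- function(fm, threshold = 0.90) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  z <- fm$z
  if (nrow(z) < ncol(z) + 1) stop("need at least one more cell than features")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  # rank by squared loadings on the leading components that reach the
  # threshold (weighting all components would give every feature the same
  # score, since the columns are standardized)
  n_keep <- which(cumsum(ev) >= threshold)[1]
  ranking <- drop((pca$rotation[, seq_len(n_keep), drop = FALSE]^2) %*%
                    ev[seq_len(n_keep)])
  names(ranking) <- colnames(z)

  total <- sum(z^2)
  span_explained <- function(sel) {
    q <- qr.Q(qr(z[, sel, drop = FALSE]))
    sum((crossprod(q, z))^2) / total
  }
  selected <- character(0)
  path <- numeric(0)
  remaining <- colnames(z)
  explained <- 0
  while (explained < threshold - 1e-12 && length(remaining)) {
    gains <- vapply(remaining, function(fn) span_explained(c(selected, fn)),
                    numeric(1))
    # marginal-gain greedy, PCA ranking as tie-break
    best_gain <- max(gains)
    cand <- remaining[gains > best_gain - 1e-9]
    pick <- cand[which.max(ranking[cand])]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    explained <- gains[pick]
    path <- c(path, explained)
  }
  list(selected = selected, explained = explained, ranking = ranking,
       path = path)
}

#' Gaussian-mixture sweep over cluster counts
#'
#' Fits diagonal-covariance Gaussian mixtures ("VVI") to the z-scored
#' selected features for each candidate cluster count and records the
#' log-likelihood, the free-parameter count `p = 2kd + (k - 1)` (means,
#' variances, weights), and `AIC = 2p - 2l`, `BIC = p ln(n) - 2l`. Each k
#' takes the best of the deterministic model-based hierarchical
#' initialization and `restarts` random-start EM runs (random starts guard
#' against the local optima the hierarchical start can fall into when
#' clusters are very unequal in spread). Deterministic given the seed;
#' restarts whose EM collapses a component below 2 expected members are
#' discarded.
#'
#' @param z numeric matrix (cells x selected features), typically
#'   `fm$z[, screened$selected]`.
#' @param k_range candidate cluster counts (default 2:12).
#' @param restarts number of random-start EM runs per k (default 100).
#' @param seed integer seed.
#' @return a `mixture_sweep`: list with `table` (tibble k, loglik, df, aic,
#'   bic, best_start) and `assignments` (list of per-k classification
#'   vectors).
#' @import mclust
#' @export
fit_mixture_sweep <- function(z, k_range = 2:12, restarts = 100, seed = 1) {
  stopifnot(is.matrix(z), nrow(z) >= max(k_range) * 3)
  n <- nrow(z)
  rows <- list()
  assignments <- list()
  local_seed(seed, {
    for (k in k_range) {
      best_ll <- -Inf
      best_cl <- NULL
      best_start <- NA_character_
      fit <- try(suppressWarnings(
        mclust::Mclust(z, G = k, modelNames = "VVI", verbose = FALSE)
      ), silent = TRUE)
      if (!inherits(fit, "try-error") && !is.null(fit) &&
            is.finite(fit$loglik)) {
        best_ll <- fit$loglik
        best_cl <- fit$classification
        best_start <- "hierarchical"
      }
      for (r in seq_len(restarts)) {
        cl0 <- sample.int(k, n, replace = TRUE)
        if (length(unique(cl0)) < k) next
        em <- try(suppressWarnings(
          mclust::me(data = z, modelName = "VVI",
                     z = mclust::unmap(cl0, groups = 1:k))
        ), silent = TRUE)
        if (inherits(em, "try-error") || is.null(em$loglik) ||
              !is.finite(em$loglik)) next
        # discard degenerate solutions: a component needs more members than
        # feature dimensions for its diagonal variances to be estimable
        # (splinters below that collapse a variance and inflate the
        # likelihood without meaning)
        if (min(colSums(em$z)) < max(2, ncol(z) + 1)) next
        if (em$loglik > best_ll + 1e-8) {
          best_ll <- em$loglik
          best_cl <- mclust::map(em$z)
          best_start <- paste0("restart_", r)
        }
      }
      if (is.null(best_cl)) {
        rows[[as.character(k)]] <- tibble::tibble(
          k = k, loglik = NA_real_, df = NA_real_,
          aic = NA_real_, bic = NA_real_, best_start = NA_character_
        )
        next
      }
      p <- 2 * k * ncol(z) + (k - 1)
      rows[[as.character(k)]] <- tibble::tibble(
        k = k, loglik = best_ll, df = p,
        aic = 2 * p - 2 * best_ll,
        bic = p * log(n) - 2 * best_ll,
        best_start = best_start
      )
      names(best_cl) <- rownames(z)
      assignments[[as.character(k)]] <- best_cl
    }
  })
  structure(list(table = dplyr::bind_rows(rows), assignments = assignments),
            class = "mixture_sweep")
}

# Summed per-cluster minority fraction of narrow/broad width classes; lower
# values mean cleaner separation of the two width classes across clusters.
width_mixing_score <- function(assignment, cell_class) {
  cls <- cell_class[names(assignment)]
  sum(vapply(split(cls, assignment), function(v) {
    tb <- table(factor(v, levels = c("narrow", "broad")))
    min(tb) / max(1, sum(tb))
  }, numeric(1)))
}

#' Select the number of clusters
#'
#' Takes the argmin of the chosen criterion. When AIC and BIC disagree, the
#' tiebreak prefers the solution with less mixing of narrow and broad
#' spiking cells within clusters (the summed per-cluster minority fraction
#' of width classes), the rationale being that waveform width is an
#' established cell-class boundary that a good partition should respect.
#'
#' @param sweep a [fit_mixture_sweep()] result.
#' @param cell_class named narrow/broad vector (required for the tiebreak).
#' @param criterion `"AIC"` (default) or `"BIC"`; used when the two agree or
#'   no width classes are supplied.
#' @return list with `k`, `assignments`, `k_aic`, `k_bic`, `mixing_scores`,
#'   and `criterion_used`.
#' @export
select_k <- function(sweep, cell_class = NULL, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  tab <- sweep$table[!is.na(sweep$table$aic), ]
  if (!nrow(tab)) stop("no successful mixture fit in sweep")
  k_aic <- tab$k[which.min(tab$aic)]
  k_bic <- tab$k[which.min(tab$bic)]
  boundary <- max(tab$k)
  if (k_aic == boundary || k_bic == boundary) {
    warning("criterion minimized at the sweep boundary (k = ", boundary, ")")
  }
  mixing <- NULL
  if (k_aic == k_bic || is.null(cell_class)) {
    k <- if (criterion == "AIC") k_aic else k_bic
    used <- criterion
  } else {
    mixing <- c(
      AIC = width_mixing_score(sweep$assignments[[as.character(k_aic)]], cell_class),
      BIC = width_mixing_score(sweep$assignments[[as.character(k_bic)]], cell_class)
    )
    if (mixing["AIC"] < mixing["BIC"] - 1e-12) {
      k <- k_aic; used <- "AIC (width-mixing tiebreak)"
    } else if (mixing["BIC"] < mixing["AIC"] - 1e-12) {
      k <- k_bic; used <- "BIC (width-mixing tiebreak)"
    } else {
      # equally clean width separation: take the more parsimonious solution
      k <- min(k_aic, k_bic); used <- "parsimony (width-mixing tied)"
    }
  }
  list(k = k, assignments = sweep$assignments[[as.character(k)]],
       k_aic = k_aic, k_bic = k_bic, mixing_scores = mixing,
       criterion_used = used)
}

#' Summarize clusters: composition, features, waveform-width bimodality
#'
#' Labels each cluster by its width composition (`B*` if broad-dominated,
#' `N*` otherwise, numbered by decreasing size within type), reports
#' narrow/broad counts and feature means +/- SD, and runs the calibrated
#' Hartigan dip test on each cluster's P2T distribution (clusters with fewer
#' than 10 cells are untestable); dip p values are FDR-adjusted across
#' clusters.
#'
#' @param assignments named cluster vector (cells -> cluster).
#' @param metrics per-cell metrics tibble (must contain `p2t_us`,
#'   `cell_class`).
#' @param dip_n_boot bootstrap draws for the dip calibration.
#' @param seed seed for the dip calibration.
#' @return list with `composition` (per-cluster tibble including dip
#'   results) and `labels` (cell -> cluster label).
#' @export
summarize_clusters <- function(assignments, metrics, dip_n_boot = 2000,
                               seed = 1) {
  met <- metrics[match(names(assignments), metrics$cell_id), ]
  rows <- list()
  for (cl in sort(unique(assignments))) {
    sel <- assignments == cl
    sub <- met[sel, ]
    n_narrow <- sum(sub$cell_class == "narrow", na.rm = TRUE)
    n_broad <- sum(sub$cell_class == "broad", na.rm = TRUE)
    dtest <- dip_test_calibrated(sub$p2t_us, n_boot = dip_n_boot,
                                 seed = derive_seed(seed, paste0("dip/", cl)))
    rows[[as.character(cl)]] <- tibble::tibble(
      cluster = cl,
      n_cells = sum(sel),
      n_narrow = n_narrow,
      n_broad = n_broad,
      minority_fraction = min(n_narrow, n_broad) / max(1, n_narrow + n_broad),
      p2t_mean = mean(sub$p2t_us, na.rm = TRUE),
      p2t_sd = stats::sd(sub$p2t_us, na.rm = TRUE),
      fr_mean = mean(sub$fr, na.rm = TRUE),
      lv_mean = mean(sub$lv, na.rm = TRUE),
      auroc_mean = mean(sub$auroc, na.rm = TRUE),
      dip = dtest$dip,
      dip_p = dtest$p_value,
      dip_testable = dtest$testable
    )
  }
  comp <- dplyr::bind_rows(rows)
  comp$dip_p_adj <- NA_real_
  testable <- comp$dip_testable
  comp$dip_p_adj[testable] <- bh_fdr(comp$dip_p[testable])
  # width-composition labels, numbered by decreasing size within type
  comp$type <- ifelse(comp$n_broad >= comp$n_narrow, "B", "N")
  comp$label <- NA_character_
  for (ty in c("B", "N")) {
    idx <- which(comp$type == ty)
    idx <- idx[order(-comp$n_cells[idx])]
    comp$label[idx] <- paste0(ty, seq_along(idx))
  }
  labels <- stats::setNames(comp$label[match(assignments, comp$cluster)],
                            names(assignments))
  list(composition = comp, labels = labels)
}
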