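#' Descriptive features of a quantified heterochromatin region
#'
#' Collapses the quantification outputs for one region into a single
#' deterministic feature vector: heterochromatin-wide features (domain
#' count, foreground volume fraction, LAC moments, effective-diameter
#' moments, skew-normal shape, mean k-NN distances, g(r) first-peak
#' position, coordination number). Regions with fewer than 4 domains are
#' flagged unstable; NN features for a single domain are emitted as
#' missing.
#'
#' @param domains a domain table from [segment_domains()].
#' @param lac_stats output of [lac_statistics()] for the region (uses the
#'   heterochromatin entry when present).
#' @param rdf an optional `rdf_result` from [domain_rdf_and_zc()].
#' @param region_volume_nm3 region volume (nm^3) for the foreground
#'   fraction; `NA` skips that feature.
#' @param k_max k-NN orders to include.
#' @return a one-row data.frame with attribute `unstable` and a
#'   `feature_version` attribute naming the feature list revision.
#' @export
extract_features <- function(domains, lac_stats = NULL, rdf = NULL,
                             region_volume_nm3 = NA, k_max = 10) {
  n <- nrow(domains)
  unstable <- n < 4
  hc <- if (!is.null(lac_stats) && !is.null(lac_stats$heterochromatin)) {
    lac_stats$heterochromatin
  } else {
    NULL
  }
  skw <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    mean((v - mean(v))^3) / stats::sd(v)^3
  }
  row <- data.frame(
    domain_count = n,
    foreground_fraction = if (is.na(region_volume_nm3)) NA_real_ else
      sum(domains$volume_nm3) / region_volume_nm3,
    lac_mean = if (!is.null(hc)) hc$mean else mean(domains$lac_mean),
    lac_sd = if (!is.null(hc)) hc$sd else stats::sd(domains$lac_mean),
    lac_skewness = if (!is.null(hc)) {
      skw(c(hc$hist$mids[rep(seq_along(hc$hist$counts),
                             hc$hist$counts)]))
    } else {
      skw(domains$lac_mean)
    },
    deff_mean = mean(domains$d_eff_nm),
    deff_sd = stats::sd(domains$d_eff_nm),
    skewnorm_alpha = if (n >= 20) {
      tryCatch(fit_skew_normal(domains$d_eff_nm, nboot = 0)$alpha,
               error = function(e) NA_real_)
    } else {
      NA_real_
    },
    lac_max_mean = mean(domains$lac_max))
  if (n >= 2) {
    kk <- knn_distances(domains[, c("x_nm", "y_nm", "z_nm")],
                        k_max = min(k_max, n - 1))
    knn_means <- colMeans(kk$distances)
    for (k in seq_len(k_max)) {
      row[[paste0("knn", k, "_mean")]] <-
        if (k <= length(knn_means)) knn_means[k] else NA_real_
    }
  } else {
    for (k in seq_len(k_max)) row[[paste0("knn", k, "_mean")]] <- NA_real_
  }
  row$gr_first_peak <- if (!is.null(rdf)) {
    pk <- rdf$curve$x[which.max(smooth3(rdf$curve$y))]
    if (length(pk)) pk else NA_real_
  } else {
    NA_real_
  }
  row$zc <- if (!is.null(rdf)) rdf$z else NA_real_
  attr(row, "unstable") <- unstable
  attr(row, "feature_version") <- "hc-wide-v1"
  row
}

#' PCA to LDA classification pipeline
#'
#' Standardizes the features (z-score), fits PCA on a stratified training
#' split only, projects onto the first `n_pcs` components, trains LDA on
#' the training scores and evaluates held-out accuracy. Per-class 95%
#' confidence ellipses for a multivariate t distribution are computed in
#' the first two discriminant coordinates.
#'
#' @param features data.frame with a `label` factor column and numeric
#'   feature columns (other non-numeric columns are ignored).
#' @param train_fraction training fraction (default 0.6).
#' @param n_pcs principal components retained (default 12, truncated to
#'   the available rank).
#' @param seed RNG seed for the split.
#' @param ellipse_level confidence level for the class ellipses.
#' @return list with `projection` (data.frame of LD scores, labels and a
#'   `split` column), `accuracy` (held-out overall), `class_accuracy`,
#'   `confusion`, `ellipses` (per class: centre, shape matrix, radius),
#'   `n_pcs`, `regularized`.
#' @export
lda_pipeline <- function(features, train_fraction = 0.6, n_pcs = 12,
                         seed = 1, ellipse_level = 0.95) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  lab <- features$label
  if (is.null(lab)) stop("features must carry a 'label' column")
  lab <- droplevels(factor(lab))
  if (nlevels(lab) < 2) stop("need at least 2 classes")
  num <- features[vapply(features, is.numeric, TRUE)]
  num <- num[, colnames(num) != "batch", drop = FALSE]
  keep <- colSums(!is.finite(as.matrix(num))) == 0
  X <- as.matrix(num[, keep, drop = FALSE])
  set.seed(seed)
  train <- unlist(lapply(levels(lab), function(cl) {
    idx <- which(lab == cl)
    sample(idx, max(1, round(train_fraction * length(idx))))
  }))
  train <- sort(train)
  test <- setdiff(seq_len(nrow(X)), train)
  # a class can be absent from the test split for tiny inputs; the
  # training split always holds every class by construction
  mu <- colMeans(X[train, , drop = FALSE])
  sd_ <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  pca <- stats::prcomp(Xs[train, , drop = FALSE], center = FALSE,
                       scale. = FALSE)
  n_pcs_used <- min(n_pcs, sum(pca$sdev > 1e-8))
  scores <- Xs %*% pca$rotation[, seq_len(n_pcs_used), drop = FALSE]
  regularized <- FALSE
  ld <- tryCatch(
    MASS::lda(scores[train, , drop = FALSE], grouping = lab[train]),
    error = function(e) NULL)
  if (is.null(ld)) {
    # singular within-class scatter: ridge the scores
    regularized <- TRUE
    scores <- scores + matrix(stats::rnorm(length(scores), 0, 1e-6),
                              nrow(scores))
    ld <- MASS::lda(scores[train, , drop = FALSE], grouping = lab[train])
  }
  pred <- stats::predict(ld, scores[test, , drop = FALSE])
  acc <- mean(pred$class == lab[test])
  confusion <- table(truth = lab[test], predicted = pred$class)
  class_acc <- diag(prop.table(confusion, 1))
  all_proj <- stats::predict(ld, scores)$x
  proj <- data.frame(all_proj, label = lab,
                     split = ifelse(seq_len(nrow(X)) %in% train,
                                    "train", "test"))
  ellipses <- list()
  if (ncol(all_proj) >= 2) {
    for (cl in levels(lab)) {
      pts <- all_proj[lab == cl, 1:2, drop = FALSE]
      if (nrow(pts) >= 4) {
        ellipses[[cl]] <- mvt_ellipse(pts, level = ellipse_level)
      }
    }
  }
  list(projection = proj, accuracy = acc, class_accuracy = class_acc,
       confusion = confusion, ellipses = ellipses, n_pcs = n_pcs_used,
       regularized = regularized, lda = ld, pca = pca,
       train_index = train)
}

#' Confidence ellipse for a multivariate t distribution
#'
#' Robust centre/scatter via [MASS::cov.trob()] with the F-quantile
#' radius used for bivariate confidence ellipses.
#'
#' @param pts n x 2 matrix.
#' @param level confidence level.
#' @param n_points polygon resolution.
#' @return list with `centre`, `shape`, `radius` and `polygon`
#'   (n_points x 2).
#' @export
mvt_ellipse <- function(pts, level = 0.95, n_points = 100) {
  stopifnot(ncol(pts) == 2, nrow(pts) >= 4)
  fit <- MASS::cov.trob(pts)
  df <- nrow(pts) - 1
  radius <- sqrt(2 * stats::qf(level, 2, df))
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  ch <- chol(fit$cov)
  poly <- sweep(radius * circ %*% ch, 2, fit$center, "+")
  list(centre = fit$center, shape = fit$cov, radius = radius,
       polygon = poly)
}

#' Random-forest validation with importance-based feature selection
#'
#' Tunes the tree count on out-of-bag error over `ntree_grid`, trains on
#' a stratified 60% split, reports held-out accuracy, and retains the
#' features whose permutation importance (mean decrease in accuracy)
#' exceeds `select_frac` of the maximum importance.
#'
#' @param features data.frame with `label` plus numeric features.
#' @param seed RNG seed.
#' @param train_fraction training fraction.
#' @param ntree_grid candidate tree counts.
#' @param select_frac importance threshold as a fraction of the maximum.
#' @return list with `accuracy`, `ntree`, `importance` (named vector),
#'   `selected` (feature names), `forest`.
#' @export
rf_validate_and_select <- function(features, seed = 1,
                                   train_fraction = 0.6,
                                   ntree_grid = c(100, 250, 500),
                                   select_frac = 0.4) {
  lab <- droplevels(factor(features$label))
  if (nlevels(lab) < 2) stop("need at least 2 classes")
  num <- features[vapply(features, is.numeric, TRUE)]
  num <- num[, colnames(num) != "batch", drop = FALSE]
  keep <- colSums(!is.finite(as.matrix(num))) == 0
  X <- as.data.frame(num[, keep, drop = FALSE])
  set.seed(seed)
  train <- unlist(lapply(levels(lab), function(cl) {
    idx <- which(lab == cl)
    sample(idx, max(1, round(train_fraction * length(idx))))
  }))
  test <- setdiff(seq_len(nrow(X)), train)
  oob <- vapply(ntree_grid, function(nt) {
    rf <- randomForest::randomForest(X[train, , drop = FALSE], lab[train],
                                     ntree = nt)
    rf$err.rate[nt, "OOB"]
  }, numeric(1))
  ntree <- ntree_grid[which.min(oob)]
  forest <- randomForest::randomForest(X[train, , drop = FALSE],
                                       lab[train], ntree = ntree,
                                       importance = TRUE)
  pred <- stats::predict(forest, X[test, , drop = FALSE])
  acc <- mean(pred == lab[test])
  imp <- forest$importance[, "MeanDecreaseAccuracy"]
  selected <- names(imp)[imp > select_frac * max(imp)]
  list(accuracy = acc, ntree = ntree, importance = imp,
       selected = selected, forest = forest)
}

#' Mann-Whitney U statistic and test
#'
#' Thin wrapper over [stats::wilcox.test()] returning the U statistic
#' explicitly; used for pairwise treatment-vs-control comparisons.
#'
#' @param x,y numeric samples.
#' @param ... passed to [stats::wilcox.test()].
#' @return list with `U`, `p_value` and the underlying `htest`.
#' @export
mann_whitney_u <- function(x, y, ...) {
  ht <- stats::wilcox.test(x, y, ...)
  list(U = unname(ht$statistic), p_value = ht$p.value, test = ht)
}
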