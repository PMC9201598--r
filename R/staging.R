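#' Assemble the subjects x 220 evoked-feature matrix
#'
#' Each subject contributes 110 LFP samples and 110 MUA samples covering -10
#' to +100 ms relative to stimulus onset on a 1 kHz grid (LFP linearly
#' resampled; MUA PSTH bin-mean down-sampled when its native bin rate exceeds
#' 1 kHz). Columns are ordered LFP first, then MUA. By default each column is
#' z-scored, since the two blocks mix millivolts and spikes/s and the
#' larger-variance modality would otherwise dominate the PCA; set
#' `scale = FALSE` for unscaled features.
#'
#' @param subjects List; each element a list with `lfp` and `mua`
#'   (`evoked_response` objects for the reference condition), `subject_id`,
#'   and `age_days`.
#' @param window Feature window, s (left-closed, right-open at 1 ms steps).
#' @param scale Z-score each column.
#' @return A `feature_matrix`: list with `matrix` (N x 220), `subject_ids`,
#'   `ages`.
#' @export
build_feature_matrix <- function(subjects, window = c(-0.010, 0.100), scale = TRUE) {
  grid <- seq(window[1], window[2] - 1e-3 / 2, by = 1e-3)
  n_feat <- length(grid)
  extract <- function(resp, what, id) {
    if (is.null(resp)) {
      abort(sprintf("subject %s missing %s response", id, what),
        class = "lamindev_completeness_error"
      )
    }
    if (what == "mua") {
      if (resp$fs < 1000) {
        abort(sprintf("subject %s MUA rate %g Hz below 1 kHz", id, resp$fs),
          class = "lamindev_completeness_error"
        )
      }
      # bin-mean down-sample to the 1 kHz grid; identity when bins are 1 ms
      vapply(grid, function(t0) {
        sel <- resp$time >= t0 - 1e-9 & resp$time < t0 + 1e-3 - 1e-9
        mean(resp$mean[sel])
      }, numeric(1))
    } else {
      approx(resp$time, resp$mean, xout = grid, rule = 2)$y
    }
  }
  rows <- purrr::map(subjects, function(s) {
    c(
      extract(s$lfp, "lfp", s$subject_id),
      extract(s$mua, "mua", s$subject_id)
    )
  })
  m <- do.call(rbind, rows)
  stopifnot(ncol(m) == 2 * n_feat)
  if (scale) {
    sds <- apply(m, 2, sd)
    m <- sweep(m, 2, colMeans(m))
    nz <- sds > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sds[nz], "/")
  }
  structure(
    list(
      matrix = m,
      subject_ids = purrr::map_chr(subjects, ~ as.character(.x$subject_id)),
      ages = purrr::map_dbl(subjects, ~ as.numeric(.x$age_days %||% NA))
    ),
    class = "feature_matrix"
  )
}

#' PCA projection of the evoked-feature matrix
#'
#' Principal components of the (centred) feature matrix; the number of
#' retained components is the smaller of the count needed to reach
#' `variance_target` cumulative explained variance and `max_pc`.
#'
#' @param fm A `feature_matrix` (or bare numeric matrix).
#' @param variance_target Cumulative explained-variance target (default 0.75).
#' @param max_pc Hard cap on retained components (default 10).
#' @return List with `scores` (N x d), `explained` (variance fractions, all
#'   components), `n_retained`.
#' @export
pca_project <- function(fm, variance_target = 0.75, max_pc = 10) {
  m <- if (inherits(fm, "feature_matrix")) fm$matrix else fm
  if (nrow(m) < 3) abort("need at least 3 subjects", class = "lamindev_size_error")
  if (all(apply(m, 2, var) == 0)) {
    abort("zero-variance feature matrix", class = "lamindev_degenerate_error")
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  n_target <- which(cumsum(explained) >= variance_target)[1]
  if (is.na(n_target)) n_target <- length(explained)
  d <- max(1, min(n_target, max_pc, ncol(p$x)))
  list(
    scores = p$x[, seq_len(d), drop = FALSE],
    explained = explained,
    n_retained = d
  )
}

#' k-means scan with silhouette-based model selection
#'
#' Runs k-means (multiple restarts, best inertia kept) for each k in
#' `k_range`, records the mean silhouette width over subjects, and selects
#' the k maximizing it (ties resolve to the smaller k). Values of k with
#' `k >= N` are skipped with a warning. A winning silhouette below
#' `weak_cutoff` sets the `weak_structure` flag.
#'
#' @param scores N x d matrix of PC scores (rows = subjects).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param n_restarts k-means restarts per k.
#' @param seed Integer seed fixing the restarts (reproducibility contract).
#' @param ages Optional per-subject ages for the per-cluster age table.
#' @param weak_cutoff Silhouette below which structure is flagged weak.
#' @return A `staging_result`: `silhouette_by_k` tibble, `best_k`,
#'   `cluster_labels`, `weak_structure`, and `age_by_cluster` when ages given.
#' @export
kmeans_silhouette_scan <- function(scores, k_range = 2:10, n_restarts = 50,
                                   seed = NULL, ages = NULL, weak_cutoff = 0.4) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (!is.null(seed)) set.seed(seed)
  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range)) {
    warn(sprintf("skipping k >= N (N = %d): %s", n,
      paste(setdiff(k_range, usable), collapse = ", ")))
  }
  if (!length(usable)) abort("no usable k (N too small)", class = "lamindev_size_error")
  d <- stats::dist(scores)
  fits <- list()
  sil <- numeric(length(usable))
  for (i in seq_along(usable)) {
    k <- usable[i]
    fit <- kmeans(scores, centers = k, nstart = n_restarts, iter.max = 100)
    sw <- cluster::silhouette(fit$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
    fits[[i]] <- fit
  }
  best_i <- which.max(sil) # which.max takes the first maximum: ties -> smaller k
  labels <- fits[[best_i]]$cluster
  res <- list(
    silhouette_by_k = tibble(k = usable, mean_silhouette = sil),
    best_k = usable[best_i],
    cluster_labels = labels,
    weak_structure = sil[best_i] < weak_cutoff
  )
  if (!is.null(ages)) {
    res$age_by_cluster <- tibble(cluster = labels, age_days = ages) |>
      group_by(.data$cluster, .data$age_days) |>
      summarise(n = n(), .groups = "drop")
  }
  structure(res, class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat(sprintf(
    "<staging_result> best k = %d (mean silhouette %.3f)%s\n", x$best_k,
    x$silhouette_by_k$mean_silhouette[x$silhouette_by_k$k == x$best_k],
    if (x$weak_structure) " [weak structure]" else ""
  ))
  invisible(x)
}

#' Full developmental staging of a cohort
#'
#' Convenience chain: feature matrix, PCA projection, silhouette-selected
#' k-means.
#'
#' @inheritParams build_feature_matrix
#' @inheritParams pca_project
#' @inheritParams kmeans_silhouette_scan
#' @return A `staging_result` additionally carrying `pca` and
#'   `feature_matrix`.
#' @export
stage_cohort <- function(subjects, variance_target = 0.75, max_pc = 10,
                         k_range = 2:10, n_restarts = 50, seed = NULL,
                         scale = TRUE) {
  fm <- build_feature_matrix(subjects, scale = scale)
  pca <- pca_project(fm, variance_target = variance_target, max_pc = max_pc)
  res <- kmeans_silhouette_scan(pca$scores,
    k_range = k_range,
    n_restarts = n_restarts, seed = seed, ages = fm$ages
  )
  res$pca <- pca
  res$feature_matrix <- fm
  res
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}
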