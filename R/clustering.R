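# Running clustering algorithms against a distance function and mapping
# their solutions onto the ROC plane, where they can be compared with the
# CROC best point of the distance itself.

#' Run a clustering algorithm
#'
#' Hierarchical methods (single, complete, average linkage) consume the
#' precomputed dissimilarity matrix through [stats::hclust()], so
#' non-geometric distances (Pearson, mutual information) are honored.
#' K-means runs a generalized Lloyd iteration on the feature matrix:
#' items are assigned to the nearest centroid under the chosen distance,
#' centroids are updated as coordinate-wise means, with restarts and a
#' fixed iteration cap, all seeded for reproducibility.
#'
#' @param X a [feature_matrix()] (needed by kmeans).
#' @param D a `distance_matrix` over the same items (needed by the
#'   hierarchical methods; also names the distance kmeans assigns with).
#' @param algorithm one of `"kmeans"`, `"single_link"`, `"complete_link"`,
#'   `"average_link"`.
#' @param k requested number of clusters, `2 <= k <= n - 1`.
#' @param seed RNG seed for kmeans restarts (ignored by hierarchical
#'   methods).
#' @param restarts,max_iter kmeans restart count and iteration cap.
#' @return list of class `clustering_run` with `algorithm`,
#'   `distance_name`, `k`, `seed`, `partition`.
#' @export
run_clustering <- function(X, D, algorithm = c("kmeans", "single_link",
                                               "complete_link",
                                               "average_link"),
                           k, seed = 1L, restarts = 10L, max_iter = 300L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(D, "distance_matrix"))
  n <- nrow(D$values)
  if (k < 2L || k > n - 1L)
    stop("k must be between 2 and n - 1 = ", n - 1L, ", got ", k)
  ids <- rownames(D$values)
  if (algorithm == "kmeans") {
    X <- as.matrix(X)
    if (!identical(rownames(X), ids))
      X <- X[ids, , drop = FALSE]
    labs <- .lloyd(X, k, D$distance_name, seed = seed, restarts = restarts,
                   max_iter = max_iter)
    prov <- sprintf("kmeans (k=%d, %s assignment, seed=%d)", k,
                    D$distance_name, seed)
  } else {
    method <- c(single_link = "single", complete_link = "complete",
                average_link = "average")[[algorithm]]
    hc <- stats::hclust(stats::as.dist(D$values), method = method)
    labs <- stats::cutree(hc, k = k)
    prov <- sprintf("%s (k=%d, %s)", algorithm, k, D$distance_name)
  }
  structure(list(algorithm = algorithm, distance_name = D$distance_name,
                 k = k, seed = seed,
                 partition = partition(stats::setNames(labs, ids), prov)),
            class = "clustering_run")
}

# generalized Lloyd iteration: assignment under an arbitrary scalar
# distance, coordinate-wise mean update. A centroid that goes empty or
# constant (undefined under Pearson/MI) is reseeded to a random item.
.lloyd <- function(X, k, distance_name, seed, restarts, max_iter) {
  n <- nrow(X)
  dfun <- switch(distance_name,
                 euclidean = euclidean_distance,
                 pearson = pearson_distance,
                 mutual_information = mutual_information_distance,
                 euclidean_distance)
  .dist_to_centroids <- function(C) {
    out <- matrix(Inf, n, nrow(C))
    for (j in seq_len(nrow(C))) {
      cj <- C[j, ]
      if (!all(is.finite(cj))) next
      if (distance_name != "euclidean" && max(cj) == min(cj)) next
      for (i in seq_len(n)) out[i, j] <- dfun(X[i, ], cj)
    }
    out
  }
  best_labs <- NULL
  best_cost <- Inf
  .with_seed(seed, {
    for (rs in seq_len(restarts)) {
      C <- X[sample.int(n, k), , drop = FALSE]
      labs <- rep(1L, n)
      for (it in seq_len(max_iter)) {
        dd <- .dist_to_centroids(C)
        new_labs <- max.col(-dd, ties.method = "first")
        for (j in seq_len(k)) {
          if (!any(new_labs == j)) {        # empty cluster: reseed
            C[j, ] <- X[sample.int(n, 1L), ]
            new_labs[which.max(dd[cbind(seq_len(n), new_labs)])] <- j
          }
        }
        if (identical(new_labs, labs) && it > 1L) break
        labs <- new_labs
        for (j in seq_len(k)) {
          members <- which(labs == j)
          C[j, ] <- if (length(members))
            colMeans(X[members, , drop = FALSE])
          else X[sample.int(n, 1L), ]    # reseed clusters emptied by a swap
        }
      }
      dd <- .dist_to_centroids(C)
      cost <- sum(dd[cbind(seq_len(n), labs)][is.finite(dd[cbind(seq_len(n), labs)])])
      if (cost < best_cost) {
        best_cost <- cost
        best_labs <- labs
      }
    }
  })
  best_labs
}

#' Map a partition to the ROC plane
#'
#' Composes connectivity matrix, pair confusion, ROC point and BMI against
#' the gold solution: the five-step mapping every clustering solution goes
#' through before it can be compared with a CROC best point.
#'
#' @param p a [partition()] (or named label vector).
#' @param gold a [gold_solution()].
#' @param alpha,beta BMI weights.
#' @return list with `point` (`roc_point`) and `bmi`.
#' @export
map_solution_to_roc <- function(p, gold, alpha = 0.5, beta = 0.5) {
  pc <- pair_confusion(connectivity_matrix(p), connectivity_matrix(gold))
  pt <- roc_point(pc, provenance = attr(p, "provenance") %||% "")
  list(point = pt, bmi = bmi(pt, alpha, beta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Divisive / agglomerative bias of an ROC point
#'
#' An algorithm that over-splits pushes FPR up (gold-co-clustered pairs
#' predicted separated); one that over-merges pushes FNR = 1 - TPR up.
#' The label is read off the dominant rate: `"divisive"` when
#' `fpr - fnr > margin`, `"agglomerative"` when `fnr - fpr > margin`,
#' `"balanced"` otherwise.
#'
#' @param p an ROC point (`c(fpr, tpr)`).
#' @param margin dominance margin on `|fpr - fnr|` (default 0.2).
#' @return one of `"divisive"`, `"agglomerative"`, `"balanced"`.
#' @export
bias_label <- function(p, margin = 0.2) {
  pt <- .as_point(p)
  fpr <- pt[, 1L]; fnr <- 1 - pt[, 2L]
  unname(ifelse(fpr - fnr > margin, "divisive",
                ifelse(fnr - fpr > margin, "agglomerative", "balanced")))
}

#' Correlation between the BMI and an external index along a CROC curve
#'
#' Every CROC solution is scored with both the BMI and one classical
#' external index (adjusted Rand, Fowlkes-Mallows or F-measure); the
#' Pearson correlation between the two series, ordered by cluster count,
#' quantifies how strongly the BMI anti-correlates with the established
#' indices. Solutions where the index is undefined are dropped pairwise.
#'
#' @param curve a [croc_curve()].
#' @param gold the [gold_solution()] the curve was built against.
#' @param index one of `"adjusted_rand"`, `"fowlkes_mallows"`,
#'   `"f_measure"`.
#' @return scalar in `[-1, 1]`.
#' @export
index_correlation <- function(curve, gold,
                              index = c("adjusted_rand", "fowlkes_mallows",
                                        "f_measure")) {
  index <- match.arg(index)
  ifun <- get(index)
  ord <- order(curve$points$k)
  bmi_series <- curve$points$bmi[ord]
  idx_series <- vapply(curve$partitions[ord], function(p) {
    tryCatch(ifun(contingency(gold, p)), error = function(e) NA_real_)
  }, numeric(1L))
  keep <- !is.na(idx_series)
  if (sum(keep) < 2L)
    stop("fewer than 2 CROC solutions with a defined ", index)
  b <- bmi_series[keep]; v <- idx_series[keep]
  if (stats::sd(b) == 0 || stats::sd(v) == 0)
    stop("constant series: correlation with ", index, " undefined")
  stats::cor(b, v)
}

#' Evaluate distance functions against clustering algorithms
#'
#' The full comparison procedure: per distance, build the CROC curve, take
#' its best point (the intrinsic discriminative ability of the distance)
#' and its AUC; per algorithm and cluster count, run the algorithm, map
#' the solution to the ROC plane, score it with BMI and the external
#' indices, test gray-region membership and label its bias; per index,
#' correlate the BMI series with the index series along the CROC.
#' Distances inapplicable to the data (mutual information on few-feature
#' matrices, Pearson on constant rows) are recorded as missing rather than
#' aborting.
#'
#' @param X a [feature_matrix()].
#' @param gold a [gold_solution()] over the same items.
#' @param distances character vector of distance names to assess.
#' @param algorithms character vector of algorithm names to run.
#' @param k_range integer cluster counts; default `2:min(n - 1, 2r + 2)`.
#' @param alpha,beta BMI weights.
#' @param seed RNG seed forwarded to kmeans.
#' @param bias_margin margin for [bias_label()].
#' @return list of class `evaluation_report` with data.frames `distances`
#'   (distance, bmi_star, auc, n_solutions, error), `solutions`
#'   (per algorithm x k x distance scores), `correlations`, `gray_tally`,
#'   plus `curves` (named list of [croc_curve()]s) and the call
#'   parameters.
#' @export
evaluate_distances <- function(X, gold,
                               distances = c("euclidean", "pearson",
                                             "mutual_information"),
                               algorithms = c("kmeans", "single_link",
                                              "complete_link",
                                              "average_link"),
                               k_range = NULL, alpha = 0.5, beta = 0.5,
                               seed = 1L, bias_margin = 0.2) {
  .check_weights(alpha, beta)
  n <- nrow(X)
  r <- attr(gold, "r") %||% length(unique(.labels_of(gold)))
  if (is.null(k_range)) k_range <- 2:min(n - 1L, 2L * r + 2L)
  dist_rows <- list(); sol_rows <- list(); cor_rows <- list()
  curves <- list()
  for (dn in distances) {
    D <- tryCatch(pairwise_distance_matrix(X, dn), error = function(e) e)
    if (inherits(D, "error")) {
      dist_rows[[dn]] <- data.frame(distance = dn, bmi_star = NA_real_,
                                    auc = NA_real_, n_solutions = NA_integer_,
                                    error = conditionMessage(D))
      next
    }
    curve <- croc_curve(D, gold, alpha = alpha, beta = beta)
    curves[[dn]] <- curve
    bp <- best_point(curve)
    dist_rows[[dn]] <- data.frame(distance = dn, bmi_star = bp$bmi_star,
                                  auc = curve$auc,
                                  n_solutions = nrow(curve$points),
                                  error = "")
    for (idx in c("adjusted_rand", "fowlkes_mallows", "f_measure")) {
      cr <- tryCatch(index_correlation(curve, gold, idx),
                     error = function(e) NA_real_)
      cor_rows[[paste(dn, idx)]] <-
        data.frame(distance = dn, index = idx, correlation = cr)
    }
    ks <- sort(unique(c(k_range, curve$points$k[curve$points$k >= 2L &
                                                curve$points$k <= n - 1L])))
    for (alg in algorithms) for (k in ks) {
      run <- run_clustering(X, D, alg, k, seed = seed)
      sc <- map_solution_to_roc(run$partition, gold, alpha, beta)
      ctab <- contingency(gold, run$partition)
      sol_rows[[paste(dn, alg, k)]] <- data.frame(
        distance = dn, algorithm = alg, k = k,
        fpr = unname(sc$point[1L]), tpr = unname(sc$point[2L]),
        bmi = sc$bmi,
        adjusted_rand = tryCatch(adjusted_rand(ctab),
                                 error = function(e) NA_real_),
        fowlkes_mallows = tryCatch(fowlkes_mallows(ctab),
                                   error = function(e) NA_real_),
        f_measure = tryCatch(f_measure(ctab), error = function(e) NA_real_),
        in_gray = gray_region_contains(sc$point, bp$bmi_star, alpha, beta),
        bias = bias_label(sc$point, bias_margin))
    }
  }
  solutions <- do.call(rbind, c(sol_rows, list(make.row.names = FALSE)))
  gray_tally <- if (!is.null(solutions) && nrow(solutions)) {
    agg <- stats::aggregate(in_gray ~ algorithm, solutions, sum)
    tot <- stats::aggregate(in_gray ~ algorithm, solutions, length)
    data.frame(algorithm = agg$algorithm, in_gray = agg$in_gray,
               total = tot$in_gray)
  } else {
    data.frame(algorithm = character(0), in_gray = integer(0),
               total = integer(0))
  }
  structure(list(
    distances = do.call(rbind, c(dist_rows, list(make.row.names = FALSE))),
    solutions = solutions,
    correlations = do.call(rbind, c(cor_rows, list(make.row.names = FALSE))),
    gray_tally = gray_tally,
    curves = curves,
    params = list(alpha = alpha, beta = beta, k_range = k_range,
                  seed = seed, bias_margin = bias_margin)),
    class = "evaluation_report")
}

#' Write an evaluation report to disk
#'
#' Emits the per-distance table (best-point BMI and AUC per distance), the
#' BMI-vs-index correlation table, the per-solution table and a JSON
#' summary into a directory.
#'
#' @param report an [evaluate_distances()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    distances = file.path(dir, "distances.tsv"),
    correlations = file.path(dir, "correlations.tsv"),
    solutions = file.path(dir, "solutions.tsv"),
    gray_tally = file.path(dir, "gray_tally.tsv"),
    summary = file.path(dir, "summary.json"))
  write_report_table(report$distances, paths[["distances"]])
  write_report_table(report$correlations, paths[["correlations"]])
  write_report_table(report$solutions, paths[["solutions"]])
  write_report_table(report$gray_tally, paths[["gray_tally"]])
  summary <- list(
    distances = report$distances,
    correlations = report$correlations,
    gray_tally = report$gray_tally,
    params = report$params)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Distance evaluation report\n\nPer-distance CROC summary:\n")
  print(x$distances, row.names = FALSE)
  cat("\nBMI-vs-index correlations along the CROC:\n")
  print(x$correlations, row.names = FALSE)
  cat("\nGray-region membership per algorithm:\n")
  print(x$gray_tally, row.names = FALSE)
  invisible(x)
}

#' @export
print.clustering_run <- function(x, ...) {
  cat(sprintf("Clustering run: %s, k=%d, distance=%s\n", x$algorithm, x$k,
              x$distance_name))
  invisible(x)
}
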