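#' Construct a partition
#'
#' A partition assigns every item to exactly one cluster. Both gold
#' solutions and clustering outputs are partitions; `provenance` records
#' where it came from (algorithm and parameters, or a CROC threshold).
#'
#' @param labels vector of cluster labels named by item id.
#' @param provenance free-text origin of the partition.
#' @return named character vector of class `partition` with attributes
#'   `t` (number of clusters) and `provenance`.
#' @export
partition <- function(labels, provenance = "") {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("partition labels must be named by item id")
  if (anyDuplicated(names(labels))) stop("duplicate item ids in partition")
  if (any(is.na(labels))) stop("missing cluster labels")
  structure(labels, class = "partition", t = length(unique(labels)),
            provenance = provenance)
}

.labels_of <- function(p) {
  stats::setNames(as.character(p), names(p))
}

#' Connectivity matrix of a partition
#'
#' Binary item-by-item matrix with 1 where two items share a cluster.
#' Because a partition has pairwise-disjoint clusters, the matrix is
#' symmetric with unit diagonal and transitive.
#'
#' @param p a [partition()], [gold_solution()], or named label vector.
#' @return 0/1 matrix of class `connectivity_matrix`.
#' @export
#' @examples
#' connectivity_matrix(partition(c(a = 1, b = 1, c = 2)))
connectivity_matrix <- function(p) {
  lab <- .labels_of(p)
  J <- outer(lab, lab, `==`) * 1L
  dimnames(J) <- list(names(lab), names(lab))
  structure(J, class = c("connectivity_matrix", class(J)))
}

#' Pair-level confusion counts between two connectivity matrices
#'
#' All n(n-1)/2 unordered item pairs are classified twice: separated or
#' co-clustered in the gold solution, and in the prediction. The positive
#' class is "pair in different clusters", so:
#' \describe{
#'   \item{T0}{separated in gold and in prediction (true positive)}
#'   \item{F1}{separated in gold, co-clustered in prediction (false negative)}
#'   \item{T1}{co-clustered in both (true negative)}
#'   \item{F0}{co-clustered in gold, separated in prediction (false positive)}
#' }
#'
#' @param pred,gold `connectivity_matrix` objects (or partitions, which are
#'   converted) over the same item set.
#' @return list of class `pair_confusion` with counts `T0`, `F1`, `T1`,
#'   `F0` and the pair total `n_pairs`.
#' @export
pair_confusion <- function(pred, gold) {
  if (!inherits(pred, "connectivity_matrix")) pred <- connectivity_matrix(pred)
  if (!inherits(gold, "connectivity_matrix")) gold <- connectivity_matrix(gold)
  if (!identical(dim(pred), dim(gold)))
    stop("connectivity matrices differ in size")
  if (!is.null(rownames(pred)) && !is.null(rownames(gold))) {
    if (!setequal(rownames(pred), rownames(gold)))
      stop("connectivity matrices cover different item sets")
    gold <- gold[rownames(pred), rownames(pred)]
  }
  ut <- upper.tri(pred)
  gp <- gold[ut] == 1; pp <- pred[ut] == 1
  structure(list(
    T0 = sum(!gp & !pp), F1 = sum(!gp & pp),
    T1 = sum(gp & pp), F0 = sum(gp & !pp),
    n_pairs = sum(ut)), class = "pair_confusion")
}

#' Map pair confusion counts to the ROC plane
#'
#' With "separated pair" as the positive class, TPR = T0/(T0+F1) is the
#' fraction of gold-separated pairs predicted separated and
#' FPR = F0/(T1+F0) the fraction of gold-co-clustered pairs predicted
#' separated. A perfect prediction maps to (0, 1).
#'
#' @param c a `pair_confusion`.
#' @param provenance free-text origin carried on the point.
#' @return named numeric `c(fpr, tpr)` of class `roc_point`.
#' @export
roc_point <- function(c, provenance = "") {
  stopifnot(inherits(c, "pair_confusion"))
  if (c$T0 + c$F1 == 0)
    stop("degenerate gold solution: no separated pair (a single class)")
  if (c$T1 + c$F0 == 0)
    stop("degenerate gold solution: no co-clustered pair (all singletons)")
  structure(c(fpr = c$F0 / (c$T1 + c$F0), tpr = c$T0 / (c$T0 + c$F1)),
            class = "roc_point", provenance = provenance)
}

.as_point <- function(p) {
  p <- unclass(p)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    return(p)
  }
  stopifnot(length(p) == 2L)
  matrix(p, ncol = 2L, dimnames = list(NULL, c("fpr", "tpr")))
}

#' Misclassification error of an ROC point
#'
#' `E_m = FPR + FNR`, the L1 distance from the point to the perfect
#' corner (0, 1); range `[0, 2]`.
#'
#' @param p an `roc_point`, a numeric `c(fpr, tpr)`, or a 2-column matrix
#'   of points.
#' @return numeric vector of errors.
#' @export
misclassification_error <- function(p) {
  pt <- .as_point(p)
  unname(pt[, 1L] + (1 - pt[, 2L]))
}

#' Balancing error of an ROC point
#'
#' `E_b = |FPR - FNR|`: how unevenly the misclassification splits between
#' over-splitting (FPR) and over-merging (FNR); range `[0, 1]`.
#'
#' @inheritParams misclassification_error
#' @return numeric vector of errors.
#' @export
balancing_error <- function(p) {
  pt <- .as_point(p)
  unname(abs(pt[, 1L] - (1 - pt[, 2L])))
}

#' Balanced Misclassification Index (BMI)
#'
#' `BMI = sqrt(alpha * E_m^2 + beta * E_b^2)` with `E_m` the
#' misclassification error and `E_b` the balancing error of an ROC point.
#' At the default weights `alpha = beta = 0.5` this is exactly the
#' Euclidean distance from the point to the perfect corner (0, 1), since
#' `0.5 (a + b)^2 + 0.5 (a - b)^2 = a^2 + b^2`. Lower is better; 0 means
#' the partition equals the gold solution.
#'
#' @inheritParams misclassification_error
#' @param alpha,beta non-negative weights of the misclassification and
#'   balancing errors; must sum to 1.
#' @return numeric vector of index values.
#' @export
#' @examples
#' bmi(c(0.5, 0.5)) # 0.7071...
bmi <- function(p, alpha = 0.5, beta = 0.5) {
  .check_weights(alpha, beta)
  sqrt(alpha * misclassification_error(p)^2 + beta * balancing_error(p)^2)
}

.check_weights <- function(alpha, beta) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop("alpha and beta must be non-negative and sum to 1")
}

#' Contingency table of a gold solution against a partition
#'
#' Cross-tabulates the r gold classes against the t predicted clusters;
#' entry (i, j) counts items in both class i and cluster j.
#'
#' @param gold a [gold_solution()] (or named label vector).
#' @param p a [partition()] (or named label vector) over the same items.
#' @return list of class `contingency_table` with `counts` (r x t),
#'   `row_margins`, `col_margins`, `N`.
#' @export
contingency <- function(gold, p) {
  g <- .labels_of(gold); q <- .labels_of(p)
  if (!setequal(names(g), names(q)))
    stop("gold solution and partition cover different item sets")
  q <- q[names(g)]
  counts <- unclass(table(g, q))
  dimnames(counts) <- stats::setNames(dimnames(counts), NULL)
  structure(list(counts = counts,
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts),
                 N = length(g)),
            class = "contingency_table")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance;
#' 1 for identical partitions, around 0 for independent ones, possibly
#' negative.
#'
#' @param ct a [contingency()] table.
#' @return scalar <= 1.
#' @export
adjusted_rand <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  if (ct$N < 2L) stop("adjusted Rand needs at least 2 items")
  np <- choose(ct$N, 2L)
  a <- sum(choose(ct$counts, 2L))
  b <- sum(choose(ct$row_margins, 2L))
  c <- sum(choose(ct$col_margins, 2L))
  expected <- b * c / np
  maximum <- (b + c) / 2
  den <- maximum - expected
  if (den == 0)
    stop("adjusted Rand undefined: both partitions trivial")
  (a - expected) / den
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pair-level precision and recall:
#' `sum(T_ij^2 - N) / sqrt((sum(T_i.^2) - N) (sum(T_.j^2) - N))`;
#' 1 for identical partitions.
#'
#' @param ct a [contingency()] table.
#' @return scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  b <- sum(ct$row_margins^2) - ct$N
  c <- sum(ct$col_margins^2) - ct$N
  if (b == 0 || c == 0)
    stop("Fowlkes-Mallows undefined: a partition has no co-clustered pair")
  (sum(ct$counts^2) - ct$N) / sqrt(b * c)
}

#' Clustering F-measure
#'
#' For each gold class, the best harmonic mean of precision
#' (`T_ij / T_.j`) and recall (`T_ij / T_i.`) over predicted clusters,
#' weighted by class size: `sum_i (T_i./N) max_j F(i, j)`.
#'
#' @param ct a [contingency()] table.
#' @return scalar in `[0, 1]`.
#' @export
f_measure <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  Tm <- ct$counts
  prec <- sweep(Tm, 2L, ct$col_margins, `/`)
  rec <- sweep(Tm, 1L, ct$row_margins, `/`)
  Fij <- 2 * prec * rec / (prec + rec)
  Fij[Tm == 0] <- 0
  sum(ct$row_margins / ct$N * apply(Fij, 1L, max))
}

#' @export
print.pair_confusion <- function(x, ...) {
  cat(sprintf("Pair confusion over %d pairs: T0=%d F1=%d T1=%d F0=%d\n",
              x$n_pairs, x$T0, x$F1, x$T1, x$F0))
  invisible(x)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d items, %d clusters", length(x), attr(x, "t")))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat(" (", prov, ")", sep = "")
  cat("\n")
  invisible(x)
}
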