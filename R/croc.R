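# Threshold-graph closure and the CROC curve.
#
# A threshold phi turns a normalized distance matrix into a graph (edge iff
# distance <= phi). That graph's indicator matrix is generally not
# transitive, so it is not a partition; taking connected components closes
# it into one. Sweeping phi over the distinct distances and closing each
# graph yields the CROC curve of the distance function.

#' Threshold indicator matrix
#'
#' Binary matrix with entry 1 iff the (normalized) distance is at most
#' `phi`. Not transitive in general: three collinear items with
#' d(1,2) = d(2,3) = phi but d(1,3) > phi switch on the two short edges
#' only.
#'
#' @param D a normalized `distance_matrix` (see
#'   [normalize_distance_matrix()]).
#' @param phi threshold in `[0, 1]`.
#' @return 0/1 matrix of class `threshold_indicator` with attribute `phi`.
#' @export
threshold_indicator <- function(D, phi) {
  stopifnot(inherits(D, "distance_matrix"))
  if (!D$normalized) stop("distance matrix must be normalized first")
  if (length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1)
    stop("phi must be a single value in [0, 1]")
  I <- (D$values <= phi) * 1L
  diag(I) <- 1L
  dimnames(I) <- dimnames(D$values)
  structure(I, class = c("threshold_indicator", class(I)), phi = phi)
}

#' Close a threshold indicator into a partition
#'
#' Clusters are the connected components of the graph whose edges are the
#' 1-entries: any two overlapping item sets are merged until a proper
#' partition remains. The resulting connectivity matrix is transitive and
#' entrywise >= the indicator.
#'
#' @param I a [threshold_indicator()] (any symmetric 0/1 matrix with unit
#'   diagonal works).
#' @return a [partition()] labelled by component.
#' @export
component_closure <- function(I) {
  n <- nrow(I)
  ids <- rownames(I)
  if (is.null(ids)) ids <- paste0("item", seq_len(n))
  parent <- seq_len(n)
  sel <- upper.tri(I) & I == 1
  ii <- row(I)[sel]; jj <- col(I)[sel]
  for (k in seq_along(ii)) {
    ra <- .uf_find(parent, ii[k]); parent <- attr(ra, "parent")
    rb <- .uf_find(parent, jj[k]); parent <- attr(rb, "parent")
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), function(i) {
    r <- .uf_find(parent, i)
    parent <<- attr(r, "parent")
    as.integer(r)
  }, integer(1L))
  labs <- match(roots, unique(roots))
  phi <- attr(I, "phi")
  partition(stats::setNames(labs, ids),
            provenance = if (is.null(phi)) "component closure"
                         else sprintf("component closure (phi=%.6g)", phi))
}

# union-find with path halving; returns root with updated parent attached
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  structure(i, parent = parent)
}

#' CROC curve of a distance matrix
#'
#' Normalizes the matrix, sweeps the threshold over the sorted distinct
#' off-diagonal distances, closes each threshold graph into a partition by
#' connected components, deduplicates consecutive identical partitions and
#' maps each surviving solution to the ROC plane against the gold solution.
#' Distances closer than `tie_tol` are treated as tied and merged at one
#' threshold, so float noise cannot split a genuine tie. The sweep is
#' implemented as a single pass over the edges sorted by distance with a
#' union-find structure, which is equivalent to extracting components
#' per threshold.
#'
#' The all-singletons configuration never appears (it would need a
#' negative threshold); the all-in-one partition always appears at
#' phi = 1 and maps to (0, 0). The area under the curve uses the solution
#' points plus the geometric anchors (0, 0) and (1, 1).
#'
#' @param D a `distance_matrix` (normalized or not).
#' @param gold a [gold_solution()] with >= 2 classes and at least one
#'   class of size >= 2.
#' @param alpha,beta BMI weights (see [bmi()]).
#' @param tie_tol absolute tolerance under which two normalized distances
#'   count as equal (default 1e-9).
#' @return object of class `croc_curve`: list with `points` (data.frame
#'   `phi`, `k`, `fpr`, `tpr`, `bmi`), `partitions` (list of [partition()]s
#'   parallel to `points`), `auc`, `distance_name`, `alpha`, `beta`.
#' @export
croc_curve <- function(D, gold, alpha = 0.5, beta = 0.5, tie_tol = 1e-9) {
  stopifnot(inherits(D, "distance_matrix"))
  .check_weights(alpha, beta)
  Dn <- normalize_distance_matrix(D)
  V <- Dn$values
  n <- nrow(V)
  ids <- rownames(V)
  g <- .labels_of(gold)
  if (!setequal(names(g), ids))
    stop("gold solution and distance matrix cover different item sets")
  g <- g[ids]
  classes <- unique(g)
  r <- length(classes)
  sizes <- as.numeric(table(g))
  P1 <- sum(choose(sizes, 2L))           # gold co-clustered pairs
  P0 <- choose(n, 2L) - P1               # gold separated pairs
  if (r < 2L) stop("degenerate gold solution: a single class")
  if (P1 == 0) stop("degenerate gold solution: all classes are singletons")

  ut <- upper.tri(V)
  d <- V[ut]; ii <- row(V)[ut]; jj <- col(V)[ut]
  ord <- order(d)
  d <- d[ord]; ii <- ii[ord]; jj <- jj[ord]
  # group tied (within tie_tol) consecutive distances into one threshold
  grp_end <- c(which(diff(d) > tie_tol), length(d))

  parent <- seq_len(n)
  csize <- rep(1, n)
  G <- matrix(0, n, r)                   # gold-class composition per root
  G[cbind(seq_len(n), match(g, classes))] <- 1
  T1 <- 0; F1 <- 0
  k <- n
  phis <- numeric(0); ks <- integer(0)
  fprs <- numeric(0); tprs <- numeric(0)
  parts <- list()
  e <- 1L
  for (b in grp_end) {
    changed <- FALSE
    while (e <= b) {
      ra <- .uf_find(parent, ii[e]); parent <- attr(ra, "parent")
      rb <- .uf_find(parent, jj[e]); parent <- attr(rb, "parent")
      if (ra != rb) {
        same <- sum(G[ra, ] * G[rb, ])
        T1 <- T1 + same
        F1 <- F1 + csize[ra] * csize[rb] - same
        parent[rb] <- ra
        G[ra, ] <- G[ra, ] + G[rb, ]
        csize[ra] <- csize[ra] + csize[rb]
        k <- k - 1L
        changed <- TRUE
      }
      e <- e + 1L
    }
    if (changed) {
      roots <- vapply(seq_len(n), function(i) {
        rt <- .uf_find(parent, i)
        parent <<- attr(rt, "parent")
        as.integer(rt)
      }, integer(1L))
      phis <- c(phis, d[b]); ks <- c(ks, k)
      fprs <- c(fprs, 1 - T1 / P1)
      tprs <- c(tprs, (P0 - F1) / P0)
      parts[[length(parts) + 1L]] <-
        partition(stats::setNames(match(roots, unique(roots)), ids),
                  provenance = sprintf("CROC threshold phi=%.6g", d[b]))
    }
  }
  points <- data.frame(phi = phis, k = ks, fpr = fprs, tpr = tprs,
                       bmi = bmi(cbind(fprs, tprs), alpha, beta))
  curve <- structure(list(points = points, partitions = parts,
                          auc = NA_real_,
                          distance_name = Dn$distance_name,
                          alpha = alpha, beta = beta, n = n),
                     class = "croc_curve")
  curve$auc <- croc_auc(curve)
  curve
}

#' Area under a CROC curve
#'
#' Trapezoidal area over the solution points plus the geometric anchors
#' (0, 0) and (1, 1), sorted by FPR then TPR. 0.5 corresponds to a random
#' assignment rule; values near 1 indicate that between-class distances
#' dominate within-class distances.
#'
#' @param curve a [croc_curve()].
#' @return scalar in `[0, 1]`.
#' @export
croc_auc <- function(curve) {
  stopifnot(inherits(curve, "croc_curve"))
  if (nrow(curve$points) == 0L) return(0.5)
  x <- c(curve$points$fpr, 0, 1)
  y <- c(curve$points$tpr, 0, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Best point of a CROC curve
#'
#' The solution with the lowest BMI, i.e. the point closest to the perfect
#' corner (0, 1) at `alpha = beta = 0.5`. Its BMI quantifies the intrinsic
#' discriminative ability of the distance function: the distance alone,
#' with the best possible threshold, cannot do better. Ties are broken
#' toward the smaller FPR, then toward fewer clusters.
#'
#' @param curve a [croc_curve()].
#' @param alpha,beta BMI weights; default to the curve's.
#' @return list with `point` (`roc_point`), `partition`, `bmi_star`,
#'   `phi`, `k`.
#' @export
best_point <- function(curve, alpha = NULL, beta = NULL) {
  stopifnot(inherits(curve, "croc_curve"))
  if (is.null(alpha)) alpha <- curve$alpha
  if (is.null(beta)) beta <- curve$beta
  pts <- curve$points
  if (nrow(pts) == 0L) stop("empty CROC curve")
  b <- bmi(cbind(pts$fpr, pts$tpr), alpha, beta)
  best <- order(b, pts$fpr, pts$k)[1L]
  list(point = structure(c(fpr = pts$fpr[best], tpr = pts$tpr[best]),
                         class = "roc_point",
                         provenance = sprintf("CROC best point phi=%.6g",
                                              pts$phi[best])),
       partition = curve$partitions[[best]],
       bmi_star = b[best], phi = pts$phi[best], k = pts$k[best])
}

#' Gray-region membership
#'
#' The gray region of a distance function is the set of ROC-plane points
#' whose BMI is strictly smaller than the distance's best-point BMI: a
#' clustering algorithm landing inside it improves on the intrinsic
#' separation ability of the distance. Points exactly on the iso-BMI
#' boundary are not inside.
#'
#' @param p an ROC point (`c(fpr, tpr)` or `roc_point`).
#' @param bmi_star best-point BMI of the distance (>= 0).
#' @param alpha,beta BMI weights.
#' @return logical.
#' @export
gray_region_contains <- function(p, bmi_star, alpha = 0.5, beta = 0.5) {
  if (bmi_star < 0) stop("bmi_star must be non-negative")
  bmi(p, alpha, beta) < bmi_star
}

#' @export
print.croc_curve <- function(x, ...) {
  cat(sprintf("CROC curve (%s): %d solutions, AUC = %.4f\n",
              x$distance_name, nrow(x$points), x$auc))
  bp <- best_point(x)
  cat(sprintf("best point: (FPR=%.4f, TPR=%.4f), k=%d, BMI=%.4f\n",
              bp$point[1L], bp$point[2L], bp$k, bp$bmi_star))
  invisible(x)
}
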