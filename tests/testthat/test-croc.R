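make_D <- function(vals, ids = NULL) {
  n <- nrow(vals)
  if (is.null(ids)) ids <- paste0("it", seq_len(n))
  dimnames(vals) <- list(ids, ids)
  new_distance_matrix(vals, "custom", normalized = max(vals) <= 1)
}

tri_D <- function(d12, d13, d23) {
  make_D(rbind(c(0, d12, d13), c(d12, 0, d23), c(d13, d23, 0)))
}

test_that("threshold indicator switches edges on monotonically in phi", {
  D <- tri_D(0.2, 1.0, 0.5)
  I1 <- threshold_indicator(D, 1)
  expect_true(all(I1 == 1))
  I03 <- threshold_indicator(D, 0.3)
  expect_equal(unclass(I03), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  for (phi in seq(0, 1, by = 0.1))
    expect_true(all(threshold_indicator(D, phi) <=
                      threshold_indicator(D, min(1, phi + 0.1))))
  expect_error(threshold_indicator(D, 1.2), "phi")
  raw <- new_distance_matrix(2 * unclass(D$values))
  expect_error(threshold_indicator(raw, 0.5), "normalized")
})

test_that("a collinear triple yields a non-transitive indicator that closure repairs", {
  # items on a line: d(1,2) = d(2,3) = phi but d(1,3) = 2 phi
  D <- tri_D(0.5, 1.0, 0.5)
  I <- threshold_indicator(D, 0.5)
  expect_false(is_transitive_oracle(I))
  p <- component_closure(I)
  expect_equal(attr(p, "t"), 1L)
  J <- connectivity_matrix(p)
  expect_true(is_transitive_oracle(J))
  expect_true(all(J >= I))
})

test_that("component closure equals the reachability oracle on small graphs", {
  # chain merge
  I <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  dimnames(I) <- list(paste0("it", 1:3), paste0("it", 1:3))
  expect_equal(attr(component_closure(I), "t"), 1L)
  # identity indicator keeps all singletons
  I0 <- diag(4); dimnames(I0) <- list(paste0("it", 1:4), paste0("it", 1:4))
  expect_equal(attr(component_closure(I0), "t"), 4L)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    A <- matrix(0L, n, n)
    on <- which(upper.tri(A))
    on <- on[runif(length(on)) < 0.3]
    A[on] <- 1L
    A <- A + t(A); diag(A) <- 1L
    dimnames(A) <- list(paste0("it", 1:n), paste0("it", 1:n))
    got <- as.integer(component_closure(A))
    want <- closure_oracle(A)
    expect_identical(match(got, unique(got)), match(want, unique(want)))
  }
})

test_that("the worked 3-item sweep produces the expected curve and AUC 1", {
  D <- tri_D(0.2, 1.0, 0.5)
  gold <- named_gold(c("a", "a", "b"), paste0("it", 1:3))
  cv <- croc_curve(D, gold)
  expect_equal(nrow(cv$points), 2L)
  expect_equal(cv$points$k, c(2L, 1L))
  expect_equal(cv$points$fpr, c(0, 0))
  expect_equal(cv$points$tpr, c(1, 0))
  expect_equal(cv$auc, 1)
  bp <- best_point(cv)
  expect_equal(bp$bmi_star, 0)
  expect_equal(as.numeric(unclass(bp$point)), c(0, 1))
  expect_equal(bp$k, 2L)
})

test_that("perfectly separated data places (0, 1) on the curve", {
  cl <- make_clouds(seed = 2, sep = 30)
  cv <- croc_curve(pairwise_distance_matrix(cl$X, "euclidean"), cl$gold)
  expect_true(any(cv$points$fpr == 0 & cv$points$tpr == 1))
  expect_equal(best_point(cv)$bmi_star, 0)
  expect_equal(cv$auc, 1)
})

test_that("CROC partitions are nested with non-increasing rates and pass transitivity", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    X <- suppressMessages(feature_matrix(matrix(rnorm(n * 4), n, 4)))
    gold <- named_gold(sample.int(3, n, TRUE), rownames(X))
    if (length(unique(gold)) < 2 || max(table(unclass(gold))) < 2) next
    cv <- croc_curve(pairwise_distance_matrix(X, "euclidean"), gold)
    pts <- cv$points
    expect_true(all(diff(pts$k) < 0))
    expect_true(all(diff(pts$fpr) <= 1e-12))
    expect_true(all(diff(pts$tpr) <= 1e-12))
    # each earlier cluster is contained in exactly one later cluster
    for (s in seq_len(nrow(pts) - 1L)) {
      early <- cv$partitions[[s]]; late <- cv$partitions[[s + 1L]]
      for (cl in unique(early)) {
        members <- names(early)[early == cl]
        expect_length(unique(late[members]), 1L)
      }
    }
    for (p in cv$partitions)
      expect_true(is_transitive_oracle(connectivity_matrix(p)))
    # the final solution is always all-in-one at (0, 0)
    expect_equal(pts$k[nrow(pts)], 1L)
    expect_equal(pts$fpr[nrow(pts)], 0)
    expect_equal(pts$tpr[nrow(pts)], 0)
  }
})

test_that("the CROC is invariant under strictly monotone distance rescaling", {
  set.seed(17)
  X <- suppressMessages(feature_matrix(matrix(rnorm(12 * 5), 12, 5)))
  gold <- named_gold(rep(1:3, each = 4), rownames(X))
  D <- pairwise_distance_matrix(X, "euclidean")
  cv1 <- croc_curve(D, gold)
  D2 <- new_distance_matrix(sqrt(D$values), "rescaled")
  cv2 <- croc_curve(D2, gold)
  expect_equal(cv1$points$k, cv2$points$k)
  expect_equal(cv1$points$fpr, cv2$points$fpr)
  expect_equal(cv1$points$tpr, cv2$points$tpr)
  expect_equal(cv1$auc, cv2$auc)
  D3 <- new_distance_matrix(D$values^3, "rescaled")
  cv3 <- croc_curve(D3, gold)
  expect_equal(cv1$points$fpr, cv3$points$fpr)
  expect_equal(cv1$points$tpr, cv3$points$tpr)
})

test_that("zero-distance pairs are co-clustered in every solution", {
  vals <- rbind(c(0, 0, 0.4, 0.9), c(0, 0, 0.4, 0.9),
                c(0.4, 0.4, 0, 0.6), c(0.9, 0.9, 0.6, 0))
  D <- make_D(vals)
  gold <- named_gold(c(1, 1, 2, 2), paste0("it", 1:4))
  cv <- croc_curve(D, gold)
  for (p in cv$partitions)
    expect_equal(unname(p["it1"]), unname(p["it2"]))
})

test_that("AUC falls to about one half on structureless data", {
  set.seed(8)
  aucs <- replicate(20, {
    X <- suppressMessages(feature_matrix(matrix(rnorm(30 * 8), 30, 8)))
    gold <- named_gold(sample(rep(1:2, 15)), rownames(X))
    croc_curve(pairwise_distance_matrix(X, "euclidean"), gold)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("AUC and best-point BMI rank in opposite directions across separations", {
  seps <- c(0.5, 1.5, 3, 6)
  res <- t(sapply(seps, function(s) {
    cl <- make_clouds(seed = 5, sep = s, sd = 1)
    cv <- croc_curve(pairwise_distance_matrix(cl$X, "euclidean"), cl$gold)
    c(auc = cv$auc, bmi = best_point(cv)$bmi_star)
  }))
  expect_lt(cor(rank(res[, "auc"]), rank(res[, "bmi"])), 0)
  expect_true(all(diff(res[, "auc"]) >= 0))
})

test_that("best-point ties break toward smaller FPR then fewer clusters", {
  curve <- structure(list(
    points = data.frame(phi = c(0.2, 0.5), k = c(3L, 2L),
                        fpr = c(0.4, 0.2), tpr = c(0.9, 0.7),
                        bmi = bmi(cbind(c(0.4, 0.2), c(0.9, 0.7)))),
    partitions = list(named_partition(c(1, 2, 3)),
                      named_partition(c(1, 1, 2))),
    auc = NA_real_, distance_name = "custom", alpha = 0.5, beta = 0.5,
    n = 3), class = "croc_curve")
  # (0.4, 0.9) and (0.2, 0.7) have equal distance to (0, 1): sqrt(0.17)
  bp <- best_point(curve)
  expect_equal(unname(bp$point[1L]), 0.2)
  expect_equal(bp$k, 2L)
})

test_that("gray-region membership is the strict disc-distance comparison", {
  expect_true(gray_region_contains(c(0, 1), 0.3))
  p <- c(0.1, 0.8)
  expect_false(gray_region_contains(p, bmi(p)))
  set.seed(14)
  for (i in 1:50) {
    q <- c(runif(1), runif(1))
    star <- runif(1)
    expect_equal(gray_region_contains(q, star),
                 sqrt(q[1]^2 + (1 - q[2])^2) < star)
  }
})
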