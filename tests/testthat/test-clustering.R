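test_that("single linkage at matching k reproduces CROC partitions", {
  set.seed(19)
  X <- suppressMessages(feature_matrix(matrix(rnorm(14 * 5), 14, 5)))
  gold <- named_gold(rep(1:2, each = 7), rownames(X))
  D <- pairwise_distance_matrix(X, "euclidean")
  cv <- croc_curve(D, gold)
  for (s in which(cv$points$k >= 2 & cv$points$k <= 13)) {
    k <- cv$points$k[s]
    run <- run_clustering(X, D, "single_link", k)
    ct <- contingency(gold_solution(unclass(cv$partitions[[s]])),
                      run$partition)
    expect_equal(adjusted_rand(ct), 1)
  }
})

test_that("complete linkage at k = n - 1 merges exactly the closest pair", {
  set.seed(23)
  X <- suppressMessages(feature_matrix(matrix(rnorm(10 * 4), 10, 4)))
  D <- pairwise_distance_matrix(X, "euclidean")
  run <- run_clustering(X, D, "complete_link", k = 9)
  sizes <- table(run$partition)
  expect_equal(sort(unname(c(sizes))), c(rep(1L, 8), 2L))
  merged <- names(run$partition)[run$partition ==
                                   names(sizes)[sizes == 2][1]]
  off <- D$values; diag(off) <- Inf
  closest <- which(off == min(off), arr.ind = TRUE)[1, ]
  expect_setequal(merged, rownames(D$values)[closest])
})

test_that("kmeans recovers well-separated clouds for any seed", {
  cl <- make_clouds(seed = 3, sep = 10, sd = 1)
  D <- pairwise_distance_matrix(cl$X, "euclidean")
  for (s in 1:10) {
    run <- run_clustering(cl$X, D, "kmeans", k = 3, seed = s)
    expect_equal(adjusted_rand(contingency(cl$gold, run$partition)), 1)
  }
  # deterministic given the seed, and the caller RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  r1 <- run_clustering(cl$X, D, "kmeans", k = 3, seed = 5)
  r2 <- run_clustering(cl$X, D, "kmeans", k = 3, seed = 5)
  expect_identical(unclass(r1$partition), unclass(r2$partition))
  set.seed(99)
  expect_equal(rnorm(1), before)
})

test_that("kmeans honors non-Euclidean assignment distances", {
  g3 <- gen_gaussian3(seed = 13, n_per_class = 6L, n_features = 60L,
                      markers_per_class = 20L)
  D <- pairwise_distance_matrix(g3$matrix, "pearson")
  run <- run_clustering(g3$matrix, D, "kmeans", k = 3, seed = 2)
  expect_equal(adjusted_rand(contingency(g3$gold, run$partition)), 1)
})

test_that("run_clustering validates k", {
  cl <- make_clouds()
  D <- pairwise_distance_matrix(cl$X, "euclidean")
  expect_error(run_clustering(cl$X, D, "kmeans", k = 1), "between 2")
  expect_error(run_clustering(cl$X, D, "average_link", k = nrow(cl$X)),
               "between 2")
})

test_that("partitions map to the expected ROC points and BMI", {
  gold <- named_gold(c("A", "A", "B", "B"))
  eq <- map_solution_to_roc(partition(unclass(gold)), gold)
  expect_equal(as.numeric(unclass(eq$point)), c(0, 1))
  expect_equal(eq$bmi, 0)
  allin <- map_solution_to_roc(named_partition(rep(1, 4)), gold)
  expect_equal(as.numeric(unclass(allin$point)), c(0, 0))
  expect_equal(allin$bmi, 1)
  mixed <- map_solution_to_roc(named_partition(c(1, 2, 2, 2)), gold)
  expect_equal(as.numeric(unclass(mixed$point)), c(0.5, 0.5))
  expect_equal(mixed$bmi, sqrt(0.5), tolerance = 1e-12)
})

test_that("bias labels read off the dominant error rate", {
  expect_equal(bias_label(c(0.6, 0.9)), "divisive")
  expect_equal(bias_label(c(0.05, 0.4)), "agglomerative")
  expect_equal(bias_label(c(0.2, 0.8)), "balanced")
  expect_equal(bias_label(c(0.3, 0.8), margin = 0.05), "divisive")
})

test_that("index correlations match a direct covariance oracle", {
  cl <- make_clouds(seed = 9, sep = 3, sd = 1.5)
  cv <- croc_curve(pairwise_distance_matrix(cl$X, "euclidean"), cl$gold)
  skip_if(nrow(cv$points) < 3L)
  for (idx in c("adjusted_rand", "fowlkes_mallows", "f_measure")) {
    got <- index_correlation(cv, cl$gold, idx)
    ifun <- get(idx)
    ord <- order(cv$points$k)
    b <- cv$points$bmi[ord]
    v <- vapply(cv$partitions[ord], function(p)
      tryCatch(ifun(contingency(cl$gold, p)), error = function(e) NA_real_),
      numeric(1))
    keep <- !is.na(v)
    b <- b[keep]; v <- v[keep]
    oracle <- sum((b - mean(b)) * (v - mean(v))) /
      sqrt(sum((b - mean(b))^2) * sum((v - mean(v))^2))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_gte(got, -1); expect_lte(got, 1)
  }
  # BMI against itself is perfectly correlated
  ord <- order(cv$points$k)
  b <- cv$points$bmi[ord]
  expect_equal(cor(b, b), 1)
})

test_that("evaluate_distances assembles a complete report with missing MI cells", {
  g5 <- gen_gaussian5(seed = 4, n_per_class = 10L)
  rep5 <- evaluate_distances(g5$matrix, g5$gold,
                             distances = c("euclidean", "mutual_information"),
                             algorithms = c("single_link", "complete_link"),
                             k_range = 2:6, seed = 1)
  expect_true(is.na(rep5$distances$bmi_star[
    rep5$distances$distance == "mutual_information"]))
  expect_match(rep5$distances$error[
    rep5$distances$distance == "mutual_information"], "features")
  # solution records exist only for the applicable distance
  expect_true(all(rep5$solutions$distance == "euclidean"))
  ks <- sort(unique(c(2:6, rep5$curves$euclidean$points$k)))
  ks <- ks[ks >= 2 & ks <= nrow(g5$matrix) - 1]
  expect_equal(nrow(rep5$solutions), 2L * length(ks))
  expect_true(all(rep5$solutions$bmi >= 0))
  expect_true(all(stats::na.omit(rep5$correlations$correlation) >= -1))
  expect_true(all(stats::na.omit(rep5$correlations$correlation) <= 1))
  # in_gray re-derivable from the distance summary
  star <- rep5$distances$bmi_star[rep5$distances$distance == "euclidean"]
  expect_equal(rep5$solutions$in_gray, rep5$solutions$bmi < star)
})

test_that("well-separated data leaves no room inside the gray region", {
  cl <- make_clouds(seed = 6, sep = 20)
  repc <- evaluate_distances(cl$X, cl$gold, distances = "euclidean",
                             k_range = 2:4, seed = 1)
  expect_equal(repc$distances$bmi_star, 0)
  expect_false(any(repc$solutions$in_gray))
  at_r <- repc$solutions[repc$solutions$k == 3, ]
  expect_true(all(at_r$bmi == 0))
})

test_that("strong algorithms reach the best-point BMI on separated marker data", {
  g3 <- gen_gaussian3(seed = 29, n_per_class = 8L, n_features = 90L,
                      markers_per_class = 30L)
  repc <- evaluate_distances(g3$matrix, g3$gold, distances = "euclidean",
                             algorithms = c("kmeans", "complete_link",
                                            "average_link"),
                             k_range = 3L, seed = 1)
  star <- repc$distances$bmi_star
  at_r <- repc$solutions[repc$solutions$k == 3, ]
  expect_true(all(at_r$bmi <= star + 1e-12))
})

test_that("report files are written and re-readable", {
  cl <- make_clouds(seed = 7)
  repc <- evaluate_distances(cl$X, cl$gold, distances = "euclidean",
                             algorithms = "single_link", k_range = 2:3,
                             seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_evaluation_report(repc, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[["distances"]])
  expect_equal(back$bmi_star, repc$distances$bmi_star, tolerance = 1e-12)
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$params$alpha, 0.5)
})
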