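#' Euclidean distance between two feature vectors
#'
#' The geometric distance sqrt(sum((x - y)^2)). Sensitive to the magnitude
#' of change in each coordinate.
#'
#' @param x,y numeric vectors of equal length with finite entries.
#' @return non-negative scalar.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  sqrt(sum((x - y)^2))
}

#' Pearson correlation distance
#'
#' `1 - r`, with `r` the sample Pearson correlation: 0 for a perfect
#' positive linear relation, 2 for a perfect negative one. With only two
#' features the sample correlation is always +-1, so the distance
#' degenerates to {0, 2}; this drives the behaviour of 2-D datasets.
#'
#' @param x,y numeric vectors, length >= 2, each with non-zero variance.
#' @return scalar in `[0, 2]`.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("Pearson distance needs at least 2 features")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Pearson correlation undefined")
  r <- stats::cor(x, y)
  1 - max(-1, min(1, r))
}

#' Joint histogram of two vectors
#'
#' Discretizes each vector into `bins` equal-width bins over its own range
#' and tabulates the joint probability mass function, the ingredient of the
#' mutual-information distance.
#'
#' @param x,y numeric vectors of equal length, non-constant.
#' @param bins number of bins per variable (>= 2); default
#'   `ceiling(sqrt(length(x)))`.
#' @return list of class `joint_histogram` with elements `joint` (bins x
#'   bins pmf), `px`, `py` (marginals), `bins`, `edges_x`, `edges_y`.
#' @export
joint_histogram <- function(x, y, bins = NULL) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  m <- length(x)
  if (is.null(bins)) bins <- ceiling(sqrt(m))
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (max(x) == min(x) || max(y) == min(y))
    stop("constant vector: histogram binning undefined")
  bx <- .equal_width_bin(x, bins)
  by <- .equal_width_bin(y, bins)
  joint <- matrix(0, bins, bins)
  for (i in seq_len(m)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
  joint <- joint / m
  structure(list(joint = joint, px = rowSums(joint), py = colSums(joint),
                 bins = bins,
                 edges_x = seq(min(x), max(x), length.out = bins + 1L),
                 edges_y = seq(min(y), max(y), length.out = bins + 1L)),
            class = "joint_histogram")
}

.equal_width_bin <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  idx <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin(idx, bins)
}

# Shannon entropy in bits with the 0 log 0 := 0 convention.
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual-information distance
#'
#' `1 - MI(X; Y) / max(H(X), H(Y))` estimated from an equal-width-binned
#' joint histogram, entropies in bits. 0 when the vectors are identical,
#' 1 when the binned variables are independent. Histogram estimation is
#' unreliable for short vectors, so at least `min_features` features are
#' required; datasets below that (e.g. 2-D point clouds) are rejected.
#'
#' @param x,y numeric vectors of equal length, non-constant.
#' @param bins bins per variable; default `ceiling(sqrt(length(x)))`.
#' @param min_features minimum vector length accepted (default 8).
#' @return scalar in `[0, 1]`.
#' @export
mutual_information_distance <- function(x, y, bins = NULL, min_features = 8L) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  if (length(x) < min_features)
    stop("mutual-information distance needs at least ", min_features,
         " features, got ", length(x))
  h <- joint_histogram(x, y, bins)
  mi <- .entropy2(h$px) + .entropy2(h$py) - .entropy2(h$joint)
  hx <- .entropy2(h$px); hy <- .entropy2(h$py)
  d <- 1 - mi / max(hx, hy)
  # clamp histogram-estimation round-off
  max(0, min(1, d))
}

#' Pairwise distance matrix of a feature matrix
#'
#' Applies one of the three scalar distances to every unordered row pair.
#' Euclidean distances are delegated to [stats::dist()]; Pearson distances
#' use the row correlation matrix; mutual information loops over pairs.
#'
#' @param X a [feature_matrix()] (items x features).
#' @param distance one of `"euclidean"`, `"pearson"`, `"mutual_information"`.
#' @param bins bin count for the mutual-information distance (default
#'   `ceiling(sqrt(m))`).
#' @return object of class `distance_matrix`: list with `values` (n x n
#'   symmetric, zero diagonal), `distance_name`, `normalized` flag.
#' @export
pairwise_distance_matrix <- function(X,
                                     distance = c("euclidean", "pearson",
                                                  "mutual_information"),
                                     bins = NULL) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  n <- nrow(X); ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("item", seq_len(n))
  if (distance == "euclidean") {
    V <- as.matrix(stats::dist(X, method = "euclidean"))
  } else {
    const <- apply(X, 1L, function(r) max(r) == min(r))
    if (any(const))
      stop("constant rows make the ", distance, " distance undefined: ",
           paste(ids[const], collapse = ", "))
    if (distance == "pearson") {
      if (ncol(X) < 2L) stop("Pearson distance needs at least 2 features")
      R <- stats::cor(t(X))
      V <- 1 - pmin(pmax(R, -1), 1)
    } else {
      if (ncol(X) < 8L)
        stop("mutual-information distance needs at least 8 features, got ",
             ncol(X))
      V <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        V[i, j] <- V[j, i] <- mutual_information_distance(X[i, ], X[j, ],
                                                          bins = bins)
      }
    }
  }
  diag(V) <- 0
  V <- (V + t(V)) / 2 # enforce exact symmetry against float noise
  dimnames(V) <- list(ids, ids)
  new_distance_matrix(V, distance_name = distance, normalized = FALSE)
}

#' Construct a distance matrix object
#'
#' @param values n x n symmetric numeric matrix, zero diagonal, finite
#'   non-negative entries, with item ids as dimnames.
#' @param distance_name label of the generating distance.
#' @param normalized logical; `TRUE` when entries were scaled into `[0, 1]`.
#' @return `distance_matrix` object.
#' @export
new_distance_matrix <- function(values, distance_name = "custom",
                                normalized = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (!all(is.finite(values))) stop("non-finite distance entries")
  if (any(values < 0)) stop("negative distance entries")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix not symmetric")
  if (is.null(rownames(values))) {
    dimnames(values) <- list(paste0("item", seq_len(n)),
                             paste0("item", seq_len(n)))
  }
  structure(list(values = values, distance_name = distance_name,
                 normalized = isTRUE(normalized)),
            class = "distance_matrix")
}

#' Normalize a distance matrix into [0, 1]
#'
#' Divides all entries by the maximum off-diagonal entry, so the largest
#' dissimilarity becomes exactly 1 and a threshold sweep over `[0, 1]`
#' reaches every partition the matrix can induce. The transform is strictly
#' monotone, hence rank-preserving, and idempotent.
#'
#' @param D a `distance_matrix`.
#' @return normalized `distance_matrix`.
#' @export
normalize_distance_matrix <- function(D) {
  stopifnot(inherits(D, "distance_matrix"))
  if (D$normalized) return(D)
  mx <- max(D$values[upper.tri(D$values)])
  if (mx == 0) stop("degenerate matrix: all off-diagonal distances are zero")
  new_distance_matrix(D$values / mx, distance_name = D$distance_name,
                      normalized = TRUE)
}

#' Write a distance matrix as square delimited text
#'
#' @param D a `distance_matrix`.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(D, path, sep = "\t") {
  stopifnot(inherits(D, "distance_matrix"))
  df <- data.frame(id = rownames(D$values),
                   as.data.frame(D$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix (%s%s): %d items\n", x$distance_name,
              if (x$normalized) ", normalized" else "", nrow(x$values)))
  invisible(x)
}
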