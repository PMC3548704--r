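# Seeded generators for the three simulated benchmark datasets. Each
# returns a feature matrix (items = samples to be clustered, rows) plus the
# gold solution used to score partitions against.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.new_synthetic <- function(values, labels, params) {
  fm <- suppressMessages(feature_matrix(values))
  structure(list(matrix = fm,
                 gold = gold_solution(stats::setNames(labels, rownames(fm))),
                 params = params),
            class = "synthetic_dataset")
}

#' Simulate the three-class marker-block dataset ("Gaussian3")
#'
#' 60 samples x 600 features at defaults, three classes of equal size.
#' The features split into three marker blocks of 200: block i is
#' up-regulated (mean `up_mean`) in class i and down-regulated (mean
#' `down_mean`) in the other two classes, with common noise `sd`. This is
#' a strongly separated regime: within-class profiles correlate highly,
#' between-class profiles anti-correlate.
#'
#' @param seed integer RNG seed.
#' @param n_per_class samples per class (default 20).
#' @param n_features total feature count (default 600); must equal
#'   `3 * markers_per_class`.
#' @param markers_per_class marker-block width (default 200).
#' @param up_mean,down_mean marker means inside/outside the class.
#' @param sd common Gaussian noise level.
#' @return list of class `synthetic_dataset` with `matrix`
#'   ([feature_matrix()]), `gold` ([gold_solution()]) and `params`.
#' @export
gen_gaussian3 <- function(seed, n_per_class = 20L, n_features = 600L,
                          markers_per_class = 200L, up_mean = 1,
                          down_mean = -1, sd = 1) {
  if (3L * markers_per_class != n_features)
    stop("need n_features = 3 * markers_per_class (got ", n_features,
         " vs 3 * ", markers_per_class, ")")
  n <- 3L * n_per_class
  cls <- rep(1:3, each = n_per_class)
  mu <- matrix(down_mean, 3L, n_features)
  for (i in 1:3)
    mu[i, ((i - 1L) * markers_per_class + 1L):(i * markers_per_class)] <- up_mean
  vals <- .with_seed(seed, {
    mu[cls, , drop = FALSE] +
      matrix(stats::rnorm(n * n_features, sd = sd), n, n_features)
  })
  rownames(vals) <- paste0("sample", seq_len(n))
  .new_synthetic(vals, paste0("class", cls),
                 params = list(generator = "gaussian3", seed = seed,
                               n_per_class = n_per_class,
                               n_features = n_features,
                               markers_per_class = markers_per_class,
                               up_mean = up_mean, down_mean = down_mean,
                               sd = sd))
}

#' Simulate five bivariate Gaussians on a square ("Gaussian5")
#'
#' Five classes of `n_per_class` points each in 2-D: four centered at the
#' corners of a square of side `lam` and one at its center
#' `(lam/2, lam/2)`, all with isotropic noise `sd`. Smaller `lam` means
#' more class overlap. With only two features the Pearson distance
#' degenerates to {0, 2} and the mutual-information distance is
#' inapplicable, which this dataset is designed to expose.
#'
#' @param seed integer RNG seed.
#' @param lam side length of the square (default 3).
#' @param n_per_class points per class (default 50).
#' @param sd isotropic Gaussian noise level.
#' @return a `synthetic_dataset` (250 x 2 at defaults).
#' @export
gen_gaussian5 <- function(seed, lam = 3, n_per_class = 50L, sd = 1) {
  if (lam < 0) stop("lam must be non-negative")
  centers <- rbind(c(0, 0), c(lam, 0), c(0, lam), c(lam, lam),
                   c(lam / 2, lam / 2))
  n <- 5L * n_per_class
  cls <- rep(1:5, each = n_per_class)
  vals <- .with_seed(seed, {
    centers[cls, , drop = FALSE] + matrix(stats::rnorm(n * 2L, sd = sd), n, 2L)
  })
  rownames(vals) <- paste0("sample", seq_len(n))
  colnames(vals) <- c("x", "y")
  .new_synthetic(vals, paste0("class", cls),
                 params = list(generator = "gaussian5", seed = seed,
                               lam = lam, n_per_class = n_per_class, sd = sd))
}

#' Simulate the six-class marker + noise-gene dataset ("Simulated6")
#'
#' 60 samples x 600 genes at defaults. Six sample classes of sizes
#' 8/12/10/15/5/10; each class is marked by its own block of 50 genes
#' up-regulated (mean `up_mean`) only in that class, against a baseline
#' `base_mean`. The remaining 300 noise genes come in six blocks of 50,
#' nominally assigned to clusters 1..6, generated with linearly decreasing
#' differential expression and linearly increasing variation: block b has
#' residual effect `noise_effect[b]` in its assigned class (default
#' `up_mean * (1 - b/6)`, reaching 0) and standard deviation
#' `noise_sd[b]` everywhere (default `sd * (1 + b/6)`). Passing
#' `noise_effect = rep(0, 6)` makes every noise gene identically
#' distributed across classes.
#'
#' @param seed integer RNG seed.
#' @param class_sizes sample counts per class (default 8,12,10,15,5,10).
#' @param markers_per_class marker-block width (default 50).
#' @param n_noise number of noise genes, a multiple of the number of
#'   classes (default 300).
#' @param up_mean,base_mean marker mean inside the class / baseline.
#' @param sd marker-gene noise level.
#' @param noise_effect per-noise-block residual effect (length
#'   `n_noise / markers_per_class`); default linear decay to 0.
#' @param noise_sd per-noise-block standard deviation; default linear
#'   growth from `sd`.
#' @return a `synthetic_dataset` (60 x 600 at defaults).
#' @export
gen_simulated6 <- function(seed, class_sizes = c(8L, 12L, 10L, 15L, 5L, 10L),
                           markers_per_class = 50L, n_noise = 300L,
                           up_mean = 1, base_mean = 0, sd = 1,
                           noise_effect = NULL, noise_sd = NULL) {
  r <- length(class_sizes)
  if (n_noise %% markers_per_class != 0L)
    stop("n_noise must be a multiple of markers_per_class")
  n_blocks <- n_noise %/% markers_per_class
  if (n_blocks > 0L && n_blocks != r)
    stop("need one noise block per class: ", n_blocks, " blocks vs ", r,
         " classes")
  if (is.null(noise_effect)) noise_effect <- up_mean * (1 - seq_len(n_blocks) / r)
  if (is.null(noise_sd)) noise_sd <- sd * (1 + seq_len(n_blocks) / r)
  if (length(noise_effect) != n_blocks || length(noise_sd) != n_blocks)
    stop("noise_effect / noise_sd must have one entry per noise block")
  n <- sum(class_sizes)
  m <- r * markers_per_class + n_noise
  cls <- rep(seq_len(r), times = class_sizes)
  mu <- matrix(base_mean, n, m)
  sdm <- matrix(sd, n, m)
  for (i in seq_len(r)) {
    block <- ((i - 1L) * markers_per_class + 1L):(i * markers_per_class)
    mu[cls == i, block] <- up_mean
  }
  for (b in seq_len(n_blocks)) {
    block <- r * markers_per_class +
      ((b - 1L) * markers_per_class + 1L):(b * markers_per_class)
    mu[cls == b, block] <- base_mean + noise_effect[b]
    sdm[, block] <- noise_sd[b]
  }
  vals <- .with_seed(seed, {
    mu + matrix(stats::rnorm(n * m), n, m) * sdm
  })
  rownames(vals) <- paste0("sample", seq_len(n))
  colnames(vals) <- c(paste0("marker", seq_len(r * markers_per_class)),
                      if (n_noise) paste0("noise", seq_len(n_noise)))
  .new_synthetic(vals, paste0("class", cls),
                 params = list(generator = "simulated6", seed = seed,
                               class_sizes = class_sizes,
                               markers_per_class = markers_per_class,
                               n_noise = n_noise, up_mean = up_mean,
                               base_mean = base_mean, sd = sd,
                               noise_effect = noise_effect,
                               noise_sd = noise_sd))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset '%s': %d items x %d features, %d classes\n",
              x$params$generator, nrow(x$matrix), ncol(x$matrix),
              attr(x$gold, "r")))
  invisible(x)
}
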