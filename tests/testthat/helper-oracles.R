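# Independent brute-force oracles used to cross-check the implementation.
# They deliberately avoid the package's own code paths: indices are
# recomputed from raw pair enumeration, closures from boolean matrix
# reachability.

# classify every unordered pair of two labelled partitions
pair_counts_oracle <- function(g, p) {
  n <- length(g)
  co_g <- 0L; co_p <- 0L; co_both <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sg <- g[i] == g[j]; sp <- p[i] == p[j]
    co_g <- co_g + sg; co_p <- co_p + sp; co_both <- co_both + (sg && sp)
  }
  list(n_pairs = choose(n, 2L), co_gold = co_g, co_pred = co_p,
       co_both = co_both)
}

ari_oracle <- function(g, p) {
  pc <- pair_counts_oracle(g, p)
  a <- pc$co_both
  exp_a <- pc$co_gold * pc$co_pred / pc$n_pairs
  max_a <- (pc$co_gold + pc$co_pred) / 2
  (a - exp_a) / (max_a - exp_a)
}

fm_oracle <- function(g, p) {
  pc <- pair_counts_oracle(g, p)
  pc$co_both / sqrt(pc$co_gold * pc$co_pred)
}

# F-measure straight from class/cluster sets, no contingency table
f_oracle <- function(g, p) {
  n <- length(g)
  total <- 0
  for (ci in unique(g)) {
    in_c <- which(g == ci)
    best <- 0
    for (pj in unique(p)) {
      in_p <- which(p == pj)
      ov <- length(intersect(in_c, in_p))
      if (ov == 0) next
      prec <- ov / length(in_p); rec <- ov / length(in_c)
      best <- max(best, 2 * prec * rec / (prec + rec))
    }
    total <- total + length(in_c) / n * best
  }
  total
}

# connected components by repeated boolean matrix powering (reachability)
closure_oracle <- function(I) {
  n <- nrow(I)
  R <- (I | diag(n)) * 1
  repeat {
    R2 <- ((R %*% R) > 0) * 1
    if (identical(R2, R)) break
    R <- R2
  }
  labs <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (labs[i] == 0L) {
      nxt <- nxt + 1L
      labs[R[i, ] > 0] <- nxt
    }
  }
  labs
}

# exhaustive triple loop transitivity check
is_transitive_oracle <- function(J) {
  n <- nrow(J)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (J[i, j] == 1 && J[j, k] == 1 && J[i, k] != 1) return(FALSE)
  TRUE
}

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

random_labels <- function(n, k, seed) {
  set.seed(seed)
  labs <- sample.int(k, n, replace = TRUE)
  labs
}

# small well-separated 3-cloud fixture
make_clouds <- function(seed = 1, n_per = 8, sep = 10, sd = 1, m = 5) {
  set.seed(seed)
  centers <- rbind(rep(0, m), rep(sep, m), c(rep(0, floor(m / 2)),
                                             rep(sep, ceiling(m / 2))))
  cls <- rep(1:3, each = n_per)
  vals <- centers[cls, ] + matrix(rnorm(3 * n_per * m, sd = sd), 3 * n_per, m)
  rownames(vals) <- paste0("it", seq_len(nrow(vals)))
  list(X = suppressMessages(feature_matrix(vals)),
       gold = gold_solution(setNames(paste0("c", cls), rownames(vals))))
}

named_partition <- function(labs, ids = paste0("it", seq_along(labs))) {
  partition(setNames(labs, ids))
}

named_gold <- function(labs, ids = paste0("it", seq_along(labs))) {
  gold_solution(setNames(labs, ids))
}
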