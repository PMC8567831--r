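# Shared fixtures: toy graphs with hand-solvable absorption algebra, random
# instances for oracle comparisons, and a brute-force convex hull.

# Toy T1: community {a, b}, unit edges a-b, a-x, b-y.
# Z = [[4/3, 2/3], [2/3, 4/3]], tau = [2, 2], Psi = [[2/3, 1/3], [1/3, 2/3]].
toy_t1 <- function() {
  ids <- c("a", "b", "x", "y")
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W["a", "b"] <- W["b", "a"] <- 1
  W["a", "x"] <- W["x", "a"] <- 1
  W["b", "y"] <- W["y", "b"] <- 1
  list(fc = sanitize_connectome(as_connectome(W)),
       partition = as_partition(c(a = "C", b = "C", x = "O", y = "O")))
}

# Toy T2: single community node a with exits w(a,x) = 0.9 s, w(a,y) = 0.1 s.
toy_t2 <- function(s = 1) {
  ids <- c("a", "x", "y")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W["a", "x"] <- W["x", "a"] <- 0.9 * s
  W["a", "y"] <- W["y", "a"] <- 0.1 * s
  list(fc = sanitize_connectome(as_connectome(W)),
       partition = as_partition(c(a = "C", x = "O", y = "O")))
}

# Random weighted graph with a designated community of size k; every
# community node is guaranteed positive strength and an escape path.
random_chain_instance <- function(n = 20, k = 4, density = 0.35, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- stats::runif(sum(up)) * (stats::runif(sum(up)) < density)
  W <- W + t(W)
  # guarantee each community node couples to something, incl. >= 1 exit overall
  for (i in seq_len(k)) {
    if (sum(W[i, ]) == 0) W[i, k + 1] <- W[k + 1, i] <- stats::runif(1, 0.2, 1)
  }
  if (sum(W[seq_len(k), (k + 1):n]) == 0) {
    W[1, k + 1] <- W[k + 1, 1] <- stats::runif(1, 0.2, 1)
  }
  ids <- sprintf("v%02d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  part <- stats::setNames(rep("out", n), ids)
  part[seq_len(k)] <- "C"
  list(fc = sanitize_connectome(as_connectome(W)),
       partition = as_partition(part))
}

# O(n^4) brute-force hull oracle: p is a hull vertex iff it lies in no closed
# triangle formed by three other points (general position assumed).
brute_force_hull_vertices <- function(points, tol = 1e-12) {
  n <- nrow(points)
  if (n <= 3) return(seq_len(n))
  in_triangle <- function(p, a, b, c) {
    d1 <- (p[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p[2] - b[2])
    d2 <- (p[1] - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (p[2] - c[2])
    d3 <- (p[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (p[2] - a[2])
    !((d1 < -tol || d2 < -tol || d3 < -tol) &&
      (d1 > tol || d2 > tol || d3 > tol))
  }
  keep <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    inside <- FALSE
    for (a in seq_len(length(others) - 2)) {
      for (b in (a + 1):(length(others) - 1)) {
        for (c in (b + 1):length(others)) {
          if (in_triangle(points[i, ], points[others[a], ],
                          points[others[b], ], points[others[c], ])) {
            inside <- TRUE
            break
          }
        }
        if (inside) break
      }
      if (inside) break
    }
    keep[i] <- !inside
  }
  which(keep)
}

# Small cohort spec used where the full default cohort shape is not needed.
small_cohort_spec <- function(n_subjects = 4, seed = 7, ...) {
  cohort_spec(
    n_subjects = n_subjects,
    partition_sizes = c(VIS = 6L, SM = 5L, DA = 5L, VA = 5L,
                        LIM = 4L, FP = 5L, DMN = 6L, SUBC = 4L),
    seed = seed, ...)
}
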