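#' Convex hull of a 2D point set
#'
#' Returns the hull with a deterministic vertex order (counterclockwise,
#' starting from the lexicographic minimum) and its measure at the hull's
#' affine dimension: a single point has measure 0, a collinear set the length
#' of its spanning segment, a full-dimensional set the polygon area (shoelace
#' formula). Collinear points interior to hull edges are excluded from the
#' vertex set.
#'
#' @param points Numeric matrix or data frame with 2 columns (finite values).
#' @param tol Relative tolerance for rank/collinearity decisions.
#' @return A `polytope`: list with `points`, `vertices` (row indices into
#'   `points`, CCW), `affine_dim` (0, 1 or 2), `measure`.
#' @export
convex_hull <- function(points, tol = 1e-12) {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 2) {
    .stopf("fnmorph_validation_error", "need >= 1 finite 2D point")
  }
  if (any(!is.finite(points))) {
    .stopf("fnmorph_validation_error", "non-finite coordinates in point set")
  }
  scale <- max(abs(points), 1)
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)$d
  dim <- sum(sv > tol * scale * max(nrow(points), 2))
  if (dim == 0) {
    poly <- list(points = points, vertices = 1L, affine_dim = 0L, measure = 0)
  } else if (dim == 1) {
    v <- svd(ctr)$v[, 1]
    proj <- drop(ctr %*% v)
    i_min <- which.min(proj); i_max <- which.max(proj)
    ends <- unique(c(i_min, i_max))
    # order endpoints so the first is the lexicographic minimum
    ord <- order(points[ends, 1], points[ends, 2])
    poly <- list(points = points, vertices = as.integer(ends[ord]),
                 affine_dim = 1L,
                 measure = sqrt(sum((points[i_max, ] - points[i_min, ])^2)))
  } else {
    h <- grDevices::chull(points[, 1], points[, 2])   # clockwise order
    h <- rev(h)                                       # counterclockwise
    h <- .prune_collinear(points, h, tol * scale)
    # rotate so traversal starts at the lexicographic minimum vertex
    start <- h[order(points[h, 1], points[h, 2])[1]]
    h <- c(h[which(h == start):length(h)], h[seq_len(which(h == start) - 1L)])
    poly <- list(points = points, vertices = as.integer(h), affine_dim = 2L,
                 measure = .shoelace(points[h, , drop = FALSE]))
  }
  class(poly) <- "polytope"
  poly
}

# drop hull vertices whose incident edges are collinear
.prune_collinear <- function(points, h, tol) {
  if (length(h) <= 3) return(h)
  keep <- rep(TRUE, length(h))
  n <- length(h)
  for (i in seq_len(n)) {
    a <- points[h[if (i == 1) n else i - 1], ]
    b <- points[h[i], ]
    c <- points[h[if (i == n) 1 else i + 1], ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cross) <= tol) keep[i] <- FALSE
  }
  h[keep]
}

.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' @export
print.polytope <- function(x, ...) {
  cat(sprintf("Polytope: %d points, affine dimension %d, %s = %.6g\n",
              nrow(x$points), x$affine_dim,
              c("measure", "length", "area")[x$affine_dim + 1L], x$measure))
  invisible(x)
}

#' Hull measure at its affine dimension
#'
#' @param polytope A `polytope`.
#' @return Numeric vector `c(affine_dim, measure)`.
#' @export
hull_measure <- function(polytope) {
  stopifnot(inherits(polytope, "polytope"))
  c(affine_dim = polytope$affine_dim, measure = polytope$measure)
}

#' Functional reconfiguration of a community
#'
#' Area of the convex hull of a community's task coordinates in the
#' morphospace: the breadth of task-evoked configurations. The rest point is
#' never part of the task set. The headline value is strictly the 2D area —
#' collinear or coincident task points give 0 — with the affine dimension and
#' the lower-dimensional measure reported alongside.
#'
#' @param task_points Matrix/data frame of (TE, EE) task coordinates.
#' @return List with `R` (area), `affine_dim`, `degenerate_measure` (length of
#'   the segment when `affine_dim == 1`, else 0), and the `polytope`.
#' @export
reconfiguration <- function(task_points) {
  poly <- convex_hull(task_points)
  list(R = if (poly$affine_dim == 2L) poly$measure else 0,
       affine_dim = poly$affine_dim,
       degenerate_measure = if (poly$affine_dim < 2L) poly$measure else 0,
       polytope = poly)
}

#' Geometric centroid of a point set
#'
#' Arithmetic mean of the task points (defined for every affine dimension,
#' unlike an area-weighted polygon centroid).
#'
#' @param points Matrix/data frame of 2D points.
#' @return Numeric length-2 vector.
#' @export
geometric_centroid <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1)
  colMeans(points)
}

#' Functional preconfiguration of a community
#'
#' Euclidean distance in the morphospace from the resting-state point to the
#' geometric centroid of the task points: how far a network must travel from
#' its resting configuration to its task-general position.
#'
#' @param rest_point Length-2 numeric (TE, EE) at rest.
#' @param task_points Matrix/data frame of task (TE, EE) coordinates.
#' @return Scalar distance.
#' @export
preconfiguration <- function(rest_point, task_points) {
  if (length(rest_point) != 2 || any(!is.finite(rest_point))) {
    .stopf("fnmorph_validation_error", "rest point must be a finite (TE, EE) pair")
  }
  sqrt(sum((as.numeric(rest_point) - geometric_centroid(task_points))^2))
}

#' Maximal pairwise task distance
#'
#' Maximum pairwise distance between two task points, per axis (absolute
#' difference in TE or EE) or in the full 2D space. Ties break by
#' lexicographic task-label order of the pair.
#'
#' @param task_points Matrix of task coordinates with task labels as rownames.
#' @param axis `"TE"`, `"EE"` or `"both"` (Euclidean).
#' @return List with `distance` and `pair` (sorted task labels).
#' @export
maximal_task_distance <- function(task_points, axis = c("TE", "EE", "both")) {
  axis <- match.arg(axis)
  task_points <- as.matrix(task_points)
  n <- nrow(task_points)
  if (n < 2) .stopf("fnmorph_validation_error", "need >= 2 task points")
  labs <- rownames(task_points) %||% sprintf("task%d", seq_len(n))
  best <- -1; best_pair <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- switch(axis,
        TE = abs(task_points[i, 1] - task_points[j, 1]),
        EE = abs(task_points[i, 2] - task_points[j, 2]),
        both = sqrt(sum((task_points[i, ] - task_points[j, ])^2)))
      pair <- sort(c(labs[i], labs[j]))
      if (d > best ||
          (d == best && paste(pair, collapse = "\r") < paste(best_pair, collapse = "\r"))) {
        best <- d; best_pair <- pair
      }
    }
  }
  list(distance = best, pair = best_pair)
}

#' Task extremity frequencies
#'
#' How often each task appears in the maximal-distance pair, per axis, across
#' communities, normalized by the number of slots (communities x 2 tasks per
#' community).
#'
#' @param pairs Data frame with columns `community`, `axis`, `task1`, `task2`.
#' @param tasks Task labels over which to report (defaults to those observed).
#' @return Data frame `axis`, `task`, `count`, `frequency`.
#' @export
task_extremity_frequency <- function(pairs, tasks = NULL) {
  stopifnot(all(c("community", "axis", "task1", "task2") %in% names(pairs)))
  tasks <- tasks %||% sort(unique(c(pairs$task1, pairs$task2)))
  out <- list()
  for (ax in unique(pairs$axis)) {
    sub <- pairs[pairs$axis == ax, ]
    slots <- 2L * length(unique(sub$community))
    cnt <- table(factor(c(sub$task1, sub$task2), levels = tasks))
    out[[ax]] <- data.frame(axis = ax, task = tasks,
                            count = as.integer(cnt),
                            frequency = as.integer(cnt) / slots,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Network configural breadth for a cohort
#'
#' For each subject x community (x session by default), collects the task
#' coordinates `W`, computes functional reconfiguration `R` (task-hull area)
#' and preconfiguration `P` (rest-to-centroid distance), plus the centroid,
#' rest point and the hull's affine dimension. Sessions can instead be
#' averaged before hull construction.
#'
#' @param coords A `coord_table` from [cohort_coordinates()].
#' @param rest_label Condition label designating rest.
#' @param average_sessions If `TRUE`, average (TE, EE) across sessions per
#'   condition before building hulls; otherwise one row per session.
#' @return A `breadth_table` data frame: subject, session, community, R, P,
#'   affine_dim, n_tasks, centroid_TE, centroid_EE, rest_TE, rest_EE.
#' @export
configural_breadth <- function(coords, rest_label = "rest",
                               average_sessions = FALSE) {
  stopifnot(is.data.frame(coords))
  if ("error" %in% names(coords)) coords <- coords[is.na(coords$error), ]
  if (!rest_label %in% coords$condition) {
    .stopf("fnmorph_validation_error", "rest condition '%s' absent from coordinates",
           rest_label)
  }
  if (average_sessions) {
    agg <- stats::aggregate(coords[c("TE", "EE")],
                            coords[c("subject", "condition", "community")], mean)
    agg$session <- "avg"
    coords <- agg
  }
  cells <- unique(coords[c("subject", "session", "community")])
  cells <- cells[order(cells$subject, cells$session, cells$community), ]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- coords[coords$subject == cell$subject &
                  coords$session == cell$session &
                  coords$community == cell$community, ]
    rest <- sub[sub$condition == rest_label, ]
    tasks <- sub[sub$condition != rest_label, ]
    if (nrow(rest) != 1 || nrow(tasks) < 1) {
      .stopf("fnmorph_validation_error",
             "subject %s session %s community %s: need one rest and >= 1 task point",
             cell$subject, cell$session, cell$community)
    }
    W <- as.matrix(tasks[c("TE", "EE")])
    rownames(W) <- tasks$condition
    rec <- reconfiguration(W)
    eta <- geometric_centroid(W)
    rows[[i]] <- data.frame(
      subject = cell$subject, session = cell$session, community = cell$community,
      R = rec$R, P = preconfiguration(c(rest$TE, rest$EE), W),
      affine_dim = rec$affine_dim, n_tasks = nrow(W),
      centroid_TE = eta[1], centroid_EE = eta[2],
      rest_TE = rest$TE, rest_EE = rest$EE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("breadth_table", "data.frame")
  out
}

#' @export
print.breadth_table <- function(x, ...) {
  cat(sprintf("Configural breadth: %d subject x session x community cells\n", nrow(x)))
  cat(sprintf("  reconfiguration R in [%.4g, %.4g]; preconfiguration P in [%.4g, %.4g]\n",
              min(x$R), max(x$R), min(x$P), max(x$P)))
  if (any(x$affine_dim < 2)) {
    cat(sprintf("  %d cells with degenerate (affine dim < 2) task hulls\n",
                sum(x$affine_dim < 2)))
  }
  invisible(x)
}
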