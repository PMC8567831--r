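test_that("convex hull excludes interior points and handles degenerate sets", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0.2, 0.2))
  poly <- convex_hull(pts)
  expect_equal(poly$affine_dim, 2L)
  expect_setequal(poly$vertices, 1:3)
  expect_equal(poly$measure, 0.5)
  # deterministic CCW order from the lexicographic minimum
  expect_equal(poly$vertices[1], 1L)

  coll <- convex_hull(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(coll$affine_dim, 1L)
  expect_equal(coll$measure, 2 * sqrt(2))
  expect_setequal(coll$vertices, c(1L, 3L))

  pt <- convex_hull(rbind(c(0.3, 0.4)))
  expect_equal(pt$affine_dim, 0L)
  expect_equal(pt$measure, 0)

  expect_error(convex_hull(rbind(c(NA, 1))), class = "fnmorph_validation_error")
})

test_that("hull vertex sets and areas match the brute-force oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:14, 1)
    pts <- matrix(stats::runif(2 * n), n, 2)
    poly <- convex_hull(pts)
    expect_setequal(poly$vertices, brute_force_hull_vertices(pts))
    # area equals fan-triangulation of the ordered hull
    v <- pts[poly$vertices, , drop = FALSE]
    fan <- 0
    for (j in 2:(nrow(v) - 1)) {
      fan <- fan + abs((v[j, 1] - v[1, 1]) * (v[j + 1, 2] - v[1, 2]) -
                       (v[j + 1, 1] - v[1, 1]) * (v[j, 2] - v[1, 2])) / 2
    }
    expect_equal(poly$measure, fan, tolerance = 1e-10)
  }
})

test_that("reconfiguration is the task-hull area, zero when degenerate", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  interior <- rbind(c(0.2, 0.2), c(0.1, 0.3), c(0.3, 0.1), c(0.25, 0.25))
  r <- reconfiguration(rbind(tri, interior))
  expect_equal(r$R, 0.5)
  expect_equal(r$affine_dim, 2L)

  two <- reconfiguration(rbind(c(0, 0), c(1, 1)))
  expect_equal(two$R, 0)
  expect_equal(two$affine_dim, 1L)
  expect_equal(two$degenerate_measure, sqrt(2))

  # adding a point inside an existing hull never changes R
  set.seed(33)
  for (i in 1:10) {
    pts <- matrix(stats::runif(16), 8, 2)
    r0 <- reconfiguration(pts)$R
    inside <- colMeans(pts[convex_hull(pts)$vertices, ])
    expect_equal(reconfiguration(rbind(pts, inside))$R, r0)
  }
})

test_that("moving a hull vertex outward never shrinks the hull", {
  set.seed(14)
  for (i in 1:10) {
    pts <- matrix(stats::runif(14), 7, 2)
    poly <- convex_hull(pts)
    v <- poly$vertices[1]
    ctr <- geometric_centroid(pts)
    moved <- pts
    moved[v, ] <- ctr + 1.5 * (pts[v, ] - ctr)
    expect_gte(reconfiguration(moved)$R, reconfiguration(pts)$R - 1e-12)
  }
})

test_that("centroid is the arithmetic mean and translation equivariant", {
  pts <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(geometric_centroid(pts), c(2 / 3, 2 / 3))
  expect_equal(geometric_centroid(rbind(c(0.4, 0.8))), c(0.4, 0.8))
  set.seed(8)
  w <- matrix(stats::runif(10), 5, 2)
  v <- c(0.3, -1.2)
  expect_equal(geometric_centroid(sweep(w, 2, -v)), geometric_centroid(w) + v)
})

test_that("preconfiguration is the rest-to-centroid distance, rigid-motion invariant", {
  tasks <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(preconfiguration(c(0, 0), tasks), sqrt(8) / 3, tolerance = 1e-10)
  expect_equal(preconfiguration(c(0, 0), tasks), 0.94281, tolerance = 1e-5)
  expect_equal(preconfiguration(geometric_centroid(tasks), tasks), 0)
  # invariance under rotation of all points about the origin
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(preconfiguration(drop(Rm %*% c(0, 0)), tasks %*% t(Rm)),
               preconfiguration(c(0, 0), tasks))
  expect_error(preconfiguration(c(NA, 0), tasks), class = "fnmorph_validation_error")
})

test_that("maximal task distance finds the extreme pair with stable ties", {
  pts <- cbind(TE = c(0.1, 0.4, 0.2), EE = c(0, 0, 0))
  rownames(pts) <- c("task1", "task2", "task3")
  res <- maximal_task_distance(pts, axis = "TE")
  expect_equal(res$distance, 0.3)
  expect_equal(res$pair, c("task1", "task2"))

  same <- cbind(TE = c(0.5, 0.5), EE = c(0.5, 0.5))
  rownames(same) <- c("a", "b")
  expect_equal(maximal_task_distance(same, "both")$distance, 0)
  expect_error(maximal_task_distance(same[1, , drop = FALSE]),
               class = "fnmorph_validation_error")

  # exhaustive oracle on random points
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(stats::runif(14), 7, 2,
                dimnames = list(sprintf("t%d", 1:7), c("TE", "EE")))
    res <- maximal_task_distance(m, "both")
    d <- as.matrix(stats::dist(m))
    expect_equal(res$distance, max(d))
  }

  # tie on a symmetric configuration breaks lexicographically
  tie <- cbind(TE = c(0, 1, 0, 1), EE = c(0, 0, 1, 1))
  rownames(tie) <- c("d", "c", "b", "a")
  res <- maximal_task_distance(tie, "TE")
  expect_equal(res$distance, 1)
  expect_equal(res$pair, c("a", "b"))
})

test_that("task extremity frequencies count argmax appearances per slot", {
  pairs <- data.frame(community = sprintf("C%d", 1:8), axis = "TE",
                      task1 = "WM", task2 = sprintf("t%d", 1:8))
  freq <- task_extremity_frequency(pairs)
  expect_equal(freq$frequency[freq$task == "WM"], 0.5)   # 8 of 16 slots
  expect_equal(sum(freq$count), 16)
  expect_equal(freq$frequency[freq$task == "t1"], 1 / 16)
  absent <- task_extremity_frequency(pairs, tasks = c("WM", "REST"))
  expect_equal(absent$frequency[absent$task == "REST"], 0)
})

test_that("configural breadth assembles per subject x session x community", {
  grid <- expand.grid(subject = c("s1", "s2"), session = c("test", "retest"),
                      community = c("DMN", "VIS"),
                      condition = c("rest", "t1", "t2", "t3"),
                      stringsAsFactors = FALSE)
  set.seed(99)
  grid$TE <- stats::runif(nrow(grid)); grid$EE <- stats::runif(nrow(grid))
  br <- configural_breadth(grid)
  expect_equal(nrow(br), 2 * 2 * 2)
  expect_true(all(br$R >= 0) && all(br$P >= 0))
  expect_equal(br$n_tasks, rep(3L, 8))
  # centroid lies in the bounding box of the task points
  one <- grid[grid$subject == "s1" & grid$session == "test" &
              grid$community == "DMN" & grid$condition != "rest", ]
  row <- br[br$subject == "s1" & br$session == "test" & br$community == "DMN", ]
  expect_gte(row$centroid_TE, min(one$TE)); expect_lte(row$centroid_TE, max(one$TE))
  expect_gte(row$centroid_EE, min(one$EE)); expect_lte(row$centroid_EE, max(one$EE))

  # averaging sessions halves the cells
  br_avg <- configural_breadth(grid, average_sessions = TRUE)
  expect_equal(nrow(br_avg), 2 * 2)
  expect_error(configural_breadth(grid[grid$condition != "rest", ]),
               class = "fnmorph_validation_error")
})
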