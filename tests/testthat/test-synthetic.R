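test_that("the noise-free limit is exactly block constant", {
  sp <- small_cohort_spec(sigma_w = 0, sigma_subj = 0, sigma_sess = 0,
                          task_effects = "none")
  fc <- generate_connectome(sp, "sub001", "rest", "test")
  part <- spec_partition(sp)
  W <- fc$weights
  within <- outer(unclass(part), unclass(part), "==")
  diag(within) <- NA
  expect_true(all(W[which(within)] == sp$mu_in))
  expect_true(all(W[which(!within)] == sp$mu_out))
  expect_equal(unname(diag(W)), rep(0, sp$n_nodes))
})

test_that("matrix generation is deterministic per (seed, subject, condition, session)", {
  sp <- small_cohort_spec()
  a <- generate_connectome(sp, "sub002", "WM", "retest")
  b <- generate_connectome(sp, "sub002", "WM", "retest")
  expect_identical(a$weights, b$weights)
  c_ <- generate_connectome(sp, "sub002", "WM", "test")
  expect_false(identical(a$weights, c_$weights))
  expect_error(generate_connectome(sp, "sub001", "nap", "test"),
               class = "fnmorph_spec_error")
})

test_that("generated matrices are already sanitary", {
  sp <- small_cohort_spec()
  for (cond in c("rest", "WM")) {
    fc <- generate_connectome(sp, "sub001", cond, "test")
    re <- sanitize_connectome(fc)
    expect_equal(re$weights, fc$weights)
    expect_true(all(fc$weights >= 0 & fc$weights <= 1))
  }
})

test_that("task effects move the morphospace coordinates in the planted direction", {
  part_sizes <- c(A = 8L, B = 8L, C = 8L, D = 8L)
  # one task concentrating A's exits into B, one damping all of A's exits
  te <- data.frame(task = c("focus", "damp"), community = "A",
                   target = c("B", NA), multiplier = c(3, 0.5),
                   stringsAsFactors = FALSE)
  sp <- cohort_spec(n_subjects = 1, conditions = c("rest", "focus", "damp"),
                    partition_sizes = part_sizes, sigma_subj = 0,
                    sigma_sess = 0, sigma_w = 0.01, task_effects = te, seed = 3)
  part <- spec_partition(sp)
  cc <- function(cond) {
    community_coordinates(generate_connectome(sp, "sub001", cond, "test"),
                          part, "A")
  }
  rest <- cc("rest"); focus <- cc("focus"); damp <- cc("damp")
  expect_lt(focus$EE, rest$EE)   # concentrated exits: lower exit entropy
  expect_gt(damp$TE, rest$TE)    # weaker exits: better trapping
  expect_equal(damp$EE, rest$EE, tolerance = 0.02)  # damping is distribution-neutral
})

test_that("an infeasible spec is rejected up front", {
  expect_error(small_cohort_spec(mu_in = 0.9, sigma_subj = 0.2),
               class = "fnmorph_spec_error")
  expect_error(small_cohort_spec(mu_out = 0.5, mu_in = 0.3),
               class = "fnmorph_spec_error")
})

test_that("cohort generation is full factorial and round-trips through disk", {
  sp <- small_cohort_spec(n_subjects = 3, conditions = c("rest", "WM", "MOT"))
  dir <- withr::local_tempdir()
  man <- generate_cohort(sp, dir = dir)
  expect_equal(nrow(man), 3 * 3 * 2)
  expect_true(all(file.exists(man$path)))

  reloaded <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(reloaded$subject, man$subject)
  part <- load_partition(file.path(dir, "partition.tsv"))
  expect_equal(sort(unique(unclass(part))), sort(names(sp$partition_sizes)))

  # disk and in-memory routes agree
  mem <- generate_cohort(sp)
  fc_disk <- sanitize_connectome(load_connectome(man$path[1]))
  key <- paste(man$subject[1], man$condition[1], man$session[1], sep = "|")
  expect_equal(fc_disk$weights, mem$matrices[[key]]$weights)

  coords <- cohort_coordinates(reloaded, part)
  expect_true(all(is.na(coords$error)))
  expect_false(anyNA(coords$TE))
})

test_that("stronger subject effects raise the subject fingerprint of preconfiguration", {
  sizes <- stats::setNames(rep(12L, 8),
                           c("VIS", "SM", "DA", "VA", "LIM", "FP", "DMN", "SUBC"))
  iccs <- vapply(c(0, 0.08), function(s) {
    sp <- cohort_spec(n_subjects = 8, partition_sizes = sizes, sigma_subj = s,
                      task_effects = "none", seed = 11)
    co <- generate_cohort(sp)
    br <- configural_breadth(cohort_coordinates(co, co$partition))
    rk <- rank_descriptors(br)
    stats::median(rk$icc[rk$measure == "P"])
  }, numeric(1))
  expect_gt(iccs[2], iccs[1])
  expect_gt(iccs[2], 0.5)
})

test_that("behavior generation recovers its own planted coefficients", {
  sp <- small_cohort_spec(n_subjects = 20)
  co <- generate_cohort(sp)
  br <- configural_breadth(cohort_coordinates(co, co$partition))
  bs <- behavior_spec(c("FP_P", "DMN_P"), c(0.6, -0.4), sigma_y = 0, seed = 5)
  beh <- generate_behavior(br, bs)
  X <- descriptor_matrix(br)[beh$subject, c("FP_P", "DMN_P", "VIS_R")]
  fit <- iterative_mlm(X, beh$score)
  sel <- fit$models[[fit$selected]]
  expect_equal(sel$r2, 1, tolerance = 1e-9)
  beta_raw <- coef(fit) * fit$y_scale
  expect_equal(unname(beta_raw[c("FP_P", "DMN_P")]), c(0.6, -0.4),
               tolerance = 1e-6)

  expect_error(generate_behavior(br, behavior_spec("NOPE_R", 1)),
               class = "fnmorph_spec_error")
})
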