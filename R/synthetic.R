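#' Specify a synthetic test-retest cohort
#'
#' Describes a cohort shaped like a test-retest task-fMRI release: ~100
#' subjects, one rest plus seven task conditions, two sessions, 374 regions
#' partitioned into 7 cortical resting-state networks plus one subcortical
#' group. Couplings are truncated-normal draws around block means (within- vs
#' between-community), clamped to [0, 1], with three planted effect layers:
#'
#' * subject effects: per subject x community, an additive offset on
#'   within-community couplings applied in every condition, plus a second
#'   rest-only within-community offset of the same sd — a subject's
#'   resting-state trait. The first shifts a subject's overall segregation
#'   level (trapping-efficiency fingerprints); the second makes the
#'   rest-vs-task contrast itself a stable subject trait, which is what
#'   preconfiguration measures.
#' * task effects: per (task, community) multipliers on exit-edge couplings,
#'   either toward one target community (reshaping the exit distribution, so
#'   exit entropy moves) or on all exit edges (rescaling leakage, so trapping
#'   efficiency moves).
#' * scan noise: each condition is acquired as its own scan run, so every
#'   (subject, condition, session) matrix receives an independent run-level
#'   gain fluctuation — all block means are scaled by `1 + N(0, sigma_sess)`,
#'   emulating global coupling-level shifts between scans without creating
#'   edges where none exist — on top of per-edge coupling noise.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Condition labels; the first is rest.
#' @param n_sessions Sessions per subject (test, retest).
#' @param partition_sizes Named integer vector of community sizes.
#' @param mu_in,mu_out Mean within-/between-community coupling (mu_out < mu_in).
#' @param sigma_w Per-edge coupling noise sd.
#' @param sigma_subj Subject-effect sd (both components).
#' @param sigma_sess Run-level (scan) gain sd; couplings scale by
#'   `1 + N(0, sigma_sess)` per scan.
#' @param task_effects Data frame `task`, `community`, `target`, `multiplier`;
#'   `target = NA` applies the multiplier to all of the community's exit
#'   edges. `NULL` = the default rotating-target map; `"none"` = no task
#'   effects.
#' @param seed Base seed; all matrices derive deterministic substreams from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        conditions = c("rest", "GAM", "REL", "SOC", "WM",
                                       "LANG", "EMOT", "MOT"),
                        n_sessions = 2L,
                        partition_sizes = c(VIS = 61L, SM = 57L, DA = 46L,
                                            VA = 47L, LIM = 26L, FP = 52L,
                                            DMN = 71L, SUBC = 14L),
                        mu_in = 0.30, mu_out = 0.08,
                        sigma_w = 0.04, sigma_subj = 0.06, sigma_sess = 0.02,
                        task_effects = NULL, seed = 1L) {
  if (is.null(names(partition_sizes))) {
    .stopf("fnmorph_spec_error", "partition_sizes must be named")
  }
  if (mu_out >= mu_in) .stopf("fnmorph_spec_error", "need mu_out < mu_in")
  tasks <- conditions[-1]
  comms <- names(partition_sizes)
  if (identical(task_effects, "none")) {
    task_effects <- data.frame(task = character(), community = character(),
                               target = character(), multiplier = numeric())
  } else if (is.null(task_effects)) {
    # default map: task t concentrates every community's exits into a target
    # community rotating with t, with task-varying magnitude
    task_effects <- do.call(rbind, lapply(seq_along(tasks), function(t) {
      tc <- vapply(seq_along(comms),
                   function(c) comms[((c - 1 + t) %% length(comms)) + 1],
                   character(1))
      data.frame(task = tasks[t], community = comms, target = tc,
                 multiplier = 1 + 0.1 * t, stringsAsFactors = FALSE)
    }))
  }
  max_mult <- if (nrow(task_effects)) max(task_effects$multiplier) else 1
  if (mu_in * (1 + 3 * sigma_sess) + 3 * (sigma_w + 2 * sigma_subj) > 1 ||
      mu_out * max_mult * (1 + 3 * sigma_sess) + 3 * sigma_w > 1) {
    .stopf("fnmorph_spec_error",
           "infeasible spec: block mean + 3 sd of planted effects exceeds 1")
  }
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 rest_label = conditions[1], tasks = tasks,
                 n_sessions = as.integer(n_sessions),
                 sessions = c("test", "retest")[seq_len(n_sessions)],
                 partition_sizes = partition_sizes,
                 n_nodes = sum(partition_sizes),
                 mu_in = mu_in, mu_out = mu_out, sigma_w = sigma_w,
                 sigma_subj = sigma_subj, sigma_sess = sigma_sess,
                 task_effects = task_effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d subjects x %d conditions x %d sessions, %d nodes in %d communities\n",
              x$n_subjects, length(x$conditions), x$n_sessions, x$n_nodes,
              length(x$partition_sizes)))
  cat(sprintf("  mu_in %.2f, mu_out %.2f, sigma_w %.2f, sigma_subj %.2f, sigma_sess %.2f, %d task-effect rows\n",
              x$mu_in, x$mu_out, x$sigma_w, x$sigma_subj, x$sigma_sess,
              nrow(x$task_effects)))
  invisible(x)
}

#' Partition implied by a cohort spec
#'
#' @param spec A `cohort_spec`.
#' @return A `partition` over nodes `n001 ... nNNN`.
#' @export
spec_partition <- function(spec) {
  ids <- sprintf("n%03d", seq_len(spec$n_nodes))
  as_partition(stats::setNames(rep(names(spec$partition_sizes),
                                   spec$partition_sizes), ids))
}

.cohort_key <- function(subject, condition, session) {
  paste(subject, condition, session, sep = "|")
}

# community index of each node, plus between-block multiplier matrix for a
# condition
.block_multipliers <- function(spec, condition) {
  comms <- names(spec$partition_sizes)
  B <- matrix(1, length(comms), length(comms), dimnames = list(comms, comms))
  te <- spec$task_effects
  te <- te[te$task == condition, , drop = FALSE]
  for (i in seq_len(nrow(te))) {
    cm <- te$community[i]; tg <- te$target[i]; m <- te$multiplier[i]
    if (is.na(tg)) {
      B[cm, ] <- B[cm, ] * m
      B[, cm] <- B[, cm] * m
      B[cm, cm] <- 1
    } else {
      B[cm, tg] <- B[cm, tg] * m
      B[tg, cm] <- B[tg, cm] * m
    }
  }
  B
}

#' Generate one synthetic connectome
#'
#' Deterministic given `(spec$seed, subject, condition, session)`: subject,
#' session and edge-noise draws come from independent hashed substreams, so
#' any matrix can be regenerated alone.
#'
#' @param spec A `cohort_spec`.
#' @param subject Subject id (e.g. `"sub001"`).
#' @param condition Condition label from `spec$conditions`.
#' @param session Session label from `spec$sessions`.
#' @return A sanitized-clean `connectome` (nonnegative, symmetric, zero
#'   diagonal, weights in [0, 1]).
#' @export
generate_connectome <- function(spec, subject, condition, session) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!condition %in% spec$conditions) {
    .stopf("fnmorph_spec_error", "unknown condition '%s'", condition)
  }
  comms <- names(spec$partition_sizes)
  node_comm <- rep(seq_along(comms), spec$partition_sizes)
  n <- spec$n_nodes
  # per-(subject, community) effects: all-condition offset + rest-only offset
  subj_eff <- vapply(comms, function(cm) {
    set.seed(.substream(spec$seed, "subj", subject, cm))
    stats::rnorm(2, 0, spec$sigma_subj)
  }, numeric(2))
  within_shift <- subj_eff[1, ]
  if (condition == spec$rest_label) within_shift <- within_shift + subj_eff[2, ]
  set.seed(.substream(spec$seed, "scan", subject, condition, session))
  scan_gain <- 1 + stats::rnorm(1, 0, spec$sigma_sess)
  B <- .block_multipliers(spec, condition)
  # block mean matrix at the node level
  mean_block <- spec$mu_out * B
  diag(mean_block) <- spec$mu_in + within_shift
  M <- mean_block[node_comm, node_comm] * scan_gain
  set.seed(.substream(spec$seed, "edge", subject, condition, session))
  up <- upper.tri(M)
  W <- matrix(0, n, n)
  W[up] <- M[up] + stats::rnorm(sum(up), 0, spec$sigma_w)
  W[W < 0] <- 0
  W[W > 1] <- 1
  W <- W + t(W)
  fc <- as_connectome(W, sprintf("n%03d", seq_len(n)))
  fc$sanitized <- TRUE
  fc$report <- list(n_negative_zeroed = 0L, max_asymmetry = 0)
  fc
}

#' Generate a full synthetic cohort
#'
#' Full factorial subject x condition x session set. With `dir = NULL`
#' (default) matrices stay in memory; with a directory, each matrix is
#' written (CSV or RDS) alongside a `manifest.csv` and `partition.tsv` that
#' round-trip through the loaders.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory, or `NULL` for in memory.
#' @param dialect On-disk matrix format, `"delim"` or `"rds"`.
#' @return In memory: a `cohort` (list with `spec`, `manifest`, `matrices`,
#'   `partition`). On disk: the validated `manifest` (invisibly the same
#'   object, with paths).
#' @export
generate_cohort <- function(spec, dir = NULL, dialect = c("delim", "rds")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("sub%03d", seq_len(spec$n_subjects))
  grid <- expand.grid(session = spec$sessions, condition = spec$conditions,
                      subject = subjects, stringsAsFactors = FALSE)
  grid <- grid[c("subject", "condition", "session")]
  partition <- spec_partition(spec)
  if (is.null(dir)) {
    mats <- vector("list", nrow(grid))
    names(mats) <- .cohort_key(grid$subject, grid$condition, grid$session)
    for (i in seq_len(nrow(grid))) {
      mats[[i]] <- generate_connectome(spec, grid$subject[i], grid$condition[i],
                                       grid$session[i])
    }
    manifest <- grid
    manifest$path <- NA_character_
    class(manifest) <- c("manifest", "data.frame")
    return(structure(list(spec = spec, manifest = manifest, matrices = mats,
                          partition = partition),
                     class = "cohort"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "rds") "rds" else "csv"
  grid$path <- sprintf("%s_%s_%s.%s", grid$subject, grid$condition,
                       grid$session, ext)
  for (i in seq_len(nrow(grid))) {
    fc <- generate_connectome(spec, grid$subject[i], grid$condition[i],
                              grid$session[i])
    write_connectome(fc, file.path(dir, grid$path[i]), dialect = dialect)
  }
  utils::write.table(grid, file.path(dir, "manifest.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(names(partition), unclass(partition)),
                     file.path(dir, "partition.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(load_manifest(file.path(dir, "manifest.csv")))
}

#' Subject-by-descriptor matrix from a breadth table
#'
#' Reshapes a per-session `breadth_table` into one row per subject and one
#' column per descriptor (`<community>_R`, `<community>_P`), averaging over
#' sessions — the predictor matrix for the behavior models.
#'
#' @param breadth A `breadth_table`.
#' @return Numeric matrix, rownames = subjects.
#' @export
descriptor_matrix <- function(breadth) {
  agg <- stats::aggregate(breadth[c("R", "P")],
                          breadth[c("subject", "community")], mean)
  subjects <- sort(unique(agg$subject))
  comms <- sort(unique(agg$community))
  out <- matrix(NA_real_, length(subjects), 2L * length(comms),
                dimnames = list(subjects,
                                paste0(rep(comms, each = 2), c("_R", "_P"))))
  for (i in seq_len(nrow(agg))) {
    out[agg$subject[i], paste0(agg$community[i], "_R")] <- agg$R[i]
    out[agg$subject[i], paste0(agg$community[i], "_P")] <- agg$P[i]
  }
  if (anyNA(out)) .stopf("fnmorph_validation_error", "incomplete breadth table")
  out
}

#' Specify planted behavior
#'
#' @param targets Descriptor names carrying true effects.
#' @param beta True coefficients on the z-scored descriptors (same length as
#'   `targets`).
#' @param beta0 Intercept.
#' @param sigma_y Noise sd.
#' @param seed RNG seed.
#' @return A `behavior_spec`.
#' @export
behavior_spec <- function(targets, beta, beta0 = 0, sigma_y = 0.5, seed = 1L) {
  stopifnot(length(targets) == length(beta))
  structure(list(targets = targets, beta = beta, beta0 = beta0,
                 sigma_y = sigma_y, seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Generate behavioral scores tied to breadth descriptors
#'
#' `y = beta0 + sum(beta_d * z(descriptor_d)) + N(0, sigma_y^2)`, one score
#' per subject, enabling recovery tests of the iterative multilinear model.
#'
#' @param breadth A per-session `breadth_table`.
#' @param bspec A `behavior_spec`.
#' @return Data frame `subject`, `score`, plus attribute `"truth"`.
#' @export
generate_behavior <- function(breadth, bspec) {
  stopifnot(inherits(bspec, "behavior_spec"))
  X <- descriptor_matrix(breadth)
  missing <- setdiff(bspec$targets, colnames(X))
  if (length(missing)) {
    .stopf("fnmorph_spec_error", "unknown descriptor(s): %s",
           paste(missing, collapse = ", "))
  }
  Z <- vapply(bspec$targets, function(d) .zscore(X[, d])$z, numeric(nrow(X)))
  set.seed(bspec$seed)
  y <- bspec$beta0 + drop(Z %*% bspec$beta) +
    stats::rnorm(nrow(X), 0, bspec$sigma_y)
  out <- data.frame(subject = rownames(X), score = y, stringsAsFactors = FALSE)
  attr(out, "truth") <- bspec
  out
}
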