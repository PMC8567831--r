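#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) from the one-way ANOVA decomposition:
#' `ICC = (MSB - MSW) / (MSB + (n - 1) * MSW)` with `k` classes and `n`
#' replicates per class. Used throughout as a sensitivity / fingerprint
#' statistic: classes are tasks (task sensitivity) or subjects (subject
#' sensitivity), replicates are sessions, subjects or tasks depending on the
#' design. When all values are identical both mean squares vanish and the ICC
#' is undefined; it is returned as `NA` with `degenerate = TRUE`.
#'
#' @param x Numeric matrix with one row per class and one column per
#'   replicate (equal replicate counts, no missing values).
#' @param design Optional design label carried through to output.
#' @return An `icc` object: list with `icc`, `msb`, `msw`, `k`, `n`,
#'   `degenerate`, `design`.
#' @export
icc_oneway <- function(x, design = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    .stopf("fnmorph_validation_error", "need >= 2 classes and >= 2 replicates")
  }
  if (any(!is.finite(x))) {
    .stopf("fnmorph_validation_error", "missing or non-finite replicate values")
  }
  k <- nrow(x); n <- ncol(x)
  grand <- mean(x)
  cls <- rowMeans(x)
  ssb <- n * sum((cls - grand)^2)
  ssw <- sum((x - cls)^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (k * (n - 1))
  degenerate <- msb == 0 && msw == 0
  icc <- if (degenerate) NA_real_ else (msb - msw) / (msb + (n - 1) * msw)
  structure(list(icc = icc, msb = msb, msw = msw, k = k, n = n,
                 degenerate = degenerate, design = design),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("One-way ICC(1,1)%s: %.5f  (MSB %.4g, MSW %.4g; %d classes x %d replicates)\n",
              if (is.null(x$design)) "" else paste0(" [", x$design, "]"),
              x$icc, x$msb, x$msw, x$k, x$n))
  invisible(x)
}

#' Permutation null for an ICC
#'
#' Destroys the class structure by permuting observations across the whole
#' table `n_perm` times and recomputing the ICC; the empirical p-value uses
#' the add-one estimator `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param x Class-by-replicate matrix as in [icc_oneway()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `observed`, `null` (length `n_perm`), `p`.
#' @export
icc_null <- function(x, n_perm = 999L, seed = 1L) {
  if (n_perm < 100) .stopf("fnmorph_validation_error", "n_perm must be >= 100")
  x <- as.matrix(x)
  obs <- icc_oneway(x)$icc
  set.seed(seed)
  k <- nrow(x); n <- ncol(x); N <- k * n
  y <- as.numeric(x)
  g <- rep(seq_len(k), times = n)    # class index of each position (column-major)
  sst <- sum(y^2) - sum(y)^2 / N
  perms <- vapply(seq_len(n_perm), function(i) y[sample.int(N)], numeric(N))
  csum <- rowsum(perms, g)           # k x n_perm class sums
  ssb <- colSums(csum^2) / n - sum(y)^2 / N
  msb <- ssb / (k - 1)
  msw <- (sst - ssb) / (k * (n - 1))
  null <- (msb - msw) / (msb + (n - 1) * msw)
  p <- if (is.na(obs)) NA_real_ else (1 + sum(null >= obs)) / (n_perm + 1)
  list(observed = obs, null = null, p = p)
}

# reshape a long table into a class x replicate matrix; every class must have
# the same replicate count
.icc_matrix <- function(values, classes, replicates) {
  ok <- !is.na(values)
  values <- values[ok]; classes <- classes[ok]; replicates <- replicates[ok]
  tab <- table(classes)
  if (length(unique(tab)) != 1) {
    .stopf("fnmorph_validation_error",
           "unbalanced design: classes have %s replicates",
           paste(sort(unique(tab)), collapse = "/"))
  }
  split_vals <- split(values[order(classes, replicates)],
                      classes[order(classes, replicates)])
  do.call(rbind, split_vals)
}

#' Task- and subject-sensitivity ICC suite
#'
#' The three test-retest sensitivity designs applied to a cohort coordinate
#' table, per community and metric (TE and EE):
#' \describe{
#'   \item{`within_subject_task`}{per subject: 2 sessions (replicates) x
#'     task conditions (classes) — how well the metric separates tasks within
#'     one person.}
#'   \item{`cohort_task`}{per session: subjects (replicates) x task
#'     conditions (classes) — cohort-level task signatures.}
#'   \item{`subject`}{per session: task conditions (replicates) x subjects
#'     (classes) — subject fingerprints.}
#' }
#' The rest condition is excluded by default (the task designs are defined
#' over task conditions).
#'
#' @param coords A `coord_table`.
#' @param design One of the three design labels.
#' @param rest_label Rest condition label to exclude.
#' @param include_rest Keep the rest condition among the class/replicate
#'   conditions.
#' @param metrics Metrics to evaluate.
#' @return Data frame of ICC results (one row per community x metric and,
#'   for `within_subject_task`, per subject; for the other designs, per
#'   session).
#' @export
sensitivity_suite <- function(coords,
                              design = c("within_subject_task", "cohort_task", "subject"),
                              rest_label = "rest", include_rest = FALSE,
                              metrics = c("TE", "EE")) {
  design <- match.arg(design)
  if ("error" %in% names(coords)) coords <- coords[is.na(coords$error), ]
  if (!include_rest) coords <- coords[coords$condition != rest_label, ]
  if (nrow(coords) == 0) .stopf("fnmorph_validation_error", "no usable coordinate rows")
  out <- list()
  for (cm in sort(unique(coords$community))) {
    sub_c <- coords[coords$community == cm, ]
    for (metric in metrics) {
      if (design == "within_subject_task") {
        for (sj in sort(unique(sub_c$subject))) {
          s <- sub_c[sub_c$subject == sj, ]
          if (length(unique(s$session)) < 2) {
            .stopf("fnmorph_validation_error",
                   "within-subject design needs both sessions (subject %s)", sj)
          }
          m <- .icc_matrix(s[[metric]], s$condition, s$session)
          r <- icc_oneway(m, design)
          out[[length(out) + 1L]] <- data.frame(
            design = design, community = cm, metric = metric, subject = sj,
            session = NA_character_, icc = r$icc, msb = r$msb, msw = r$msw,
            stringsAsFactors = FALSE)
        }
      } else {
        for (se in sort(unique(sub_c$session))) {
          s <- sub_c[sub_c$session == se, ]
          m <- if (design == "cohort_task") {
            .icc_matrix(s[[metric]], s$condition, s$subject)
          } else {
            .icc_matrix(s[[metric]], s$subject, s$condition)
          }
          r <- icc_oneway(m, design)
          out[[length(out) + 1L]] <- data.frame(
            design = design, community = cm, metric = metric,
            subject = NA_character_, session = se, icc = r$icc,
            msb = r$msb, msw = r$msw, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank configural-breadth descriptors by subject sensitivity
#'
#' Each community contributes two descriptors (reconfiguration `R` and
#' preconfiguration `P`). Subject sensitivity is the one-way ICC with
#' subjects as classes and the two sessions as replicates. Descriptors are
#' returned in descending ICC order with a stable alphabetical tie-break —
#' the order in which the iterative multilinear model consumes them.
#'
#' @param breadth A per-session `breadth_table`.
#' @return Data frame `descriptor`, `community`, `measure`, `icc`, sorted.
#' @export
rank_descriptors <- function(breadth) {
  stopifnot(is.data.frame(breadth))
  if (length(unique(breadth$session)) < 2) {
    .stopf("fnmorph_validation_error",
           "subject-sensitivity ranking needs >= 2 sessions as replicates")
  }
  out <- list()
  for (cm in sort(unique(breadth$community))) {
    s <- breadth[breadth$community == cm, ]
    for (ms in c("R", "P")) {
      m <- .icc_matrix(s[[ms]], s$subject, s$session)
      out[[length(out) + 1L]] <- data.frame(
        descriptor = paste0(cm, "_", ms), community = cm, measure = ms,
        icc = icc_oneway(m)$icc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$icc, out$descriptor), ]
  rownames(out) <- NULL
  out
}
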