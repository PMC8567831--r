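#' Trapping efficiency of a community
#'
#' `TE = ||tau||_2 / L` (units: steps/weight), where `tau` is the mean time to
#' absorption of the community's nodes and `L` is the community's total exiting
#' strength (the L1 mass of the transient-to-absorbing block). The L2 norm in
#' the numerator accentuates between-configuration differences; the L1
#' denominator accounts for community size via its total leakage. Higher TE
#' means a more segregated (less integrated) module.
#'
#' @param summary An `absorption` object.
#' @param norm Numerator norm exponent; 2 (default) is the headline definition.
#' @return Scalar TE.
#' @export
trapping_efficiency <- function(summary, norm = 2) {
  stopifnot(inherits(summary, "absorption"))
  if (summary$exit_strength <= 0) {
    .stopf("fnmorph_degenerate_error", "community has zero exiting strength")
  }
  (sum(abs(summary$tau)^norm))^(1 / norm) / summary$exit_strength
}

#' Exit entropy of a community
#'
#' Normalized Shannon entropy of the preferential exit distribution `psi`:
#' `EE = -sum(psi * log(psi)) / log(n_abs)` (natural log; the base cancels in
#' the ratio; `0 * log 0 := 0`). EE = 1 for a uniform exit distribution
#' (homogeneous integration with the rest of the system); low EE indicates
#' preferential, specific exit channels. With a single exit node the
#' normalizer is log(1) = 0; the distribution on one support point is uniform,
#' so EE is defined as 1 with a warning.
#'
#' @param psi Probability vector over exit nodes.
#' @param n_abs Number of exit nodes; defaults to `length(psi)`.
#' @return List with `EE` (in (0, 1]) and raw entropy `H_e` (nats).
#' @export
exit_entropy <- function(psi, n_abs = length(psi)) {
  if (abs(sum(psi) - 1) > 1e-8 || any(psi < -1e-12)) {
    .stopf("fnmorph_validation_error", "psi must be a probability vector")
  }
  p <- psi[psi > 0]
  H <- -sum(p * log(p))
  if (n_abs == 1) {
    warning("single exit node: exit entropy defined as 1", call. = FALSE)
    return(list(EE = 1, H_e = H))
  }
  list(EE = H / log(n_abs), H_e = H)
}

#' Morphospace coordinate of one community
#'
#' Runs the absorbing-chain pipeline end to end and returns the community's
#' point `u(C) = (TE, EE)` in the 2D morphospace.
#'
#' @inheritParams absorption
#' @return One-row data frame: `community`, `TE`, `EE`, `H_e`, `n_abs`,
#'   `n_trans`.
#' @export
community_coordinates <- function(fc, partition, community,
                                  start = c("uniform", "strength")) {
  summ <- absorption(fc, partition, community, start = start)
  ee <- exit_entropy(summ$psi, length(summ$s_abs))
  data.frame(community = community,
             TE = trapping_efficiency(summ),
             EE = ee$EE, H_e = ee$H_e,
             n_abs = length(summ$s_abs), n_trans = length(summ$s_trans),
             stringsAsFactors = FALSE)
}

#' Morphospace coordinates for a whole cohort
#'
#' Computes `(TE, EE)` for every (subject, condition, session, community)
#' cell. Inputs are either a `manifest` (matrices loaded and sanitized from
#' disk) or an in-memory cohort from [generate_cohort()]. Per-cell failures
#' are recorded in the `error` column and the run continues.
#'
#' @param cohort A `manifest` or in-memory `cohort`.
#' @param partition A `partition`.
#' @param communities Communities to evaluate; default all in the partition.
#' @param start Start distribution for the exit aggregation.
#' @param symmetry_tol Passed to [sanitize_connectome()] for disk inputs.
#' @return A `coord_table` data frame: subject, condition, session, community,
#'   TE, EE, H_e, n_abs, error.
#' @export
cohort_coordinates <- function(cohort, partition, communities = NULL,
                               start = c("uniform", "strength"),
                               symmetry_tol = 1e-8) {
  start <- match.arg(start)
  in_memory <- inherits(cohort, "cohort")
  manifest <- if (in_memory) cohort$manifest else cohort
  if (nrow(manifest) == 0) .stopf("fnmorph_validation_error", "empty manifest")
  communities <- communities %||% sort(unique(unclass(partition)))
  # partition coverage problems are global, not per-cell: fail fast on the
  # first loadable matrix instead of flagging every row
  first <- tryCatch({
    if (in_memory) cohort$matrices[[1]] else
      sanitize_connectome(load_connectome(manifest$path[1]),
                          symmetry_tol = symmetry_tol)
  }, error = function(e) NULL)
  if (!is.null(first)) validate_partition(partition, first)
  rows <- vector("list", nrow(manifest) * length(communities))
  k <- 0L
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    fc <- tryCatch({
      if (in_memory) {
        cohort$matrices[[.cohort_key(rec$subject, rec$condition, rec$session)]]
      } else {
        sanitize_connectome(load_connectome(rec$path), symmetry_tol = symmetry_tol)
      }
    }, error = function(e) e)
    for (cm in communities) {
      k <- k + 1L
      base <- data.frame(subject = rec$subject, condition = rec$condition,
                         session = rec$session, community = cm,
                         TE = NA_real_, EE = NA_real_, H_e = NA_real_,
                         n_abs = NA_integer_, error = NA_character_,
                         stringsAsFactors = FALSE)
      if (inherits(fc, "error")) {
        base$error <- class(fc)[1]
      } else {
        cc <- tryCatch(community_coordinates(fc, partition, cm, start = start),
                       error = function(e) e)
        if (inherits(cc, "error")) {
          base$error <- class(cc)[1]
        } else {
          base$TE <- cc$TE; base$EE <- cc$EE; base$H_e <- cc$H_e
          base$n_abs <- cc$n_abs
        }
      }
      rows[[k]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coord_table", "data.frame")
  out
}

#' @export
print.coord_table <- function(x, ...) {
  ok <- is.na(x$error)
  cat(sprintf("Morphospace coordinates: %d rows (%d failed), %d subjects, %d conditions, %d communities\n",
              nrow(x), sum(!ok), length(unique(x$subject)),
              length(unique(x$condition)), length(unique(x$community))))
  if (any(ok)) {
    cat(sprintf("  TE in [%.4g, %.4g], EE in [%.4g, %.4g]\n",
                min(x$TE[ok]), max(x$TE[ok]), min(x$EE[ok]), max(x$EE[ok])))
  }
  invisible(x)
}

#' Plot morphospace coordinates
#'
#' Scatter of (TE, EE) points, colored by community.
#'
#' @param x A `coord_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coord_table <- function(x, ...) {
  ok <- is.na(x$error)
  comm <- factor(x$community[ok])
  graphics::plot(x$TE[ok], x$EE[ok], col = as.integer(comm), pch = 16,
                 xlab = "Trapping efficiency (steps/weight)",
                 ylab = "Exit entropy", ...)
  graphics::legend("bottomright", legend = levels(comm),
                   col = seq_along(levels(comm)), pch = 16, cex = 0.7)
  invisible(x)
}
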