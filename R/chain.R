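#' Transient and absorbing state space of a community
#'
#' For a community \eqn{C} embedded in the connectome, the random-walk model
#' uses the community's own nodes as transient states and, as absorbing states,
#' every outside node with a positive coupling to at least one community node:
#' a walker diffusing inside the community terminates the moment it steps onto
#' any such exit node. Node order follows the connectome's node order, so the
#' construction is deterministic.
#'
#' @param fc A sanitized `connectome`.
#' @param partition A `partition` covering the connectome.
#' @param community Community label.
#' @return A `state_space`: list with `community`, `s_trans`, `s_abs`
#'   (character vectors of node ids).
#' @export
build_state_space <- function(fc, partition, community) {
  stopifnot(inherits(fc, "connectome"))
  if (!isTRUE(fc$sanitized)) {
    .stopf("fnmorph_validation_error", "connectome must be sanitized first")
  }
  partition <- validate_partition(partition, fc)
  if (!community %in% partition) {
    .stopf("fnmorph_validation_error", "community '%s' not present in partition", community)
  }
  s_trans <- fc$node_ids[partition == community]
  outside <- fc$node_ids[partition != community]
  if (length(outside) == 0) {
    .stopf("fnmorph_degenerate_error",
           "community '%s' is the whole graph: no absorbing states", community)
  }
  # outside node is absorbing iff it couples positively to >= 1 community node
  touches <- colSums(fc$weights[s_trans, outside, drop = FALSE] > 0) > 0
  s_abs <- outside[touches]
  if (length(s_abs) == 0) {
    .stopf("fnmorph_degenerate_error",
           "community '%s' has no exit edges: no absorbing states", community)
  }
  structure(list(community = community, s_trans = s_trans, s_abs = s_abs),
            class = "state_space")
}

#' Induced community matrix
#'
#' Submatrix of the sanitized connectome over `S = S_trans U S_abs`, rows and
#' columns ordered transient-first.
#'
#' @param fc A sanitized `connectome`.
#' @param ss A `state_space`.
#' @return Numeric matrix `|S| x |S|`.
#' @export
community_matrix <- function(fc, ss) {
  s <- c(ss$s_trans, ss$s_abs)
  fc$weights[s, s, drop = FALSE]
}

#' Terminating Markov chain of a community
#'
#' Row-normalizes the induced community matrix by node strength (row sums over
#' all of `S`) to obtain `Q`, then forms the absorbing-chain transition matrix
#' `P = [[Q_tt, Q_ta], [0, I]]`: edges among absorbing states are discarded,
#' absorbing states are lock-in states.
#'
#' @param fc A sanitized `connectome`.
#' @param ss A `state_space`.
#' @return A `terminating_chain`: list with `P`, `q_tt`, `q_ta`, `s_trans`,
#'   `s_abs`, `strengths` (transient node strengths over `S`).
#' @export
terminating_chain <- function(fc, ss) {
  A <- community_matrix(fc, ss)
  nt <- length(ss$s_trans)
  na <- length(ss$s_abs)
  strength <- rowSums(A)[seq_len(nt)]
  dead <- strength <= 0
  if (any(dead)) {
    .stopf("fnmorph_isolated_node_error",
           "transient node(s) with zero strength: %s",
           paste(ss$s_trans[dead], collapse = ", "))
  }
  q_tt <- A[seq_len(nt), seq_len(nt), drop = FALSE] / strength
  q_ta <- A[seq_len(nt), nt + seq_len(na), drop = FALSE] / strength
  P <- matrix(0, nt + na, nt + na, dimnames = list(c(ss$s_trans, ss$s_abs),
                                                   c(ss$s_trans, ss$s_abs)))
  P[seq_len(nt), seq_len(nt)] <- q_tt
  P[seq_len(nt), nt + seq_len(na)] <- q_ta
  P[cbind(nt + seq_len(na), nt + seq_len(na))] <- 1
  structure(list(P = P, q_tt = q_tt, q_ta = q_ta,
                 s_trans = ss$s_trans, s_abs = ss$s_abs,
                 strengths = strength,
                 exit_strength = sum(A[seq_len(nt), nt + seq_len(na)])),
            class = "terminating_chain")
}

#' Absorption quantities of a terminating chain
#'
#' Solves the absorbing-chain algebra: fundamental matrix
#' `Z = (I - Q_tt)^-1` (expected visit counts before absorption), mean time to
#' absorption `tau = Z 1`, absorption probability matrix `Psi = Z Q_ta`, the
#' preferential exit distribution `psi` (average of `Psi` rows over start
#' nodes), and the community's total exiting strength `L`. Linear solves are
#' used rather than an explicit inverse for `tau` and `Psi`.
#'
#' @param chain A `terminating_chain`.
#' @param start Start distribution over transient nodes used for `psi`:
#'   `"uniform"` (default) or `"strength"` (proportional to node strength).
#' @return An `absorption` object: list with `Z`, `tau`, `Psi`, `psi`,
#'   `exit_strength`, `s_trans`, `s_abs`.
#' @export
absorption_summary <- function(chain, start = c("uniform", "strength")) {
  start <- match.arg(start)
  nt <- length(chain$s_trans)
  M <- diag(nt) - chain$q_tt
  res <- tryCatch(
    list(Z = solve(M), tau = solve(M, rep(1, nt)), Psi = solve(M, chain$q_ta)),
    error = function(e) NULL
  )
  if (is.null(res) || any(!is.finite(res$tau))) {
    .stopf("fnmorph_absorption_unreachable_error",
           "I - P_tt is singular: some transient state cannot reach an absorbing state")
  }
  dimnames(res$Z) <- list(chain$s_trans, chain$s_trans)
  names(res$tau) <- chain$s_trans
  dimnames(res$Psi) <- list(chain$s_trans, chain$s_abs)
  out <- structure(
    list(Z = res$Z, tau = res$tau, Psi = res$Psi,
         psi = exit_distribution(res$Psi, chain, start),
         exit_strength = chain$exit_strength,
         s_trans = chain$s_trans, s_abs = chain$s_abs, start = start),
    class = "absorption")
  out
}

#' Preferential exit distribution
#'
#' Aggregates the rows of the absorption probability matrix into one
#' probability vector over exit nodes. The default start distribution over
#' transient nodes is uniform (the minimal assumption); a strength-weighted
#' start is available.
#'
#' @param Psi Row-stochastic absorption probability matrix.
#' @param chain The `terminating_chain` (needed for strength weighting).
#' @param start `"uniform"` or `"strength"`.
#' @return Probability vector over `S_abs` summing to 1.
#' @export
exit_distribution <- function(Psi, chain = NULL, start = c("uniform", "strength")) {
  start <- match.arg(start)
  rs <- rowSums(Psi)
  if (any(abs(rs - 1) > 1e-8)) {
    .stopf("fnmorph_validation_error", "Psi rows must sum to 1 (max dev %.3g)",
           max(abs(rs - 1)))
  }
  if (start == "uniform") {
    colMeans(Psi)
  } else {
    w <- chain$strengths / sum(chain$strengths)
    drop(crossprod(Psi, w))
  }
}

#' Run the absorbing-chain pipeline for one community
#'
#' Convenience wrapper: state space, terminating chain, absorption algebra.
#'
#' @inheritParams build_state_space
#' @inheritParams absorption_summary
#' @return An `absorption` object.
#' @export
absorption <- function(fc, partition, community, start = c("uniform", "strength")) {
  ss <- build_state_space(fc, partition, community)
  chain <- terminating_chain(fc, ss)
  withCallingHandlers(
    absorption_summary(chain, start = start),
    fnmorph_error = function(e) {
      e$message <- sprintf("[community %s] %s", community, e$message)
      stop(e)
    }
  )
}

#' @export
print.absorption <- function(x, ...) {
  cat(sprintf("Absorbing-chain summary: %d transient, %d absorbing states\n",
              length(x$s_trans), length(x$s_abs)))
  cat(sprintf("  mean time to absorption: %.3f to %.3f steps\n",
              min(x$tau), max(x$tau)))
  cat(sprintf("  total exiting strength: %.4g\n", x$exit_strength))
  invisible(x)
}

#' Monte-Carlo simulation of the terminating chain
#'
#' Independent random walkers are released from each transient start node and
#' stepped through `P` until absorbed; empirical mean steps to absorption and
#' exit frequencies estimate `tau` and `Psi`. This is the independent oracle
#' against which the matrix algebra is validated.
#'
#' @param chain A `terminating_chain`.
#' @param n_walkers Walkers per start node.
#' @param max_steps Cap on walk length; walkers hitting the cap are counted in
#'   `n_exceeded` (their steps are recorded censored at the cap).
#' @param seed RNG seed (required for reproducibility).
#' @return List with `tau_hat`, `tau_se`, `Psi_hat` (exit frequencies),
#'   `n_exceeded`.
#' @export
simulate_absorption <- function(chain, n_walkers = 1000L, max_steps = 100000L,
                                seed = 1L) {
  stopifnot(n_walkers >= 1)
  set.seed(seed)
  nt <- length(chain$s_trans)
  na <- length(chain$s_abs)
  P <- chain$P
  tau_hat <- tau_se <- numeric(nt)
  psi_hat <- matrix(0, nt, na, dimnames = list(chain$s_trans, chain$s_abs))
  n_exceeded <- 0L
  for (s0 in seq_len(nt)) {
    state <- rep.int(s0, n_walkers)
    steps <- integer(n_walkers)
    exit <- integer(n_walkers)
    active <- seq_len(n_walkers)
    t <- 0L
    while (length(active) && t < max_steps) {
      t <- t + 1L
      cur <- state[active]
      nxt <- integer(length(cur))
      for (s in unique(cur)) {
        idx <- cur == s
        nxt[idx] <- sample.int(nt + na, sum(idx), replace = TRUE, prob = P[s, ])
      }
      absorbed <- nxt > nt
      done <- active[absorbed]
      steps[done] <- t
      exit[done] <- nxt[absorbed] - nt
      state[active] <- nxt
      active <- active[!absorbed]
    }
    if (length(active)) {
      n_exceeded <- n_exceeded + length(active)
      steps[active] <- max_steps
    }
    tau_hat[s0] <- mean(steps)
    tau_se[s0] <- stats::sd(steps) / sqrt(n_walkers)
    tab <- tabulate(exit, nbins = na)
    psi_hat[s0, ] <- tab / sum(tab)
  }
  names(tau_hat) <- names(tau_se) <- chain$s_trans
  list(tau_hat = tau_hat, tau_se = tau_se, Psi_hat = psi_hat,
       n_exceeded = n_exceeded)
}
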