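# F2 genotype hidden Markov model over states (AA, AB, BB).
#
# Stationary prior (1/4, 1/2, 1/4); transitions between positions d cM apart
# come from two independent meioses each recombining with the Haldane
# r = (1 - exp(-d/50)) / 2; emissions are the symmetric miscall model
# (correct call with probability 1 - e, each wrong call e/2; missing calls
# emit uniformly).

#' @noRd
f2_transition <- function(r) {
  matrix(c(
    (1 - r)^2, 2 * r * (1 - r), r^2,
    r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
    r^2, 2 * r * (1 - r), (1 - r)^2
  ), 3, 3, byrow = TRUE)
}

# Core forward-backward, vectorized over individuals.
# obs_idx: n_pos x n_ind integer matrix (1 = AA, 2 = AB, 3 = BB, NA = missing
# call or pseudo-marker position). Returns posterior and leave-one-out
# posterior arrays [n_pos, n_ind, 3] plus per-individual log-likelihoods.
#' @noRd
f2_hmm_engine <- function(obs_idx, pos_cM, error_prob) {
  n_pos <- nrow(obs_idx); n_ind <- ncol(obs_idx)
  prior <- c(0.25, 0.5, 0.25)
  E_lookup <- matrix(error_prob / 2, 3, 3)
  diag(E_lookup) <- 1 - error_prob

  emis <- function(t) {
    e <- matrix(1, n_ind, 3)
    o <- obs_idx[t, ]
    ok <- !is.na(o)
    if (any(ok)) e[ok, ] <- E_lookup[o[ok], , drop = FALSE]
    e
  }
  Ts <- lapply(seq_len(max(n_pos - 1, 0)), function(k) {
    f2_transition(haldane_r(max(pos_cM[k + 1] - pos_cM[k], 0)))
  })

  phi <- array(0, c(n_pos, n_ind, 3))      # filtered (scaled forward)
  pre <- array(0, c(n_pos, n_ind, 3))      # one-step-ahead prediction
  logc <- matrix(0, n_pos, n_ind)
  pre[1, , ] <- matrix(prior, n_ind, 3, byrow = TRUE)
  for (t in seq_len(n_pos)) {
    if (t > 1) {
      prev <- matrix(phi[t - 1, , ], n_ind, 3)
      pre[t, , ] <- prev %*% Ts[[t - 1]]
    }
    a <- matrix(pre[t, , ], n_ind, 3)
    f <- a * emis(t)
    cs <- rowSums(f)
    logc[t, ] <- log(cs)
    phi[t, , ] <- f / cs
  }

  beta <- array(0, c(n_pos, n_ind, 3))
  beta[n_pos, , ] <- 1
  for (t in seq(n_pos - 1, length.out = max(n_pos - 1, 0), by = -1)) {
    nb <- matrix(beta[t + 1, , ], n_ind, 3)
    b <- (emis(t + 1) * nb) %*% t(Ts[[t]])
    beta[t, , ] <- b / rowSums(b)
  }

  post <- phi * beta
  post <- post / as.vector(apply(post, c(1, 2), sum))
  loo <- pre * beta
  loo <- loo / as.vector(apply(loo, c(1, 2), sum))
  list(post = post, loo = loo, loglik = colSums(logc))
}

# Observation index matrix for the given markers (n_pos x n_ind).
#' @noRd
obs_matrix <- function(g, marker_ids) {
  m <- matrix(match(g$calls[marker_ids, , drop = FALSE], GENO_LEVELS),
              nrow = length(marker_ids))
  m
}

#' @noRd
f2_hmm_forward <- function(g, marker_ids, pos_cM, error_prob) {
  ord <- order(pos_cM)
  eng <- f2_hmm_engine(obs_matrix(g, marker_ids[ord]), pos_cM[ord], error_prob)
  list(loglik = eng$loglik)
}

# Posterior genotype probabilities at marker positions; leave_one_out = TRUE
# conditions each marker's posterior on the flanking markers only.
# Returns array [n_markers, n_ind, 3] in the input marker order.
#' @noRd
f2_hmm_posteriors <- function(g, marker_ids, pos_cM, error_prob,
                              leave_one_out = FALSE) {
  ord <- order(pos_cM)
  eng <- f2_hmm_engine(obs_matrix(g, marker_ids[ord]), pos_cM[ord], error_prob)
  res <- if (leave_one_out) eng$loo else eng$post
  res[order(ord), , , drop = FALSE]
}
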