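# Brute-force oracles: exhaustive enumeration over all 3^L hidden paths.
# Deliberately independent of the package's forward-backward / Viterbi
# implementation (direct products of parameter entries, no recursion).

# Joint probability of one hidden path and the observations (obs: L x 4
# matrix of codes with NA).
oracle_path_prob <- function(params, path, obs) {
  p <- params$pi[path[1]]
  L <- length(path)
  if (L >= 2) {
    for (t in 2:L) {
      p <- p * params$trans[path[t - 1], path[t]]
    }
  }
  for (t in seq_len(L)) {
    for (s in 1:4) {
      if (!is.na(obs[t, s])) {
        p <- p * params$emissions[[s]][path[t], obs[t, s]]
      }
    }
  }
  p
}

oracle_all_paths <- function(L) {
  as.matrix(expand.grid(rep(list(1:3), L)))
}

# Marginal likelihood, per-week posteriors, per-step pair posteriors, and
# the most probable path, all by full enumeration.
oracle_enumerate <- function(params, obs) {
  L <- nrow(obs)
  paths <- oracle_all_paths(L)
  probs <- apply(paths, 1, function(pp) oracle_path_prob(params, pp, obs))
  lik <- sum(probs)
  gamma <- matrix(0, L, 3)
  for (t in seq_len(L)) {
    for (i in 1:3) {
      gamma[t, i] <- sum(probs[paths[, t] == i]) / lik
    }
  }
  xi <- NULL
  if (L >= 2) {
    xi <- array(0, c(L - 1, 3, 3))
    for (t in seq_len(L - 1)) {
      for (i in 1:3) {
        for (j in 1:3) {
          sel <- paths[, t] == i & paths[, t + 1] == j
          xi[t, i, j] <- sum(probs[sel]) / lik
        }
      }
    }
  }
  best <- which.max(probs)
  list(loglik = log(lik), gamma = gamma, xi = xi,
       viterbi = unname(paths[best, ]),
       viterbi_logprob = log(probs[best]))
}

# Random valid parameters and a random partially observed sequence.
random_params <- function() {
  rnorm_mat <- function() {
    m <- matrix(stats::runif(9, 0.05, 1), 3, 3)
    m / rowSums(m)
  }
  pi <- stats::runif(3, 0.1, 1)
  emissions <- lapply(seq_len(4), function(s) rnorm_mat())
  names(emissions) <- source_ids()
  hmm_params(pi = pi / sum(pi), trans = rnorm_mat(),
             emissions = emissions)
}

random_obs <- function(L, p_missing = 0.5) {
  m <- matrix(sample(c(NA, 1:3), L * 4, replace = TRUE,
                     prob = c(p_missing, rep((1 - p_missing) / 3, 3))),
              L, 4)
  storage.mode(m) <- "integer"
  m
}
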