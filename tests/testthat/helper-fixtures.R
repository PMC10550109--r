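# Small in-code fixtures shared across test files.

make_panel <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(district_id = r[[1]], district_name = r[[2]], state = r[[3]],
               week = r[[4]], source = r[[5]], modality = r[[6]])
  }))
  tibble::as_tibble(df)
}

# Identity-emission, fully observed parameters: every source reports the
# truth with certainty (up to a tiny off-diagonal mass so rows are valid
# under the strict stochasticity check yet decoding is unambiguous).
near_identity_params <- function(eps = 0) {
  if (eps == 0) {
    eye <- diag(3)
  } else {
    eye <- diag(3) * (1 - 2 * eps) + eps
  }
  emissions <- lapply(1:4, function(s) eye)
  names(emissions) <- source_ids()
  hmm_params(pi = rep(1 / 3, 3),
             trans = matrix(1 / 3, 3, 3),
             emissions = emissions)
}

# Cache for the expensive shared recovery run used by the acceptance tests.
recovery_cache <- new.env(parent = emptyenv())

shared_recovery <- function() {
  if (is.null(recovery_cache$result)) {
    spec <- reference_generator_spec(n_districts = 3000, n_weeks = 43,
                                     seed = 20210901)
    recovery_cache$spec <- spec
    recovery_cache$result <- recovery_experiment(spec, seed = 1,
                                                 restarts = 5,
                                                 tol = 1e-6, max_iter = 500)
  }
  recovery_cache$result
}
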