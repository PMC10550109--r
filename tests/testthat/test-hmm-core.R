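test_that("emission probability multiplies present channels and marginalizes missing ones", {
  p <- reference_hmm_params()
  # all four sources missing: full marginalization
  expect_identical(emission_prob(p, 1, rep(NA_integer_, 4)), 1)
  # single present source reads its matrix cell (BURBIO in-person fidelity)
  expect_equal(emission_prob(p, "in_person",
                             c(BURBIO = "in_person", MCH = NA, R2LT = NA,
                               SD = NA)),
               p$emissions$BURBIO[3, 3])
  # two present sources multiply (R2LT and SD both reporting hybrid)
  expect_equal(emission_prob(p, "hybrid",
                             c(BURBIO = NA, MCH = NA, R2LT = "hybrid",
                               SD = "hybrid")),
               p$emissions$R2LT[2, 2] * p$emissions$SD[2, 2])
  expect_equal(emission_prob(p, "hybrid",
                             c(BURBIO = NA, MCH = NA, R2LT = "hybrid",
                               SD = "hybrid")),
               0.997 * 0.863, tolerance = 0.01)
})

test_that("sequence log-likelihood has its closed-form degenerate values", {
  p <- reference_hmm_params()
  # all-missing sequence marginalizes to probability 1
  expect_equal(sequence_loglik(p, matrix(NA_integer_, 1, 4)), 0)
  expect_equal(sequence_loglik(p, matrix(NA_integer_, 7, 4)), 0)
  # uniform pi, one perfect source, length 1: probability 1/3
  q <- near_identity_params()
  obs <- matrix(c(2L, NA, NA, NA), 1, 4)
  expect_equal(sequence_loglik(q, obs), log(1 / 3))
})

test_that("loglik, posteriors, and Viterbi agree with exhaustive enumeration", {
  withr::local_seed(101)
  for (k in 1:25) {
    L <- sample(2:6, 1)
    p <- random_params()
    obs <- random_obs(L)
    orc <- oracle_enumerate(p, obs)
    fb <- forward_backward(p, obs)
    expect_equal(fb$loglik, orc$loglik, tolerance = 1e-10)
    expect_equal(unname(fb$gamma), orc$gamma, tolerance = 1e-10)
    expect_equal(fb$xi, orc$xi, tolerance = 1e-10)
    v <- viterbi(p, obs)
    # any maximizer is acceptable; compare achieved joint log-probability
    expect_equal(log(oracle_path_prob(p, v, obs)), orc$viterbi_logprob,
                 tolerance = 1e-10)
  }
})

test_that("forward-backward satisfies its internal consistency identities", {
  withr::local_seed(202)
  p <- random_params()
  obs <- random_obs(8, p_missing = 0.3)
  fb <- forward_backward(p, obs)
  expect_equal(unname(rowSums(fb$gamma)), rep(1, 8), tolerance = 1e-9)
  for (t in 1:7) {
    expect_equal(sum(fb$xi[t, , ]), 1, tolerance = 1e-9)
    # row-marginal of xi over next state equals gamma at t
    expect_equal(unname(rowSums(fb$xi[t, , ])), unname(fb$gamma[t, ]),
                 tolerance = 1e-9)
  }
  expect_equal(fb$loglik, sequence_loglik(p, obs))
})

test_that("no-information and deterministic limits decode as expected", {
  # all-missing with uniform pi and uniform transitions: uniform posteriors
  p_unif <- hmm_params(
    pi = rep(1 / 3, 3), trans = matrix(1 / 3, 3, 3),
    emissions = setNames(lapply(1:4, function(s) diag(3)), source_ids()))
  fb <- forward_backward(p_unif, matrix(NA_integer_, 5, 4))
  expect_equal(unname(fb$gamma), matrix(1 / 3, 5, 3), tolerance = 1e-12)

  # identity emissions, fully observed consistent sequence: point masses
  q <- near_identity_params()
  seqn <- c(1L, 1L, 2L, 3L, 3L)
  obs <- matrix(rep(seqn, 4), ncol = 4)
  fbq <- forward_backward(q, obs)
  expect_equal(unname(fbq$gamma[cbind(1:5, seqn)]), rep(1, 5))
  expect_equal(viterbi(q, obs), seqn)

  # all-missing under sticky dynamics with pi concentrated on in-person:
  # the Viterbi path stays in-person (self-transition 0.983 dominates)
  ref <- reference_hmm_params()
  sticky <- hmm_params(pi = c(0.001, 0.001, 0.998), trans = ref$trans,
                       emissions = ref$emissions)
  expect_equal(viterbi(sticky, matrix(NA_integer_, 10, 4)), rep(3L, 10))
})

test_that("Baum-Welch iteration control and degenerate fits behave", {
  sim <- simulate_panel(reference_generator_spec(n_districts = 30,
                                                 n_weeks = 10, seed = 31))
  # tol = Inf: exactly one EM iteration, trace length 2
  fit1 <- fit_hmm(sim$panel, seed = 1, restarts = 1, tol = Inf)
  expect_equal(fit1$n_iter, 1L)
  expect_length(fit1$loglik_trace, 2)

  # empty panel is a fit error
  expect_error(fit_hmm(sim$panel[0, ]), "no observations")

  # a single district fully observed by one perfect source drives that
  # source's emission rows (on visited states) toward identity
  weeks <- paste0("2020-W", 36:45)
  obs_seq <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  panel1 <- tibble::tibble(
    district_id = "d1", district_name = "A", state = "OH",
    week = weeks, source = "R2LT", modality = modality_label(obs_seq))
  fitp <- fit_hmm(panel1, seed = 2, restarts = 3, max_iter = 200)
  labeling <- derive_labeling(panel1, decode_panel(panel1, fitp))
  aligned <- align_params(fitp$params, labeling)
  expect_gt(min(diag(aligned$emissions$R2LT)), 0.95)
})

test_that("EM log-likelihood is non-decreasing and improves on its start", {
  sim <- simulate_panel(reference_generator_spec(n_districts = 120,
                                                 n_weeks = 15, seed = 77))
  fit <- fit_hmm(sim$panel, seed = 3, restarts = 2, max_iter = 60)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_gt(fit$loglik, fit$loglik_trace[1])
  expect_equal(fit$loglik, max(fit$restarts$loglik))
})

test_that("a source with no observations keeps its initialization untouched", {
  spec <- generator_spec(n_districts = 80, n_weeks = 12,
                         params = reference_hmm_params(),
                         presence = c(BURBIO = 0, MCH = 0.5, R2LT = 0.8,
                                      SD = 0.5), seed = 41)
  sim <- simulate_panel(spec)
  init <- init_hmm_params(99)
  fit <- fit_hmm(sim$panel, init = init, max_iter = 25)
  # BURBIO never reports, so its emission rows have zero expected counts
  # and must never be re-estimated
  expect_identical(fit$params$emissions$BURBIO, init$emissions$BURBIO)
  expect_false(identical(fit$params$emissions$R2LT, init$emissions$R2LT))
})

test_that("relabeling hidden states permutes decoding output identically", {
  withr::local_seed(55)
  p <- random_params()
  obs <- random_obs(7, p_missing = 0.3)
  perm <- c(3L, 1L, 2L)  # hidden state h of q represents state perm[h] of p
  q <- hmm_params(
    pi = p$pi[perm],
    trans = p$trans[perm, perm],
    emissions = lapply(p$emissions, function(e) e[perm, ]))
  fb_p <- forward_backward(p, obs)
  fb_q <- forward_backward(q, obs)
  expect_equal(fb_q$loglik, fb_p$loglik, tolerance = 1e-10)
  expect_equal(unname(fb_q$gamma), unname(fb_p$gamma[, perm]),
               tolerance = 1e-10)
  expect_equal(perm[viterbi(q, obs)], viterbi(p, obs))
})

test_that("decoding a panel matches per-sequence smoothing and flags confidence", {
  sim <- simulate_panel(reference_generator_spec(n_districts = 12,
                                                 n_weeks = 9, seed = 13))
  fitp <- reference_hmm_params()
  dec <- decode_panel(sim$panel, fitp)
  expect_s3_class(dec, "decoded_panel")
  expect_equal(rowSums(as.matrix(dec[, c("p1", "p2", "p3")])),
               rep(1, nrow(dec)), tolerance = 1e-9)
  expect_true(all(dec$map_state %in% 1:3))
  expect_true(all(dec$viterbi_state %in% 1:3))
  expect_equal(dec$confidence,
               pmax(dec$p1, dec$p2, dec$p3))

  # cross-check one district against the single-sequence API
  d1 <- sort(unique(sim$panel$district_id))[1]
  rows1 <- dplyr::filter(sim$panel, district_id == d1)
  fb1 <- forward_backward(fitp, rows1)
  got <- dplyr::filter(tibble::as_tibble(dec), district_id == d1)
  expect_equal(as.matrix(got[, c("p1", "p2", "p3")]), unname(fb1$gamma),
               ignore_attr = TRUE, tolerance = 1e-12)
})
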