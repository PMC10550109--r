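# Core HMM machinery: factored categorical emissions over four source
# channels, scaled forward-backward, Baum-Welch over many independent
# district sequences, Viterbi and posterior decoding.
#
# Internal representation: a panel becomes an integer array obs[d, t, s]
# (district x local week x source) holding modality codes with NA = not
# reported. Sequences of unequal length are right-padded with all-missing
# weeks; an all-missing week has emission probability 1 in every state, so
# padding changes neither the likelihood nor the posteriors of real weeks,
# and the per-week scaling constant of a padded week is exactly 1.

EMISSION_FLOOR <- 1e-10

# ---- panel <-> array -----------------------------------------------------

panel_to_obs <- function(panel) {
  panel <- validate_panel(panel)
  if (nrow(panel) == 0) {
    stop("panel contains no observations", call. = FALSE)
  }
  districts <- panel |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      district_name = dplyr::first(.data$district_name),
      state = dplyr::first(.data$state),
      .groups = "drop") |>
    dplyr::arrange(.data$district_id)
  d_idx <- match(panel$district_id, districts$district_id)
  monday <- iso_week_monday(panel$week)
  first <- as.Date(tapply(monday, d_idx, min), origin = "1970-01-01")
  last <- as.Date(tapply(monday, d_idx, max), origin = "1970-01-01")
  len <- as.integer((last - first) / 7) + 1L
  D <- nrow(districts)
  W <- max(len)
  t_idx <- as.integer((monday - first[d_idx]) / 7) + 1L
  s_idx <- match(panel$source, source_ids())
  obs <- array(NA_integer_, c(D, W, 4))
  obs[cbind(d_idx, t_idx, s_idx)] <- modality_code(panel$modality)
  list(obs = obs, len = len, W = W, D = D,
       districts = dplyr::mutate(districts,
                                 start_week = date_iso_week(first)))
}

# Per-district week identifiers for local indices 1..len.
obs_week_grid <- function(obsdata) {
  start <- iso_week_monday(obsdata$districts$start_week)
  purrr::map2(start, obsdata$len,
              function(s, l) date_iso_week(s + 7 * (seq_len(l) - 1)))
}

# Coerce a single-sequence observation input (W x 4 matrix of codes with NA,
# or a long data frame with week/source/modality) to the canonical matrix.
obs_matrix <- function(obs) {
  if (is.data.frame(obs)) {
    required <- c("week", "source", "modality")
    if (!all(required %in% names(obs))) {
      stop("a sequence data frame needs columns week, source, modality",
           call. = FALSE)
    }
    monday <- iso_week_monday(obs$week)
    t_idx <- as.integer((monday - min(monday)) / 7) + 1L
    m <- matrix(NA_integer_, max(t_idx), 4,
                dimnames = list(NULL, source_ids()))
    m[cbind(t_idx, match(obs$source, source_ids()))] <-
      modality_code(obs$modality)
    return(m)
  }
  obs <- as.matrix(obs)
  if (ncol(obs) != 4) {
    stop("a sequence matrix must have 4 columns (one per source)",
         call. = FALSE)
  }
  storage.mode(obs) <- "integer"
  if (!all(obs %in% c(NA, 1:3))) {
    stop("sequence entries must be modality codes 1..3 or NA",
         call. = FALSE)
  }
  colnames(obs) <- source_ids()
  obs
}

# ---- emission field ------------------------------------------------------

# b[d, t, i] = P(observed source reports at (d, t) | hidden state i);
# missing channels contribute factor 1 (they are marginalized out).
emission_field <- function(params, obs) {
  D <- dim(obs)[1]
  W <- dim(obs)[2]
  b <- array(1, c(D, W, 3))
  for (s in seq_along(source_ids())) {
    o <- obs[, , s, drop = FALSE]
    dim(o) <- c(D, W)
    idx <- which(!is.na(o))
    if (length(idx) == 0) next
    ov <- o[idx]
    E <- params$emissions[[s]]
    for (i in 1:3) {
      slice <- b[, , i]
      slice[idx] <- slice[idx] * E[i, ][ov]
      b[, , i] <- slice
    }
  }
  b
}

#' Emission probability of one week's multi-source report vector
#'
#' The four sources report conditionally independently given the true
#' modality, so the probability of a week's observed report vector is the
#' product over *present* sources of the corresponding emission-matrix
#' entry; sources that did not report are marginalized out and contribute a
#' factor of 1. An all-missing week therefore has probability exactly 1 in
#' every state.
#'
#' @param params An [hmm_params()] object.
#' @param state True modality (code 1..3 or label).
#' @param obs_vec Length-4 vector of reported modalities (codes or labels)
#'   with `NA` for sources that did not report; names, if given, must be
#'   [source_ids()] (unnamed vectors are taken in that order).
#' @return A single probability.
#' @examples
#' p <- reference_hmm_params()
#' emission_prob(p, "in_person", c(BURBIO = "in_person", MCH = NA,
#'                                 R2LT = NA, SD = NA))
#' @export
emission_prob <- function(params, state, obs_vec) {
  check_hmm_params(params)
  if (is.character(state)) state <- modality_code(state)
  stopifnot(length(state) == 1, state %in% 1:3)
  if (length(obs_vec) != 4) {
    stop("obs_vec must have one entry per source", call. = FALSE)
  }
  if (!is.null(names(obs_vec))) {
    if (!setequal(names(obs_vec), source_ids())) {
      stop("obs_vec names must be ", paste(source_ids(), collapse = ", "),
           call. = FALSE)
    }
    obs_vec <- obs_vec[source_ids()]
  }
  if (is.character(obs_vec)) {
    codes <- rep(NA_integer_, 4)
    codes[!is.na(obs_vec)] <- modality_code(obs_vec[!is.na(obs_vec)])
  } else {
    codes <- as.integer(obs_vec)
  }
  prob <- 1
  for (s in seq_along(source_ids())) {
    if (!is.na(codes[s])) {
      prob <- prob * params$emissions[[s]][state, codes[s]]
    }
  }
  prob
}

# ---- scaled forward-backward (vectorized over districts) -----------------

# Returns scaled forward/backward variables, per-week scaling constants,
# smoothed posteriors gamma, and per-district log-likelihoods.
engine_forward_backward <- function(params, obs, len, b = NULL) {
  D <- dim(obs)[1]
  W <- dim(obs)[2]
  if (is.null(b)) b <- emission_field(params, obs)
  trans <- params$trans
  ahat <- array(NA_real_, c(D, W, 3))
  cs <- matrix(NA_real_, D, W)
  a <- matrix(params$pi, D, 3, byrow = TRUE) * matrix(b[, 1, ], ncol = 3)
  ct <- rowSums(a)
  dead <- ct == 0
  if (any(dead)) a[dead, ] <- 1 / 3
  cs[, 1] <- ct
  ahat[, 1, ] <- a / pmax(ct, .Machine$double.xmin)
  if (W >= 2) {
    for (t in 2:W) {
      a <- (matrix(ahat[, t - 1, ], ncol = 3) %*% trans) *
        matrix(b[, t, ], ncol = 3)
      ct <- rowSums(a)
      dead <- ct == 0
      if (any(dead)) a[dead, ] <- 1 / 3
      cs[, t] <- ct
      ahat[, t, ] <- a / pmax(ct, .Machine$double.xmin)
    }
  }
  bhat <- array(NA_real_, c(D, W, 3))
  bhat[, W, ] <- 1
  if (W >= 2) {
    for (t in (W - 1):1) {
      v <- matrix(bhat[, t + 1, ], ncol = 3) * matrix(b[, t + 1, ], ncol = 3)
      bhat[, t, ] <- (v %*% t(trans)) /
        pmax(cs[, t + 1], .Machine$double.xmin)
    }
  }
  gamma <- ahat * bhat
  loglik_d <- rowSums(log(cs))
  list(gamma = gamma, ahat = ahat, bhat = bhat, cs = cs, b = b,
       loglik_d = loglik_d, loglik = sum(loglik_d))
}

# Pooled expected transition counts sum_t xi_t over real (unpadded) steps.
engine_xi_sum <- function(params, fb, len) {
  W <- dim(fb$gamma)[2]
  trans <- params$trans
  xi_sum <- matrix(0, 3, 3)
  if (W < 2) return(xi_sum)
  for (t in 1:(W - 1)) {
    act <- which(len > t)
    if (length(act) == 0) next
    U <- matrix(fb$ahat[act, t, ], ncol = 3)
    V <- matrix(fb$bhat[act, t + 1, ], ncol = 3) *
      matrix(fb$b[act, t + 1, ], ncol = 3) /
      pmax(fb$cs[act, t + 1], .Machine$double.xmin)
    xi_sum <- xi_sum + crossprod(U, V) * trans
  }
  xi_sum
}

#' Forward-backward smoothing for one district sequence
#'
#' Computes, by the scaled forward-backward recursions, the per-week
#' posterior distribution over hidden modalities (`gamma`), the per-step
#' posterior transition distributions (`xi`), and the log-likelihood of the
#' observed sequence with missing reports marginalized out.
#'
#' @param params An [hmm_params()] object.
#' @param obs One district's observations: a `W x 4` matrix of modality
#'   codes (columns in [source_ids()] order, `NA` = not reported) or a long
#'   data frame with columns `week`, `source`, `modality`.
#' @return A list with `gamma` (`W x 3`, rows sum to 1), `xi`
#'   (`(W-1) x 3 x 3`, each slice sums to 1; `NULL` for `W = 1`), and
#'   `loglik`.
#' @seealso [sequence_loglik()], [viterbi()], [decode_panel()]
#' @export
forward_backward <- function(params, obs) {
  check_hmm_params(params)
  m <- obs_matrix(obs)
  W <- nrow(m)
  # obs_matrix gives W x 4; reshape so dim 1 indexes the single district
  arr <- aperm(array(m, c(W, 4, 1)), c(3, 1, 2))
  fb <- engine_forward_backward(params, arr, len = W)
  gamma <- matrix(fb$gamma[1, , ], ncol = 3)
  colnames(gamma) <- modality_labels()
  xi <- NULL
  if (W >= 2) {
    xi <- array(NA_real_, c(W - 1, 3, 3))
    for (t in 1:(W - 1)) {
      U <- fb$ahat[1, t, ]
      V <- fb$bhat[1, t + 1, ] * fb$b[1, t + 1, ] /
        pmax(fb$cs[1, t + 1], .Machine$double.xmin)
      xi[t, , ] <- outer(U, V) * params$trans
    }
  }
  list(gamma = gamma, xi = xi, loglik = fb$loglik)
}

#' Log-likelihood of one district's observation sequence
#'
#' @inheritParams forward_backward
#' @return The log of the marginal probability of the observed reports,
#'   missing entries marginalized out. A fully missing sequence has
#'   log-likelihood 0.
#' @export
sequence_loglik <- function(params, obs) {
  forward_backward(params, obs)$loglik
}

# ---- Viterbi -------------------------------------------------------------

# Vectorized over districts; log-space; ties resolved toward the lowest
# state index at every argmax.
engine_viterbi <- function(params, obs, len, b = NULL) {
  D <- dim(obs)[1]
  W <- dim(obs)[2]
  if (is.null(b)) b <- emission_field(params, obs)
  lT <- log(params$trans)
  delta <- array(NA_real_, c(D, W, 3))
  psi <- array(1L, c(D, W, 3))
  delta[, 1, ] <- matrix(log(params$pi), D, 3, byrow = TRUE) +
    log(matrix(b[, 1, ], ncol = 3))
  if (W >= 2) {
    for (t in 2:W) {
      prev <- matrix(delta[, t - 1, ], ncol = 3)
      for (j in 1:3) {
        cand <- prev + matrix(lT[, j], D, 3, byrow = TRUE)
        best <- max.col(cand, ties.method = "first")
        psi[, t, j] <- best
        delta[, t, j] <- cand[cbind(seq_len(D), best)] +
          log(b[, t, j])
      }
    }
  }
  path <- matrix(NA_integer_, D, W)
  for (d in seq_len(D)) {
    L <- len[d]
    path[d, L] <- which.max(delta[d, L, ])
    if (L >= 2) {
      for (t in L:2) {
        path[d, t - 1] <- psi[d, t, path[d, t]]
      }
    }
  }
  path
}

#' Most likely hidden modality path for one district
#'
#' Computes the Viterbi path: the jointly most probable sequence of true
#' modalities given the observed multi-source reports. Argmax ties are
#' broken toward the lowest state index, so output is deterministic.
#'
#' @inheritParams forward_backward
#' @return Integer vector of modality codes, one per week.
#' @export
viterbi <- function(params, obs) {
  check_hmm_params(params)
  m <- obs_matrix(obs)
  W <- nrow(m)
  arr <- aperm(array(m, c(W, 4, 1)), c(3, 1, 2))
  as.integer(engine_viterbi(params, arr, len = W)[1, ])
}

# ---- Baum-Welch ----------------------------------------------------------

# Expected emission counts pooled over districts: counts[[s]][i, j] is the
# gamma-weighted number of weeks where source s reported j while the hidden
# state was i. Only weeks where source s actually reported enter; padding
# and missing weeks are excluded automatically because their obs is NA.
emission_counts <- function(fb, obs) {
  D <- dim(obs)[1]
  W <- dim(obs)[2]
  counts <- vector("list", 4)
  for (s in seq_along(source_ids())) {
    o <- obs[, , s, drop = FALSE]
    dim(o) <- c(D, W)
    cm <- matrix(0, 3, 3)
    for (j in 1:3) {
      idx <- which(o == j)
      if (length(idx) == 0) next
      for (i in 1:3) {
        g <- fb$gamma[, , i]
        cm[i, j] <- sum(g[idx])
      }
    }
    counts[[s]] <- cm
  }
  names(counts) <- source_ids()
  counts
}

# One M-step from expected sufficient statistics. Rows with zero support
# (a state never visited, or a source never co-present with a state) keep
# their previous values; emission rows are floored at EMISSION_FLOOR and
# renormalized so later decoding never takes log(0).
m_step <- function(params, fb, xi_sum, ecounts) {
  pi_new <- colMeans(matrix(fb$gamma[, 1, ], ncol = 3))
  pi_new <- pi_new / sum(pi_new)
  trans_new <- params$trans
  rs <- rowSums(xi_sum)
  for (i in 1:3) {
    if (rs[i] > 0) trans_new[i, ] <- xi_sum[i, ] / rs[i]
  }
  em_new <- params$emissions
  for (s in seq_along(source_ids())) {
    cm <- ecounts[[s]]
    rs <- rowSums(cm)
    for (i in 1:3) {
      if (rs[i] > 0) {
        row <- pmax(cm[i, ] / rs[i], EMISSION_FLOOR)
        em_new[[s]][i, ] <- row / sum(row)
      }
    }
  }
  params$pi <- pi_new
  params$trans <- trans_new
  params$emissions <- em_new
  params
}

# Seeded diagonal-dominant initialization: sticky transitions and
# diagonal-heavy emissions plus uniform noise, the structure toward which
# a well-identified modality fit converges; avoids label-degenerate starts.
init_hmm_params <- function(seed) {
  set.seed(seed)
  lab <- modality_labels()
  noisy <- function(base) {
    row_normalize(base + matrix(stats::runif(9, 0, 0.05), 3, 3))
  }
  trans0 <- matrix(0.05, 3, 3)
  diag(trans0) <- 0.9
  em0 <- matrix(0.1, 3, 3)
  diag(em0) <- 0.8
  emissions <- lapply(source_ids(), function(s) {
    m <- noisy(em0)
    dimnames(m) <- list(lab, lab)
    m
  })
  names(emissions) <- source_ids()
  tm <- noisy(trans0)
  dimnames(tm) <- list(lab, lab)
  hmm_params(pi = rep(1 / 3, 3), trans = tm, emissions = emissions)
}

# Single EM run from given starting parameters.
em_run <- function(obsdata, params, tol, max_iter) {
  obs <- obsdata$obs
  len <- obsdata$len
  fb <- engine_forward_backward(params, obs, len)
  trace <- fb$loglik
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    xi_sum <- engine_xi_sum(params, fb, len)
    ecounts <- emission_counts(fb, obs)
    params <- m_step(params, fb, xi_sum, ecounts)
    fb <- engine_forward_backward(params, obs, len)
    trace <- c(trace, fb$loglik)
    prev <- trace[length(trace) - 1]
    rel <- (fb$loglik - prev) / abs(prev)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(params = params, loglik = fb$loglik, loglik_trace = trace,
       n_iter = it, converged = converged)
}

#' Fit the multi-source modality HMM by Baum-Welch
#'
#' Estimates the initial distribution, transition matrix, and the four
#' per-source emission matrices by expectation-maximization over all
#' district sequences jointly (districts are independent realizations of
#' the same chain; expected counts are pooled in the M-step). Each source's
#' emission matrix is re-estimated only from weeks where that source
#' reported. The total log-likelihood is non-decreasing across iterations;
#' iteration stops when its relative improvement falls below `tol` or after
#' `max_iter` iterations. Because the likelihood is multimodal, `restarts`
#' independent seeded initializations are fitted and the best final
#' log-likelihood kept.
#'
#' Hidden states are *unlabeled* after fitting (the likelihood is invariant
#' under state permutation); use [derive_labeling()] on a decoded panel to
#' map them to modalities.
#'
#' @param panel A validated observation panel (see [read_panel()]).
#' @param seed Integer; restart `r` uses initialization seed `seed + r - 1`.
#' @param restarts Number of random restarts (default 5).
#' @param tol Relative log-likelihood improvement below which EM stops
#'   (default `1e-6`).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param init Optional [hmm_params()] starting values; if supplied a single
#'   run from these values is performed and `restarts`/`seed` are ignored.
#' @return An object of class `hmm_fit`: a list with `params`
#'   ([hmm_params()]), `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `restarts` (per-restart summary tibble), `n_districts`, `n_obs`.
#' @seealso [decode_panel()], [tidy.hmm_fit()], [glance.hmm_fit()]
#' @examples
#' spec <- reference_generator_spec(n_districts = 40, n_weeks = 12, seed = 7)
#' sim <- simulate_panel(spec)
#' fit <- fit_hmm(sim$panel, seed = 1, restarts = 1, max_iter = 30)
#' glance(fit)
#' @export
fit_hmm <- function(panel, seed = 1, restarts = 5, tol = 1e-6,
                    max_iter = 500, init = NULL) {
  stopifnot(tol > 0, max_iter >= 1, restarts >= 1)
  obsdata <- panel_to_obs(panel)
  n_obs <- sum(!is.na(obsdata$obs))
  if (n_obs == 0) {
    stop("panel contains no observations", call. = FALSE)
  }
  if (!is.null(init)) {
    check_hmm_params(init)
    starts <- list(list(seed = NA_integer_, params = init))
  } else {
    starts <- lapply(seq_len(restarts), function(r) {
      list(seed = as.integer(seed + r - 1),
           params = init_hmm_params(seed + r - 1))
    })
  }
  runs <- lapply(starts, function(st) {
    run <- em_run(obsdata, st$params, tol, max_iter)
    run$seed <- st$seed
    run
  })
  logliks <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which.max(logliks)]]
  structure(
    list(params = best$params,
         loglik = best$loglik,
         loglik_trace = best$loglik_trace,
         n_iter = best$n_iter,
         converged = best$converged,
         restarts = tibble::tibble(
           seed = vapply(runs, function(r) r$seed, integer(1)),
           loglik = logliks,
           n_iter = vapply(runs, function(r) r$n_iter, integer(1)),
           converged = vapply(runs, function(r) r$converged, logical(1))),
         n_districts = obsdata$D,
         n_obs = n_obs),
    class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit>: ", x$n_districts, " districts, ", x$n_obs,
      " observations\n", sep = "")
  cat("log-likelihood ", format(x$loglik), " after ", x$n_iter,
      " EM iterations (", if (x$converged) "converged" else "not converged",
      "; best of ", nrow(x$restarts), " restart(s))\n", sep = "")
  print(x$params, ...)
  invisible(x)
}

#' Tidy and glance methods for fitted modality HMMs
#'
#' `tidy()` returns the estimated parameters in long form (see
#' [tidy.hmm_params()]); `glance()` returns a one-row model summary.
#'
#' @param x An `hmm_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  tidy.hmm_params(x$params)
}

#' @rdname tidy.hmm_fit
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    n_restarts = nrow(x$restarts),
    n_districts = x$n_districts,
    n_obs = x$n_obs)
}

# ---- posterior decoding --------------------------------------------------

#' Decode a panel: per district-week posteriors, MAP and Viterbi states
#'
#' Runs forward-backward smoothing and Viterbi decoding for every district
#' in the panel under fixed parameters. Weeks inside a district's observed
#' window with no reports are decoded too (the chain interpolates through
#' them). States are the fit's *hidden* indices until a labeling is applied
#' with [apply_labeling()].
#'
#' @param panel A validated observation panel.
#' @param params An [hmm_params()] object or an `hmm_fit`.
#' @return A `decoded_panel` tibble with columns `district_id`, `state`
#'   (district's U.S. state, carried through for stratified reporting),
#'   `week`, `p1`, `p2`, `p3` (posterior over hidden states), `map_state`
#'   (argmax of the posterior, ties to the lowest index), `viterbi_state`,
#'   and `confidence` (the maximum posterior probability).
#' @seealso [derive_labeling()], [apply_labeling()], [confidence_filter()]
#' @export
decode_panel <- function(panel, params) {
  if (inherits(params, "hmm_fit")) params <- params$params
  check_hmm_params(params)
  obsdata <- panel_to_obs(panel)
  fb <- engine_forward_backward(params, obsdata$obs, obsdata$len)
  vit <- engine_viterbi(params, obsdata$obs, obsdata$len, b = fb$b)
  weeks <- obs_week_grid(obsdata)
  rows <- purrr::map_dfr(seq_len(obsdata$D), function(d) {
    L <- obsdata$len[d]
    g <- matrix(fb$gamma[d, seq_len(L), ], ncol = 3)
    tibble::tibble(
      district_id = obsdata$districts$district_id[d],
      state = obsdata$districts$state[d],
      week = weeks[[d]],
      p1 = g[, 1], p2 = g[, 2], p3 = g[, 3],
      map_state = max.col(g, ties.method = "first"),
      viterbi_state = vit[d, seq_len(L)],
      confidence = pmax(g[, 1], g[, 2], g[, 3]))
  })
  new_decoded_panel(rows, labeled = FALSE)
}

new_decoded_panel <- function(df, labeled) {
  structure(df,
            class = c("decoded_panel", class(tibble::tibble())),
            labeled = labeled)
}

#' @export
print.decoded_panel <- function(x, ...) {
  labeled <- isTRUE(attr(x, "labeled"))
  cat("<decoded_panel>: ", dplyr::n_distinct(x$district_id), " districts, ",
      nrow(x), " district-weeks (",
      if (labeled) "modality-labeled" else "unlabeled hidden states",
      ")\n", sep = "")
  NextMethod()
}
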