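# Synthetic multi-source modality panels: Markov modality paths, per-source
# categorical misreporting, and per-source coverage windows, so the whole
# fusion pipeline can be exercised and validated without any external feed.

#' Specify a synthetic panel generator
#'
#' A generator draws, for each district, a hidden Markov path of weekly
#' modalities from `params`, then for each district-week-source decides
#' independently whether the source reports (its presence probability,
#' possibly restricted to an active window of weeks) and, if it reports,
#' draws the reported modality from the emission row of the true state.
#'
#' `presence` gives each source's *marginal* presence rate over the whole
#' week grid. When a source has an active `window`, its per-week presence
#' inside the window is scaled up by `n_weeks / length(window)` so the
#' marginal rate (and hence the expected total district-week count) is
#' preserved.
#'
#' @param n_districts Number of districts.
#' @param n_weeks Number of weeks in the grid.
#' @param params Ground-truth [hmm_params()].
#' @param presence Named numeric vector of marginal presence probabilities
#'   in `[0, 1]`, one per source in [source_ids()].
#' @param windows Named list of integer week-index vectors; a source absent
#'   from the list is active in every week.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param start_week ISO week of the first grid column.
#' @param states Character vector of U.S. state codes districts are
#'   assigned to uniformly at random (used only by stratified reporting).
#' @param urban_rural Character vector of urban-rural classes assigned
#'   uniformly at random.
#' @return A `generator_spec` list.
#' @seealso [reference_generator_spec()], [simulate_panel()]
#' @export
generator_spec <- function(n_districts,
                           n_weeks = 43,
                           params = reference_hmm_params(),
                           presence = c(BURBIO = 1, MCH = 1, R2LT = 1,
                                        SD = 1),
                           windows = list(),
                           seed = 1,
                           start_week = "2020-W36",
                           states = c("OH", "PA", "SC", "IA", "VT"),
                           urban_rural = urban_rural_classes()) {
  stopifnot(n_districts >= 1, n_weeks >= 1)
  check_hmm_params(params)
  if (!setequal(names(presence), source_ids())) {
    stop("presence must be named with all of ",
         paste(source_ids(), collapse = ", "), call. = FALSE)
  }
  presence <- presence[source_ids()]
  if (any(presence < 0 | presence > 1)) {
    stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad_window <- setdiff(names(windows), source_ids())
  if (length(bad_window) > 0) {
    stop("unknown source(s) in windows: ",
         paste(bad_window, collapse = ", "), call. = FALSE)
  }
  for (w in windows) {
    if (length(w) == 0 || any(w < 1 | w > n_weeks)) {
      stop("window week indices must lie in 1..n_weeks", call. = FALSE)
    }
  }
  structure(
    list(n_districts = as.integer(n_districts),
         n_weeks = as.integer(n_weeks),
         params = params, presence = presence, windows = windows,
         seed = as.integer(seed), start_week = start_week,
         states = states, urban_rural = urban_rural),
    class = "generator_spec")
}

#' Reference generator: the 2020-2021 multi-source surveillance setting
#'
#' The default synthetic study conditions: ground-truth dynamics and
#' per-source misreporting from [reference_hmm_params()], and per-source
#' coverage matching the observed district-week volumes of the 2020-2021
#' school year on a 14,688-district grid — marginal presence rates
#' BURBIO 37589/616896, MCH 58137/616896, R2LT 343596/616896,
#' SD 24732/616896 (about 0.061 / 0.094 / 0.557 / 0.040). Two structural
#' coverage features are reproduced: state dashboards only come online for
#' the final 40% of the grid (they were largely unavailable before
#' February 2021), and the MCH survey goes dark for a contiguous 8-week
#' block in February-March.
#'
#' @param n_districts Number of districts (default 3000, the recovery-study
#'   size).
#' @param n_weeks Number of weeks (default 43, a September-June school
#'   year).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [generator_spec()].
#' @return A `generator_spec`.
#' @examples
#' spec <- reference_generator_spec(n_districts = 50, seed = 3)
#' round(spec$presence, 3)
#' @export
reference_generator_spec <- function(n_districts = 3000, n_weeks = 43,
                                     seed = 1, ...) {
  total <- 14688 * 42
  presence <- c(BURBIO = 37589, MCH = 58137, R2LT = 343596, SD = 24732) /
    total
  sd_weeks <- max(1L, round(0.4 * n_weeks))
  sd_window <- seq.int(n_weeks - sd_weeks + 1L, n_weeks)
  gap_start <- min(n_weeks, max(1L, round(23 / 43 * n_weeks)))
  gap <- seq.int(gap_start, min(n_weeks, gap_start + 7L))
  mch_window <- setdiff(seq_len(n_weeks), gap)
  if (length(mch_window) == 0) mch_window <- seq_len(n_weeks)
  generator_spec(n_districts = n_districts, n_weeks = n_weeks,
                 params = reference_hmm_params(),
                 presence = presence,
                 windows = list(SD = sd_window, MCH = mch_window),
                 seed = seed, ...)
}

# Per-week presence probabilities (n_weeks x 4), marginal rate preserved
# under window masking.
presence_schedule <- function(spec) {
  p <- matrix(0, spec$n_weeks, 4, dimnames = list(NULL, source_ids()))
  for (s in source_ids()) {
    window <- spec$windows[[s]]
    if (is.null(window)) window <- seq_len(spec$n_weeks)
    rate <- spec$presence[[s]] * spec$n_weeks / length(window)
    if (rate > 1 + 1e-12) {
      stop("window for ", s, " too short to carry marginal presence ",
           spec$presence[[s]], call. = FALSE)
    }
    p[window, s] <- min(rate, 1)
  }
  p
}

# Vectorized draw of one categorical step: rows of `mat` indexed by `state`.
draw_categorical <- function(mat, state) {
  n <- length(state)
  u <- stats::runif(n)
  cm <- t(apply(mat, 1, cumsum))
  1L + (u > cm[state, 1]) + (u > cm[state, 2])
}

#' Simulate ground-truth modality paths
#'
#' Draws each district's week-1 state from `spec$params$pi` and each later
#' state from the transition-matrix row of the current state, plus the
#' district attributes (state, urban-rural class) used by stratified
#' reporting.
#'
#' @param spec A [generator_spec()].
#' @return A `true_paths` object: list with `paths` (integer
#'   `n_districts x n_weeks` matrix of modality codes), `districts` (tibble
#'   of attributes), `weeks` (ISO week identifiers).
#' @seealso [simulate_observations()], [truth_table()]
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  check_hmm_params(spec$params)
  set.seed(spec$seed)
  D <- spec$n_districts
  W <- spec$n_weeks
  paths <- matrix(NA_integer_, D, W)
  paths[, 1] <- draw_categorical(matrix(spec$params$pi, 1, 3),
                                 rep(1L, D))
  if (W >= 2) {
    for (t in 2:W) {
      paths[, t] <- draw_categorical(spec$params$trans, paths[, t - 1])
    }
  }
  ids <- sprintf("d%05d", seq_len(D))
  districts <- tibble::tibble(
    district_id = ids,
    district_name = sprintf("District %05d", seq_len(D)),
    state = sample(spec$states, D, replace = TRUE),
    urban_rural_class = sample(spec$urban_rural, D, replace = TRUE))
  structure(
    list(paths = paths, districts = districts,
         weeks = date_iso_week(iso_week_monday(spec$start_week) +
                                 7 * (seq_len(W) - 1))),
    class = "true_paths")
}

#' Ground-truth paths as a long tibble
#'
#' @param truth A `true_paths` object from [simulate_truth()].
#' @return Tibble with columns `district_id`, `week`, `modality`.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "true_paths"))
  D <- nrow(truth$paths)
  W <- ncol(truth$paths)
  tibble::tibble(
    district_id = rep(truth$districts$district_id, times = W),
    week = rep(truth$weeks, each = D),
    modality = modality_label(as.integer(truth$paths))) |>
    dplyr::arrange(.data$district_id, .data$week)
}

#' Simulate noisy, sparsely observed multi-source reports
#'
#' For each district-week-source, the source reports with its scheduled
#' presence probability; a present source draws its reported modality from
#' the emission-matrix row of the true state. Draws are reproducible given
#' `spec$seed` (an observation stream independent of the truth stream).
#'
#' @param truth A `true_paths` object.
#' @param spec The [generator_spec()] used to create it.
#' @return An observation panel tibble (see [read_panel()] for columns).
#' @export
simulate_observations <- function(truth, spec) {
  stopifnot(inherits(truth, "true_paths"), inherits(spec, "generator_spec"))
  check_hmm_params(spec$params)
  D <- nrow(truth$paths)
  W <- ncol(truth$paths)
  if (D != spec$n_districts || W != spec$n_weeks) {
    stop("truth dimensions do not match spec", call. = FALSE)
  }
  set.seed(spec$seed + 1L)
  sched <- presence_schedule(spec)
  pieces <- vector("list", 4)
  for (s_i in seq_along(source_ids())) {
    s <- source_ids()[s_i]
    pw <- matrix(sched[, s_i], D, W, byrow = TRUE)
    present <- which(matrix(stats::runif(D * W), D, W) < pw)
    if (length(present) == 0) next
    d_idx <- ((present - 1) %% D) + 1
    t_idx <- ((present - 1) %/% D) + 1
    state <- truth$paths[present]
    reported <- draw_categorical(spec$params$emissions[[s]], state)
    pieces[[s_i]] <- tibble::tibble(
      district_id = truth$districts$district_id[d_idx],
      district_name = truth$districts$district_name[d_idx],
      state = truth$districts$state[d_idx],
      week = truth$weeks[t_idx],
      source = s,
      modality = modality_label(reported))
  }
  panel <- dplyr::bind_rows(pieces)
  if (nrow(panel) == 0) {
    return(tibble::tibble(district_id = character(),
                          district_name = character(),
                          state = character(), week = character(),
                          source = character(), modality = character()))
  }
  validate_panel(panel)
}

#' Simulate truth and observations in one call
#'
#' @param spec A [generator_spec()].
#' @return List with `truth` (a `true_paths`), `panel` (observation
#'   tibble), and `crosswalk` (district to urban-rural table matching
#'   [read_crosswalk()] output).
#' @examples
#' sim <- simulate_panel(reference_generator_spec(n_districts = 20,
#'                                                n_weeks = 10, seed = 2))
#' dplyr::count(sim$panel, source)
#' @export
simulate_panel <- function(spec) {
  truth <- simulate_truth(spec)
  panel <- simulate_observations(truth, spec)
  crosswalk <- tibble::tibble(
    district_id = truth$districts$district_id,
    county_fips = NA_character_,
    urban_rural_class = truth$districts$urban_rural_class)
  list(truth = truth, panel = panel, crosswalk = crosswalk)
}
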