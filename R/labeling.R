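# Resolution of hidden-state label switching: an unsupervised fit's state
# indices are arbitrary; they are mapped to modalities by the most common
# modality reported within each posterior cluster.

#' Derive a hidden-state to modality labeling by majority report
#'
#' For each hidden state, pools every reported modality (all four sources,
#' unweighted) over the district-weeks whose MAP state is that hidden
#' state, then assigns states to modalities greedily in descending count
#' order (ties broken toward the lowest modality code, then the lowest
#' hidden index) so that the result is a valid permutation even when two
#' states share the same majority modality.
#'
#' @param panel The observation panel that was decoded.
#' @param decoded The (unlabeled) [decode_panel()] output for `panel`.
#' @return A `state_labeling` object: list with `mapping` (integer
#'   permutation; `mapping[h]` is the modality code of hidden state `h`)
#'   and `support` (the 3x3 hidden-state x reported-modality count matrix).
#' @seealso [apply_labeling()]
#' @export
derive_labeling <- function(panel, decoded) {
  panel <- validate_panel(panel)
  stopifnot(inherits(decoded, "decoded_panel"))
  joined <- panel |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(decoded),
                    dplyr::all_of(c("district_id", "week", "map_state"))),
      by = c("district_id", "week"))
  support <- matrix(0, 3, 3,
                    dimnames = list(hidden = paste0("state", 1:3),
                                    reported = modality_labels()))
  tab <- joined |>
    dplyr::count(.data$map_state, .data$modality)
  support[cbind(tab$map_state, modality_code(tab$modality))] <- tab$n
  if (any(rowSums(support) == 0)) {
    empty <- which(rowSums(support) == 0)
    stop("hidden state(s) ", paste(empty, collapse = ", "),
         " have no supporting reports; refit or supply a manual mapping",
         call. = FALSE)
  }
  mapping <- rep(NA_integer_, 3)
  taken_state <- rep(FALSE, 3)
  taken_mod <- rep(FALSE, 3)
  cells <- expand.grid(hidden = 1:3, modality = 1:3)
  cells$count <- support[cbind(cells$hidden, cells$modality)]
  cells <- cells[order(-cells$count, cells$modality, cells$hidden), ]
  for (k in seq_len(nrow(cells))) {
    h <- cells$hidden[k]
    m <- cells$modality[k]
    if (!taken_state[h] && !taken_mod[m]) {
      mapping[h] <- m
      taken_state[h] <- TRUE
      taken_mod[m] <- TRUE
    }
  }
  structure(list(mapping = mapping, support = support),
            class = "state_labeling")
}

#' @export
print.state_labeling <- function(x, ...) {
  cat("<state_labeling>: hidden state -> modality\n")
  for (h in 1:3) {
    cat("  state", h, "->", modality_label(x$mapping[h]), "\n")
  }
  cat("support (reports per MAP cluster):\n")
  print(x$support)
  invisible(x)
}

#' Apply a state labeling to a decoded panel
#'
#' Permutes the posterior columns and relabels the MAP and Viterbi states
#' so that state indices become modality codes. The labeled panel gains
#' columns `p_remote`, `p_hybrid`, `p_in_person`, `map_modality`,
#' `viterbi_modality` and keeps `confidence`. Applying the identity mapping
#' changes only column names.
#'
#' @param decoded A [decode_panel()] output.
#' @param labeling A `state_labeling` from [derive_labeling()], or an
#'   integer permutation of `1:3`.
#' @return A labeled `decoded_panel` tibble.
#' @export
apply_labeling <- function(decoded, labeling) {
  stopifnot(inherits(decoded, "decoded_panel"))
  mapping <- if (inherits(labeling, "state_labeling")) {
    labeling$mapping
  } else {
    as.integer(labeling)
  }
  if (!identical(sort(mapping), 1:3)) {
    stop("labeling must be a permutation of 1:3", call. = FALSE)
  }
  df <- tibble::as_tibble(decoded)
  post <- as.matrix(df[, c("p1", "p2", "p3")])
  # mapping[h] = modality of hidden state h, so modality m's probability
  # comes from hidden state mapping^{-1}(m)
  inv <- order(mapping)
  out <- df |>
    dplyr::mutate(
      p_remote = post[, inv[1]],
      p_hybrid = post[, inv[2]],
      p_in_person = post[, inv[3]],
      map_modality = modality_label(mapping[df$map_state]),
      viterbi_modality = modality_label(mapping[df$viterbi_state])) |>
    dplyr::select(dplyr::all_of(c(
      "district_id", "state", "week",
      "p_remote", "p_hybrid", "p_in_person",
      "map_modality", "viterbi_modality", "confidence")))
  new_decoded_panel(out, labeled = TRUE)
}

#' Keep only high-confidence district-weeks
#'
#' Retains the district-weeks whose maximum posterior modality probability
#' is at least `threshold` (inclusive, matching the \eqn{\ge 0.75}
#' high-confidence convention). The retained count and fraction are
#' attached as attributes `n_retained` and `retained_fraction`.
#'
#' @param decoded A `decoded_panel` (labeled or not).
#' @param threshold Posterior probability cutoff in `(0, 1]`; default 0.75.
#' @return The filtered `decoded_panel`.
#' @examples
#' # confidence_filter(decoded, threshold = 0.75)
#' @export
confidence_filter <- function(decoded, threshold = 0.75) {
  stopifnot(inherits(decoded, "decoded_panel"),
            threshold > 0, threshold <= 1)
  keep <- decoded$confidence >= threshold
  out <- dplyr::filter(tibble::as_tibble(decoded), keep)
  out <- new_decoded_panel(out, labeled = attr(decoded, "labeled"))
  attr(out, "n_retained") <- sum(keep)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Decode, label, and annotate a panel in one step
#'
#' Convenience wrapper: [decode_panel()], [derive_labeling()],
#' [apply_labeling()], and a `high_confidence` indicator column at the
#' given threshold.
#'
#' @param panel An observation panel.
#' @param fit An `hmm_fit` or [hmm_params()].
#' @param threshold High-confidence posterior cutoff (default 0.75).
#' @return A labeled `decoded_panel` with a logical `high_confidence`
#'   column; the `state_labeling` used is attached as attribute
#'   `"labeling"`.
#' @examples
#' sim <- simulate_panel(reference_generator_spec(n_districts = 40,
#'                                                n_weeks = 12, seed = 5))
#' fit <- fit_hmm(sim$panel, seed = 1, restarts = 1, max_iter = 40)
#' inferred <- infer_modalities(sim$panel, fit)
#' head(inferred)
#' @export
infer_modalities <- function(panel, fit, threshold = 0.75) {
  decoded <- decode_panel(panel, fit)
  labeling <- derive_labeling(panel, decoded)
  labeled <- apply_labeling(decoded, labeling)
  labeled <- dplyr::mutate(tibble::as_tibble(labeled),
                           high_confidence = .data$confidence >= threshold)
  labeled <- new_decoded_panel(labeled, labeled = TRUE)
  attr(labeled, "labeling") <- labeling
  labeled
}
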