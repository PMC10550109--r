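# Evaluation and descriptive outputs: pairwise inter-tracker agreement,
# the paired one-sided t-test that the fused estimate agrees better than
# any single source, and weekly modality-share trend tables.

#' Stack source reports and fused output into one tracker table
#'
#' Reshapes a panel (one tracker per source) and, optionally, a labeled
#' decoded panel (tracker `"HMM"`, using the MAP modality) into the long
#' tracker format consumed by [pairwise_agreement()] and
#' [agreement_ttest()].
#'
#' @param panel An observation panel.
#' @param decoded Optional labeled `decoded_panel` to include as tracker
#'   `"HMM"`.
#' @param high_confidence_only If `TRUE` and `decoded` has a
#'   `high_confidence` column, only high-confidence district-weeks enter
#'   the `"HMM"` tracker.
#' @return Tibble with columns `tracker`, `district_id`, `week`,
#'   `modality`.
#' @export
bind_trackers <- function(panel, decoded = NULL,
                          high_confidence_only = FALSE) {
  panel <- validate_panel(panel)
  out <- panel |>
    dplyr::transmute(tracker = .data$source, .data$district_id,
                     .data$week, .data$modality)
  if (!is.null(decoded)) {
    stopifnot(inherits(decoded, "decoded_panel"))
    if (!isTRUE(attr(decoded, "labeled"))) {
      stop("decoded panel must be labeled before agreement analysis",
           call. = FALSE)
    }
    dec <- tibble::as_tibble(decoded)
    if (high_confidence_only && "high_confidence" %in% names(dec)) {
      dec <- dplyr::filter(dec, .data$high_confidence)
    }
    out <- dplyr::bind_rows(
      out,
      dplyr::transmute(dec, tracker = "HMM", .data$district_id,
                       .data$week, modality = .data$map_modality))
  }
  out
}

#' Pairwise agreement between modality trackers
#'
#' For every unordered pair of trackers, computes over the district-weeks
#' where *both* report: the overlap count, the number of matching reports,
#' and their ratio. Pairs with no overlap get `NA` agreement (undefined,
#' not zero).
#'
#' @param trackers Long tracker table from [bind_trackers()] (columns
#'   `tracker`, `district_id`, `week`, `modality`).
#' @param per_week If `TRUE`, also break the counts down by week (adds a
#'   `week` column).
#' @param include_self If `TRUE`, include each tracker paired with itself
#'   (agreement 1 on its own coverage).
#' @return An `agreement_table` tibble with columns `tracker1`, `tracker2`,
#'   (`week`,) `n_overlap`, `n_match`, `agreement`.
#' @examples
#' tr <- tibble::tibble(
#'   tracker = rep(c("A", "B"), each = 3),
#'   district_id = rep(c("d1", "d2", "d3"), 2),
#'   week = "2020-W40",
#'   modality = c("remote", "hybrid", "in_person",
#'                "remote", "remote", "in_person"))
#' pairwise_agreement(tr)
#' @export
pairwise_agreement <- function(trackers, per_week = FALSE,
                               include_self = FALSE) {
  stopifnot(all(c("tracker", "district_id", "week", "modality") %in%
                  names(trackers)))
  names_u <- sort(unique(trackers$tracker))
  if (length(names_u) < 2 && !include_self) {
    stop("need at least two trackers", call. = FALSE)
  }
  pairs <- expand.grid(tracker1 = names_u, tracker2 = names_u,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tracker1 < pairs$tracker2 |
                   (include_self & pairs$tracker1 == pairs$tracker2), ]
  out <- purrr::pmap_dfr(pairs, function(tracker1, tracker2) {
    a <- dplyr::filter(trackers, .data$tracker == tracker1)
    b <- dplyr::filter(trackers, .data$tracker == tracker2)
    both <- dplyr::inner_join(
      dplyr::select(a, dplyr::all_of(c("district_id", "week", "modality"))),
      dplyr::select(b, dplyr::all_of(c("district_id", "week", "modality"))),
      by = c("district_id", "week"), suffix = c("_1", "_2"),
      relationship = "one-to-one")
    if (per_week) {
      grp <- dplyr::group_by(both, .data$week)
    } else {
      grp <- both
    }
    res <- dplyr::summarise(
      grp,
      n_overlap = dplyr::n(),
      n_match = sum(.data$modality_1 == .data$modality_2),
      .groups = "drop")
    if (nrow(res) == 0 && !per_week) {
      res <- tibble::tibble(n_overlap = 0L, n_match = 0L)
    }
    dplyr::mutate(res, tracker1 = tracker1, tracker2 = tracker2,
                  .before = 1)
  })
  out <- dplyr::mutate(
    out, agreement = ifelse(.data$n_overlap > 0,
                            .data$n_match / .data$n_overlap, NA_real_))
  structure(out, class = c("agreement_table", class(tibble::tibble())))
}

#' Does the fused estimate agree with a tracker better than other sources?
#'
#' For a chosen tracker, builds two weekly agreement series: the fraction
#' of that tracker's district-weeks matching the fused `"HMM"` modality,
#' and the fraction matching each remaining source (over each pair's own
#' weekly overlap). A *paired* one-sided t-test across weeks then asks
#' whether mean HMM agreement exceeds the comparator's. Weeks where either
#' series is undefined (no overlap) are dropped pairwise. If every weekly
#' difference is zero the statistic is 0 and the one-sided p-value 0.5.
#'
#' @param trackers Long tracker table from [bind_trackers()] including an
#'   `"HMM"` tracker.
#' @param tracker The tracker whose agreement is compared (e.g.
#'   `"BURBIO"`).
#' @return Tibble with one row per comparator: `tracker`, `comparator`,
#'   `mean_diff` (mean weekly HMM-minus-comparator agreement),
#'   `statistic`, `p_value` (one-sided, alternative "HMM higher"),
#'   `n_weeks`.
#' @export
agreement_ttest <- function(trackers, tracker) {
  stopifnot("HMM" %in% trackers$tracker, tracker %in% trackers$tracker,
            tracker != "HMM")
  weekly <- pairwise_agreement(trackers, per_week = TRUE)
  pair_series <- function(t1, t2) {
    dplyr::filter(weekly,
                  (.data$tracker1 == t1 & .data$tracker2 == t2) |
                    (.data$tracker1 == t2 & .data$tracker2 == t1)) |>
      dplyr::select(dplyr::all_of(c("week", "agreement")))
  }
  hmm_series <- pair_series(tracker, "HMM")
  comparators <- setdiff(unique(trackers$tracker), c(tracker, "HMM"))
  purrr::map_dfr(comparators, function(comp) {
    comp_series <- pair_series(tracker, comp)
    paired <- dplyr::inner_join(hmm_series, comp_series, by = "week",
                                suffix = c("_hmm", "_comp")) |>
      dplyr::filter(!is.na(.data$agreement_hmm),
                    !is.na(.data$agreement_comp))
    if (nrow(paired) < 2) {
      stop("fewer than 2 paired weeks for ", tracker, " vs ", comp,
           call. = FALSE)
    }
    d <- paired$agreement_hmm - paired$agreement_comp
    if (stats::sd(d) == 0) {
      statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p_value <- if (mean(d) == 0) 0.5 else as.numeric(mean(d) < 0)
    } else {
      tt <- stats::t.test(d, alternative = "greater")
      statistic <- unname(tt$statistic)
      p_value <- tt$p.value
    }
    tibble::tibble(tracker = tracker, comparator = comp,
                   mean_diff = mean(d), statistic = statistic,
                   p_value = p_value, n_weeks = nrow(paired))
  })
}

#' Weekly modality shares, overall or stratified
#'
#' For each week (and optional stratum), the fraction of districts whose
#' inferred (labeled MAP) modality is remote, hybrid, and in-person, among
#' districts with an inferred modality that week. Districts missing from
#' the crosswalk fall in an `"unclassified"` stratum.
#'
#' @param decoded A labeled `decoded_panel`.
#' @param crosswalk Optional crosswalk tibble from [read_crosswalk()]
#'   (required for `strata = "urban_rural"`).
#' @param strata One of `"none"`, `"state"`, `"urban_rural"`.
#' @param high_confidence_only If `TRUE`, restrict to district-weeks whose
#'   confidence is at least `threshold`.
#' @param threshold Confidence cutoff used when `high_confidence_only`.
#' @return A `trend_table` tibble with columns (`stratum`,) `week`,
#'   `share_remote`, `share_hybrid`, `share_in_person`, `n_districts`;
#'   shares sum to 1 on every row with `n_districts > 0`.
#' @seealso [state_endpoint_summary()], [autoplot.trend_table()]
#' @export
weekly_shares <- function(decoded, crosswalk = NULL,
                          strata = c("none", "state", "urban_rural"),
                          high_confidence_only = FALSE,
                          threshold = 0.75) {
  strata <- match.arg(strata)
  stopifnot(inherits(decoded, "decoded_panel"))
  if (!isTRUE(attr(decoded, "labeled"))) {
    stop("decoded panel must be labeled before computing shares",
         call. = FALSE)
  }
  df <- tibble::as_tibble(decoded)
  if (nrow(df) == 0) stop("decoded panel is empty", call. = FALSE)
  if (high_confidence_only) {
    df <- dplyr::filter(df, .data$confidence >= threshold)
  }
  if (strata == "state") {
    df <- dplyr::mutate(df, stratum = dplyr::coalesce(.data$state,
                                                      "unclassified"))
  } else if (strata == "urban_rural") {
    if (is.null(crosswalk)) {
      stop("urban_rural stratification requires a crosswalk",
           call. = FALSE)
    }
    df <- df |>
      dplyr::left_join(
        dplyr::select(crosswalk,
                      dplyr::all_of(c("district_id", "urban_rural_class"))),
        by = "district_id") |>
      dplyr::mutate(stratum = dplyr::coalesce(.data$urban_rural_class,
                                              "unclassified"))
  } else {
    df <- dplyr::mutate(df, stratum = "all")
  }
  out <- df |>
    dplyr::group_by(.data$stratum, .data$week) |>
    dplyr::summarise(
      share_remote = mean(.data$map_modality == "remote"),
      share_hybrid = mean(.data$map_modality == "hybrid"),
      share_in_person = mean(.data$map_modality == "in_person"),
      n_districts = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$stratum, .data$week)
  if (strata == "none") out$stratum <- NULL
  structure(out, class = c("trend_table", class(tibble::tibble())),
            strata = strata)
}

#' In-person shares by state at chosen reference weeks
#'
#' Reads a state-stratified trend table at three reference weeks (e.g.
#' early fall, mid winter, end of school year) and reports each state's
#' in-person percentage at those weeks plus the start-to-end change in
#' percentage points. States absent from the trend table at a requested
#' week are omitted.
#'
#' @param trend A `trend_table` computed with `strata = "state"`.
#' @param weeks Character vector of exactly three ISO week identifiers.
#' @return Tibble with columns `state`, `pct_start`, `pct_mid`, `pct_end`
#'   (in-person percentages, 0-100), `change` (`pct_end - pct_start`).
#'   The week identifiers are kept in attribute `"weeks"`.
#' @export
state_endpoint_summary <- function(trend, weeks) {
  stopifnot(inherits(trend, "trend_table"))
  if (!identical(attr(trend, "strata"), "state")) {
    stop("trend table must be stratified by state", call. = FALSE)
  }
  if (length(weeks) != 3) {
    stop("supply exactly three reference weeks", call. = FALSE)
  }
  missing_weeks <- setdiff(weeks, trend$week)
  if (length(missing_weeks) > 0) {
    stop("week(s) not present in trend table: ",
         paste(missing_weeks, collapse = ", "), call. = FALSE)
  }
  wide <- trend |>
    dplyr::filter(.data$week %in% weeks) |>
    dplyr::mutate(which_week = factor(.data$week, levels = weeks,
                                      labels = c("pct_start", "pct_mid",
                                                 "pct_end")),
                  pct = 100 * .data$share_in_person) |>
    dplyr::select(state = "stratum", "which_week", "pct") |>
    tidyr::pivot_wider(names_from = "which_week", values_from = "pct") |>
    tidyr::drop_na()
  out <- dplyr::mutate(wide, change = .data$pct_end - .data$pct_start)
  attr(out, "weeks") <- weeks
  out
}
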