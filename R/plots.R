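# ggplot2 displays for the main result types.

#' Stacked band chart of weekly modality shares
#'
#' Displays a trend table as stacked weekly shares of remote, hybrid, and
#' in-person districts; stratified tables are facetted by stratum.
#'
#' @param object A `trend_table` from [weekly_shares()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_table
#' @export
autoplot.trend_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("share_remote", "share_hybrid", "share_in_person")),
      names_to = "modality", values_to = "share",
      names_prefix = "share_") |>
    dplyr::mutate(
      modality = factor(.data$modality, levels = modality_labels()),
      week_date = iso_week_monday(.data$week))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$week_date,
                                        y = .data$share,
                                        fill = .data$modality)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "week", y = "share of districts",
                  fill = "modality") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' Heatmap of pairwise tracker agreement
#'
#' @param object An `agreement_table` from [pairwise_agreement()] (not
#'   per-week).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_table
#' @export
autoplot.agreement_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("week" %in% names(df)) {
    stop("plot the aggregate table (per_week = FALSE)", call. = FALSE)
  }
  both <- dplyr::bind_rows(
    df,
    dplyr::rename(df, tracker1 = "tracker2", tracker2 = "tracker1"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$tracker1,
                                     y = .data$tracker2,
                                     fill = .data$agreement)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$agreement), "-",
                     sprintf("%.1f%%\n(%d)", 100 * .data$agreement,
                             .data$n_overlap)))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "agreement") +
    ggplot2::theme_minimal()
}

#' EM log-likelihood trace of a fitted HMM
#'
#' @param object An `hmm_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the (non-decreasing) total
#'   log-likelihood across EM iterations of the best restart.
#' @method autoplot hmm_fit
#' @export
autoplot.hmm_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace) - 1,
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "total log-likelihood") +
    ggplot2::theme_minimal()
}
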