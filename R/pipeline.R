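# End-to-end orchestration: simulate (or read) -> fit -> label -> decode ->
# report, with every stage's artifact written to one output directory, and
# the bundled parameter-recovery experiment.

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param panel Path to a panel CSV, or `NULL` to simulate with
#'   `generator`.
#' @param generator A [generator_spec()] used when `panel` is `NULL`.
#' @param crosswalk Optional crosswalk CSV path, or a crosswalk tibble.
#' @param seed,restarts,tol,max_iter Fit settings, see [fit_hmm()].
#' @param threshold High-confidence posterior cutoff in `(0, 1]`.
#' @param strata Stratification for the trend table: `"none"`, `"state"`,
#'   or `"urban_rural"`.
#' @param high_confidence_only Restrict reports to high-confidence
#'   district-weeks.
#' @return A `run_config` list.
#' @seealso [run_pipeline()]
#' @export
run_config <- function(out_dir,
                       panel = NULL,
                       generator = NULL,
                       crosswalk = NULL,
                       seed = 1, restarts = 5, tol = 1e-6, max_iter = 500,
                       threshold = 0.75,
                       strata = c("none", "state", "urban_rural"),
                       high_confidence_only = FALSE) {
  strata <- match.arg(strata)
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(panel) && is.null(generator)) {
    stop("supply either a panel path or a generator spec", call. = FALSE)
  }
  if (!is.null(panel) && !file.exists(panel)) {
    stop("panel file not found: ", panel, call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, panel = panel, generator = generator,
         crosswalk = crosswalk, seed = seed, restarts = restarts,
         tol = tol, max_iter = max_iter, threshold = threshold,
         strata = strata, high_confidence_only = high_confidence_only),
    class = "run_config")
}

pipeline_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(NULL)
}

#' Run the full fusion pipeline
#'
#' Simulates (or reads) a panel, fits the HMM, resolves state labels,
#' decodes every district-week, and writes all artifacts to
#' `config$out_dir`: `panel.csv` (and `truth.csv` for simulated runs),
#' `params.json`, `decoded.csv`, `agreement.csv`, `ttests.csv`,
#' `trends.csv`, a `run.log`, and `manifest.json` (configuration hash and
#' session versions). Runs are deterministic given the configured seeds.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted model (`fit`), the labeled
#'   decoded panel (`decoded`), the report tables, and the artifact paths.
#' @examples
#' \donttest{
#' cfg <- run_config(out_dir = tempfile(),
#'                   generator = reference_generator_spec(50, 12, seed = 4),
#'                   restarts = 1, max_iter = 40)
#' res <- run_pipeline(cfg)
#' res$fit$loglik
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  paths <- list(log = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(config$panel)) {
    pipeline_log(con, "simulate: ", config$generator$n_districts,
                 " districts x ", config$generator$n_weeks,
                 " weeks, seed ", config$generator$seed)
    sim <- stage("simulate", simulate_panel(config$generator))
    panel <- sim$panel
    crosswalk <- sim$crosswalk
    paths$panel <- file.path(config$out_dir, "panel.csv")
    write_panel(panel, paths$panel)
    paths$truth <- file.path(config$out_dir, "truth.csv")
    readr::write_csv(truth_table(sim$truth), paths$truth, progress = FALSE)
  } else {
    pipeline_log(con, "read panel: ", config$panel)
    panel <- stage("read_panel", read_panel(config$panel))
    panel <- stage("filter", filter_virtual_districts(panel))
    crosswalk <- NULL
    if (!is.null(config$crosswalk)) {
      crosswalk <- if (is.character(config$crosswalk)) {
        stage("read_crosswalk", read_crosswalk(config$crosswalk))
      } else {
        config$crosswalk
      }
    }
  }
  pipeline_log(con, "panel: ", nrow(panel), " observations, ",
               dplyr::n_distinct(panel$district_id), " districts")

  pipeline_log(con, "fit: seed ", config$seed, ", ", config$restarts,
               " restart(s), tol ", config$tol)
  fit <- stage("fit", fit_hmm(panel, seed = config$seed,
                              restarts = config$restarts,
                              tol = config$tol,
                              max_iter = config$max_iter))
  pipeline_log(con, "fit: loglik ", format(fit$loglik), " after ",
               fit$n_iter, " iterations (converged: ", fit$converged, ")")
  pipeline_log(con, "fit: loglik trace ",
               paste(format(fit$loglik_trace, digits = 10),
                     collapse = " "))
  paths$params <- file.path(config$out_dir, "params.json")
  write_hmm_params(fit$params, paths$params)

  decoded <- stage("decode", infer_modalities(panel, fit,
                                              threshold = config$threshold))
  labeling <- attr(decoded, "labeling")
  pipeline_log(con, "labeling: ",
               paste(sprintf("state%d->%s", 1:3,
                             modality_label(labeling$mapping)),
                     collapse = ", "))
  paths$decoded <- file.path(config$out_dir, "decoded.csv")
  readr::write_csv(
    dplyr::mutate(tibble::as_tibble(decoded),
                  high_confidence = as.integer(.data$high_confidence)),
    paths$decoded, progress = FALSE)

  trackers <- bind_trackers(panel, decoded,
                            high_confidence_only =
                              config$high_confidence_only)
  agreement <- stage("agreement", pairwise_agreement(trackers))
  paths$agreement <- file.path(config$out_dir, "agreement.csv")
  readr::write_csv(tibble::as_tibble(agreement), paths$agreement,
                   progress = FALSE)

  ttests <- NULL
  sources_present <- intersect(source_ids(), unique(panel$source))
  if (length(sources_present) >= 2) {
    ttests <- stage("ttests", purrr::map_dfr(
      sources_present, function(s) {
        tryCatch(agreement_ttest(trackers, s),
                 error = function(e) tibble::tibble())
      }))
    paths$ttests <- file.path(config$out_dir, "ttests.csv")
    readr::write_csv(ttests, paths$ttests, progress = FALSE)
  }

  trend <- stage("trends", weekly_shares(
    decoded, crosswalk = crosswalk, strata = config$strata,
    high_confidence_only = config$high_confidence_only,
    threshold = config$threshold))
  paths$trends <- file.path(config$out_dir, "trends.csv")
  readr::write_csv(tibble::as_tibble(trend), paths$trends,
                   progress = FALSE)

  manifest <- list(
    config_hash = rlang::hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("modalhmm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  pipeline_log(con, "done: artifacts in ", config$out_dir)

  invisible(list(fit = fit, decoded = decoded, labeling = labeling,
                 agreement = agreement, ttests = ttests, trend = trend,
                 paths = paths))
}

#' Parameter-recovery experiment on synthetic panels
#'
#' Simulates a panel from known ground-truth parameters, fits the HMM from
#' scratch, aligns hidden states to modalities by majority labeling, and
#' measures elementwise absolute errors of the aligned transition and
#' emission estimates against the truth, plus the fraction of
#' district-weeks where the labeled MAP modality equals the simulated true
#' modality.
#'
#' @param spec A [generator_spec()] holding the ground truth.
#' @param seed,restarts,tol,max_iter Fit settings, see [fit_hmm()].
#' @return A `recovery_report` list: `fit`, `labeling`, `aligned_params`
#'   (fitted parameters after state alignment), `errors` (tidy tibble of
#'   truth, estimate, and absolute error per parameter cell),
#'   `max_abs_error_trans`, `mean_abs_error_trans`,
#'   `max_abs_error_emissions`, `state_accuracy`.
#' @examples
#' \donttest{
#' rec <- recovery_experiment(
#'   reference_generator_spec(n_districts = 200, n_weeks = 20, seed = 2),
#'   restarts = 2)
#' rec$max_abs_error_trans
#' }
#' @export
recovery_experiment <- function(spec, seed = 1, restarts = 5, tol = 1e-6,
                                max_iter = 500) {
  stopifnot(inherits(spec, "generator_spec"))
  sim <- simulate_panel(spec)
  fit <- fit_hmm(sim$panel, seed = seed, restarts = restarts, tol = tol,
                 max_iter = max_iter)
  decoded <- decode_panel(sim$panel, fit)
  labeling <- derive_labeling(sim$panel, decoded)
  aligned <- align_params(fit$params, labeling)
  labeled <- apply_labeling(decoded, labeling)

  truth_long <- truth_table(sim$truth)
  joined <- dplyr::inner_join(
    tibble::as_tibble(labeled), truth_long,
    by = c("district_id", "week"))
  state_accuracy <- mean(joined$map_modality == joined$modality)

  est <- tidy.hmm_params(aligned) |>
    dplyr::rename(estimate = "probability")
  tru <- tidy.hmm_params(spec$params) |>
    dplyr::rename(truth = "probability")
  errors <- dplyr::inner_join(tru, est,
                              by = c("component", "from", "to")) |>
    dplyr::mutate(abs_error = abs(.data$estimate - .data$truth))
  trans_err <- dplyr::filter(errors, .data$component == "trans")$abs_error
  em_err <- dplyr::filter(errors,
                          .data$component %in% source_ids())$abs_error
  structure(
    list(fit = fit, labeling = labeling, aligned_params = aligned,
         errors = errors,
         max_abs_error_trans = max(trans_err),
         mean_abs_error_trans = mean(trans_err),
         max_abs_error_emissions = max(em_err),
         state_accuracy = state_accuracy),
    class = "recovery_report")
}

#' Align fitted parameters to modality labels
#'
#' Permutes fitted parameters so hidden state `h` becomes modality
#' `mapping[h]`: both axes of the transition matrix, `pi`, and the
#' true-state axis of each emission matrix (the report axis is already
#' modality-coded).
#'
#' @param params An [hmm_params()] with arbitrary hidden-state order.
#' @param labeling A `state_labeling` or integer permutation of `1:3`.
#' @return The permuted [hmm_params()], rows/columns named by modality.
#' @export
align_params <- function(params, labeling) {
  mapping <- if (inherits(labeling, "state_labeling")) {
    labeling$mapping
  } else {
    as.integer(labeling)
  }
  stopifnot(identical(sort(mapping), 1:3))
  inv <- order(mapping)  # inv[m] = hidden state mapped to modality m
  lab <- modality_labels()
  trans <- params$trans[inv, inv, drop = FALSE]
  dimnames(trans) <- list(lab, lab)
  emissions <- lapply(params$emissions, function(e) {
    m <- e[inv, , drop = FALSE]
    dimnames(m) <- list(lab, lab)
    m
  })
  hmm_params(pi = params$pi[inv], trans = trans, emissions = emissions)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat("  labeling:",
      paste(sprintf("state%d->%s", 1:3, modality_label(x$labeling$mapping)),
            collapse = ", "), "\n")
  cat("  max |error| transition:",
      format(x$max_abs_error_trans, digits = 3), "\n")
  cat("  max |error| emissions: ",
      format(x$max_abs_error_emissions, digits = 3), "\n")
  cat("  labeled MAP state accuracy:",
      format(x$state_accuracy, digits = 4), "\n")
  invisible(x)
}
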