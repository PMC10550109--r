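#' Read a long-format modality observation panel
#'
#' An observation panel records, one row per report, the learning modality a
#' source reported for a district in an ISO week. Absence of a row means the
#' source did not report that district-week (missingness is never encoded as
#' a sentinel value). Reading validates the schema, the source and modality
#' tokens, and the week format; exact duplicate rows are collapsed with a
#' warning, while duplicate `(district, week, source)` keys that *disagree*
#' on modality are an error, because weekly input must already be
#' deconflicted within each source.
#'
#' @param path Path to a CSV file with columns `district_id`, `week`
#'   (ISO year-week, e.g. `"2020-W37"`), `source` (one of
#'   [source_ids()]), `modality` (one of [modality_labels()]), and
#'   optionally `district_name` and `state`.
#' @return A validated panel tibble with columns `district_id`,
#'   `district_name`, `state`, `week`, `source`, `modality`.
#' @seealso [write_panel()], [filter_virtual_districts()], [simulate_panel()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "district_id,district_name,state,week,source,modality",
#'   "d1,Springfield USD,OH,2020-W37,R2LT,in_person"
#' ), tf)
#' read_panel(tf)
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_panel(raw)
}

#' Validate an in-memory observation panel
#'
#' Applies the same checks as [read_panel()]: required columns, known source
#' and modality tokens, well-formed ISO week strings, deduplication of
#' identical rows, and rejection of conflicting duplicate keys.
#'
#' @param panel A data frame with at least `district_id`, `week`, `source`,
#'   `modality`.
#' @return A validated panel tibble (see [read_panel()] for columns).
#' @export
validate_panel <- function(panel) {
  required <- c("district_id", "week", "source", "modality")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)
  if (!"district_name" %in% names(panel)) panel$district_name <- NA_character_
  if (!"state" %in% names(panel)) panel$state <- NA_character_

  bad_source <- setdiff(unique(panel$source), source_ids())
  if (length(bad_source) > 0) {
    rows <- which(panel$source %in% bad_source)
    stop("unknown source token(s) ", paste(bad_source, collapse = ", "),
         " (first at row ", rows[1], ")", call. = FALSE)
  }
  bad_mod <- setdiff(unique(panel$modality), modality_labels())
  if (length(bad_mod) > 0) {
    rows <- which(panel$modality %in% bad_mod)
    stop("unknown modality token(s) ", paste(bad_mod, collapse = ", "),
         " (first at row ", rows[1], ")", call. = FALSE)
  }
  iso_week_check(panel$week)

  panel <- dplyr::select(panel, dplyr::all_of(
    c("district_id", "district_name", "state", "week", "source", "modality")))

  n_before <- nrow(panel)
  panel <- dplyr::distinct(panel)
  n_dupes <- n_before - nrow(panel)
  if (n_dupes > 0) {
    warning(n_dupes, " exact duplicate panel row(s) collapsed",
            call. = FALSE)
  }

  conflicts <- panel |>
    dplyr::count(.data$district_id, .data$week, .data$source) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    c1 <- conflicts[1, ]
    stop("conflicting modalities for ", nrow(conflicts),
         " (district, week, source) key(s); first: district ",
         c1$district_id, ", week ", c1$week, ", source ", c1$source,
         call. = FALSE)
  }
  dplyr::arrange(panel, .data$district_id, .data$week, .data$source)
}

#' Write an observation panel to CSV
#'
#' The inverse of [read_panel()]: `read_panel(write_panel(p, f))` returns a
#' panel identical to `p`. Missing district-week-source observations are
#' simply absent rows, never blank fields.
#'
#' @param panel A validated panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

# Name keywords indicating a pre-pandemic virtual-only district.
virtual_keywords <- function() {
  c("online", "cyber", "distance", "remote", "virtual", "digital")
}

#' Drop districts that are virtual schools by design
#'
#' Districts whose *name* contains any of "online", "cyber", "distance",
#' "remote", "virtual", or "digital" (case-insensitive substring match) are
#' excluded from analysis: such districts do not offer in-person instruction
#' even outside a pandemic, so their modality carries no reopening signal.
#'
#' @param panel A validated panel tibble with `district_name` populated.
#' @return The panel with all rows of matching districts removed. The number
#'   of removed districts is reported via `message()`.
#' @examples
#' p <- tibble::tibble(
#'   district_id = c("d1", "d2"),
#'   district_name = c("Springfield USD", "Ohio Virtual Academy"),
#'   state = "OH", week = "2020-W37", source = "R2LT",
#'   modality = c("in_person", "remote")
#' )
#' filter_virtual_districts(p)
#' @export
filter_virtual_districts <- function(panel) {
  panel <- validate_panel(panel)
  pattern <- paste(virtual_keywords(), collapse = "|")
  names_by_district <- panel |>
    dplyr::distinct(.data$district_id, .data$district_name)
  hit <- grepl(pattern, names_by_district$district_name, ignore.case = TRUE)
  drop_ids <- unique(names_by_district$district_id[hit & !is.na(
    names_by_district$district_name)])
  if (length(drop_ids) > 0) {
    message("filter_virtual_districts: removed ", length(drop_ids),
            " district(s) with virtual-indicating names")
  }
  dplyr::filter(panel, !.data$district_id %in% drop_ids)
}

# The six-level county urban-rural scheme used for stratified trends.
urban_rural_classes <- function() {
  c("large central metro", "large fringe metro", "medium metro",
    "small metro", "micropolitan", "non-core")
}

#' Read a district to urban-rural crosswalk
#'
#' Maps districts to the county six-level urban-rural classification
#' (`large central metro`, `large fringe metro`, `medium metro`,
#' `small metro`, `micropolitan`, `non-core`) for stratified trend tables.
#' Districts absent from the crosswalk are allowed and are reported
#' downstream under an `"unclassified"` stratum.
#'
#' @param path CSV with columns `district_id`, `urban_rural_class`, and
#'   optionally `county_fips`.
#' @return A tibble with columns `district_id`, `county_fips`,
#'   `urban_rural_class`.
#' @seealso [weekly_shares()]
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) {
    stop("crosswalk file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    return(tibble::tibble(district_id = character(),
                          county_fips = character(),
                          urban_rural_class = character()))
  }
  required <- c("district_id", "urban_rural_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("crosswalk is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"county_fips" %in% names(raw)) raw$county_fips <- NA_character_
  bad <- setdiff(unique(raw$urban_rural_class), urban_rural_classes())
  if (length(bad) > 0) {
    stop("unknown urban-rural class token(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$district_id)) {
    stop("crosswalk lists some district_id more than once", call. = FALSE)
  }
  dplyr::select(tibble::as_tibble(raw), dplyr::all_of(
    c("district_id", "county_fips", "urban_rural_class")))
}
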