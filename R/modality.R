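#' Learning-modality codes and labels
#'
#' School-district operating status is coded on a fixed three-level scale:
#' 1 = `remote` (no face-to-face instruction), 2 = `hybrid` (partial
#' face-to-face instruction), 3 = `in_person` (five days per week for all
#' grades). All panel and decoding functions in modalhmm use this encoding.
#'
#' @return `modality_labels()` returns the character vector
#'   `c("remote", "hybrid", "in_person")` in code order.
#' @examples
#' modality_labels()
#' modality_code(c("in_person", "remote"))
#' modality_label(c(1L, 3L))
#' @export
modality_labels <- function() {
  c("remote", "hybrid", "in_person")
}

#' @rdname modality_labels
#' @param label Character vector of modality labels.
#' @return `modality_code()` returns the integer codes for `label`.
#' @export
modality_code <- function(label) {
  code <- match(label, modality_labels())
  if (anyNA(code) && !anyNA(label)) {
    bad <- unique(label[is.na(code)])
    stop("unknown modality label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code
}

#' @rdname modality_labels
#' @param code Integer vector of modality codes in `{1, 2, 3}`.
#' @return `modality_label()` returns the labels for `code`.
#' @export
modality_label <- function(code) {
  ok <- is.na(code) | (code %in% 1:3)
  if (!all(ok)) {
    stop("modality codes must be in {1, 2, 3}", call. = FALSE)
  }
  modality_labels()[code]
}

#' Surveillance source identifiers
#'
#' The four modality trackers whose reports the model fuses, in the fixed
#' slot order used for emission matrices: `BURBIO` (media reports and manual
#' website review), `MCH` (phone surveys), `R2LT` (automated
#' website/dashboard scraping), `SD` (state dashboards).
#'
#' @return Character vector of the four source names.
#' @examples
#' source_ids()
#' @export
source_ids <- function() {
  c("BURBIO", "MCH", "R2LT", "SD")
}

# ---- ISO week arithmetic -------------------------------------------------
# Weeks are identified by ISO-8601 year-week strings ("2020-W37"). The
# helpers below convert between those strings and the Monday date of the
# week, which gives a total order and supports contiguous sequences across
# year boundaries (2020 has 53 ISO weeks).

iso_week_check <- function(week) {
  ok <- grepl("^\\d{4}-W\\d{2}$", week)
  if (!all(ok)) {
    stop("malformed ISO week identifier(s): ",
         paste(utils::head(unique(week[!ok]), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(week)
}

# Monday (as Date) of an ISO year-week.
iso_week_monday <- function(week) {
  iso_week_check(week)
  year <- as.integer(substr(week, 1, 4))
  wk <- as.integer(substr(week, 7, 8))
  jan4 <- as.Date(paste0(year, "-01-04"))
  # ISO weekday of Jan 4 (Mon = 1 ... Sun = 7)
  wd <- as.integer(format(jan4, "%u"))
  monday_w1 <- jan4 - (wd - 1)
  monday_w1 + 7L * (wk - 1L)
}

# ISO year-week string for a Date.
date_iso_week <- function(date) {
  format(as.Date(date), "%G-W%V")
}

# Contiguous sequence of ISO weeks from `from` to `to` inclusive.
iso_week_seq <- function(from, to) {
  m1 <- iso_week_monday(from)
  m2 <- iso_week_monday(to)
  if (m2 < m1) stop("'to' week precedes 'from' week", call. = FALSE)
  date_iso_week(seq(m1, m2, by = 7))
}

# Offset a week by n weeks.
iso_week_shift <- function(week, n) {
  date_iso_week(iso_week_monday(week) + 7L * as.integer(n))
}
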