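#' Construct and validate HMM parameters
#'
#' The model has three hidden states (the true weekly modality of a
#' district) and four conditionally independent categorical emission
#' channels, one per source. Parameters are the initial state distribution
#' `pi`, the 3x3 row-stochastic transition matrix `trans`
#' (`trans[i, j] = P(next = j | current = i)`), and one 3x3 row-stochastic
#' emission matrix per source (`emissions$R2LT[i, j] = P(R2LT reports j |
#' true state i)`). Rows and `pi` must each sum to 1 within `1e-9` with all
#' entries non-negative.
#'
#' @param pi Numeric length-3 initial state distribution.
#' @param trans Numeric 3x3 transition matrix.
#' @param emissions Named list of 3x3 emission matrices, one per source in
#'   [source_ids()].
#' @return An object of class `hmm_params`.
#' @seealso [reference_hmm_params()], [fit_hmm()], [write_hmm_params()]
#' @export
hmm_params <- function(pi, trans, emissions) {
  pi <- as.numeric(pi)
  trans <- as.matrix(trans)
  emissions <- emissions[source_ids()]
  if (any(vapply(emissions, is.null, logical(1)))) {
    stop("emissions must contain one matrix per source: ",
         paste(source_ids(), collapse = ", "), call. = FALSE)
  }
  emissions <- lapply(emissions, as.matrix)
  obj <- structure(
    list(pi = pi, trans = trans, emissions = emissions),
    class = "hmm_params")
  check_hmm_params(obj)
  obj
}

check_stochastic <- function(x, what, tol = 1e-9) {
  if (anyNA(x) || any(x < 0)) {
    stop(what, " must be non-negative and free of NA", call. = FALSE)
  }
  sums <- if (is.matrix(x)) rowSums(x) else sum(x)
  if (any(abs(sums - 1) > tol)) {
    stop(what, " rows must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  invisible(x)
}

check_hmm_params <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  if (length(params$pi) != 3) stop("pi must have length 3", call. = FALSE)
  if (!all(dim(params$trans) == c(3, 3))) {
    stop("trans must be 3x3", call. = FALSE)
  }
  check_stochastic(params$pi, "pi")
  check_stochastic(params$trans, "transition matrix")
  for (s in source_ids()) {
    e <- params$emissions[[s]]
    if (!all(dim(e) == c(3, 3))) {
      stop("emission matrix for ", s, " must be 3x3", call. = FALSE)
    }
    check_stochastic(e, paste("emission matrix", s))
  }
  invisible(params)
}

#' @export
print.hmm_params <- function(x, digits = 3, ...) {
  lab <- modality_labels()
  cat("<hmm_params>: 3-state modality HMM, 4 emission channels\n")
  cat("pi:", paste(sprintf("%s=%.*f", lab, digits, x$pi), collapse = " "),
      "\n")
  cat("transition matrix:\n")
  tm <- round(x$trans, digits)
  dimnames(tm) <- list(lab, lab)
  print(tm)
  for (s in source_ids()) {
    cat("emissions[", s, "]:\n", sep = "")
    em <- round(x$emissions[[s]], digits)
    dimnames(em) <- list(true = lab, reported = lab)
    print(em)
  }
  invisible(x)
}

#' Tidy HMM parameters into a long tibble
#'
#' @param x An `hmm_params` object.
#' @param ... Unused.
#' @return A tibble with columns `component` (`"pi"`, `"trans"`, or a source
#'   name), `from` (current/true modality; `NA` for `pi`), `to`
#'   (next/reported modality), and `probability`.
#' @method tidy hmm_params
#' @export
tidy.hmm_params <- function(x, ...) {
  lab <- modality_labels()
  rows <- list(
    tibble::tibble(component = "pi", from = NA_character_, to = lab,
                   probability = x$pi),
    tibble::tibble(component = "trans",
                   from = rep(lab, each = 3), to = rep(lab, 3),
                   probability = as.vector(t(x$trans)))
  )
  for (s in source_ids()) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = s, from = rep(lab, each = 3), to = rep(lab, 3),
      probability = as.vector(t(x$emissions[[s]])))
  }
  dplyr::bind_rows(rows)
}

# Row-normalize a non-negative matrix, flooring all-zero rows to uniform.
row_normalize <- function(m) {
  s <- rowSums(m)
  s[s == 0] <- 1
  out <- m / s
  zero <- rowSums(m) == 0
  if (any(zero)) out[zero, ] <- 1 / ncol(m)
  out
}

#' Reference parameter set for the 2020-2021 school year
#'
#' A fitted national parameterization of the modality HMM representative of
#' the 2020-2021 U.S. school year: strongly sticky weekly dynamics
#' (self-transition probabilities 0.903 / 0.961 / 0.983 for remote / hybrid
#' / in-person) and diagonal-dominant per-source emission fidelities, with
#' R2LT by far the most faithful channel (on-diagonal ~0.99) and MCH and SD
#' noticeably noisier off the diagonal. Rows are renormalized to sum to 1
#' exactly, since the published three-decimal values can be off by 1e-3.
#' Used as the ground truth for synthetic panels and recovery experiments.
#'
#' @return An [hmm_params()] object.
#' @seealso [reference_generator_spec()], [recovery_experiment()]
#' @examples
#' reference_hmm_params()$trans
#' @export
reference_hmm_params <- function() {
  lab <- modality_labels()
  trans <- matrix(c(
    0.903, 0.079, 0.018,
    0.014, 0.961, 0.025,
    0.004, 0.013, 0.983), nrow = 3, byrow = TRUE,
    dimnames = list(lab, lab))
  em <- list(
    BURBIO = c(0.805, 0.145, 0.050,
               0.067, 0.617, 0.317,
               0.016, 0.161, 0.823),
    MCH = c(0.795, 0.178, 0.027,
            0.090, 0.775, 0.135,
            0.055, 0.347, 0.598),
    R2LT = c(0.992, 0.008, 0.001,
             0.002, 0.997, 0.001,
             0.001, 0.001, 0.997),
    SD = c(0.642, 0.330, 0.028,
           0.003, 0.863, 0.134,
           0.001, 0.042, 0.956))
  emissions <- lapply(em, function(v) {
    m <- matrix(v, nrow = 3, byrow = TRUE, dimnames = list(lab, lab))
    row_normalize(m)
  })
  hmm_params(pi = c(0.25, 0.35, 0.40),
             trans = row_normalize(trans),
             emissions = emissions)
}

#' Serialize HMM parameters to JSON
#'
#' Parameters are written as
#' `{"pi": [...], "T": [[...]], "emissions": {"BURBIO": [[...]], ...}}`,
#' the layout consumed by [read_hmm_params()] and by the pipeline artifacts.
#'
#' @param params An `hmm_params` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_hmm_params <- function(params, path) {
  check_hmm_params(params)
  payload <- list(
    pi = params$pi,
    T = unname(apply(params$trans, 1, as.numeric, simplify = FALSE)),
    emissions = lapply(params$emissions, function(m) {
      unname(apply(m, 1, as.numeric, simplify = FALSE))
    }))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_params
#' @return `read_hmm_params()` returns the `hmm_params` object stored at
#'   `path`.
#' @export
read_hmm_params <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- modality_labels()
  as_m <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(lab, lab)
    m
  }
  hmm_params(pi = as.numeric(payload$pi),
             trans = as_m(payload$T),
             emissions = lapply(payload$emissions, as_m))
}
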