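make_trackers <- function(...) {
  dplyr::bind_rows(...)
}

tracker_rows <- function(tracker, district_id, week, modality) {
  tibble::tibble(tracker = tracker, district_id = district_id,
                 week = week, modality = modality)
}

test_that("pairwise agreement counts overlap and matches by hand", {
  # A=(r,h,i), B=(r,r,i) on 3 shared district-weeks -> agreement 2/3
  tr <- make_trackers(
    tracker_rows("A", c("d1", "d2", "d3"), "2020-W40",
                 c("remote", "hybrid", "in_person")),
    tracker_rows("B", c("d1", "d2", "d3"), "2020-W40",
                 c("remote", "remote", "in_person")))
  ag <- pairwise_agreement(tr)
  expect_equal(ag$n_overlap, 3L)
  expect_equal(ag$n_match, 2L)
  expect_equal(ag$agreement, 2 / 3)

  # identical trackers agree perfectly on every overlapping cell
  tr2 <- make_trackers(
    tracker_rows("A", c("d1", "d2"), "2020-W40", c("remote", "hybrid")),
    tracker_rows("B", c("d1", "d2"), "2020-W40", c("remote", "hybrid")))
  expect_equal(pairwise_agreement(tr2)$agreement, 1)

  # self-agreement on own coverage is exactly 1
  self <- pairwise_agreement(tr, include_self = TRUE)
  expect_equal(self$agreement[self$tracker1 == self$tracker2],
               c(1, 1))

  # disjoint coverage: overlap 0, agreement missing (not zero)
  tr3 <- make_trackers(
    tracker_rows("A", "d1", "2020-W40", "remote"),
    tracker_rows("B", "d2", "2020-W40", "remote"))
  ag3 <- pairwise_agreement(tr3)
  expect_equal(ag3$n_overlap, 0L)
  expect_true(is.na(ag3$agreement))
})

test_that("paired one-sided t-test separates clear wins and degenerate ties", {
  weeks <- sprintf("2021-W%02d", 1:10)
  districts <- sprintf("d%02d", 1:30)
  grid <- tidyr::expand_grid(district_id = districts, week = weeks)
  base <- sample(modality_labels(), nrow(grid), replace = TRUE)

  # HMM identical to the tracker; comparator agrees only ~half the time
  withr::local_seed(90)
  flip <- function(m, p_wrong) {
    wrong <- runif(length(m)) < p_wrong
    m[wrong] <- vapply(m[wrong], function(x) {
      sample(setdiff(modality_labels(), x), 1)
    }, character(1))
    m
  }
  tr <- make_trackers(
    tracker_rows("BURBIO", grid$district_id, grid$week, base),
    tracker_rows("HMM", grid$district_id, grid$week, base),
    tracker_rows("MCH", grid$district_id, grid$week, flip(base, 0.5)))
  res <- agreement_ttest(tr, "BURBIO")
  expect_equal(res$comparator, "MCH")
  expect_equal(res$n_weeks, 10L)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$mean_diff, 0.3)

  # comparator series equal to the HMM series every week: t = 0, p = 0.5
  tr_tie <- make_trackers(
    tracker_rows("BURBIO", grid$district_id, grid$week, base),
    tracker_rows("HMM", grid$district_id, grid$week, base),
    tracker_rows("MCH", grid$district_id, grid$week, base))
  res_tie <- agreement_ttest(tr_tie, "BURBIO")
  expect_equal(res_tie$statistic, 0)
  expect_equal(res_tie$p_value, 0.5)

  # fewer than 2 paired weeks is an error
  tr_short <- make_trackers(
    tracker_rows("BURBIO", "d1", "2021-W01", "remote"),
    tracker_rows("HMM", "d1", "2021-W01", "remote"),
    tracker_rows("MCH", "d1", "2021-W01", "remote"))
  expect_error(agreement_ttest(tr_short, "BURBIO"), "paired weeks")
})

test_that("fusion beats single sources in mean agreement on synthetic data", {
  sim <- simulate_panel(reference_generator_spec(n_districts = 800,
                                                 n_weeks = 30, seed = 83))
  inferred <- infer_modalities(sim$panel, reference_hmm_params())
  trackers <- bind_trackers(sim$panel, inferred)
  ag <- pairwise_agreement(trackers)
  pair_val <- function(a, b) {
    row <- dplyr::filter(ag, (tracker1 == a & tracker2 == b) |
                           (tracker1 == b & tracker2 == a))
    row$agreement
  }
  # the fused estimate agrees with R2LT more than with the noisier feeds
  expect_gt(pair_val("HMM", "R2LT"), pair_val("HMM", "BURBIO"))
  expect_gt(pair_val("HMM", "R2LT"), pair_val("HMM", "MCH"))
  # direction check: for each source, mean weekly agreement with the HMM
  # exceeds agreement with every other single source
  for (src in c("MCH", "BURBIO")) {
    res <- agreement_ttest(trackers, src)
    expect_true(all(res$mean_diff > 0))
  }
})

test_that("weekly shares are hand-countable, sum to one, and stratify", {
  decoded <- modalhmm:::new_decoded_panel(tibble::tibble(
    district_id = c("d1", "d2", "d3", "d4"),
    state = c("OH", "OH", "PA", "PA"),
    week = "2021-W10",
    p_remote = 0.1, p_hybrid = 0.1, p_in_person = 0.8,
    map_modality = c("in_person", "in_person", "hybrid", "remote"),
    viterbi_modality = c("in_person", "in_person", "hybrid", "remote"),
    confidence = c(0.9, 0.9, 0.9, 0.6)), labeled = TRUE)
  tr <- weekly_shares(decoded)
  expect_equal(tr$share_remote, 0.25)
  expect_equal(tr$share_hybrid, 0.25)
  expect_equal(tr$share_in_person, 0.5)
  expect_equal(tr$n_districts, 4L)
  expect_equal(tr$share_remote + tr$share_hybrid + tr$share_in_person, 1)

  # high-confidence restriction never increases the denominator
  tr_hc <- weekly_shares(decoded, high_confidence_only = TRUE)
  expect_lte(tr_hc$n_districts, tr$n_districts)
  expect_equal(tr_hc$n_districts, 3L)

  # state strata
  by_state <- weekly_shares(decoded, strata = "state")
  expect_equal(nrow(by_state), 2)
  expect_equal(by_state$share_in_person[by_state$stratum == "OH"], 1)

  # urban-rural strata with a partial crosswalk
  cw <- tibble::tibble(district_id = c("d1", "d2", "d3"),
                       county_fips = NA_character_,
                       urban_rural_class = c("large central metro",
                                             "large central metro",
                                             "non-core"))
  by_ur <- weekly_shares(decoded, crosswalk = cw, strata = "urban_rural")
  expect_setequal(by_ur$stratum,
                  c("large central metro", "non-core", "unclassified"))
  expect_equal(by_ur$n_districts[by_ur$stratum == "unclassified"], 1L)
  expect_error(weekly_shares(decoded, strata = "urban_rural"),
               "crosswalk")
})

test_that("all-in-person decodes give degenerate shares every week", {
  decoded <- modalhmm:::new_decoded_panel(tidyr::expand_grid(
    district_id = c("d1", "d2"),
    week = c("2021-W01", "2021-W02")) |>
      dplyr::mutate(state = "OH", p_remote = 0, p_hybrid = 0,
                    p_in_person = 1, map_modality = "in_person",
                    viterbi_modality = "in_person", confidence = 1),
    labeled = TRUE)
  tr <- weekly_shares(decoded)
  expect_equal(tr$share_in_person, c(1, 1))
  expect_equal(tr$share_remote, c(0, 0))
})

test_that("long-run inferred shares approach the stationary distribution", {
  # stationary distribution of the sticky reference dynamics via an
  # independent eigenvector oracle
  trans <- reference_hmm_params()$trans
  ev <- eigen(t(trans))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)

  spec <- generator_spec(n_districts = 3000, n_weeks = 60,
                         params = hmm_params(pi = stat, trans = trans,
                                             emissions =
                                               reference_hmm_params()$emissions),
                         presence = c(BURBIO = 0.2, MCH = 0.2, R2LT = 0.8,
                                      SD = 0.2),
                         seed = 97)
  sim <- simulate_panel(spec)
  inferred <- infer_modalities(sim$panel, spec$params)
  tr <- weekly_shares(inferred)
  mean_shares <- c(mean(tr$share_remote), mean(tr$share_hybrid),
                   mean(tr$share_in_person))
  expect_lt(max(abs(mean_shares - stat)), 0.03)
})

test_that("state endpoint summary reports percentages and changes", {
  trend <- structure(tibble::tibble(
    stratum = rep(c("SC", "FL"), each = 3),
    week = rep(c("2020-W37", "2021-W03", "2021-W25"), 2),
    share_remote = 0.1, share_hybrid = 0.2,
    share_in_person = c(0.063, 0.5, 0.975, 1, 1, 1),
    n_districts = 40L),
    class = c("trend_table", class(tibble::tibble())), strata = "state")
  res <- state_endpoint_summary(trend,
                                c("2020-W37", "2021-W03", "2021-W25"))
  sc <- dplyr::filter(res, state == "SC")
  expect_equal(sc$pct_start, 6.3)
  expect_equal(sc$pct_end, 97.5)
  expect_equal(sc$change, 91.2, tolerance = 1e-9)
  fl <- dplyr::filter(res, state == "FL")
  expect_equal(fl$change, 0)
  expect_error(state_endpoint_summary(trend, c("2020-W37", "2021-W03")),
               "three")
  expect_error(
    state_endpoint_summary(trend, c("2020-W37", "2021-W03", "2021-W26")),
    "not present")
})
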