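#' Item rosters for the three instruments
#'
#' Canonical column names for the item-level tables used throughout the
#' package: 28 MMAPP items coded 0-3, 15 DERS short-form items coded 0-4,
#' and 8 DBIS items coded 0-3. Response options are coded from 0 so that the
#' instrument maxima match the scale maxima used for the equivalence bounds
#' (27 for the embedded PHQ-A, 21 for the GAD-7, 60 for DERS, 24 for DBIS).
#'
#' @return A named list with character vectors `mmapp`, `ders`, `dbis`, and
#'   the derived-item groupings `phqa_domains` and `gad7_items`.
#' @export
mh_item_roster <- function() {
  mmapp <- c(
    # PHQ-A constituents
    "mmapp_sad_depressed", "mmapp_annoyed_irritable", "mmapp_hopeless",
    "mmapp_difficulty_falling_asleep", "mmapp_waking_up_at_night",
    "mmapp_sleeping_too_much",
    "mmapp_moving_slowly", "mmapp_restless",
    "mmapp_not_enjoying", "mmapp_easily_tired", "mmapp_appetite_change",
    "mmapp_felt_like_failure", "mmapp_trouble_concentrating",
    "mmapp_self_harm_thoughts",
    # GAD-7 constituents not already listed
    "mmapp_nervous_anxious", "mmapp_uncontrollable_worry",
    "mmapp_worried_many_things", "mmapp_difficulty_relaxing",
    "mmapp_worried_bad_things",
    # remaining screener items
    "mmapp_lonely", "mmapp_cried_a_lot", "mmapp_fearful",
    "mmapp_angry_outbursts", "mmapp_frequent_arguments",
    "mmapp_rule_breaking", "mmapp_physical_complaints",
    "mmapp_low_self_worth", "mmapp_social_withdrawal"
  )
  ders <- c("ders_attend", "ders_care", "ders_aware",
            paste0("ders_item", sprintf("%02d", 4:15)))
  dbis <- paste0("dbis_item", 1:8)
  list(
    mmapp = mmapp,
    ders = ders,
    dbis = dbis,
    ders_reversed = c("ders_attend", "ders_care", "ders_aware"),
    phqa_domains = list(
      negative_mood = c("mmapp_sad_depressed", "mmapp_annoyed_irritable",
                        "mmapp_hopeless"),
      sleep = c("mmapp_difficulty_falling_asleep", "mmapp_waking_up_at_night",
                "mmapp_sleeping_too_much"),
      motor = c("mmapp_moving_slowly", "mmapp_restless"),
      singles = c("mmapp_not_enjoying", "mmapp_easily_tired",
                  "mmapp_appetite_change", "mmapp_felt_like_failure",
                  "mmapp_trouble_concentrating", "mmapp_self_harm_thoughts")
    ),
    gad7_items = c("mmapp_nervous_anxious", "mmapp_uncontrollable_worry",
                   "mmapp_worried_many_things", "mmapp_difficulty_relaxing",
                   "mmapp_restless", "mmapp_annoyed_irritable",
                   "mmapp_worried_bad_things")
  )
}

# Default roster for the MMAPP total: the three sleep items enter through
# the max term only, and the motor/anxiety duplicate item is dropped, so the
# theoretical maximum is 3 + 24 * 3 = 75, consistent with the 5% equivalence
# bound of 3.75.
mmapp_total_default_roster <- function() {
  r <- mh_item_roster()
  setdiff(r$mmapp, c(r$phqa_domains$sleep, "mmapp_restless"))
}

# rowwise max/sum that propagate NA (scores are defined for complete rows only)
row_stat <- function(items, cols, fun) {
  miss <- setdiff(cols, names(items))
  if (length(miss)) stop("missing item columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(items[, cols, drop = FALSE])
  apply(m, 1, function(x) if (anyNA(x)) NA_real_ else fun(x))
}

check_item_range <- function(items, cols, max_val) {
  m <- as.matrix(items[, intersect(cols, names(items)), drop = FALSE])
  bad <- m < 0 | m > max_val
  if (any(bad, na.rm = TRUE)) {
    stop("item responses out of range 0..", max_val)
  }
}

#' Score the embedded PHQ-A depression items
#'
#' Items split into subquestions during cultural adaptation are collapsed to
#' their symptom domain by taking the highest score among them: negative
#' mood = max(sad/depressed, annoyed/irritable, hopeless); sleep =
#' max(difficulty falling asleep, waking up at night, sleeping too much);
#' motor = max(moving slowly, restless). The three domain maxima are added
#' to the six remaining single items, giving 9 domains and a 0-27 range.
#'
#' @param items data frame with the MMAPP item columns of
#'   [mh_item_roster()]; one row per participant.
#' @return Numeric vector of scores (0-27); `NA` where any constituent item
#'   is missing.
#' @export
score_phqa <- function(items) {
  d <- mh_item_roster()$phqa_domains
  check_item_range(items, unlist(d), 3)
  row_stat(items, d$negative_mood, max) +
    row_stat(items, d$sleep, max) +
    row_stat(items, d$motor, max) +
    row_stat(items, d$singles, sum)
}

#' Score the embedded GAD-7 anxiety items
#'
#' Plain sum of the seven anxiety-related items; range 0-21.
#'
#' @inheritParams score_phqa
#' @return Numeric vector of scores (0-21); `NA` for incomplete rows.
#' @export
score_gad7 <- function(items) {
  g <- mh_item_roster()$gad7_items
  check_item_range(items, g, 3)
  row_stat(items, g, sum)
}

#' Score the MMAPP total
#'
#' The total takes the maximum of the three sleep items and adds it to the
#' sum over the item roster. The default roster excludes the sleep items
#' (represented by their maximum) and the motor/anxiety duplicate item, so
#' the theoretical maximum is 75; pass `roster` to change the set of summed
#' items.
#'
#' @inheritParams score_phqa
#' @param roster character vector of MMAPP item columns entering the sum.
#' @return Numeric vector of total scores; `NA` for incomplete rows.
#' @export
score_mmapp_total <- function(items, roster = mmapp_total_default_roster()) {
  r <- mh_item_roster()
  check_item_range(items, r$mmapp, 3)
  row_stat(items, r$phqa_domains$sleep, max) + row_stat(items, roster, sum)
}

#' Score the DERS short form
#'
#' Reverse-codes the three positively worded awareness items
#' (`x -> 4 - x`) and sums all 15 items; range 0-60.
#'
#' @param items data frame with the DERS item columns of [mh_item_roster()].
#' @return Numeric vector of scores (0-60); `NA` for incomplete rows.
#' @export
score_ders <- function(items) {
  r <- mh_item_roster()
  check_item_range(items, r$ders, 4)
  rev_cols <- r$ders_reversed
  fwd_cols <- setdiff(r$ders, rev_cols)
  rev_sum <- row_stat(items, rev_cols, function(x) sum(4 - x))
  rev_sum + row_stat(items, fwd_cols, sum)
}

#' Score the DBIS externalizing scale
#'
#' Sum of all eight items; range 0-24.
#'
#' @param items data frame with the DBIS item columns of [mh_item_roster()].
#' @return Numeric vector of scores (0-24); `NA` for incomplete rows.
#' @export
score_dbis <- function(items) {
  r <- mh_item_roster()
  check_item_range(items, r$dbis, 3)
  row_stat(items, r$dbis, sum)
}

#' False-alarm percentage from an emotional go/no-go log
#'
#' A false alarm is a response on a no-go trial. The percentage divides the
#' number of false alarms by the total number of responses (go and no-go
#' alike), times 100; practice trials are excluded. Set
#' `denominator = "nogo_trials"` for the alternative convention that divides
#' by the number of no-go trials instead.
#'
#' @param trials data frame with columns `trial_type` ("go"/"nogo"),
#'   `response` (logical or 0/1) and `practice` (logical); one row per trial.
#' @param denominator `"responses"` (default) or `"nogo_trials"`.
#' @return False-alarm percentage (0-100); `NA` when the denominator is 0.
#' @export
score_egng <- function(trials, denominator = c("responses", "nogo_trials")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("trial_type", "response", "practice") %in% names(trials)))
  t <- trials[!as.logical(trials$practice), , drop = FALSE]
  resp <- as.logical(t$response)
  fa <- sum(resp & t$trial_type == "nogo")
  den <- switch(denominator,
                responses = sum(resp),
                nogo_trials = sum(t$trial_type == "nogo"))
  if (den == 0) return(NA_real_)
  100 * fa / den
}

#' Immediate-reward percentage from a delay discounting log
#'
#' Divides the number of immediate-reward selections by the number of
#' responded trials, times 100.
#'
#' @param trials data frame with a `choice` column taking values
#'   `"immediate"`, `"delayed"` or `NA` (no response).
#' @return Immediate-reward percentage (0-100); `NA` with zero responses.
#' @export
score_ddt <- function(trials) {
  stopifnot("choice" %in% names(trials))
  ch <- trials$choice[!is.na(trials$choice)]
  if (!length(ch)) return(NA_real_)
  100 * sum(ch == "immediate") / length(ch)
}

#' Score a cohort item table into the seven outcome variables
#'
#' Applies all scoring rules to a wide participant table and returns the
#' seven outcomes used in the analyses. Rows with missing constituent items
#' yield `NA` scores (scoring is intended for completed, post-imputation
#' tables).
#'
#' @param data data frame with `participant_id` and the item columns of
#'   [mh_item_roster()]; task percentages are taken from columns
#'   `false_alarm_pct` / `immediate_reward_pct` when present.
#' @return A data frame keyed by `participant_id` with columns `ders`,
#'   `false_alarm_pct`, `immediate_reward_pct`, `mmapp_gad7`, `mmapp_phqa`,
#'   `mmapp_total`, `dbis`.
#' @export
score_cohort <- function(data) {
  out <- data.frame(participant_id = data$participant_id)
  out$ders <- score_ders(data)
  out$false_alarm_pct <- if ("false_alarm_pct" %in% names(data)) {
    data$false_alarm_pct
  } else {
    NA_real_
  }
  out$immediate_reward_pct <- if ("immediate_reward_pct" %in% names(data)) {
    data$immediate_reward_pct
  } else {
    NA_real_
  }
  out$mmapp_gad7 <- score_gad7(data)
  out$mmapp_phqa <- score_phqa(data)
  out$mmapp_total <- score_mmapp_total(data)
  out$dbis <- score_dbis(data)
  out
}
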