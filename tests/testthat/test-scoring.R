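test_that("PHQ-A scoring applies the derived-item maximum rule", {
  z <- constant_item_table()
  expect_equal(score_phqa(z), 0)

  d <- constant_item_table()
  d$mmapp_sad_depressed <- 2
  d$mmapp_annoyed_irritable <- 1
  d$mmapp_hopeless <- 3
  expect_equal(score_phqa(d), 3)  # forced by the negative-mood max

  expect_equal(score_phqa(constant_item_table(value = 3)), 27)
})

test_that("PHQ-A score is monotone non-decreasing in each constituent", {
  r <- mh_item_roster()
  constituents <- unlist(r$phqa_domains)
  set.seed(12)
  for (k in 1:20) {
    d <- constant_item_table()
    d[constituents] <- lapply(constituents, function(x) sample(0:3, 1))
    base <- score_phqa(d)
    v <- sample(constituents, 1)
    if (d[[v]] < 3) {
      d[[v]] <- d[[v]] + 1
      expect_gte(score_phqa(d), base)
    }
  }
})

test_that("GAD-7 is a plain sum of seven items", {
  expect_equal(score_gad7(constant_item_table()), 0)
  expect_equal(score_gad7(constant_item_table(value = 3)), 21)
  d <- constant_item_table()
  g <- mh_item_roster()$gad7_items
  d[g] <- as.list(c(1, 2, 0, 3, 1, 0, 2))
  expect_equal(score_gad7(d), 9)
})

test_that("MMAPP total follows the sleep-max rule under both rosters", {
  expect_equal(score_mmapp_total(constant_item_table()), 0)
  # default roster is calibrated to a theoretical maximum of 75
  expect_equal(score_mmapp_total(constant_item_table(value = 3)), 75)
  # the literal rule (max of sleep items + sum of ALL items) double-counts
  d <- constant_item_table()
  d$mmapp_waking_up_at_night <- 2
  all_items <- mh_item_roster()$mmapp
  expect_equal(score_mmapp_total(d, roster = all_items), 4)
  expect_equal(score_mmapp_total(d), 2)  # default roster: sleep via max only
})

test_that("DERS reverse-codes the three awareness items", {
  expect_equal(score_ders(constant_item_table(value = 0)), 12)  # 3 x 4
  expect_equal(score_ders(constant_item_table(value = 4)), 48)  # 12 x 4
  expect_equal(score_ders(constant_item_table(value = 2)), 30)  # fixed point
  # double reversal is the identity
  for (x in 0:4) expect_equal(4 - (4 - x), x)
})

test_that("DBIS is a plain sum of eight items", {
  expect_equal(score_dbis(constant_item_table()), 0)
  expect_equal(score_dbis(constant_item_table(value = 3)), 24)
  d <- constant_item_table()
  d[mh_item_roster()$dbis] <- as.list(c(3, 0, 1, 2, 0, 0, 1, 1))
  expect_equal(score_dbis(d), 8)
})

test_that("go/no-go false alarms divide by total responses", {
  trials <- data.frame(
    trial_type = c(rep("go", 82), rep("nogo", 40)),
    response = c(rep(TRUE, 82), rep(TRUE, 3), rep(FALSE, 37)),
    practice = FALSE
  )
  expect_equal(score_egng(trials), 3 / 85 * 100)
  expect_equal(score_egng(trials, denominator = "nogo_trials"), 3 / 40 * 100)

  none <- transform(trials, response = response & trial_type == "go")
  expect_equal(score_egng(none), 0)
  only_nogo <- data.frame(trial_type = rep("nogo", 5), response = TRUE,
                          practice = FALSE)
  expect_equal(score_egng(only_nogo), 100)
  silent <- data.frame(trial_type = "go", response = FALSE, practice = FALSE)
  expect_true(is.na(score_egng(silent)))
  # practice trials never count
  with_practice <- rbind(trials,
                         data.frame(trial_type = "nogo", response = TRUE,
                                    practice = TRUE))
  expect_equal(score_egng(with_practice), 3 / 85 * 100)
})

test_that("delay discounting divides immediate choices by responded trials", {
  expect_equal(score_ddt(data.frame(choice = rep("delayed", 30))), 0)
  expect_equal(score_ddt(data.frame(choice = rep(c("immediate", "delayed"),
                                                 15))), 50)
  d <- data.frame(choice = c(rep("immediate", 12), rep("delayed", 17), NA))
  expect_equal(score_ddt(d), 12 / 29 * 100)
  expect_true(is.na(score_ddt(data.frame(choice = rep(NA_character_, 30)))))
})

test_that("all scores stay in range on random valid tables and ignore row order", {
  set.seed(77)
  r <- mh_item_roster()
  n <- 40
  d <- constant_item_table(n)
  d[r$mmapp] <- lapply(r$mmapp, function(x) sample(0:3, n, TRUE))
  d[r$ders] <- lapply(r$ders, function(x) sample(0:4, n, TRUE))
  d[r$dbis] <- lapply(r$dbis, function(x) sample(0:3, n, TRUE))
  sc <- score_cohort(d)
  expect_true(all(sc$mmapp_phqa >= 0 & sc$mmapp_phqa <= 27))
  expect_true(all(sc$mmapp_gad7 >= 0 & sc$mmapp_gad7 <= 21))
  expect_true(all(sc$mmapp_total >= 0 & sc$mmapp_total <= 75))
  expect_true(all(sc$ders >= 0 & sc$ders <= 60))
  expect_true(all(sc$dbis >= 0 & sc$dbis <= 24))

  perm <- sample(n)
  sc_perm <- score_cohort(d[perm, ])
  expect_equal(sc_perm$ders, sc$ders[perm])

  d$mmapp_hopeless[3] <- NA
  expect_true(is.na(score_phqa(d)[3]))
  expect_false(anyNA(score_phqa(d)[-3]))
  d$mmapp_hopeless[3] <- 9
  expect_error(score_phqa(d), "out of range")
})

test_that("simulated task logs have the documented block structure", {
  eg <- simulate_egng_log(seed = 4)
  expect_equal(sum(!eg$practice), 120)
  expect_equal(sum(eg$trial_type == "nogo" & !eg$practice), 40)
  expect_equal(sum(eg$practice), 20)
  fa <- score_egng(eg)
  expect_true(fa >= 0 && fa <= 100)
  dd <- simulate_ddt_log(seed = 4)
  expect_equal(nrow(dd), 30)
  expect_true(score_ddt(dd) >= 0 && score_ddt(dd) <= 100)
})
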