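lesion_table <- function(suvs, ids = sprintf("L%02d", seq_along(suvs))) {
  data.frame(lesion_id = ids, suv_max = suvs, stringsAsFactors = FALSE)
}

# baseline/followup pair with given summed SUVmax (single target lesion)
pair_with_sums <- function(sum_b, sum_f, new_lesion = FALSE) {
  b <- select_targets(lesion_table(sum_b, "L01"), scan_id = "S0")
  f <- select_targets(lesion_table(sum_f, "L01"), scan_id = "S1",
                      new_lesion_flag = new_lesion)
  list(b = b, f = f)
}

test_that("select_targets takes the top-k by SUVmax", {
  ts <- select_targets(lesion_table(1:7))
  expect_equal(nrow(ts$targets), 5)
  expect_equal(ts$summed_suv_max, sum(3:7))
  # oracle: the selected sum equals the max over all 5-subsets
  combs <- combn(7, 5, function(ix) sum((1:7)[ix]))
  expect_equal(ts$summed_suv_max, max(combs))
  # fewer than five: all are targets
  expect_equal(select_targets(lesion_table(c(4, 2, 9)))$summed_suv_max, 15)
  # empty input: sum 0
  expect_equal(select_targets(lesion_table(numeric(0)))$summed_suv_max, 0)
})

test_that("SUVmax ties break lexicographically by lesion id", {
  les <- data.frame(lesion_id = c("d", "c", "a", "b", "f", "e"),
                    suv_max = c(9, 8, 5, 5, 7, 6))
  ts <- select_targets(les)
  # one slot remains for the tie at 5.0: "a" wins over "b"
  expect_setequal(ts$targets$lesion_id, c("d", "c", "f", "e", "a"))
})

test_that("classification thresholds follow the adapted PERCIST rules", {
  # decrease > 30% -> PR
  expect_equal(classify_response(pair_with_sums(20, 13)$b,
                                 pair_with_sums(20, 13)$f)$category, "PR")
  # decrease 40% but new foci -> PD overrides
  p <- pair_with_sums(20, 12, new_lesion = TRUE)
  expect_equal(classify_response(p$b, p$f)$category, "PD")
  # exactly -30% is SD (strict inequalities define PR/PD)
  p30 <- pair_with_sums(20, 14)
  a30 <- classify_response(p30$b, p30$f)
  expect_equal(a30$category, "SD")
  expect_equal(a30$delta_pct, -30)
  # exactly +30% is SD too
  p30u <- pair_with_sums(20, 26)
  expect_equal(classify_response(p30u$b, p30u$f)$category, "SD")
  # just beyond the boundaries flips the category
  expect_equal(classify_response(pair_with_sums(20, 26.02)$b,
                                 pair_with_sums(20, 26.02)$f)$category, "PD")
  expect_equal(classify_response(pair_with_sums(20, 13.98)$b,
                                 pair_with_sums(20, 13.98)$f)$category, "PR")
})

test_that("CR requires all baseline targets at or below background", {
  b <- select_targets(lesion_table(c(10, 8), c("L1", "L2")), scan_id = "S0")
  f_quiet <- select_targets(lesion_table(c(1.2, 0.9), c("L1", "L2")),
                            scan_id = "S1")
  expect_equal(classify_response(b, f_quiet,
                                 background_suv = 1.5)$category, "CR")
  # one lesion above background: not CR, graded on the delta (here PR)
  f_warm <- select_targets(lesion_table(c(2.5, 0.9), c("L1", "L2")),
                           scan_id = "S1")
  expect_equal(classify_response(b, f_warm,
                                 background_suv = 1.5)$category, "PR")
  # without a background reference the CR check is disabled
  expect_equal(classify_response(b, f_quiet)$category, "PR")
  # a lesion missing from follow-up counts as resolved
  f_gone <- select_targets(lesion_table(0.5, "L1"), scan_id = "S1")
  expect_equal(classify_response(b, f_gone,
                                 background_suv = 1.5)$category, "CR")
})

test_that("zero-uptake baselines classify by re-appearance", {
  b0 <- select_targets(lesion_table(numeric(0)), scan_id = "S0")
  f0 <- select_targets(lesion_table(numeric(0)), scan_id = "S1")
  expect_equal(classify_response(b0, f0)$category, "CR")
  f1 <- select_targets(lesion_table(4), scan_id = "S1")
  a <- classify_response(b0, f1)
  expect_equal(a$category, "PD")
  expect_match(a$note, "re-appeared")
})

test_that("the classifier is total and monotone in follow-up uptake", {
  cat_rank <- c(PR = 1, SD = 2, PD = 3)
  sums <- seq(2, 40, by = 0.5)
  cats <- vapply(sums, function(s) {
    p <- pair_with_sums(20, s)
    classify_response(p$b, p$f)$category
  }, character(1))
  expect_true(all(cats %in% c("CR", "PR", "SD", "PD")))
  expect_true(all(diff(cat_rank[cats]) >= 0))
  # new-lesion flag forces PD at every delta
  cats_new <- vapply(c(2, 14, 20, 26, 40), function(s) {
    p <- pair_with_sums(20, s, new_lesion = TRUE)
    classify_response(p$b, p$f)$category
  }, character(1))
  expect_true(all(cats_new == "PD"))
})

test_that("longitudinal evaluation keeps only the last scan's verdict", {
  mk <- function(sum, id, new = FALSE)
    select_targets(lesion_table(sum, "L01"), scan_id = id,
                   new_lesion_flag = new)
  # PD, PR, SD across three follow-ups -> final SD
  ev <- evaluate_patient(list(mk(20, "S0"), mk(30, "S1"), mk(13, "S2"),
                              mk(18, "S3")))
  expect_equal(vapply(ev$assessments, `[[`, character(1), "category"),
               c("PD", "PR", "SD"))
  expect_equal(ev$final_category, "SD")
  # SD, SD, PR -> final PR
  ev2 <- evaluate_patient(list(mk(20, "S0"), mk(22, "S1"), mk(24, "S2"),
                               mk(13, "S3")))
  expect_equal(ev2$final_category, "PR")
  # two identical scans -> SD at delta 0
  ev3 <- evaluate_patient(list(mk(20, "S0"), mk(20, "S1")))
  expect_equal(ev3$final_category, "SD")
  expect_equal(ev3$assessments[[1]]$delta_pct, 0)
  # a single scan cannot be assessed
  expect_error(evaluate_patient(list(mk(20, "S0"))), "at least two")
})

test_that("vs_previous comparison references the preceding scan", {
  mk <- function(sum, id) select_targets(lesion_table(sum, "L01"),
                                         scan_id = id)
  # 20 -> 28 (+40 PD) -> 28 (0 SD vs previous, +40 PD vs baseline)
  scans <- list(mk(20, "S0"), mk(28, "S1"), mk(28, "S2"))
  expect_equal(evaluate_patient(scans, "vs_previous")$final_category, "SD")
  expect_equal(evaluate_patient(scans, "vs_baseline")$final_category, "PD")
})

test_that("cohort distribution reports two-decimal percentages", {
  d <- cohort_distribution(c(rep("SD", 9), rep("PD", 2), rep("PR", 3)))
  expect_equal(d$percent[d$category == "SD"], 64.29)
  expect_equal(d$percent[d$category == "PD"], 14.29)
  expect_equal(d$percent[d$category == "PR"], 21.43)
  expect_equal(sum(d$n), 14)
  expect_lt(abs(sum(d$percent) - 100), 0.02)
  # trivial distributions
  expect_equal(cohort_distribution(rep("SD", 5))$percent,
               c(0, 0, 100, 0))
  expect_equal(cohort_distribution(c("CR", "PR", "SD", "PD"))$percent,
               rep(25, 4))
  # invariant under reordering
  set.seed(1)
  cats <- sample(c(rep("SD", 9), rep("PD", 2), rep("PR", 3)))
  expect_equal(cohort_distribution(cats), d)
  expect_error(cohort_distribution(character(0)), "at least one")
  expect_error(cohort_distribution("XX"), "unknown")
})
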