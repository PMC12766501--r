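# Preprocessing: binning, missingness filters, IQR censoring, filling
# imputation, normalization and the leakage-free split discipline.

toy_events <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    t_hours = c(1, 3, 47.5, 0.5, 10),
    feature_id = c("hr", "hr", "hr", "hr", "rr"),
    value = c(4, 6, 10, 80, 18),
    stringsAsFactors = FALSE)
}

test_that("binning averages within intervals and flags empty cells", {
  tz <- bin_events(toy_events(), window_h = 48, bin_h = 4)
  expect_equal(dim(tz$values), c(2, 12, 2))  # 48 h / 4 h -> 12 steps
  # two readings (4, 6) in bin 1 average to 5 with mask 1
  i1 <- match("p1", tz$patient_ids); fhr <- match("hr", tz$feature_ids)
  expect_equal(tz$values[i1, 1, fhr], 5)
  expect_equal(tz$mask[i1, 1, fhr], 1)
  # empty bin: NA value, mask 0
  expect_true(is.na(tz$values[i1, 2, fhr]))
  expect_equal(tz$mask[i1, 2, fhr], 0)
  # final-bin measurement at 47.5 lands in bin 12
  expect_equal(tz$values[i1, 12, fhr], 10)
  # timestamp at the window end goes to the closed final bin
  ev <- toy_events(); ev$t_hours[2] <- 48
  tz2 <- bin_events(ev, 48, 4)
  expect_equal(tz2$mask[i1, 12, fhr], 1)
})

test_that("out-of-window timestamps are rejected with a warning", {
  ev <- rbind(toy_events(),
              data.frame(patient_id = "p1", t_hours = -2, feature_id = "hr", value = 1),
              data.frame(patient_id = "p1", t_hours = 50, feature_id = "hr", value = 1))
  expect_warning(tz <- bin_events(ev, 48, 4), "dropped")
  expect_equal(sum(tz$mask), sum(bin_events(toy_events(), 48, 4)$mask))
  expect_error(bin_events(toy_events(), 48, 5), "divisible")
})

test_that("missingness filters drop features, then patients, then the unmonitored", {
  set.seed(1)
  coh <- make_cohort(n = 30, seed = 3)
  tz <- bin_events(coh$events, 48, 4)
  # a feature observed in 59% of cells exceeds a 40% missing threshold
  f <- 1
  nm <- dim(tz$values)[1] * dim(tz$values)[2]
  drop_n <- ceiling(0.41 * nm) - sum(tz$mask[, , f] == 0)
  obs_cells <- which(tz$mask[, , f] == 1)
  kill <- obs_cells[seq_len(max(drop_n, 0))]
  m <- tz$mask[, , f]; v <- tz$values[, , f]
  m[kill] <- 0; v[kill] <- NA
  tz$mask[, , f] <- m; tz$values[, , f] <- v
  filt <- filter_missing(tz, feature_thresh = 0.4, patient_thresh = 0.99)
  expect_true(tz$feature_ids[f] %in% filt$dropped_features)

  # a fully observed tensor passes unchanged
  full <- tz
  full$mask[] <- 1
  full$values[is.na(full$values)] <- 0
  f2 <- filter_missing(full)
  expect_identical(f2$tensor$values, full$values)
  expect_length(f2$dropped_features, 0)

  # a patient with no heart-rate observations in the first 24 h is removed
  ess <- tz$feature_ids[2]
  fe <- match(ess, tz$feature_ids)
  p1 <- 1
  m2 <- tz$mask[, , fe]; v2 <- tz$values[, , fe]
  m2[p1, 1:6] <- 0; v2[p1, 1:6] <- NA
  tz$mask[, , fe] <- m2; tz$values[, , fe] <- v2
  f3 <- filter_missing(tz, feature_thresh = 1, patient_thresh = 1,
                       essential_features = ess, essential_window_h = 24)
  expect_true(tz$patient_ids[p1] %in% f3$dropped_patients)
})

test_that("fill imputation follows forward-then-backward order with mean fallback", {
  vals <- array(NA_real_, c(2, 4, 2))
  mask <- array(0, c(2, 4, 2))
  vals[1, , 1] <- c(NA, 5, NA, 7); mask[1, c(2, 4), 1] <- 1
  vals[2, , 1] <- c(1, 2, 3, 4); mask[2, , 1] <- 1
  # feature 2: patient 1 entirely missing
  vals[2, , 2] <- c(3, NA, NA, 3.4); mask[2, c(1, 4), 2] <- 1
  tz <- odtgclust:::new_feature_tensor(vals, mask, seq(0, 16, 4), c("a", "b"), c("p1", "p2"))
  st <- preprocess_stats(tz)
  out <- impute_fill(tz, st)
  expect_equal(out$values[1, , 1], c(5, 5, 5, 7))
  # fully observed series unchanged
  expect_equal(out$values[2, , 1], c(1, 2, 3, 4))
  # all-missing series -> cohort mean of feature b = (3 + 3.4) / 2
  expect_equal(out$values[1, , 2], rep(3.2, 4))
  # the observation mask is preserved
  expect_identical(out$mask, tz$mask)
})

test_that("IQR censoring uses closed Tukey fences and skips flat features", {
  # 25 train values of 2/4/6/8/10 -> Q1 = 4, Q3 = 8, fences [-2, 14] at k = 1.5
  vals <- array(NA_real_, c(5, 5, 2))
  mask <- array(0, c(5, 5, 2))
  base <- c(2, 4, 6, 8, 10)
  for (p in 1:5) { vals[p, , 1] <- base; mask[p, , 1] <- 1 }
  vals[, , 2] <- 1; mask[, , 2] <- 1  # constant feature
  tz <- odtgclust:::new_feature_tensor(vals, mask, seq(0, 20, 4), c("x", "const"), paste0("p", 1:5))
  st <- preprocess_stats(tz)  # quartiles from the clean training values
  tz$values[1, 1, 1] <- 20    # above the 14 fence
  tz$values[2, 2, 1] <- 14    # exactly at the fence: retained
  expect_warning(out <- censor_outliers_iqr(tz, st, k = 1.5), "zero IQR")
  expect_true(is.na(out$values[1, 1, 1]))
  expect_equal(out$mask[1, 1, 1], 0)
  expect_equal(out$values[2, 2, 1], 14)
  expect_equal(out$mask[2, 2, 1], 1)
  expect_equal(out$values[, , 2], tz$values[, , 2])
})

test_that("normalization z-scores with train statistics and guards sd = 0", {
  vals <- array(rnorm(60, 5, 2), c(3, 10, 2))
  vals[, , 2] <- 3  # constant
  mask <- array(1, dim(vals))
  tz <- odtgclust:::new_feature_tensor(vals, mask, seq(0, 40, 4), c("a", "b"), paste0("p", 1:3))
  st <- preprocess_stats(tz)
  out <- normalize_features(tz, st)
  expect_equal(mean(out$values[, , 1]), 0, tolerance = 1e-10)
  expect_equal(sd(as.vector(out$values[, , 1])), 1, tolerance = 1e-2)
  expect_true(all(out$values[, , 2] == 0))
  # worked z-score: mean 5, sd 2, value 9 -> 2
  st2 <- st; st2$mean[1] <- 5; st2$sd[1] <- 2
  tz2 <- tz; tz2$values[1, 1, 1] <- 9
  expect_equal(normalize_features(tz2, st2)$values[1, 1, 1], 2)
})

test_that("cohort split is proportioned, disjoint, exhaustive and seeded", {
  ids <- paste0("p", 1:10)
  sp <- split_cohort(ids, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(lengths(sp), c(train = 6, validation = 2, test = 2))
  expect_setequal(unlist(sp), ids)
  expect_identical(sp, split_cohort(ids, c(0.6, 0.2, 0.2), seed = 4))
  expect_error(split_cohort(paste0("p", 1:2), c(0.6, 0.2, 0.2), 1), "too small")
})

test_that("no test-split value influences the preprocessing statistics", {
  coh <- make_cohort(n = 40, seed = 9)
  tz <- bin_events(coh$events, 48, 4)
  sp <- split_cohort(tz$patient_ids, seed = 2)
  st <- preprocess_stats(tz, sp$train)
  # perturb every test patient's values wildly; train statistics unchanged
  rows <- which(tz$patient_ids %in% sp$test)
  tz2 <- tz
  tz2$values[rows, , ] <- tz2$values[rows, , ] * 1000 + 5
  st2 <- preprocess_stats(tz2, sp$train)
  expect_identical(st$mean, st2$mean)
  expect_identical(st$sd, st2$sd)
  expect_identical(st$q1, st2$q1)
  expect_identical(st$q3, st2$q3)
})
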