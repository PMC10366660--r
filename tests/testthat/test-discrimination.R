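# Random-forest training, confidence-thresholded classification, relative
# concentration, and misclassification accounting.

toy_records <- function(n, d_range, ri_range, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      particle_id = seq_len(n),
      diameter_nm = runif(n, d_range[1], d_range[2]),
      sigma_nm2 = runif(n, 0.1, 10),
      ri = runif(n, ri_range[1], ri_range[2]))
  })
}

test_that("perfectly separated classes give perfect out-of-bag accuracy", {
  ev <- toy_records(150, c(80, 120), c(1.35, 1.39), 31)
  lp <- toy_records(150, c(40, 60), c(1.45, 1.55), 32)
  m <- train_ev_classifier(ev, lp, n_trees = 50, seed = 1)
  expect_identical(glance(m)$oob_accuracy, 1)
})

test_that("indistinguishable classes give chance-level accuracy", {
  a <- toy_records(300, c(40, 120), c(1.35, 1.55), 33)
  b <- toy_records(300, c(40, 120), c(1.35, 1.55), 34)
  m <- train_ev_classifier(a, b, n_trees = 50, seed = 1)
  # binomial 99.9% band around 0.5 over 600 OOB votes
  expect_lt(abs(glance(m)$oob_accuracy - 0.5),
            qnorm(0.9995) * sqrt(0.25 / 600))
})

test_that("training demands 100 records per class and complete features", {
  ev <- toy_records(99, c(80, 120), c(1.35, 1.39), 35)
  lp <- toy_records(150, c(40, 60), c(1.45, 1.55), 36)
  expect_error(train_ev_classifier(ev, lp), "100")
  lp$ri[5] <- NA
  expect_error(train_ev_classifier(toy_records(150, c(80, 120),
                                               c(1.35, 1.39), 37), lp),
               "missing feature")
})

test_that("threshold rule: ties go to EV, midrange stays unclassified", {
  rec <- toy_records(5, c(80, 120), c(1.35, 1.39), 38)
  expect_identical(
    unique(classify_particles(rec, constant_prob_classifier(0.80))$label),
    "EV")
  expect_identical(
    unique(classify_particles(rec, constant_prob_classifier(0.20))$label),
    "LP")
  expect_identical(
    unique(classify_particles(rec, constant_prob_classifier(0.5))$label),
    "unclassified")
  expect_identical(
    unique(classify_particles(rec, constant_prob_classifier(0.79))$label),
    "unclassified")
})

test_that("relative EV concentration is the classified count ratio", {
  cl <- tibble::tibble(label = rep(c("EV", "LP"), each = 50))
  expect_identical(relative_ev_concentration(cl), 0.5)
  expect_identical(
    relative_ev_concentration(tibble::tibble(label = rep("LP", 10))), 0)
  expect_error(
    relative_ev_concentration(tibble::tibble(label = rep("unclassified", 3))),
    "undefined")
})

test_that("misclassification report matches a hand count", {
  cl <- tibble::tibble(
    population = c(rep("EV", 6), rep("VLDL", 4)),
    label = c("EV", "EV", "LP", "EV", "unclassified", "EV",
              "LP", "EV", "LP", "unclassified"))
  rep_ <- misclassification_report(cl)
  ev_row <- rep_[rep_$true_class == "EV", ]
  lp_row <- rep_[rep_$true_class == "LP", ]
  expect_identical(ev_row$n, 6L)
  expect_equal(ev_row$mislabel_rate, 1 / 5)
  expect_equal(ev_row$unclassified_fraction, 1 / 6)
  expect_equal(lp_row$mislabel_rate, 1 / 3)
  expect_equal(lp_row$unclassified_fraction, 1 / 4)
  # a perfect classifier has zero error rates
  perfect <- tibble::tibble(population = c("EV", "VLDL"),
                            label = c("EV", "LP"))
  expect_true(all(misclassification_report(perfect)$mislabel_rate == 0))
})

test_that("raising the confidence threshold never classifies more records", {
  rec <- dplyr::bind_rows(ev_stock_records()[1:150, ],
                          vldl_stock_records()[1:150, ])
  model <- ev_vldl_classifier()
  n_classified <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.95), function(thr) {
    m <- model
    m$confidence_threshold <- thr
    sum(classify_particles(rec, m)$label != "unclassified")
  }, numeric(1))
  expect_true(all(diff(n_classified) <= 0))
})

test_that("training and classification are deterministic given seeds", {
  ev <- ev_stock_records()[1:200, ]
  lp <- vldl_stock_records()[1:200, ]
  m1 <- train_ev_classifier(ev, lp, n_trees = 30, seed = 9)
  m2 <- train_ev_classifier(ev, lp, n_trees = 30, seed = 9)
  rec <- dplyr::bind_rows(ev[1:50, ], lp[1:50, ])
  expect_identical(classify_particles(rec, m1)$p_ev,
                   classify_particles(rec, m2)$p_ev)
})
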