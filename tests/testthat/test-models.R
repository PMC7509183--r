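test_that("6:2:2 split produces exact disjoint partitions", {
  rows <- toy_feature_rows(10)
  sp <- split_patient(rows, split_spec())
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 6L, val = 2L, test = 2L))
  rows100 <- toy_feature_rows(100)
  sp100 <- split_patient(rows100, split_spec())
  expect_equal(sp100$train, rows100[1:60, ])
  expect_equal(sp100$val, rows100[61:80, ])
  expect_equal(sp100$test, rows100[81:100, ])
  r1 <- split_patient(rows100, split_spec(mode = "random", seed = 5))
  r2 <- split_patient(rows100, split_spec(mode = "random", seed = 5))
  expect_identical(r1, r2)
  expect_false(identical(r1$train, sp100$train))
  expect_error(split_patient(rows100[1:9, ]), "at least 10")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("a full-depth decision tree interpolates its training data", {
  rows <- toy_feature_rows(60, seed = 2)
  sp <- split_patient(rows)
  m <- train_model("DTR", sp$train, sp$val, target = "sbp")
  pred <- predict(m, sp$train)
  expect_equal(sqrt(mean((pred - sp$train$ref_sbp)^2)), 0, tolerance = 1e-9)
})

test_that("stochastic fits are deterministic given the seed", {
  rows <- toy_feature_rows(80, seed = 3)
  sp <- split_patient(rows)
  for (alg in c("RFR", "AdaboostR")) {
    m1 <- train_model(alg, sp$train, sp$val, target = "sbp", seed = 7)
    m2 <- train_model(alg, sp$train, sp$val, target = "sbp", seed = 7)
    expect_equal(predict(m1, sp$test), predict(m2, sp$test))
  }
})

test_that("random forest recovers a single-feature pressure rule", {
  coh <- simulate_feature_cohort(n_patients = 1, n_beats = 500, seed = 21)
  sp <- split_patient(coh[[1]])
  m <- train_model("RFR", sp$train, sp$val, target = "sbp", seed = 1)
  rmse <- sqrt(mean((predict(m, sp$test) - sp$test$ref_sbp)^2))
  expect_lte(rmse, 6)  # twice the 3 mmHg generative noise floor
  expect_true(all(m$importance >= 0))
  expect_equal(names(which.max(m$importance)), "PTTrm")
})

test_that("SVR grid search stores the chosen hyperparameters", {
  rows <- toy_feature_rows(80, seed = 4)
  sp <- split_patient(rows)
  m <- train_model("SVR", sp$train, sp$val, target = "dbp")
  expect_true(m$hyperparameters$C %in% c(0.1, 1, 10, 100))
  expect_true(m$hyperparameters$gamma %in% c(0.001, 0.01, 0.1, 1))
  expect_true(is.finite(m$val_rmse))
})

test_that("degenerate training targets are rejected", {
  rows <- toy_feature_rows(40)
  rows$ref_sbp <- 120
  sp <- split_patient(rows)
  expect_error(train_model("DTR", sp$train, sp$val, target = "sbp"),
               "zero variance")
})

test_that("trained models ignore test-set targets entirely", {
  rows <- toy_feature_rows(60, seed = 6)
  sp <- split_patient(rows)
  m <- train_model("RFR", sp$train, sp$val, target = "sbp", seed = 2)
  p1 <- predict(m, sp$test)
  permuted <- sp$test
  permuted$ref_sbp <- sample(permuted$ref_sbp)
  expect_equal(predict(m, permuted), p1)
})

test_that("algorithm selection minimises mean validation RMSE with fixed tie-break", {
  # group mean RMSEs reported for systolic estimation
  means <- c(DTR = 7.68, SVR = 7.63, AdaboostR = 6.24, RFR = 5.87)
  m <- matrix(rep(means, each = 5), nrow = 5,
              dimnames = list(NULL, names(means)))
  expect_equal(select_best_algorithm(m), "RFR")
  ties <- matrix(5, 3, 4, dimnames = list(NULL, names(means)))
  expect_equal(select_best_algorithm(ties), "DTR")
  single <- matrix(4.2, 1, 1, dimnames = list(NULL, "SVR"))
  expect_equal(select_best_algorithm(single), "SVR")
  m[2, 1] <- NA
  expect_error(select_best_algorithm(m), "NaN")
})

test_that("paired algorithm comparison behaves like a t-test", {
  m <- cbind(DTR = c(7, 8, 7.5, 9, 8.2, 7.7, 8.4, 7.9, 8.1, 7.6),
             RFR = c(5, 6, 5.5, 7, 6.2, 5.7, 6.4, 5.9, 6.1, 5.6) +
               rnorm(10, 0, 0.01))
  p <- compare_algorithms(m, "DTR", "RFR")
  expect_lt(p, 0.05)
  expect_equal(compare_algorithms(m, "RFR", "DTR"), p)
  ident <- cbind(DTR = m[, 1], RFR = m[, 1])
  expect_error(compare_algorithms(ident, "DTR", "RFR"), "degenerate")
})

test_that("importance normalisation and averaging follow the weight rules", {
  mk <- function(omega, pid) {
    structure(list(algorithm = "RFR", target = "sbp", patient_id = pid,
                   features = c("a", "b", "c"),
                   importance = stats::setNames(omega, c("a", "b", "c"))),
              class = "bp_model")
  }
  gi <- group_importance(list(mk(c(2, 1, 1), "p1"), mk(c(1, 1, 2), "p2")))
  expect_equal(unname(gi$FI[1, ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(gi$FI[2, ]), c(0.25, 0.25, 0.5))
  expect_equal(gi$group[["a"]], 0.375)
  expect_equal(gi$group[["c"]], 0.375)
  expect_equal(gi$group[["b"]], 0.25)
  expect_equal(sum(gi$group), 1, tolerance = 1e-12)
  expect_equal(gi$table$importance, sort(gi$table$importance,
                                         decreasing = TRUE))
  one <- group_importance(list(mk(c(3, 1, 0), "p1")))
  expect_equal(unname(one$group[order(names(one$group))]),
               c(0.75, 0.25, 0))
  expect_error(group_importance(list(mk(c(0, 0, 0), "p1"))), "all-zero")
})
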