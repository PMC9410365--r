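# brute-force reference implementations, kept deliberately naive
softmax_oracle <- function(x) exp(x) / sum(exp(x))
ce_oracle <- function(scores, true_idx) {
  -log(softmax_oracle(scores)[true_idx])
}

test_that("softmax matches its definition and is shift-invariant", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(round(softmax(c(1, 2, 3)), 5),
               c(0.09003, 0.24473, 0.66524))
  expect_equal(softmax(c(5, 5 + 2)), softmax(c(0, 2)))
  expect_error(softmax(numeric()), "empty")
  expect_error(softmax(c(1, Inf)), "finite")
  set.seed(71)
  for (i in 1:250) {
    x <- runif(sample(2:12, 1), -50, 50)
    expect_equal(softmax(x), softmax_oracle(x), tolerance = 1e-12)
    expect_equal(sum(softmax(x)), 1, tolerance = 1e-12)
  }
  # matrix form agrees with row-wise evaluation
  m <- matrix(rnorm(12), 3)
  expect_equal(softmax(m), t(apply(m, 1, softmax)))
})

test_that("cross-entropy averages per-sample losses over the minibatch", {
  expect_equal(cross_entropy(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), log(2))
  expect_lt(cross_entropy(matrix(c(100, 0), 1), matrix(c(1, 0), 1)), 1e-10)
  l1 <- cross_entropy(matrix(c(1, 0), 1), matrix(c(1, 0), 1))
  l2 <- cross_entropy(matrix(c(0, 3), 1), matrix(c(0, 1), 1))
  both <- cross_entropy(matrix(c(1, 0, 0, 3), 2, byrow = TRUE),
                        matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(both, (l1 + l2) / 2)
  expect_error(cross_entropy(matrix(0, 1, 2), matrix(c(0.5, 0.4), 1)),
               "sum to 1")
  set.seed(72)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    x <- runif(k, -30, 30)
    j <- sample(k, 1)
    y <- replace(numeric(k), j, 1)
    expect_lt(abs(cross_entropy(matrix(x, 1), matrix(y, 1)) -
                  ce_oracle(x, j)), 1e-10)
  }
})

test_that("flat models are built with the requested head and registry", {
  m23 <- build_flat_model("tiny", 23)
  expect_identical(ncol(m23$head$W), 23L)
  expect_length(m23$class_order, 23)
  m15 <- build_flat_model("tiny", sprintf("sp%02d", 1:15))
  expect_identical(ncol(m15$head$W), 15L)
  expect_error(build_flat_model("tiny", 1), "at least 2")
  expect_error(build_flat_model("resnext101", 5), "custom_trunk")
  expect_error(build_flat_model("tiny", c("a", "a", "b")), "duplicate")
})

test_that("training only touches unfrozen parameters", {
  fx <- default_fixture()
  species <- record_species(fx$records)
  hyper <- training_config(epochs = 2, seed = 0)
  model <- build_flat_model("tiny", sort(unique(species)), seed = 0)
  conv_sum <- param_checksum(list(model$trunk$conv1, model$trunk$conv2))
  dense_sum <- param_checksum(model$trunk$dense)
  head_sum <- param_checksum(model$head)
  fit <- train_flat(model, fx$records, fx$split, hyper, conv_cache = fx$conv)
  # frozen stages: bitwise identical; head: changed
  expect_identical(param_checksum(list(fit$model$trunk$conv1,
                                       fit$model$trunk$conv2)), conv_sum)
  expect_identical(param_checksum(fit$model$trunk$dense), dense_sum)
  expect_false(identical(param_checksum(fit$model$head), head_sum))
  # the conv_only policy unfreezes the dense stage
  m2 <- build_flat_model("tiny", sort(unique(species)),
                         freeze = "conv_only", seed = 0)
  fit2 <- train_flat(m2, fx$records, fx$split, hyper, conv_cache = fx$conv)
  expect_false(identical(param_checksum(fit2$model$trunk$dense),
                         param_checksum(m2$trunk$dense)))
  # zero epochs: model unchanged
  fit0 <- train_flat(model, fx$records, fx$split,
                     training_config(epochs = 0), conv_cache = fx$conv)
  expect_identical(fit0$model$head, model$head)
  expect_length(fit0$history$epochs, 0)
})

test_that("a separable fixture is fit to full training accuracy", {
  # three well-separated classes: the head must fit the train set exactly
  gen3 <- generate_synthetic(synth_spec(n_families = 3,
                                        species_per_family = c(1, 1, 1),
                                        samples_per_species = 10, seed = 4))
  recs3 <- standardize(gen3$records)
  split3 <- holdout_split(recs3, 0.8, seed = 0)
  m3 <- build_flat_model("tiny", sort(unique(record_species(recs3))),
                         seed = 0)
  fit3 <- train_flat(m3, recs3, split3, training_config(epochs = 30, seed = 0))
  p3 <- predict_flat(fit3$model, recs3[split3$train])
  expect_identical(mean(p3$labels == record_species(recs3)[split3$train]), 1)

  fx <- default_fixture()
  fit <- trained_fixture()$flat
  species <- record_species(fx$records)
  tr <- fx$split$train
  pred <- predict_flat(fit$model, fx$records[tr],
                       conv_cache = fx$conv[tr, , drop = FALSE])
  expect_gte(mean(pred$labels == species[tr]), 0.95)
  # per-epoch, per-class accounting exists for every class
  expect_identical(dim(fit$history$train),
                   c(30L, length(unique(species))))
  # training loss decreased over the run
  expect_lt(tail(fit$history$global_train, 1), fit$history$global_train[1])
})

test_that("prediction is deterministic and breaks ties by class order", {
  fx <- default_fixture()
  fit <- trained_fixture()$flat
  sub <- fx$records[fx$split$test[1:5]]
  p1 <- predict_flat(fit$model, sub)
  p2 <- predict_flat(fit$model, sub)
  expect_identical(p1, p2)
  expect_identical(length(p1$labels), 5L)
  expect_equal(unname(rowSums(p1$probabilities)), rep(1, 5),
               tolerance = 1e-6)
  # untrained zero head scores every class equally: first label wins
  zero <- build_flat_model("tiny", c("aa", "bb"), seed = 0)
  zero$head$W[] <- 0
  zero$head$b[] <- 0
  pz <- predict_flat(zero, sub)
  expect_identical(unique(pz$labels), "aa")
})

test_that("training rejects inconsistent inputs", {
  fx <- default_fixture()
  model <- build_flat_model("tiny", c("x", "y"), seed = 0)
  expect_error(train_flat(model, fx$records, fx$split,
                          conv_cache = fx$conv),
               "outside the model's class order")
  empty_split <- fx$split
  empty_split$train <- integer()
  good <- build_flat_model("tiny",
                           sort(unique(record_species(fx$records))))
  expect_error(train_flat(good, fx$records, empty_split), "empty train")
})
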