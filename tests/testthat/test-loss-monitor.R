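mk_history <- function(classes = c("a", "b"), train_n = c(a = 10, b = 10),
                       val_n = c(a = 5, b = 5)) {
  loss_history(classes, train_n, val_n)
}

test_that("epoch recording keeps curves aligned and globally weighted", {
  h <- mk_history()
  h <- record_epoch(h, 1, c(a = 0.2, b = 0.4), c(a = 0.3, b = 0.5))
  expect_length(h$epochs, 1)
  expect_identical(nrow(h$train), 1L)
  # equal class sizes: global is the plain mean
  expect_equal(h$global_train, 0.3)
  expect_equal(h$global_val, 0.4)
  # unequal weights
  h2 <- mk_history(train_n = c(a = 30, b = 10))
  h2 <- record_epoch(h2, 1, c(a = 0.1, b = 0.5), c(a = 0.1, b = 0.5))
  expect_equal(h2$global_train, (30 * 0.1 + 10 * 0.5) / 40)
  # a class absent from an epoch is missing, not zero
  h <- record_epoch(h, 2, c(a = 0.1), c(a = 0.2))
  expect_true(is.na(h$train[2, "b"]))
  expect_equal(h$global_train[2], 0.1)
  expect_error(record_epoch(h, 2, c(a = 0.1), c(a = 0.1)), "not after")
  expect_error(record_epoch(h, 3, c(a = -1), c(a = 0.1)), "nonnegative")
})

test_that("divergence scores measure the clamped val-train gap", {
  h <- mk_history()
  for (e in 1:6) {
    h <- record_epoch(h, e, c(a = 0.1, b = 0.25), c(a = 0.3, b = 0.2))
  }
  # coincident or val-below-train curves score zero
  expect_equal(divergence_score(h, "b"), 0)
  # absolute gap: 0.3 - 0.1 over the whole window
  expect_equal(divergence_score(h, "a"), 0.2)
  # the relative normalization divides by the train level: 0.2 / 0.1
  expect_equal(divergence_score(h, "a", normalize = "relative"), 2,
               tolerance = 1e-6)
  expect_error(divergence_score(h, "zz"), "unknown class")
  expect_error(divergence_score(h, "a", window = 10), "window")
  # identical curves
  hid <- mk_history()
  for (e in 1:5) hid <- record_epoch(hid, e, c(a = 0.4, b = 0.1),
                                     c(a = 0.4, b = 0.1))
  expect_equal(divergence_score(hid, "a"), 0)
})

test_that("score behaves predictably under curve shifts", {
  base <- mk_history()
  shifted <- mk_history()
  for (e in 1:5) {
    base <- record_epoch(base, e, c(a = 0.1, b = 0.1), c(a = 0.5, b = 0.1))
    shifted <- record_epoch(shifted, e, c(a = 1.1, b = 1.1),
                            c(a = 1.5, b = 1.1))
  }
  # absolute score is invariant under adding a constant to both curves
  expect_equal(divergence_score(base, "a"), divergence_score(shifted, "a"))
  # relative score shrinks as the train level grows with the gap fixed
  expect_gt(divergence_score(base, "a", normalize = "relative"),
            divergence_score(shifted, "a", normalize = "relative"))
})

test_that("flagging respects thresholds and minimum validation support", {
  h <- loss_history(c("good", "bad", "tiny"),
                    train_n = c(good = 20, bad = 20, tiny = 20),
                    val_n = c(good = 5, bad = 5, tiny = 2))
  for (e in 1:6) {
    h <- record_epoch(h, e,
                      c(good = 0.1, bad = 0.1, tiny = 0.1),
                      c(good = 0.12, bad = 1.4, tiny = 1.4))
  }
  rep <- flag_classes(h, threshold = 0.5, window = 5, min_val_samples = 2)
  expect_setequal(rep$flagged, c("bad", "tiny"))
  expect_identical(rep$threshold, 0.5)
  # converged set: nothing flagged
  expect_length(flag_classes(h, threshold = Inf)$flagged, 0)
  # threshold 0 flags every class with a positive gap
  expect_setequal(flag_classes(h, threshold = 0, min_val_samples = 2)$flagged,
                  c("good", "bad", "tiny"))
  # too few validation samples: suppressed with a warning
  expect_warning(sup <- flag_classes(h, threshold = 0.5, min_val_samples = 3),
                 "tiny")
  expect_identical(sup$flagged, "bad")
})

test_that("loss curves are plotted and persisted", {
  h <- mk_history()
  for (e in 1:3) h <- record_epoch(h, e, c(a = 0.3, b = 0.2),
                                   c(a = 0.35, b = 0.22))
  dir <- withr::local_tempdir()
  files <- plot_curves(h, c("a", "b"), dir)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  expect_length(plot_curves(h, "global", dir), 1)
  expect_warning(none <- plot_curves(h, character(), dir), "nothing")
  expect_length(none, 0)
  expect_error(plot_curves(h, "zz", dir), "unknown class")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_loss_history(h, csv)
  long <- read.csv(csv)
  expect_identical(nrow(long), 12L)  # 3 epochs x 2 classes x 2 splits
  expect_setequal(unique(long$split), c("train", "validation"))
})

test_that("a label-noised class earns the top divergence score", {
  fx <- difficult_fixture()
  trained <- difficult_fit()
  scores <- vapply(trained$history$classes, function(cl)
    divergence_score(trained$history, cl), numeric(1))
  expect_identical(names(which.max(scores)), fx$difficult)
  # rank separation is decisive, not marginal
  expect_gt(max(scores), 2 * sort(scores, decreasing = TRUE)[2])
})
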