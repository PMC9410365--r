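test_that("annotation tables round-trip through image files", {
  dir <- withr::local_tempdir()
  tree <- load_taxonomy(data.frame(species = c("sp1", "sp2"),
                                   family = c("famA", "famB")))
  for (f in c("a.png", "b.png", "c.png")) {
    write_image_file(textured_record(24)$image, file.path(dir, f))
  }
  tab <- data.frame(path = c("a.png", "b.png", "c.png"),
                    species = c("sp1", "sp1", "sp2"),
                    source_id = c("v1", "v1", "v2"))
  recs <- read_annotations(dir, tab, tree)
  expect_length(recs, 3)
  expect_identical(record_species(recs), c("sp1", "sp1", "sp2"))
  expect_identical(record_family(recs), c("famA", "famA", "famB"))
  expect_false(any(vapply(recs, function(r) r$is_augmented, logical(1))))
  # PNG round-trip preserves pixels
  expect_identical(recs[[1]]$image, textured_record(24)$image)

  expect_error(read_annotations(dir, data.frame(path = "zz.png",
                                                species = "sp1"), tree),
               "missing image")
  expect_error(read_annotations(dir, data.frame(path = "a.png",
                                                species = "spX"), tree),
               "spX")
  expect_warning(
    empty <- read_annotations(dir, tab[0, ], tree), "empty")
  expect_length(empty, 0)
})

test_that("standardize resizes any native size to the network input", {
  for (dims in list(c(20, 20), c(200, 200), c(50, 200))) {
    rec <- image_record(array(55L, dim = c(dims, 3L)), "sp", "fam")
    out <- standardize(rec)
    expect_identical(dim(out$image), c(224L, 224L, 3L))
    expect_identical(out$species, "sp")
  }
  # exact-size input passes through unchanged
  rec <- textured_record(224)
  expect_identical(standardize(rec)$image, rec$image)
  # non-3-channel input is rejected at the boundary
  expect_error(image_record(array(0L, dim = c(10, 10, 1)), "sp"),
               "3 channels")
})

test_that("stratified k-fold deals classes evenly and reproducibly", {
  labels <- c(rep("big", 12112), rep("small", 14))
  splits <- stratified_kfold(labels, k = 7, seed = 11)
  expect_length(splits, 7)
  fold_sizes <- table(vapply(splits, function(s) s$fold_id, integer(1)))
  # per-class fold cardinalities differ by at most one
  for (cl in c("big", "small")) {
    idx <- which(labels == cl)
    sizes <- vapply(splits, function(s) length(intersect(s$test, idx)),
                    integer(1))
    expect_lte(diff(range(sizes)), 1)
  }
  small_sizes <- vapply(splits, function(s)
    length(intersect(s$test, which(labels == "small"))), integer(1))
  expect_identical(sort(small_sizes), rep(2L, 7))
  big_sizes <- sort(vapply(splits, function(s)
    length(intersect(s$test, which(labels == "big"))), integer(1)))
  expect_identical(big_sizes, c(rep(1730L, 5), rep(1731L, 2)))
  # test folds are disjoint and cover everything
  all_test <- sort(unlist(lapply(splits, `[[`, "test")))
  expect_identical(all_test, seq_along(labels))
  for (s in splits) {
    expect_length(intersect(s$train, s$validation), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$validation, s$test), 0)
  }
  # byte-identical reruns; different seed reshuffles
  expect_identical(splits, stratified_kfold(labels, k = 7, seed = 11))
  expect_false(identical(splits, stratified_kfold(labels, k = 7, seed = 12)))
})

test_that("tiny classes and bad arguments are reported", {
  expect_warning(splits <- stratified_kfold(c("a", "a", rep("b", 7)), k = 7),
                 "'a' has 2 samples")
  a_test <- vapply(splits, function(s)
    length(intersect(s$test, 1:2)), integer(1))
  expect_identical(sort(a_test), c(rep(0L, 5), 1L, 1L))
  expect_error(stratified_kfold(letters, k = 2), "at least 3")
  expect_error(stratified_kfold(character()), "no records")
})

test_that("holdout split reproduces the published per-class 80/20 sizes", {
  tab <- lcf15_table()
  labels <- rep(tab$species, tab$train + tab$validation)
  split <- holdout_split(labels, train_fraction = 0.8, seed = 4)
  expect_length(split$train, 25008)
  expect_length(split$validation, 6252)
  expect_length(split$test, 0)
  got <- table(labels[split$train])[tab$species]
  expect_identical(as.integer(got), tab$train)

  ten <- holdout_split(rep("x", 10), 0.8)
  expect_length(ten$train, 8)
  expect_length(ten$validation, 2)
  expect_warning(one <- holdout_split("x", 0.8), "no validation")
  expect_length(one$train, 1)
  expect_error(holdout_split(letters, 1.2), "train_fraction")
})

test_that("dataset summaries count every record once", {
  fx <- default_fixture()
  s <- dataset_summary(fx$records)
  expect_identical(sum(s$n), length(fx$records))
  expect_identical(s, dataset_summary(fx$records[sample.int(length(fx$records))]))
  expect_identical(nrow(dataset_summary(character())), 0L)
  expect_identical(dataset_summary("one")$n, 1L)
})

test_that("split manifests list every partition member", {
  split <- holdout_split(rep(c("a", "b"), each = 10), 0.8, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(split, sprintf("img%02d.png", 1:20), f)
  m <- read.csv(f)
  expect_identical(nrow(m), 20L)
  expect_identical(sum(m$partition == "train"), 16L)
})
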