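test_that("tree models are sized by the taxonomy and confusable set", {
  tree <- lcf15_tree()
  plain <- build_tree_model("tiny", tree)
  expect_identical(ncol(plain$root_head$W), 6L)
  conf <- build_tree_model("tiny", tree, lcf15_confusable())
  pom <- conf$leaf_heads[["Pomacentridae"]]
  expect_identical(pom$type, "head")
  expect_identical(ncol(pom$head$W), 8L)  # 7 species + Others
  expect_identical(conf$leaf_heads[["Labridae"]]$type, "identity")
  expect_identical(conf$leaf_heads[["Holocentridae"]]$type, "identity")
  # a single-species family in a confusable pair is no longer degenerate
  conf2 <- build_tree_model("tiny", tree,
                            list(c("Labridae", "Pempheridae")))
  expect_identical(conf2$leaf_heads[["Labridae"]]$type, "head")
  expect_identical(ncol(conf2$leaf_heads[["Labridae"]]$head$W), 2L)
})

test_that("leaf training subsets relabel foreign samples as Others", {
  fx <- default_fixture()
  tree <- fx$tree
  conf <- list(c("fam01", "fam06"))
  space <- leaf_label_space(tree, "fam01", conf)
  sub <- assemble_leaf_training_set(fx$records, "fam01", space)
  fams <- record_family(fx$records)
  expect_setequal(sub$indices[sub$labels != others_label()],
                  which(fams == "fam01"))
  expect_setequal(sub$indices[sub$labels == others_label()],
                  which(fams == "fam06"))
  # capping downsamples the Others pool reproducibly
  capped <- assemble_leaf_training_set(fx$records, "fam01", space,
                                       cap = 10, seed = 5)
  expect_identical(sum(capped$labels == others_label()), 10L)
  expect_identical(capped,
                   assemble_leaf_training_set(fx$records, "fam01", space,
                                              cap = 10, seed = 5))
  expect_warning(
    none <- assemble_leaf_training_set(fx$records, "fam01", space, cap = 0),
    "excluded")
  expect_false(others_label() %in% none$labels)
  # families outside any confusable pair keep their own records only
  plain <- assemble_leaf_training_set(fx$records, "fam01",
                                      leaf_label_space(tree, "fam01"))
  expect_setequal(plain$indices, which(fams == "fam01"))
})

test_that("staged training isolates the stages it claims to", {
  fx <- default_fixture()
  tm <- build_tree_model("tiny", fx$tree, seed = 0)
  conv_sum0 <- param_checksum(list(tm$trunk$conv1, tm$trunk$conv2))
  dense_sum0 <- param_checksum(tm$trunk$dense)
  hyper <- training_config(epochs = 2, seed = 0)
  root_fit <- train_root(tm, fx$records, fx$split, hyper,
                         conv_cache = fx$conv)
  m <- root_fit$model
  # the root stage trains the trunk's dense stage (conv stays fixed)
  expect_identical(param_checksum(list(m$trunk$conv1, m$trunk$conv2)),
                   conv_sum0)
  expect_false(identical(param_checksum(m$trunk$dense), dense_sum0))
  # ... after which the trunk and root head never move again
  trunk_sum <- param_checksum(m$trunk$dense)
  root_sum <- param_checksum(m$root_head)
  leaf_fit <- train_leaves(m, fx$records, fx$split, hyper,
                           conv_cache = fx$conv)
  expect_identical(param_checksum(leaf_fit$model$trunk$dense), trunk_sum)
  expect_identical(param_checksum(leaf_fit$model$root_head), root_sum)
  # leaves may not be trained before the root
  expect_error(train_leaves(build_tree_model("tiny", fx$tree), fx$records,
                            fx$split, hyper), "root node")
  # a family absent from train aborts root training
  bad_split <- fx$split
  fams <- record_family(fx$records)
  bad_split$train <- setdiff(bad_split$train, which(fams == "fam03"))
  expect_error(train_root(build_tree_model("tiny", fx$tree), fx$records,
                          bad_split, hyper, conv_cache = fx$conv),
               "fam03")
})

test_that("routing conserves the hierarchy over random inputs", {
  model <- trained_fixture()$tree
  set.seed(99)
  feats <- matrix(abs(rnorm(10000 * model$trunk$output_dim)),
                  nrow = 10000)
  routed <- finclass:::route_from_features(model, feats)
  ok <- vapply(seq_len(nrow(feats)), function(i) {
    fam <- routed$predictions$family[i]
    fam %in% model$tree$family_labels &&
      routed$predictions$species[i] %in%
        c(model$spaces[[fam]]$classes, reject_label())
  }, logical(1))
  expect_identical(sum(ok), nrow(feats))
  expect_equal(unname(rowSums(routed$root_probs)), rep(1, 10000),
               tolerance = 1e-6)
})

test_that("routing reuses one trunk evaluation for root and leaf", {
  fx <- default_fixture()
  model <- trained_fixture()$tree
  sub <- fx$records[fx$split$test[1:8]]
  direct <- route_predict(model, sub)
  feats <- trunk_features(model$trunk, sub)
  refed <- finclass:::route_from_features(model, feats)
  expect_identical(direct, refed)
})

test_that("identity leaves pass their single species through", {
  fx <- default_fixture()
  model <- trained_fixture()$tree
  species <- record_species(fx$records)
  single <- which(record_family(fx$records) == "fam03")[1]
  routed <- route_predict(model, fx$records[single],
                          conv_cache = fx$conv[single, , drop = FALSE])
  if (routed$predictions$family == "fam03") {
    expect_identical(routed$predictions$species, species[single])
    expect_identical(routed$predictions$leaf_confidence, 1)
  }
  expect_identical(model$leaf_heads[["fam03"]]$type, "identity")
})

test_that("a leaf that answers Others yields the REJECT label", {
  fx <- default_fixture()
  model <- build_tree_model("tiny", fx$tree,
                            confusable = list(c("fam01", "fam06")),
                            seed = 0)
  model$root_trained <- TRUE
  # force routing to fam01 and force its leaf to answer Others
  model$root_head$W[] <- 0
  model$root_head$b <- as.numeric(fx$tree$family_labels == "fam01") * 10
  leaf <- model$leaf_heads[["fam01"]]
  leaf$head$W[] <- 0
  k <- length(model$spaces[["fam01"]]$classes)
  leaf$head$b <- c(rep(0, k - 1), 10)
  model$leaf_heads[["fam01"]] <- leaf
  routed <- route_predict(model, fx$records[1],
                          conv_cache = fx$conv[1, , drop = FALSE])
  expect_identical(routed$predictions$family, "fam01")
  expect_identical(routed$predictions$species, reject_label())
})

test_that("family accuracy is no lower than species accuracy", {
  fx <- default_fixture()
  model <- trained_fixture()$tree
  te <- fx$split$test
  routed <- route_predict(model, fx$records[te],
                          conv_cache = fx$conv[te, , drop = FALSE])
  fam_acc <- mean(routed$predictions$family == record_family(fx$records)[te])
  sp_acc <- mean(routed$predictions$species == record_species(fx$records)[te])
  expect_gte(fam_acc, sp_acc)
})
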