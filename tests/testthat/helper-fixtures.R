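# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

extdata <- function(file) {
  system.file("extdata", file, package = "finclass", mustWork = TRUE)
}

lcf15_table <- function() read.csv(extdata("lcf15_species.csv"))

lcf15_tree <- function() {
  load_taxonomy(lcf15_table()[, c("species", "family")])
}

# confusable pairs chosen for the LCF-15 hierarchy
lcf15_confusable <- function() {
  list(c("Acanthuridae", "Pomacentridae"),
       c("Chaetodontidae", "Pomacentridae"))
}

# quick uniform-color record for unit tests that only need shapes/labels
solid_record <- function(value = 128L, h = 32L, w = 32L,
                         species = "spA", family = "famA") {
  image_record(array(as.integer(value), dim = c(h, w, 3L)),
               species, family)
}

# a textured deterministic record (gradient + sinusoid), standardized
textured_record <- function(side = 64L, species = "spA", family = "famA") {
  r <- matrix(rep(seq_len(side), times = side), nrow = side)
  c <- matrix(rep(seq_len(side), each = side), nrow = side)
  img <- array(0L, dim = c(side, side, 3L))
  img[, , 1] <- as.integer(round(255 * r / side))
  img[, , 2] <- as.integer(round(127 + 100 * sin(r / 4) * cos(c / 5)))
  img[, , 3] <- as.integer(round(255 * c / side))
  image_record(img, species, family)
}

# The standard desk-scale study conditions: 6 families with the LCF-15
# family-size profile, 30 samples/species, generator seed 1.
default_fixture <- function() {
  cached("default_fixture", function() {
    gen <- generate_synthetic(synth_spec(seed = 1))
    recs <- standardize(gen$records)
    conv <- trunk_conv_features(build_trunk("tiny"), recs)
    split <- stratified_kfold(recs, k = 7, seed = 0)[[1]]
    list(gen = gen, records = recs, tree = gen$tree, conv = conv,
         split = split)
  })
}

# Flat and hierarchical models trained under matched budgets on the
# default fixture (shared by structural, consistency and end-to-end
# checks).
trained_fixture <- function() {
  cached("trained_fixture", function() {
    fx <- default_fixture()
    hyper <- training_config(epochs = 30, seed = 0)
    species <- record_species(fx$records)
    flat <- build_flat_model("tiny", sort(unique(species)), seed = 0)
    flat_fit <- train_flat(flat, fx$records, fx$split, hyper,
                           conv_cache = fx$conv)
    tm <- build_tree_model("tiny", fx$tree, seed = 0)
    root_fit <- train_root(tm, fx$records, fx$split, hyper,
                           conv_cache = fx$conv)
    leaf_fit <- train_leaves(root_fit$model, fx$records, fx$split, hyper,
                             conv_cache = fx$conv)
    list(flat = flat_fit, root = root_fit, tree = leaf_fit$model,
         hyper = hyper)
  })
}

# Study conditions for the targeted-augmentation behavior: one minority
# species (15 instead of 30 samples) in the 7-species family whose
# validation samples are blended strongly (weight 0.65) toward sibling
# species, so the class generalizes badly enough that the first
# training round cannot produce it at all.
difficult_fixture <- function() {
  cached("difficult_fixture", function() {
    counts <- rep(30L, 15)
    counts[15] <- 15L
    gen <- generate_synthetic(synth_spec(samples_per_species = counts,
                                         seed = 2))
    recs <- standardize(gen$records)
    split <- holdout_split(recs, 0.8, seed = 0)
    recs <- make_difficult_class(recs, "fam06_sp07", noise_rate = 0.65,
                                 indices = split$validation, seed = 3)
    conv <- trunk_conv_features(build_trunk("tiny"), recs)
    list(records = recs, tree = gen$tree, split = split, conv = conv,
         difficult = "fam06_sp07")
  })
}

# first-round flat fit on the difficult fixture (fine-tuning setting:
# the trunk's dense stage trains alongside the head)
difficult_fit <- function() {
  cached("difficult_fit", function() {
    fx <- difficult_fixture()
    train_flat(
      build_flat_model("tiny", sort(unique(record_species(fx$records))),
                       freeze = "conv_only", seed = 0),
      fx$records, fx$split, training_config(epochs = 30, seed = 0),
      conv_cache = fx$conv
    )
  })
}

# color/shape moment features: the trivial oracle for the
# family-separability guard. Background color is estimated from the
# image border; saliency (color distance from background) weights both
# the foreground color means and the scale-normalized central moments
# that describe the silhouette.
moment_features <- function(records) {
  t(vapply(records, function(r) {
    img <- r$image / 255
    h <- dim(img)[1]; w <- dim(img)[2]
    frame <- unique(c(1:ceiling(h * 0.08), (h - ceiling(h * 0.08) + 1):h))
    bg <- vapply(1:3, function(ch) {
      plane <- img[, , ch]
      mean(c(plane[frame, ], plane[, frame]))
    }, numeric(1))
    sal <- sqrt((img[, , 1] - bg[1])^2 + (img[, , 2] - bg[2])^2 +
                (img[, , 3] - bg[3])^2)
    sal <- sal / max(sal, 1e-8)
    wt <- sal / sum(sal)
    fg <- vapply(1:3, function(ch) sum(img[, , ch] * wt), numeric(1))
    rr <- row(sal) / h - sum(wt * row(sal) / h)
    cc <- col(sal) / w - sum(wt * col(sal) / w)
    mu <- function(p, q) sum(wt * rr^p * cc^q)
    s2 <- sqrt(mu(2, 0) + mu(0, 2))
    nm <- function(p, q) mu(p, q) / s2^(p + q)
    c(fg, bg, fg - bg,
      nm(2, 0), nm(0, 2), nm(1, 1), nm(2, 2), nm(3, 0), nm(0, 3),
      nm(2, 1), nm(1, 2), mean(sal))
  }, numeric(18)))
}

nearest_centroid_accuracy <- function(features, labels, train_idx, test_idx) {
  centroids <- do.call(rbind, lapply(split(
    seq_along(labels)[train_idx], labels[train_idx]),
    function(i) colMeans(features[i, , drop = FALSE])))
  scale_sd <- apply(features[train_idx, , drop = FALSE], 2, sd) + 1e-8
  pred <- vapply(test_idx, function(i) {
    d <- colSums(((t(centroids) - features[i, ]) / scale_sd)^2)
    rownames(centroids)[which.min(d)]
  }, character(1))
  mean(pred == labels[test_idx])
}
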