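# Taxonomy-driven tree classifier: shared trunk, family-level root head,
# per-family species leaf heads, staged training, greedy test routing.
#
# Training is staged to sidestep the minibatch-routing imbalance of
# training a whole tree jointly: (i) the root stage trains the trunk's
# dense projection and the family head, after which the trunk is frozen;
# (ii) each leaf head then trains independently on its own family's
# samples (plus foreign samples relabeled 'Others' where the family is
# confusable); (iii) at test time the trunk runs once per image, the
# root's argmax picks the leaf, and the leaf's argmax names the species.

#' Build a hierarchical tree model
#'
#' @param trunk a `feature_trunk` or trunk name.
#' @param tree a `taxonomy_tree`.
#' @param confusable set of confusable family pairs (see
#'   [leaf_label_space()]); leaves of confusable families gain an
#'   `Others` class.
#' @param seed seed for head initializations.
#' @return an object of class `tree_model`. Families with a single
#'   species and no `Others` class get an identity leaf (no trained
#'   head).
#' @export
build_tree_model <- function(trunk = "tiny", tree, confusable = list(),
                             seed = 0L) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!inherits(trunk, "feature_trunk")) trunk <- build_trunk(trunk)
  if (trunk$name != "custom" && !isTRUE(trunk$dense_initialized)) {
    trunk <- init_trunk_dense(trunk, seed + 1000L)
  }
  spaces <- lapply(tree$family_labels, function(f) {
    leaf_label_space(tree, f, confusable)
  })
  names(spaces) <- tree$family_labels
  head_dim <- trunk$output_dim
  leaf_heads <- lapply(tree$family_labels, function(f) {
    space <- spaces[[f]]
    if (length(space$classes) == 1L) {
      list(type = "identity")
    } else {
      list(type = "head",
           head = new_head(head_dim, length(space$classes),
                           seed + match(f, tree$family_labels)))
    }
  })
  names(leaf_heads) <- tree$family_labels
  structure(
    list(
      trunk = trunk,
      root_head = new_head(head_dim, length(tree$family_labels), seed),
      leaf_heads = leaf_heads,
      tree = tree,
      spaces = spaces,
      root_trained = FALSE
    ),
    class = "tree_model"
  )
}

#' @export
print.tree_model <- function(x, ...) {
  n_identity <- sum(vapply(x$leaf_heads, function(l) l$type == "identity",
                           logical(1)))
  cat("<tree_model>", x$trunk$name, "trunk,",
      length(x$tree$family_labels), "families (",
      n_identity, "identity leaves ),",
      length(x$tree$species_labels), "species\n")
  invisible(x)
}

#' Stage (i): train the root (family) node
#'
#' Trains the trunk's dense projection stage jointly with the family
#' head on family labels, then freezes the trunk: later stages see
#' checksum-identical trunk parameters.
#'
#' @param model a `tree_model`.
#' @param records a `fish_records` collection with family labels.
#' @param split a `dataset_split` over `records`.
#' @param hyper a [training_config()].
#' @param history optional `loss_history` (family classes) to extend.
#' @param conv_cache optional precomputed conv features for `records`.
#' @return list with `model` (root trained, trunk frozen) and `history`.
#' @export
train_root <- function(model, records, split, hyper = training_config(),
                       history = NULL, conv_cache = NULL) {
  stopifnot(inherits(model, "tree_model"), inherits(split, "dataset_split"))
  fams <- record_family(records)
  missing_fam <- setdiff(model$tree$family_labels,
                         unique(fams[split$train]))
  if (length(missing_fam)) {
    stop("family with no train samples: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  conv <- conv_cache %||% trunk_conv_features(model$trunk, records)
  trainable_dense <- if (model$trunk$name != "custom") model$trunk$dense
  fit <- sgd_softmax_train(
    X = conv[split$train, , drop = FALSE], labels = fams[split$train],
    Xval = conv[split$validation, , drop = FALSE],
    val_labels = fams[split$validation],
    class_order = model$tree$family_labels,
    head = model$root_head, dense = trainable_dense,
    skip = if (!is.null(trainable_dense)) model$trunk$skip,
    hyper = hyper, history = history
  )
  model$root_head <- fit$head
  if (!is.null(fit$dense)) model$trunk$dense <- fit$dense
  model$root_trained <- TRUE
  list(model = model, history = fit$history)
}

#' Assemble the training subset of one leaf node
#'
#' Own-family records keep their species labels; records from the leaf's
#' `others_sources` families are relabeled to the reserved `Others`
#' class, optionally downsampled (seeded) to `cap`.
#'
#' @param records a `fish_records` collection.
#' @param family the leaf's family.
#' @param space the leaf's `leaf_label_space`.
#' @param cap maximum number of `Others` samples (`NULL` = use all;
#'   `0` excludes `Others` samples entirely, with a warning).
#' @param seed seed for the downsampling draw.
#' @return list with `indices` (positions into `records`) and `labels`
#'   (species or `Others`), aligned.
#' @export
assemble_leaf_training_set <- function(records, family, space, cap = NULL,
                                       seed = 0L) {
  stopifnot(inherits(space, "leaf_label_space"))
  species <- record_species(records)
  fams <- record_family(records)
  own <- which(fams == family)
  if (!length(own)) {
    stop("no samples of family '", family, "'", call. = FALSE)
  }
  idx <- own
  labels <- species[own]
  if (length(space$others_sources)) {
    foreign <- which(fams %in% space$others_sources)
    if (!is.null(cap)) {
      if (cap == 0L) {
        warning("cap = 0: 'Others' samples excluded from leaf '", family,
                "'", call. = FALSE)
        foreign <- integer()
      } else if (length(foreign) > cap) {
        rng <- make_rng(seed)
        foreign <- sort(foreign[rng$sample_int(length(foreign), cap)])
      }
    }
    idx <- c(idx, foreign)
    labels <- c(labels, rep(others_label(), length(foreign)))
  }
  list(indices = idx, labels = labels)
}

#' Stage (ii): train the leaf (species) nodes
#'
#' Each non-degenerate leaf head trains independently on its assembled
#' subset over the frozen trunk features; the trunk and root head are
#' untouched (checksum-stable). Identity leaves are skipped.
#'
#' Leaf node subsets are much smaller than the full collection, so a
#' fixed epoch count would give each leaf head only a fraction of the
#' SGD updates the root (or a flat model) receives. Each leaf therefore
#' trains for as many epochs as needed to receive the same number of
#' minibatch updates as `hyper$epochs` passes over the full train
#' partition — the budget is matched in updates, not passes.
#'
#' @inheritParams train_root
#' @param cap `Others` downsampling cap passed to
#'   [assemble_leaf_training_set()].
#' @return list with `model` and `histories` (one `loss_history` per
#'   trained leaf, named by family).
#' @export
train_leaves <- function(model, records, split, hyper = training_config(),
                         cap = NULL, conv_cache = NULL) {
  stopifnot(inherits(model, "tree_model"))
  if (!isTRUE(model$root_trained)) {
    stop("train the root node before the leaves", call. = FALSE)
  }
  conv <- conv_cache %||% trunk_conv_features(model$trunk, records)
  feats <- trunk_project(model$trunk, conv)
  target_updates <- hyper$epochs *
    ceiling(length(split$train) / hyper$batch_size)
  histories <- list()
  for (f in model$tree$family_labels) {
    leaf <- model$leaf_heads[[f]]
    if (leaf$type == "identity") next
    space <- model$spaces[[f]]
    sub <- assemble_leaf_training_set(records, f, space, cap = cap,
                                      seed = hyper$seed)
    tr <- intersect(sub$indices, split$train)
    va <- intersect(sub$indices, split$validation)
    lab_of <- stats::setNames(sub$labels, sub$indices)
    tr_labels <- unname(lab_of[as.character(tr)])
    va_labels <- unname(lab_of[as.character(va)])
    empty <- setdiff(setdiff(space$classes, others_label()),
                     unique(tr_labels))
    if (length(empty)) {
      stop("leaf '", f, "' has class(es) with 0 train samples: ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
    leaf_hyper <- hyper
    leaf_hyper$epochs <- ceiling(
      target_updates / ceiling(length(tr) / hyper$batch_size))
    fit <- sgd_softmax_train(
      X = feats[tr, , drop = FALSE], labels = tr_labels,
      Xval = feats[va, , drop = FALSE], val_labels = va_labels,
      class_order = space$classes, head = leaf$head, dense = NULL,
      hyper = leaf_hyper
    )
    model$leaf_heads[[f]]$head <- fit$head
    histories[[f]] <- fit$history
  }
  list(model = model, histories = histories)
}

# routing from precomputed trunk features (single-pass contract: the
# same feature matrix feeds the root head and the routed leaf head)
route_from_features <- function(model, feats) {
  root_scores <- sweep(feats %*% model$root_head$W, 2L, model$root_head$b, `+`)
  root_probs <- softmax(rbind(root_scores))
  colnames(root_probs) <- model$tree$family_labels
  fam_idx <- apply(rbind(root_scores), 1L, which.max)
  n <- nrow(rbind(root_scores))
  family <- model$tree$family_labels[fam_idx]
  species <- character(n)
  leaf_conf <- numeric(n)
  leaf_probs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- family[i]
    leaf <- model$leaf_heads[[f]]
    space <- model$spaces[[f]]
    if (leaf$type == "identity") {
      species[i] <- space$classes[1L]
      leaf_conf[i] <- 1
      leaf_probs[[i]] <- stats::setNames(1, space$classes[1L])
    } else {
      s <- as.vector(feats[i, , drop = FALSE] %*% leaf$head$W) + leaf$head$b
      p <- softmax(s)
      names(p) <- space$classes
      k <- which.max(s)
      pred <- space$classes[k]
      species[i] <- if (pred == others_label()) reject_label() else pred
      leaf_conf[i] <- p[k]
      leaf_probs[[i]] <- p
    }
  }
  list(
    predictions = data.frame(
      family = family, species = species,
      root_confidence = root_probs[cbind(seq_len(n), fam_idx)],
      leaf_confidence = leaf_conf, stringsAsFactors = FALSE
    ),
    root_probs = root_probs,
    leaf_probs = leaf_probs
  )
}

#' Stage (iii): routed prediction
#'
#' The trunk is evaluated once per image; the root head's argmax selects
#' the leaf, which assigns the species over the same features. A leaf
#' predicting `Others` yields the reserved `REJECT` species label.
#'
#' @param model a trained `tree_model`.
#' @param records a `fish_records` collection.
#' @param conv_cache optional precomputed conv features for `records`.
#' @return list with `predictions` (data.frame: `family`, `species`,
#'   `root_confidence`, `leaf_confidence`), `root_probs` (n x families
#'   matrix) and `leaf_probs` (list of named vectors over the routed
#'   leaf's classes).
#' @export
route_predict <- function(model, records, conv_cache = NULL) {
  stopifnot(inherits(model, "tree_model"))
  conv <- conv_cache %||% trunk_conv_features(model$trunk, records)
  route_from_features(model, trunk_project(model$trunk, conv))
}
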