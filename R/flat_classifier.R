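# Flat transfer-learning classifier: pluggable trunk, freshly initialized
# N-way softmax head, minibatch SGD with momentum, per-class loss tracking.
#
# The score vector x of a sample is turned into class probabilities by
#   softmax(x)_i = exp(x_i) / sum_j exp(x_j)
# (computed with the usual max-shift for stability) and trained with the
# minibatch-averaged cross-entropy
#   l = (1/M) sum_n l_n,   l_n = -sum_i y_{n,i} log softmax(x_n)_i.

#' Numerically stable softmax
#'
#' @param scores numeric vector of class scores (logits), or a matrix with
#'   one score vector per row.
#' @return probabilities of the same shape; each vector sums to 1.
#' @export
softmax <- function(scores) {
  if (is.matrix(scores)) {
    if (ncol(scores) == 0L) stop("empty score matrix", call. = FALSE)
    shifted <- scores - apply(scores, 1L, max)
    e <- exp(shifted)
    return(e / rowSums(e))
  }
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  e <- exp(scores - max(scores))
  e / sum(e)
}

# per-sample cross-entropy losses for a score matrix and a 0/1 target matrix
per_sample_ce <- function(score_matrix, target_matrix) {
  shifted <- score_matrix - apply(score_matrix, 1L, max)
  log_z <- log(rowSums(exp(shifted)))
  # l_n = log Z - x_true (after shift), generalized to soft targets
  rowSums(target_matrix * (log_z - shifted))
}

#' Minibatch cross-entropy loss
#'
#' @param batch_scores M x N matrix of class scores (one row per sample).
#' @param targets M x N matrix of one-hot (or soft, row-sum 1) targets.
#' @return the minibatch mean of the per-sample losses.
#' @export
cross_entropy <- function(batch_scores, targets) {
  batch_scores <- rbind(batch_scores)
  targets <- rbind(targets)
  if (!all(dim(batch_scores) == dim(targets))) {
    stop("score and target dimensions disagree", call. = FALSE)
  }
  if (any(abs(rowSums(targets) - 1) > 1e-6)) {
    stop("each target row must sum to 1", call. = FALSE)
  }
  mean(per_sample_ce(batch_scores, targets))
}

one_hot <- function(labels, class_order) {
  m <- matrix(0, nrow = length(labels), ncol = length(class_order),
              dimnames = list(NULL, class_order))
  m[cbind(seq_along(labels), match(labels, class_order))] <- 1
  m
}

new_head <- function(input_dim, n_classes, seed) {
  rng <- make_rng(seed)
  list(
    W = matrix(rng$runif(input_dim * n_classes, -0.05, 0.05),
               nrow = input_dim),
    b = numeric(n_classes)  # zero bias
  )
}

#' Default training hyperparameters
#'
#' @param epochs number of passes over the train partition.
#' @param lr SGD learning rate.
#' @param momentum classical momentum coefficient.
#' @param batch_size minibatch size.
#' @param weight_decay L2 penalty on weights (not biases).
#' @param seed seed for head initialization and epoch shuffling.
#' @export
training_config <- function(epochs = 30L, lr = 0.01, momentum = 0.9,
                            batch_size = 32L, weight_decay = 1e-4,
                            seed = 0L) {
  list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
       batch_size = as.integer(batch_size), weight_decay = weight_decay,
       seed = as.integer(seed))
}

# Core trainer: linear softmax head on top of features, optionally
# back-propagating into a trainable trunk dense stage.
#
# X / Xval: conv-stage feature matrices; labels / val_labels: characters.
# dense: NULL (head consumes X directly through trunk_project upstream)
# or list(W, b) updated jointly with the head; skip: the trunk's frozen
# companion projection, concatenated after the dense activations.
# Returns list(head, dense, history).
sgd_softmax_train <- function(X, labels, Xval, val_labels, class_order,
                              head, dense = NULL, skip = NULL,
                              hyper = training_config(), history = NULL) {
  n <- nrow(X)
  if (n == 0L) stop("empty train partition", call. = FALSE)
  targets <- one_hot(labels, class_order)
  d1 <- if (!is.null(dense)) ncol(dense$W)
  forward <- function(M) {
    if (is.null(dense)) {
      return(list(h = M, scores = sweep(M %*% head$W, 2L, head$b, `+`)))
    }
    h <- relu(sweep(M %*% dense$W, 2L, dense$b, `+`))
    if (!is.null(skip)) {
      h <- cbind(h, relu(sweep(M %*% skip$W, 2L, skip$b, `+`)))
    }
    list(h = h, scores = sweep(h %*% head$W, 2L, head$b, `+`))
  }
  if (is.null(history)) {
    tr_n <- table(factor(labels, levels = class_order))
    va_n <- table(factor(val_labels, levels = class_order))
    history <- loss_history(class_order,
                            stats::setNames(as.integer(tr_n), class_order),
                            stats::setNames(as.integer(va_n), class_order))
  }
  record <- function(hist, epoch) {
    per_class <- function(M, lbls) {
      if (!length(lbls)) return(stats::setNames(numeric(0), character(0)))
      ce <- per_sample_ce(forward(M)$scores, one_hot(lbls, class_order))
      vapply(split(ce, factor(lbls, levels = class_order)), function(v) {
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }
    record_epoch(hist, epoch, per_class(X, labels),
                 per_class(Xval, val_labels))
  }
  rng <- make_rng(hyper$seed + 1L)
  vel <- list(hW = head$W * 0, hb = head$b * 0)
  if (!is.null(dense)) vel <- c(vel, list(dW = dense$W * 0, db = dense$b * 0))
  for (epoch in seq_len(hyper$epochs)) {
    ord <- rng$sample_perm(n)
    for (start in seq(1L, n, by = hyper$batch_size)) {
      idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- targets[idx, , drop = FALSE]
      fw <- forward(Xb)
      P <- softmax(fw$scores)
      G <- (P - Yb) / length(idx)           # dl/dscores
      g_hW <- crossprod(fw$h, G) + hyper$weight_decay * head$W
      g_hb <- colSums(G)
      if (!is.null(dense)) {
        Gh <- (G %*% t(head$W))[, seq_len(d1), drop = FALSE]
        Gh[fw$h[, seq_len(d1), drop = FALSE] <= 0] <- 0   # ReLU gate
        g_dW <- crossprod(Xb, Gh) + hyper$weight_decay * dense$W
        g_db <- colSums(Gh)
        vel$dW <- hyper$momentum * vel$dW - hyper$lr * g_dW
        vel$db <- hyper$momentum * vel$db - hyper$lr * g_db
        dense$W <- dense$W + vel$dW
        dense$b <- dense$b + vel$db
      }
      vel$hW <- hyper$momentum * vel$hW - hyper$lr * g_hW
      vel$hb <- hyper$momentum * vel$hb - hyper$lr * g_hb
      head$W <- head$W + vel$hW
      head$b <- head$b + vel$hb
    }
    history <- record(history, epoch)
  }
  list(head = head, dense = dense, history = history)
}

#' Build a flat (single-level) classification model
#'
#' The trunk's earlier (convolutional) stages are always frozen; the
#' freeze policy decides whether the trunk's dense projection stage may
#' be updated alongside the new head.
#'
#' @param trunk a `feature_trunk` or a trunk name passed to
#'   [build_trunk()].
#' @param classes ordered character vector of class labels (>= 2), or an
#'   integer count (labels are then auto-named `class01`, ...).
#' @param freeze `"all"` (default: only the head trains — the
#'   transfer-learning setting) or `"conv_only"` (the trunk's dense stage
#'   trains too).
#' @param seed seed for head and dense-stage initialization.
#' @return an object of class `flat_model`.
#' @export
build_flat_model <- function(trunk = "tiny", classes, freeze = c("all", "conv_only"),
                             seed = 0L) {
  freeze <- match.arg(freeze)
  if (!inherits(trunk, "feature_trunk")) trunk <- build_trunk(trunk)
  if (is.numeric(classes) && length(classes) == 1L) {
    classes <- sprintf("class%02d", seq_len(classes))
  }
  classes <- as.character(classes)
  if (length(classes) < 2L) {
    stop("a classifier needs at least 2 classes", call. = FALSE)
  }
  if (anyDuplicated(classes)) stop("duplicate class labels", call. = FALSE)
  if (trunk$name != "custom" && !isTRUE(trunk$dense_initialized)) {
    trunk <- init_trunk_dense(trunk, seed + 1000L)
  }
  head_dim <- trunk$output_dim %||% stop("custom trunk needs output_dim",
                                         call. = FALSE)
  structure(
    list(trunk = trunk, head = new_head(head_dim, length(classes), seed),
         class_order = classes, freeze = freeze),
    class = "flat_model"
  )
}

#' @export
print.flat_model <- function(x, ...) {
  cat("<flat_model>", x$trunk$name, "trunk ->", length(x$class_order),
      "classes (freeze:", x$freeze, ")\n")
  invisible(x)
}

#' Train the flat model
#'
#' Runs minibatch SGD on the head (and, under the `"conv_only"` freeze
#' policy, the trunk's dense stage), recording per-class train and
#' validation losses each epoch. Frozen stages are untouched — their
#' [param_checksum()] is identical before and after.
#'
#' @param model a `flat_model`.
#' @param records a `fish_records` collection.
#' @param split a `dataset_split` over `records`.
#' @param hyper a [training_config()].
#' @param history an existing `loss_history` to extend, or `NULL`.
#' @param conv_cache optional precomputed [trunk_conv_features()] matrix
#'   for all of `records` (avoids recomputation across training rounds).
#' @return list with elements `model` (trained) and `history`.
#' @export
train_flat <- function(model, records, split, hyper = training_config(),
                       history = NULL, conv_cache = NULL) {
  stopifnot(inherits(model, "flat_model"), inherits(split, "dataset_split"))
  if (!length(split$train)) stop("empty train partition", call. = FALSE)
  labels <- record_species(records)
  unknown <- setdiff(unique(labels[c(split$train, split$validation)]),
                     model$class_order)
  if (length(unknown)) {
    stop("labels outside the model's class order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  conv <- conv_cache %||% trunk_conv_features(model$trunk, records)
  dense <- if (model$freeze == "conv_only" && model$trunk$name != "custom") {
    model$trunk$dense
  }
  to_input <- function(idx) {
    m <- conv[idx, , drop = FALSE]
    if (is.null(dense)) trunk_project(model$trunk, m) else m
  }
  fit <- sgd_softmax_train(
    X = to_input(split$train), labels = labels[split$train],
    Xval = to_input(split$validation), val_labels = labels[split$validation],
    class_order = model$class_order, head = model$head, dense = dense,
    skip = if (!is.null(dense)) model$trunk$skip,
    hyper = hyper, history = history
  )
  model$head <- fit$head
  if (!is.null(fit$dense)) model$trunk$dense <- fit$dense
  list(model = model, history = fit$history)
}

#' Predict species for a collection
#'
#' @param model a trained `flat_model`.
#' @param records a `fish_records` collection.
#' @param conv_cache optional precomputed conv features for `records`.
#' @return list with `labels` (argmax class, ties broken by lowest class
#'   index) and `probabilities` (n x N matrix).
#' @export
predict_flat <- function(model, records, conv_cache = NULL) {
  stopifnot(inherits(model, "flat_model"))
  conv <- conv_cache %||% trunk_conv_features(model$trunk, records)
  feats <- trunk_project(model$trunk, conv)
  scores <- sweep(feats %*% model$head$W, 2L, model$head$b, `+`)
  probs <- softmax(scores)
  colnames(probs) <- model$class_order
  list(
    labels = model$class_order[apply(scores, 1L, which.max)],
    probabilities = probs
  )
}
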