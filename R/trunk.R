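# Pluggable feature trunks.
#
# A trunk maps a standardized 224 x 224 x 3 image to a feature vector.
# It is split into two parts mirroring a transfer-learning backbone:
#   * fixed convolutional stages ("earlier layers"): two 3x3 convolutions
#     with seeded filters, interleaved with average pooling — never
#     trained, so their activations can be computed once and cached;
#   * a dense projection stage (the last trunk stage), the only trunk
#     part that staged training may update before it is frozen.
# The trunk's output concatenates the dense stage's activations with a
# frozen generic projection of the conv activations: adapting the dense
# stage to one task (the family level, say) then cannot erase the
# generic features the finer task (species) still needs — the same
# reason transfer learning keeps early layers.
# The bundled "tiny" trunk keeps every stage small enough that the whole
# pipeline runs on one CPU; heavy pretrained backbones plug in as
# user-supplied feature functions via `custom_trunk()`.

TINY_SIDE <- 224L
TINY_CONV_DIM <- 7L * 7L * 24L   # flattened conv-stage output
TINY_DENSE_DIM <- 96L
TINY_SKIP_DIM <- 96L

#' Build a feature trunk by name
#'
#' @param name `"tiny"` (bundled desk-scale trunk) or the name of a trunk
#'   registered via [custom_trunk()]. Heavyweight named backbones are not
#'   shipped: supply them as custom trunks wrapping your own weights.
#' @param seed seed for the fixed convolution filters and the dense-stage
#'   initialization.
#' @return an object of class `feature_trunk`.
#' @export
build_trunk <- function(name = "tiny", seed = 42L) {
  if (is.function(name)) return(custom_trunk(name))
  registry <- c("tiny")
  if (!name %in% registry) {
    stop("unknown trunk '", name, "'; available: ",
         paste(registry, collapse = ", "),
         ". Pretrained backbones (e.g. a ResNeXt-class network) plug in ",
         "via custom_trunk(feature_fun).", call. = FALSE)
  }
  rng <- make_rng(seed)
  he <- function(fan_in, n) rng$rnorm(n, sd = sqrt(2 / fan_in))
  structure(
    list(
      name = "tiny",
      side = TINY_SIDE,
      conv1 = matrix(he(27, 27 * 12), nrow = 27),    # 3x3x3 -> 12 maps
      conv2 = matrix(he(108, 108 * 24), nrow = 108), # 3x3x12 -> 24 maps
      dense = list(
        W = matrix(0, nrow = TINY_CONV_DIM, ncol = TINY_DENSE_DIM),
        b = numeric(TINY_DENSE_DIM)
      ),
      skip = list(
        W = matrix(he(TINY_CONV_DIM, TINY_CONV_DIM * TINY_SKIP_DIM),
                   nrow = TINY_CONV_DIM),
        b = numeric(TINY_SKIP_DIM)
      ),
      conv_dim = TINY_CONV_DIM,
      output_dim = TINY_DENSE_DIM + TINY_SKIP_DIM,
      dense_initialized = FALSE,
      seed = as.integer(seed)
    ),
    class = "feature_trunk"
  )
}

# fresh seeded He init for the dense stage (called by model builders so
# that two models built from the same trunk spec start identically)
init_trunk_dense <- function(trunk, seed) {
  rng <- make_rng(seed)
  width <- ncol(trunk$dense$W)
  trunk$dense$W <- matrix(
    rng$rnorm(trunk$conv_dim * width, sd = sqrt(2 / trunk$conv_dim)),
    nrow = trunk$conv_dim
  )
  trunk$dense$b <- numeric(width)
  trunk$dense_initialized <- TRUE
  trunk
}

#' Wrap a user feature function as a trunk
#'
#' @param feature_fun function taking a `fish_records` collection and
#'   returning an n x d numeric feature matrix (its weights are the
#'   user's responsibility and are treated as frozen).
#' @param output_dim feature dimensionality; inferred on first use when
#'   `NULL`.
#' @export
custom_trunk <- function(feature_fun, output_dim = NULL) {
  stopifnot(is.function(feature_fun))
  structure(
    list(name = "custom", feature_fun = feature_fun,
         output_dim = output_dim, conv_dim = output_dim),
    class = "feature_trunk"
  )
}

#' @export
print.feature_trunk <- function(x, ...) {
  cat("<feature_trunk>", x$name, "-> dim", x$output_dim %||% "?", "\n")
  invisible(x)
}

# f x f average pooling along rows then columns
avg_pool <- function(x, f) {
  d <- dim(x)
  y <- array(colMeans(matrix(x, nrow = f)), dim = c(d[1L] / f, d[2L], d[3L]))
  y <- aperm(y, c(2L, 1L, 3L))
  d <- dim(y)
  y <- array(colMeans(matrix(y, nrow = f)), dim = c(d[1L] / f, d[2L], d[3L]))
  aperm(y, c(2L, 1L, 3L))
}

# im2col for a 3x3 convolution with zero padding 1: returns (H*W) x (9*C)
im2col3 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; ch <- dim(x)[3L]
  padded <- array(0, dim = c(h + 2L, w + 2L, ch))
  padded[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, nrow = h * w, ncol = 9L * ch)
  k <- 1L
  for (c_i in seq_len(ch)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        cols[, k] <- as.vector(padded[dy + seq_len(h), dx + seq_len(w), c_i])
        k <- k + 1L
      }
    }
  }
  cols
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# fixed convolutional stages for one record -> length conv_dim vector
tiny_conv_forward <- function(trunk, img) {
  x <- (img / 255 - 0.5) / 0.5
  x <- avg_pool(x, 4L)                               # 56 x 56 x 3
  a1 <- relu(im2col3(x) %*% trunk$conv1)             # (56*56) x 12
  a1 <- avg_pool(array(a1, dim = c(56L, 56L, 12L)), 4L)  # 14 x 14 x 12
  a2 <- relu(im2col3(a1) %*% trunk$conv2)            # (14*14) x 24
  a2 <- avg_pool(array(a2, dim = c(14L, 14L, 24L)), 2L)  # 7 x 7 x 24
  as.vector(a2)
}

#' Fixed-stage (cacheable) trunk activations for a collection
#'
#' Standardizes each record to the trunk's input side if needed and runs
#' the frozen convolutional stages. This is the expensive, cache-once
#' part of the forward pass; the trainable dense stage is applied
#' separately by [trunk_project()].
#'
#' @param trunk a `feature_trunk`.
#' @param records a `fish_records` collection.
#' @return an n x conv_dim numeric matrix.
#' @export
trunk_conv_features <- function(trunk, records) {
  stopifnot(inherits(trunk, "feature_trunk"))
  if (trunk$name == "custom") {
    out <- trunk$feature_fun(records)
    return(as.matrix(out))
  }
  out <- matrix(0, nrow = length(records), ncol = trunk$conv_dim)
  for (i in seq_along(records)) {
    img <- records[[i]]$image
    if (!all(dim(img) == c(trunk$side, trunk$side, 3L))) {
      img <- resize_pixels(img, trunk$side, trunk$side)
    }
    out[i, ] <- tiny_conv_forward(trunk, img)
  }
  out
}

#' Apply the trunk's projection stages
#'
#' Concatenates the (trainable) dense stage's activations with the
#' frozen generic projection of the conv activations.
#'
#' @param trunk a `feature_trunk`.
#' @param conv_features matrix from [trunk_conv_features()].
#' @return n x output_dim matrix of trunk features (ReLU activations).
#' @export
trunk_project <- function(trunk, conv_features) {
  if (trunk$name == "custom") return(conv_features)
  cbind(
    relu(sweep(conv_features %*% trunk$dense$W, 2L, trunk$dense$b, `+`)),
    relu(sweep(conv_features %*% trunk$skip$W, 2L, trunk$skip$b, `+`))
  )
}

#' Full trunk features for a collection
#' @inheritParams trunk_conv_features
#' @export
trunk_features <- function(trunk, records) {
  trunk_project(trunk, trunk_conv_features(trunk, records))
}

#' Checksum of a parameter set
#'
#' Order-sensitive numeric summary used to assert that staged training
#' leaves frozen parameters untouched.
#'
#' @param params a numeric vector/matrix or (nested) list of them.
#' @return a numeric vector; identical parameters give identical
#'   checksums.
#' @export
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  if (!length(v)) return(c(0, 0, 0))
  c(sum(v), sum(v^2), sum(v * seq_along(v)) / length(v))
}
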