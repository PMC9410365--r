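# Labeled image collections, annotation I/O and stratified split protocols.

#' Construct one labeled image record
#'
#' @param image H x W x 3 integer pixel array (8-bit channels).
#' @param species species label.
#' @param family family label (usually derived from the taxonomy).
#' @param source_id free-form origin tag (video or file id).
#' @param is_augmented whether the record is an augmentation variant.
#' @return a list of class `image_record`.
#' @export
image_record <- function(image, species, family = NA_character_,
                         source_id = NA_character_, is_augmented = FALSE) {
  assert_pixel_array(image)
  structure(
    list(image = image, species = as.character(species),
         family = as.character(family), source_id = as.character(source_id),
         is_augmented = isTRUE(is_augmented)),
    class = "image_record"
  )
}

#' Bundle records into a collection
#' @param records a list of `image_record` objects.
#' @export
fish_records <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "image_record")))
  structure(records, class = "fish_records")
}

#' @export
`[.fish_records` <- function(x, i) {
  structure(unclass(x)[i], class = "fish_records")
}

#' @export
print.fish_records <- function(x, ...) {
  cat("<fish_records>", length(x), "records,",
      length(unique(record_species(x))), "species\n")
  invisible(x)
}

#' Species labels of a collection
#' @param records a `fish_records` collection.
#' @export
record_species <- function(records) {
  vapply(records, function(r) r$species, character(1))
}

#' Family labels of a collection
#' @param records a `fish_records` collection.
#' @export
record_family <- function(records) {
  vapply(records, function(r) r$family, character(1))
}

# accept either a collection or a bare label vector for split protocols
split_labels <- function(records) {
  if (inherits(records, "fish_records")) record_species(records)
  else as.character(records)
}

#' Read an annotation table into a record collection
#'
#' @param images_dir directory that image paths are relative to.
#' @param table a data.frame with columns `path`, `species` and optionally
#'   `source_id`, or the path of a CSV file with that header.
#' @param tree a `taxonomy_tree` used to resolve each species' family.
#' @return a `fish_records` collection, one record per row
#'   (`is_augmented = FALSE`).
#' @export
read_annotations <- function(images_dir, table, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  if (!all(c("path", "species") %in% names(table))) {
    stop("annotation table must have columns 'path' and 'species'",
         call. = FALSE)
  }
  if (nrow(table) == 0L) {
    warning("annotation table is empty; returning empty collection",
            call. = FALSE)
    return(fish_records(list()))
  }
  paths <- file.path(images_dir, table$path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing image file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(table$species), tree$species_labels)
  if (length(unknown)) {
    stop("species not in taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  src <- if ("source_id" %in% names(table)) as.character(table$source_id)
         else rep(NA_character_, nrow(table))
  fish_records(lapply(seq_len(nrow(table)), function(i) {
    image_record(
      image = read_image_file(paths[i]),
      species = table$species[i],
      family = family_of(tree, table$species[i]),
      source_id = src[i]
    )
  }))
}

#' Standardize a record to the network input size
#'
#' Bilinear resize to `side` x `side` x 3 without preserving aspect ratio;
#' label fields are unchanged.
#'
#' @param record an `image_record` (or a `fish_records` collection, which
#'   is standardized element-wise).
#' @param side target side length in pixels (default 224).
#' @export
standardize <- function(record, side = 224L) {
  if (inherits(record, "fish_records")) {
    return(fish_records(lapply(record, standardize, side = side)))
  }
  stopifnot(inherits(record, "image_record"))
  record$image <- resize_pixels(record$image, side, side)
  record
}

is_standardized <- function(record, side = 224L) {
  all(dim(record$image) == c(side, side, 3L))
}

new_dataset_split <- function(train, validation, test, fold_id = NA_integer_) {
  idx <- c(train, validation, test)
  stopifnot(!anyDuplicated(idx))
  structure(
    list(train = sort(train), validation = sort(validation),
         test = sort(test), fold_id = fold_id),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>", if (!is.na(x$fold_id)) paste0("fold ", x$fold_id, ":"),
      length(x$train), "train /", length(x$validation), "validation /",
      length(x$test), "test\n")
  invisible(x)
}

#' Stratified k-fold cross-validation splits
#'
#' Within each class, samples are shuffled (seeded) and dealt into k folds
#' whose sizes differ by at most one. Split i uses fold i as test, fold
#' (i mod k) + 1 as validation, and the remaining k - 2 folds as train,
#' giving the (k-2)/k : 1/k : 1/k proportions of the 7-fold protocol.
#'
#' @param records a `fish_records` collection or a character vector of
#'   class labels.
#' @param k number of folds (>= 3; default 7).
#' @param seed RNG seed for the per-class shuffles.
#' @return a list of k `dataset_split` objects.
#' @export
stratified_kfold <- function(records, k = 7L, seed = 0L) {
  labels <- split_labels(records)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  if (!length(labels)) stop("no records to split", call. = FALSE)
  classes <- sort(unique(labels))
  fold_of <- integer(length(labels))
  rng <- make_rng(seed)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      warning("class '", cl, "' has ", length(idx),
              " samples for ", k, "-fold CV; some folds will be empty",
              call. = FALSE)
    }
    idx <- idx[rng$sample_perm(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(i) {
    val_fold <- (i %% k) + 1L
    new_dataset_split(
      train = which(!fold_of %in% c(i, val_fold)),
      validation = which(fold_of == val_fold),
      test = which(fold_of == i),
      fold_id = i
    )
  })
}

#' Stratified holdout split
#'
#' Per class, `round(train_fraction * n)` samples go to train and the rest
#' to validation (no test partition). Rounding to the nearest integer
#' reproduces the published per-class 80/20 split sizes of the LCF-15
#' protocol exactly.
#'
#' @inheritParams stratified_kfold
#' @param train_fraction fraction of each class assigned to train.
#' @return a `dataset_split` with an empty test partition.
#' @export
holdout_split <- function(records, train_fraction = 0.8, seed = 0L) {
  labels <- split_labels(records)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!length(labels)) stop("no records to split", call. = FALSE)
  rng <- make_rng(seed)
  train <- integer(); val <- integer()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    n_train <- round(train_fraction * length(idx))
    if (n_train == length(idx)) {
      warning("class '", cl, "' has no validation samples", call. = FALSE)
    }
    train <- c(train, idx[seq_len(n_train)])
    val <- c(val, idx[setdiff(seq_along(idx), seq_len(n_train))])
  }
  new_dataset_split(train = train, validation = val, test = integer())
}

#' Per-class sample counts
#'
#' @param records a `fish_records` collection or a character label vector.
#' @return a data.frame with columns `species` and `n`, sorted by label;
#'   counts sum to the collection size.
#' @export
dataset_summary <- function(records) {
  labels <- split_labels(records)
  if (!length(labels)) {
    return(data.frame(species = character(), n = integer()))
  }
  tab <- table(labels)
  data.frame(species = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a split manifest as CSV
#'
#' @param split a `dataset_split`.
#' @param paths character vector of per-record identifiers (image paths).
#' @param file output CSV path.
#' @export
write_split_manifest <- function(split, paths, file) {
  rows <- data.frame(path = character(), partition = character(),
                     fold = integer())
  for (part in c("train", "validation", "test")) {
    idx <- split[[part]]
    if (length(idx)) {
      rows <- rbind(rows, data.frame(path = paths[idx], partition = part,
                                     fold = split$fold_id))
    }
  }
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

# Deterministic local RNG (does not disturb the global .Random.seed).
make_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = globalenv())
    expr_fun()
  }
  list(
    sample_perm = function(n) run(function() sample.int(n)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE) {
      run(function() sample.int(n, size, replace = replace))
    }
  )
}
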