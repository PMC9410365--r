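# Geometric transform bank and targeted training-set enlargement.
#
# The bank mirrors the augmentations used for underwater fish crops: a
# horizontal flip (fish swimming the other way), rescaling to a tinier
# and a larger size, a central crop trimming background from every side,
# and small in-plane rotations. Each enabled transform produces exactly
# one variant; transforms are applied singly, never composed.

#' Configure the augmentation transform bank
#'
#' @param flip_horizontal apply a horizontal mirror (default TRUE).
#' @param scale_factors positive rescaling factors; the defaults 0.75 and
#'   1.25 realize one "tinier" and one "larger" variant. Scaled images are
#'   brought back to the standard side (reflection padding when shrunk,
#'   central crop when grown) so downstream shape is constant.
#' @param crop_fraction_per_side fraction of each side removed by the
#'   central crop, in (0, 0.5); 0.25 keeps the central half in each
#'   dimension. `NULL` disables the crop.
#' @param rotation_angles_deg rotation angles in degrees (default
#'   -20, -10, 10, 20); exposed corners are reflection-padded.
#' @param flagged_classes classes whose training samples are to be
#'   enlarged (filled in from a [flag_classes()] report).
#' @return an object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(flip_horizontal = TRUE,
                              scale_factors = c(0.75, 1.25),
                              crop_fraction_per_side = 0.25,
                              rotation_angles_deg = c(-20, -10, 10, 20),
                              flagged_classes = character()) {
  if (!is.null(scale_factors) && any(scale_factors <= 0)) {
    stop("scale factors must be positive", call. = FALSE)
  }
  if (!is.null(crop_fraction_per_side) &&
      (crop_fraction_per_side <= 0 || crop_fraction_per_side >= 0.5)) {
    stop("crop_fraction_per_side must lie in (0, 0.5)", call. = FALSE)
  }
  plan <- structure(
    list(flip_horizontal = isTRUE(flip_horizontal),
         scale_factors = as.numeric(scale_factors %||% numeric()),
         crop_fraction_per_side = crop_fraction_per_side,
         rotation_angles_deg = as.numeric(rotation_angles_deg %||% numeric()),
         flagged_classes = as.character(flagged_classes)),
    class = "augmentation_plan"
  )
  if (variants_per_image(plan) < 1L) {
    stop("augmentation plan enables no transform", call. = FALSE)
  }
  plan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of variants the plan produces per input image
#' @param plan an `augmentation_plan`.
#' @export
variants_per_image <- function(plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  as.integer(plan$flip_horizontal) + length(plan$scale_factors) +
    as.integer(!is.null(plan$crop_fraction_per_side)) +
    length(plan$rotation_angles_deg)
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("<augmentation_plan>", variants_per_image(x), "variants/image;",
      length(x$flagged_classes), "flagged class(es)\n")
  invisible(x)
}

# rescale then restore the standard side: shrunk images are centered on a
# reflection-padded canvas, grown images are center-cropped
scale_restore <- function(img, factor, side) {
  new_side <- max(1L, round(side * factor))
  scaled <- resize_pixels(img, new_side, new_side)
  if (new_side == side) return(scaled)
  if (new_side > side) {
    off <- floor((new_side - side) / 2)
    return(scaled[off + seq_len(side), off + seq_len(side), , drop = FALSE])
  }
  pad <- side - new_side
  lo <- floor(pad / 2)
  rows <- reflect_index(seq_len(side) - lo, new_side)
  scaled[rows, rows, , drop = FALSE]
}

#' Generate augmentation variants of one record
#'
#' Applies each enabled transform of the plan singly to a standardized
#' record and returns the variants (the original is not included). Every
#' variant is standardized back to the input side, keeps the record's
#' labels, and is marked `is_augmented = TRUE`.
#'
#' @param record a standardized `image_record`.
#' @param plan an `augmentation_plan`.
#' @return a list of `image_record` variants, one per enabled transform.
#' @export
augment_image <- function(record, plan) {
  stopifnot(inherits(record, "image_record"),
            inherits(plan, "augmentation_plan"))
  side <- dim(record$image)[1L]
  if (!is_standardized(record, side) || dim(record$image)[2L] != side) {
    stop("augment_image expects a standardized (square) record",
         call. = FALSE)
  }
  imgs <- list()
  if (plan$flip_horizontal) {
    imgs <- c(imgs, list(flip_pixels_h(record$image)))
  }
  for (s in plan$scale_factors) {
    imgs <- c(imgs, list(scale_restore(record$image, s, side)))
  }
  if (!is.null(plan$crop_fraction_per_side)) {
    cropped <- crop_pixels(record$image, plan$crop_fraction_per_side)
    imgs <- c(imgs, list(resize_pixels(cropped, side, side)))
  }
  for (a in plan$rotation_angles_deg) {
    imgs <- c(imgs, list(rotate_pixels(record$image, a)))
  }
  lapply(imgs, function(im) {
    v <- record
    v$image <- im
    v$is_augmented <- TRUE
    v
  })
}

#' Enlarge a training partition by targeted augmentation
#'
#' Records whose species belongs to the plan's flagged classes receive
#' one variant per enabled transform; all originals are kept, so a
#' flagged class with n samples grows to n * (1 + variants_per_image).
#' Unflagged classes pass through untouched. Only ever apply this to the
#' train partition: validation and test must stay augmentation-free.
#'
#' @param records a `fish_records` collection (train partition), already
#'   standardized.
#' @param plan an `augmentation_plan` with `flagged_classes` set.
#' @return a `fish_records` collection of originals plus variants.
#' @export
enlarge_training_set <- function(records, plan) {
  stopifnot(inherits(records, "fish_records"),
            inherits(plan, "augmentation_plan"))
  if (!length(plan$flagged_classes)) return(records)
  out <- list()
  for (r in records) {
    out <- c(out, list(r))
    if (r$species %in% plan$flagged_classes) {
      out <- c(out, augment_image(r, plan))
    }
  }
  fish_records(out)
}
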