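# Synthetic taxonomy-structured image generator.
#
# Emulates the structure of cropped underwater fish datasets at desk
# scale: species grouped into families, where the FAMILY determines the
# coarse trait (body silhouette, drawn from a fixed shape bank) and the
# SPECIES determines fine traits (base hue, stripe count, texture
# frequency). Images are rendered at random native sizes (~20-200 px,
# exercising the resize path), over a water-like background with
# luminance jitter, Gaussian blur and background clutter as nuisance.
# Coarse traits are deliberately more separable than fine ones, so
# family classification is strictly easier than species classification
# — the premise a coarse-to-fine hierarchy relies on.

SHAPE_BANK <- c("ellipse", "triangle", "crescent", "rectangle",
                "diamond", "ring", "cross", "capsule")

#' Specify a synthetic dataset
#'
#' Defaults mirror the family-size profile of the LCF-15 taxonomy
#' (6 families with 2, 3, 1, 1, 1 and 7 species), so degenerate
#' single-species leaves and multi-species leaves are both exercised.
#'
#' @param n_families number of families (at most `length(SHAPE_BANK)`).
#' @param species_per_family integer vector of species counts, one per
#'   family.
#' @param samples_per_species integer vector of per-species sample
#'   counts (recycled), e.g. from [imbalance_profile()]. Default 30.
#' @param native_size_range min/max native side length in pixels.
#' @param nuisance list with `luminance_jitter` (max relative brightness
#'   shift), `blur_sigma` (max Gaussian blur sigma, px) and
#'   `clutter_density` (expected clutter blobs per 1000 px^2).
#' @param seed generator seed; identical specs and seeds give
#'   byte-identical images.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_families = 6L,
                       species_per_family = c(2L, 3L, 1L, 1L, 1L, 7L),
                       samples_per_species = 30L,
                       native_size_range = c(20L, 200L),
                       nuisance = list(luminance_jitter = 0.15,
                                       blur_sigma = 0.8,
                                       clutter_density = 0.15),
                       seed = 0L) {
  if (length(species_per_family) != n_families) {
    stop("species_per_family must have one entry per family", call. = FALSE)
  }
  if (n_families > length(SHAPE_BANK)) {
    stop("at most ", length(SHAPE_BANK), " families supported (shape bank)",
         call. = FALSE)
  }
  if (any(species_per_family < 1L)) {
    stop("every family needs at least one species", call. = FALSE)
  }
  n_species <- sum(species_per_family)
  samples <- rep_len(as.integer(samples_per_species), n_species)
  if (any(samples < 1L)) stop("sample counts must be >= 1", call. = FALSE)
  structure(
    list(n_families = as.integer(n_families),
         species_per_family = as.integer(species_per_family),
         samples_per_species = samples,
         native_size_range = as.integer(native_size_range),
         nuisance = utils::modifyList(
           list(luminance_jitter = 0.15, blur_sigma = 0.8,
                clutter_density = 0.15),
           nuisance %||% list()),
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Deterministic trait table, one row per species. Coarse appearance
# (silhouette shape and base hue band) is a FAMILY trait; fine
# appearance (hue shade within the band, body brightness, stripe count,
# texture frequency) is a SPECIES trait — so the family task is
# strictly easier than the species task.
synth_traits <- function(spec) {
  fam_ids <- sprintf("fam%02d", seq_len(spec$n_families))
  rows <- list()
  k <- 0L
  for (i in seq_len(spec$n_families)) {
    fam_hue <- (i - 1) / spec$n_families     # evenly spaced hue bands
    n_sp <- spec$species_per_family[i]
    for (j in seq_len(n_sp)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        species = sprintf("%s_sp%02d", fam_ids[i], j),
        family = fam_ids[i],
        shape = SHAPE_BANK[i],
        hue = (fam_hue + (j - (n_sp + 1) / 2) * 0.012) %% 1,
        saturation = 0.55 + 0.40 * ((j * 0.618034) %% 1),
        shade = 0.70 + 0.25 * ((j * 0.37) %% 1),
        stripes = (j - 1L) %% 4L,             # 0..3 stripe bands
        texture_freq = 1L + (j %% 3L),
        n = spec$samples_per_species[k],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

hue_to_rgb <- function(h, s = 0.75, v = 0.85) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

# foreground mask of a shape on an s x s grid, centered, radius ~ 0.36 s
shape_mask <- function(shape, s, cx, cy, r) {
  x <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
  y <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
  dx <- (x - cx) / r; dy <- (y - cy) / r
  switch(shape,
    ellipse   = (dx / 1.4)^2 + dy^2 <= 1,
    triangle  = (dy <= 0.9) & (abs(dx) <= 0.9 * (dy + 1) / 1.9),
    crescent  = (dx^2 + dy^2 <= 1.1) & ((dx - 0.55)^2 + dy^2 >= 0.55),
    rectangle = (abs(dx) <= 1.25) & (abs(dy) <= 0.65),
    diamond   = abs(dx) + abs(dy) <= 1.1,
    ring      = (dx^2 + dy^2 <= 1.15) & (dx^2 + dy^2 >= 0.35),
    cross     = (abs(dx) <= 0.4) | (abs(dy) <= 0.4 & abs(dx) <= 1.1),
    capsule   = (abs(dx) <= 0.7 & abs(dy) <= 0.55) |
                ((abs(dx) - 0.7)^2 + dy^2 <= 0.55^2),
    stop("unknown shape: ", shape, call. = FALSE)
  )
}

# render one sample; `draw` is a closure over the generator's RNG
render_sample <- function(traits, spec, rng) {
  rg <- spec$native_size_range
  s <- rg[1L] + floor(rng$runif(1) * (rg[2L] - rg[1L] + 1))
  s <- as.integer(min(s, rg[2L]))
  # water-like background: blue-green with a vertical luminance gradient
  bg_col <- c(0.10 + rng$runif(1) * 0.1,
              0.35 + rng$runif(1) * 0.15,
              0.45 + rng$runif(1) * 0.2)
  grad <- matrix(rep(seq(1.15, 0.85, length.out = s), times = s), nrow = s)
  img <- array(0, dim = c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- bg_col[ch] * grad
  # background clutter: small random blobs
  n_blobs <- floor(spec$nuisance$clutter_density * s * s / 1000) +
    as.integer(rng$runif(1) < (spec$nuisance$clutter_density * s * s / 1000) %% 1)
  for (b in seq_len(n_blobs)) {
    bx <- 1 + rng$runif(1) * (s - 1); by <- 1 + rng$runif(1) * (s - 1)
    br <- max(1, rng$runif(1) * s / 10)
    bcol <- bg_col * (0.5 + rng$runif(1))
    m <- shape_mask("ellipse", s, bx, by, br)
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[m] <- min(1, bcol[ch]); img[, , ch] <- plane
    }
  }
  # fish body: family shape, species hue/stripes/texture
  cx <- s / 2 + rng$runif(1, -0.05, 0.05) * s
  cy <- s / 2 + rng$runif(1, -0.05, 0.05) * s
  r <- s * rng$runif(1, 0.30, 0.38)
  mask <- shape_mask(traits$shape, s, cx, cy, r)
  base <- hue_to_rgb(traits$hue, s = traits$saturation, v = traits$shade)
  rowpos <- matrix(rep(seq_len(s), times = s), nrow = s)
  colpos <- matrix(rep(seq_len(s), each = s), nrow = s)
  shade <- 1 + 0.12 * sin(2 * pi * traits$texture_freq * rowpos / s)
  if (traits$stripes > 0) {
    band <- floor((colpos - (cx - r)) / (2 * r) * (2 * traits$stripes)) %% 2L
    shade <- shade * ifelse(band == 0L, 1, 0.55)
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- pmin(1, base[ch] * shade[mask])
    img[, , ch] <- plane
  }
  # nuisance: luminance shift then blur
  img <- img * (1 + rng$runif(1, -1, 1) * spec$nuisance$luminance_jitter)
  img <- quantize_pixels(img * 255)
  sigma <- rng$runif(1) * spec$nuisance$blur_sigma
  if (sigma > 0.2) img <- blur_pixels(img, sigma)
  img
}

#' Generate a synthetic dataset
#'
#' @param spec a [synth_spec()].
#' @param out_dir optional directory; when given, images are written as
#'   PNGs together with `annotations.csv` (`path,species,source_id`) and
#'   `taxonomy.csv` (`species,family`).
#' @return list with `records` (a `fish_records` collection at native
#'   sizes), `tree` (the generated `taxonomy_tree`), `annotations`
#'   (data.frame) and `traits` (the per-species trait table).
#' @export
generate_synthetic <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  traits <- synth_traits(spec)
  tree <- load_taxonomy(traits[, c("species", "family")])
  rng <- make_rng(spec$seed)
  records <- list()
  ann <- list()
  n_total <- 0L
  for (k in seq_len(nrow(traits))) {
    for (m in seq_len(traits$n[k])) {
      n_total <- n_total + 1L
      img <- render_sample(traits[k, ], spec, rng)
      rec <- image_record(img, traits$species[k], traits$family[k],
                          source_id = sprintf("synth%05d", n_total))
      records[[n_total]] <- rec
      ann[[n_total]] <- data.frame(
        path = sprintf("%s_%03d.png", traits$species[k], m),
        species = traits$species[k],
        source_id = rec$source_id, stringsAsFactors = FALSE
      )
    }
  }
  records <- fish_records(records)
  annotations <- do.call(rbind, ann)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(records)) {
      write_image_file(records[[i]]$image,
                       file.path(out_dir, annotations$path[i]))
    }
    utils::write.csv(annotations, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
    utils::write.csv(traits[, c("species", "family")],
                     file.path(out_dir, "taxonomy.csv"), row.names = FALSE)
  }
  list(records = records, tree = tree, annotations = annotations,
       traits = traits)
}

#' Per-class sample-count profiles
#'
#' @param kind `"uniform"` (equal counts), `"geometric"` (counts decay by
#'   `ratio` per class) or `"frgt-like"` (seeded long tail whose
#'   majority/minority ratio is at least 100, emulating a heavily
#'   imbalanced field dataset).
#' @param n_classes number of classes.
#' @param total total sample count; counts always sum to `total`.
#' @param ratio decay ratio for `"geometric"` (default 2).
#' @param seed seed for the `"frgt-like"` jitter.
#' @return integer vector of length `n_classes`.
#' @export
imbalance_profile <- function(kind = c("uniform", "geometric", "frgt-like"),
                              n_classes, total, ratio = 2, seed = 0L) {
  kind <- match.arg(kind)
  if (total < n_classes) {
    stop("infeasible total: fewer samples than classes", call. = FALSE)
  }
  weights <- switch(kind,
    uniform = rep(1, n_classes),
    geometric = ratio^(-(seq_len(n_classes) - 1)),
    `frgt-like` = {
      if (total < 100 + n_classes - 1) {
        stop("infeasible total for a >= 100x imbalance ratio", call. = FALSE)
      }
      alpha <- log(1000) / max(1, n_classes - 1)
      rng <- make_rng(seed)
      exp(-alpha * (seq_len(n_classes) - 1)) *
        exp(rng$rnorm(n_classes, sd = 0.25))
    }
  )
  counts <- largest_remainder(weights / sum(weights) * total, total)
  counts <- pmax(counts, 1L)
  # restore the exact total after the minimum-1 floor
  while (sum(counts) > total) {
    i <- which.max(counts); counts[i] <- counts[i] - 1L
  }
  if (kind == "frgt-like") {
    counts <- sort(counts, decreasing = TRUE)
    if (max(counts) / min(counts) < 100) {
      counts[1L] <- counts[1L] + (min(counts) * 100L - max(counts))
      while (sum(counts) > total) {
        i <- utils::tail(which(counts > 1L), 1L)
        excess <- sum(counts) - total
        drop <- min(counts[i] - 1L, excess)
        counts[i] <- counts[i] - drop
      }
    }
    stopifnot(max(counts) / min(counts) >= 100)
  }
  stopifnot(sum(counts) == total)
  as.integer(counts)
}

# round nonnegative reals to integers preserving their (integer) sum
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    order_frac <- order(x - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Make one class deliberately confusable with a sibling species
#'
#' Interpolates the pixel traits of the class's samples toward samples
#' of a sibling species (same family) at weight `noise_rate`, creating
#' the badly-converged train/validation regime that the loss monitor is
#' designed to flag. At `noise_rate = 1` the class is indistinguishable
#' from its sibling.
#'
#' @param records a `fish_records` collection.
#' @param class the species to corrupt.
#' @param noise_rate interpolation weight in \[0, 1\].
#' @param indices optional positions into `records` to restrict the
#'   corruption to (e.g. a split's validation indices); default all of
#'   the class's samples.
#' @param seed seed for the sibling draws.
#' @return the modified collection.
#' @export
make_difficult_class <- function(records, class, noise_rate,
                                 indices = NULL, seed = 0L) {
  stopifnot(inherits(records, "fish_records"),
            noise_rate >= 0, noise_rate <= 1)
  species <- record_species(records)
  fams <- record_family(records)
  own <- which(species == class)
  if (!length(own)) stop("class not present: ", class, call. = FALSE)
  fam <- fams[own[1L]]
  sib <- which(fams == fam & species != class)
  if (!length(sib)) {
    stop("class '", class, "' has no sibling species in its family",
         call. = FALSE)
  }
  target <- if (is.null(indices)) own else intersect(own, indices)
  if (noise_rate == 0 || !length(target)) return(records)
  rng <- make_rng(seed)
  for (i in target) {
    donor <- records[[sib[rng$sample_int(length(sib), 1L)]]]$image
    d <- dim(records[[i]]$image)
    donor <- resize_pixels(donor, d[1L], d[2L])
    blended <- (1 - noise_rate) * records[[i]]$image + noise_rate * donor
    records[[i]]$image <- quantize_pixels(blended)
  }
  records
}
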