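# Species -> family taxonomy and hierarchical label spaces.

#' Reserved label for the leaf-level rejection class
#'
#' Leaf nodes of confusable families carry an extra class that absorbs
#' samples routed in from their confusion partners. The label is reserved:
#' it may not appear as a species or family name in user data.
#'
#' @return the reserved class label, a length-1 character vector.
#' @export
others_label <- function() "Others"

#' Reserved label emitted when a leaf predicts the rejection class
#' @return the reserved reject label.
#' @export
reject_label <- function() "REJECT"

#' Load a species-to-family taxonomy
#'
#' Reads a two-column mapping (one row per species) and builds the
#' two-taxon tree that defines the root (family) and leaf (species) label
#' spaces. Label orderings are lexicographic so that class indices are
#' reproducible across runs.
#'
#' @param table a data.frame with columns `species` and `family`, or the
#'   path of a CSV file with that header.
#' @return an object of class `taxonomy_tree` with elements
#'   `species_labels`, `family_labels` (both sorted) and `parent`
#'   (named character vector, species -> family).
#' @export
load_taxonomy <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table) || !all(c("species", "family") %in% names(table))) {
    stop("taxonomy table must have columns 'species' and 'family'",
         call. = FALSE)
  }
  if (nrow(table) == 0L) stop("taxonomy table is empty", call. = FALSE)
  sp <- trimws(as.character(table$species))
  fa <- trimws(as.character(table$family))
  if (anyNA(sp) || anyNA(fa) || any(sp == "") || any(fa == "")) {
    stop("taxonomy table contains missing species or family values",
         call. = FALSE)
  }
  reserved <- c(others_label(), reject_label())
  bad <- intersect(reserved, c(sp, fa))
  if (length(bad)) {
    stop("reserved label(s) used in taxonomy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(sp[duplicated(sp)])
  for (s in dup) {
    fams <- unique(fa[sp == s])
    if (length(fams) > 1L) {
      stop("species '", s, "' mapped to multiple families: ",
           paste(fams, collapse = ", "), call. = FALSE)
    }
  }
  keep <- !duplicated(sp)
  parent <- stats::setNames(fa[keep], sp[keep])
  ord <- order(names(parent))
  parent <- parent[ord]
  structure(
    list(
      species_labels = names(parent),
      family_labels = sort(unique(unname(parent))),
      parent = parent
    ),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree>", length(x$species_labels), "species in",
      length(x$family_labels), "families\n")
  for (f in x$family_labels) {
    cat("  ", f, ": ", paste(species_in_family(x, f), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Family of a species
#'
#' @param tree a `taxonomy_tree`.
#' @param species a species identifier known to the tree.
#' @return the parent family identifier.
#' @export
family_of <- function(tree, species) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  miss <- setdiff(species, tree$species_labels)
  if (length(miss)) {
    stop("unknown species: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  unname(tree$parent[species])
}

#' Species belonging to one family, in label order
#' @inheritParams family_of
#' @param family a family identifier known to the tree.
#' @export
species_in_family <- function(tree, family) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!family %in% tree$family_labels) {
    stop("unknown family: ", family, call. = FALSE)
  }
  tree$species_labels[unname(tree$parent[tree$species_labels]) == family]
}

# normalize confusable pairs: accepts NULL, a list of length-2 character
# vectors, or a 2-column matrix; returns a list of sorted pairs (deduped)
normalize_confusable <- function(tree, confusable) {
  if (is.null(confusable) || length(confusable) == 0L) return(list())
  if (is.matrix(confusable)) {
    confusable <- lapply(seq_len(nrow(confusable)),
                         function(i) as.character(confusable[i, ]))
  }
  pairs <- lapply(confusable, function(p) {
    p <- as.character(p)
    if (length(p) != 2L || p[1] == p[2]) {
      stop("confusable entries must be pairs of two distinct families",
           call. = FALSE)
    }
    miss <- setdiff(p, tree$family_labels)
    if (length(miss)) {
      stop("confusable pair references unknown family: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    sort(p)
  })
  unique(pairs)
}

#' Leaf-node label space for one family
#'
#' A leaf node classifies among the family's own species; when the family
#' participates in a confusable pair its label space is extended by the
#' reserved `Others` class (always last), populated at training time by
#' samples from the partner families.
#'
#' @inheritParams species_in_family
#' @param confusable set of confusable family pairs: a list of length-2
#'   character vectors (or a 2-column matrix); may be empty.
#' @return an object of class `leaf_label_space` with elements `family`,
#'   `classes` (ordered, `Others` last when present) and `others_sources`
#'   (character vector of partner families, possibly empty).
#' @export
leaf_label_space <- function(tree, family, confusable = list()) {
  own <- species_in_family(tree, family)
  pairs <- normalize_confusable(tree, confusable)
  partners <- character()
  for (p in pairs) {
    if (family %in% p) partners <- c(partners, setdiff(p, family))
  }
  partners <- sort(unique(partners))
  classes <- own
  if (length(partners)) classes <- c(classes, others_label())
  structure(
    list(family = family, classes = classes, others_sources = partners),
    class = "leaf_label_space"
  )
}

#' @export
print.leaf_label_space <- function(x, ...) {
  cat("<leaf_label_space> node ", x$family, ": ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  if (length(x$others_sources)) {
    cat("  Others drawn from: ", paste(x$others_sources, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Detect confusable family pairs from a root confusion matrix
#'
#' Mechanizes the manual inspection step that decides which leaf nodes
#' receive an `Others` class: pair (A, B) is flagged when the number of A
#' samples predicted as B exceeds `fraction` of A's row total (or vice
#' versa) in the family-level validation confusion matrix.
#'
#' @param cm a family-level `confusion_matrix` (see [confusion()]).
#' @param fraction flagging threshold as a fraction of the true class's
#'   sample count (default 0.02).
#' @return a list of sorted family pairs suitable for
#'   [leaf_label_space()] / [build_tree_model()].
#' @export
auto_confusable_pairs <- function(cm, fraction = 0.02) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  fams <- rownames(counts)
  pairs <- list()
  rs <- rowSums(counts)
  for (a in fams) {
    for (b in setdiff(intersect(fams, colnames(counts)), a)) {
      if (rs[a] > 0 && counts[a, b] > fraction * rs[a]) {
        pairs <- c(pairs, list(sort(c(a, b))))
      }
    }
  }
  unique(pairs)
}
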