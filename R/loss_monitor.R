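# Per-class train/validation loss tracking and the targeted-augmentation
# flagging criterion.
#
# After each epoch the trainer records, for every class, the mean
# cross-entropy over that class's train samples and over its validation
# samples. A class whose validation curve sits persistently above its
# train curve (relative to the train level) is "badly converged" —
# overfitting for lack of representative data — and becomes a candidate
# for targeted augmentation.

#' Create an empty loss history
#'
#' @param classes ordered class labels tracked by the history.
#' @param train_n,val_n named integer vectors of per-class sample counts
#'   in the train and validation partitions (weights for the global
#'   curves, and the basis of the minimum-support rule in
#'   [flag_classes()]).
#' @return an object of class `loss_history`.
#' @export
loss_history <- function(classes, train_n, val_n) {
  classes <- as.character(classes)
  train_n <- train_n[classes]; val_n <- val_n[classes]
  train_n[is.na(train_n)] <- 0L; val_n[is.na(val_n)] <- 0L
  structure(
    list(
      epochs = integer(),
      classes = classes,
      train = matrix(numeric(), ncol = length(classes),
                     dimnames = list(NULL, classes)),
      val = matrix(numeric(), ncol = length(classes),
                   dimnames = list(NULL, classes)),
      train_n = stats::setNames(as.integer(train_n), classes),
      val_n = stats::setNames(as.integer(val_n), classes),
      global_train = numeric(),
      global_val = numeric()
    ),
    class = "loss_history"
  )
}

weighted_global <- function(losses, n) {
  ok <- !is.na(losses) & n > 0
  if (!any(ok)) return(NA_real_)
  sum(losses[ok] * n[ok]) / sum(n[ok])
}

#' Append one epoch of per-class losses
#'
#' @param history a `loss_history`.
#' @param epoch epoch number, strictly greater than the last recorded.
#' @param train_losses,val_losses named numeric vectors of per-class mean
#'   losses; a class with no samples in a partition that epoch is
#'   recorded as missing (`NA`), never as zero.
#' @return the extended `loss_history`; the global curves are the
#'   sample-count-weighted means of the per-class losses.
#' @export
record_epoch <- function(history, epoch, train_losses, val_losses) {
  stopifnot(inherits(history, "loss_history"))
  if (length(history$epochs) && epoch <= max(history$epochs)) {
    stop("epoch ", epoch, " is not after the last recorded epoch ",
         max(history$epochs), call. = FALSE)
  }
  if (any(c(train_losses, val_losses) < 0, na.rm = TRUE)) {
    stop("losses must be nonnegative", call. = FALSE)
  }
  tr <- stats::setNames(rep(NA_real_, length(history$classes)), history$classes)
  va <- tr
  tr[intersect(names(train_losses), history$classes)] <-
    train_losses[intersect(names(train_losses), history$classes)]
  va[intersect(names(val_losses), history$classes)] <-
    val_losses[intersect(names(val_losses), history$classes)]
  history$epochs <- c(history$epochs, as.integer(epoch))
  history$train <- rbind(history$train, tr)
  history$val <- rbind(history$val, va)
  rownames(history$train) <- rownames(history$val) <- NULL
  history$global_train <- c(history$global_train,
                            weighted_global(tr, history$train_n))
  history$global_val <- c(history$global_val,
                          weighted_global(va, history$val_n))
  history
}

#' @export
print.loss_history <- function(x, ...) {
  cat("<loss_history>", length(x$epochs), "epochs,",
      length(x$classes), "classes")
  if (length(x$epochs)) {
    cat(sprintf("; last global train/val = %.4f / %.4f",
                utils::tail(x$global_train, 1), utils::tail(x$global_val, 1)))
  }
  cat("\n")
  invisible(x)
}

#' Loss-curve divergence score of one class
#'
#' The score is the mean, over the last `window` recorded epochs, of the
#' clamped gap `max(0, val - train)` between the class's validation and
#' train loss curves, in nats. It is 0 when the curves coincide (or
#' validation runs below train) and grows with the overfitting gap.
#' `normalize = "relative"` divides each epoch's gap by
#' `(train + epsilon)`, for label sets whose classes sit at very
#' different base-loss scales; note that near full convergence the
#' per-class train loss approaches zero and the relative score then
#' amplifies negligible absolute gaps, which is why the plain difference
#' between the curves is the default.
#'
#' @param history a `loss_history` with at least `window` epochs.
#' @param class a tracked class label.
#' @param window number of trailing epochs averaged (default 5).
#' @param normalize `"absolute"` (default) or `"relative"`.
#' @param epsilon division guard for the relative mode (default 1e-8).
#' @return a nonnegative score.
#' @export
divergence_score <- function(history, class, window = 5L,
                             normalize = c("absolute", "relative"),
                             epsilon = 1e-8) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(history, "loss_history"))
  if (!class %in% history$classes) {
    stop("unknown class: ", class, call. = FALSE)
  }
  if (length(history$epochs) < window) {
    stop("history has ", length(history$epochs),
         " epochs; window is ", window, call. = FALSE)
  }
  idx <- utils::tail(seq_along(history$epochs), window)
  tr <- history$train[idx, class]
  va <- history$val[idx, class]
  if (all(is.na(va))) {
    stop("class '", class, "' has no recorded validation losses",
         call. = FALSE)
  }
  ok <- !is.na(tr) & !is.na(va)
  gap <- pmax(0, va[ok] - tr[ok])
  if (normalize == "relative") gap <- gap / (tr[ok] + epsilon)
  mean(gap)
}

#' Flag badly converged classes for targeted augmentation
#'
#' @inheritParams divergence_score
#' @param threshold flagging threshold on the divergence score
#'   (default 0.5 nats under the default absolute score).
#' @param min_val_samples classes with fewer validation samples than this
#'   are never auto-flagged (their score is too unreliable); a warning
#'   directs the user to manual curve inspection. Default 3.
#' @return an object of class `divergence_report` with `per_class_score`,
#'   `threshold`, `window` and the `flagged` class set.
#' @export
flag_classes <- function(history, threshold = 0.5, window = 5L,
                         min_val_samples = 3L,
                         normalize = c("absolute", "relative")) {
  stopifnot(inherits(history, "loss_history"))
  normalize <- match.arg(normalize)
  scores <- vapply(history$classes, function(cl) {
    tryCatch(divergence_score(history, cl, window, normalize),
             error = function(e) NA_real_)
  }, numeric(1))
  unreliable <- history$classes[history$val_n < min_val_samples]
  candidates <- !is.na(scores) & scores > threshold
  suppressed <- intersect(history$classes[candidates], unreliable)
  if (length(suppressed)) {
    warning("class(es) with < ", min_val_samples,
            " validation samples not auto-flagged (inspect curves manually): ",
            paste(suppressed, collapse = ", "), call. = FALSE)
  }
  flagged <- setdiff(history$classes[candidates], unreliable)
  structure(
    list(per_class_score = scores, threshold = threshold,
         window = as.integer(window), flagged = flagged),
    class = "divergence_report"
  )
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report> threshold =", x$threshold,
      ", window =", x$window, "\n")
  cat("  flagged:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Plot train/validation loss curves
#'
#' Writes one PNG per requested class (train and validation curves
#' overlaid); the special selection `"global"` plots the dataset-level
#' curves.
#'
#' @param history a nonempty `loss_history`.
#' @param classes character vector of class labels and/or `"global"`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
plot_curves <- function(history, classes, out_dir) {
  stopifnot(inherits(history, "loss_history"))
  if (!length(history$epochs)) stop("loss history is empty", call. = FALSE)
  if (!length(classes)) {
    warning("no classes selected; nothing plotted", call. = FALSE)
    return(invisible(character()))
  }
  unknown <- setdiff(classes, c(history$classes, "global"))
  if (length(unknown)) {
    stop("unknown class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (cl in classes) {
    if (cl == "global") {
      df <- data.frame(
        epoch = rep(history$epochs, 2L),
        loss = c(history$global_train, history$global_val),
        split = rep(c("train", "validation"), each = length(history$epochs))
      )
      title <- "Global loss"
    } else {
      df <- data.frame(
        epoch = rep(history$epochs, 2L),
        loss = c(history$train[, cl], history$val[, cl]),
        split = rep(c("train", "validation"), each = length(history$epochs))
      )
      title <- paste("Loss curves:", cl)
    }
    p <- ggplot2::ggplot(df[!is.na(df$loss), ],
                         ggplot2::aes(x = .data$epoch, y = .data$loss,
                                      colour = .data$split)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = title, x = "epoch", y = "mean cross-entropy") +
      ggplot2::theme_minimal()
    file <- file.path(out_dir, paste0("loss_curves_",
                                      gsub("[^A-Za-z0-9_.-]", "_", cl), ".png"))
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 100)
    files <- c(files, file)
  }
  invisible(files)
}

#' Persist a loss history as a long-format CSV
#'
#' @param history a `loss_history`.
#' @param file output CSV path (`epoch,class,split,loss`).
#' @export
write_loss_history <- function(history, file) {
  stopifnot(inherits(history, "loss_history"))
  n_ep <- length(history$epochs)
  rows <- data.frame(
    epoch = rep(history$epochs, times = 2L * length(history$classes)),
    class = rep(rep(history$classes, each = n_ep), times = 2L),
    split = rep(c("train", "validation"),
                each = n_ep * length(history$classes)),
    loss = c(as.vector(history$train), as.vector(history$val))
  )
  utils::write.csv(rows[!is.na(rows$loss), ], file, row.names = FALSE)
  invisible(file)
}
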