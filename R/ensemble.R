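# Soft-voting ensemble and reported summaries.

#' Soft-vote two predictions
#'
#' Element-wise sum of the two per-class probability vectors; the winner is
#' the argmax of the sums, ties broken by the lowest class index.
#'
#' @param pred_transferred,pred_target Probability vectors of equal length
#'   `K` (or the `prediction` element of [classifier_forward()] with one
#'   column).
#' @return A `vote_result`: list with `scores` (length `K`), `winner`
#'   (class index), and the two `components`.
#' @export
soft_vote <- function(pred_transferred, pred_target) {
  getp <- function(p) {
    if (is.list(p)) p <- p$probabilities
    if (is.matrix(p)) p <- p[, 1L]
    as.numeric(p)
  }
  p1 <- getp(pred_transferred)
  p2 <- getp(pred_target)
  if (length(p1) != length(p2)) {
    abort_arg("predictions disagree on the number of classes K.")
  }
  s <- p1 + p2
  structure(list(scores = s, winner = which.max(s),
                 components = list(transferred = p1, target = p2)),
            class = "vote_result")
}

#' Evaluate one target subject with the transferred-plus-target ensemble
#'
#' For each test trial `x_T`: the source classifier scores the generated
#' image `G(x_T)`, the target classifier scores `x_T` itself, and the
#' soft vote of the two probability vectors decides. Also reports the two
#' single-path accuracies.
#'
#' @param generator Trained `ssstn_generator` (or an `ssstn_transfer`).
#' @param source_classifier,target_classifier Frozen classifiers
#'   (`ssstn_classifier` or `ssstn_pretrain`).
#' @param test_data A `scalogram_set` of trials never seen in training.
#' @return An `ssstn_eval`: list with `accuracy` (ensemble, percent),
#'   `source_path_accuracy` (source classifier on generated images),
#'   `target_path_accuracy`, `pre_transfer_accuracy` (source classifier on
#'   raw target images), and a per-trial `records` tibble.
#' @export
evaluate_subject <- function(generator, source_classifier,
                             target_classifier, test_data) {
  if (inherits(generator, "ssstn_transfer")) generator <- generator$generator
  asm <- function(x) if (inherits(x, "ssstn_pretrain")) x$model else x
  cs <- asm(source_classifier)
  ct <- asm(target_classifier)
  stopifnot(inherits(generator, "ssstn_generator"),
            inherits(cs, "ssstn_classifier"),
            inherits(ct, "ssstn_classifier"),
            inherits(test_data, "scalogram_set"))
  n <- dim(test_data$images)[1L]
  if (n < 1L) abort_arg("empty test set.", "test_data")
  labels <- test_data$labels
  gen_images <- generator_forward(generator, test_data, training = FALSE)
  p_src <- predict_proba(cs, gen_images)
  p_tgt <- predict_proba(ct, test_data)
  p_pre <- predict_proba(cs, test_data)
  vote <- p_src + p_tgt
  winner <- apply(vote, 2L, which.max)
  records <- tibble::tibble(
    trial = seq_len(n), label = labels,
    pred_source_path = apply(p_src, 2L, which.max),
    pred_target_path = apply(p_tgt, 2L, which.max),
    pred_vote = winner, correct = winner == labels)
  structure(list(
    accuracy = 100 * mean(winner == labels),
    source_path_accuracy = 100 * mean(records$pred_source_path == labels),
    target_path_accuracy = 100 * mean(records$pred_target_path == labels),
    pre_transfer_accuracy = 100 * mean(apply(p_pre, 2L, which.max) == labels),
    records = records, subject_id = test_data$subject_id),
    class = "ssstn_eval")
}

#' @export
#' @method print ssstn_eval
print.ssstn_eval <- function(x, ...) {
  cat(sprintf(
    "<ssstn_eval> subject %s: ensemble %.2f%% (source path %.2f%%, target path %.2f%%, pre-transfer %.2f%%)\n",
    x$subject_id, x$accuracy, x$source_path_accuracy,
    x$target_path_accuracy, x$pre_transfer_accuracy))
  invisible(x)
}

# Round half away from zero to `digits`, matching printed-table convention.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize per-subject accuracies, with optional baseline deltas
#'
#' @param table Data frame with `subject_id` and `accuracy` columns (one
#'   row per subject), or a list of `ssstn_pretrain`/`ssstn_eval` results.
#' @param baselines Optional second table with the same subjects; the
#'   report then includes `delta = accuracy - baseline` per subject,
#'   rounded half-up to 2 decimals.
#' @param threshold_pct Illiteracy threshold passed to
#'   [flag_illiterates()].
#' @return A list with `per_subject` (tibble), `mean` (arithmetic mean
#'   accuracy), `source_id`, and `illiterate_ids`.
#' @export
summarize_accuracy <- function(table, baselines = NULL,
                               threshold_pct = 70) {
  to_tab <- function(x) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (inherits(x, c("ssstn_pretrain", "ssstn_eval"))) x <- list(x)
    tibble::tibble(
      subject_id = vapply(x, function(r) as.character(r$subject_id),
                          character(1L)),
      accuracy = vapply(x, function(r) {
        if (inherits(r, "ssstn_eval")) r$accuracy else r$test_accuracy
      }, numeric(1L)))
  }
  tab <- to_tab(table)
  per <- tibble::tibble(subject_id = as.character(tab$subject_id),
                        accuracy = tab$accuracy)
  if (!is.null(baselines)) {
    bas <- to_tab(baselines)
    if (!identical(as.character(bas$subject_id), per$subject_id)) {
      abort_arg("baseline subject ids are not aligned with the table.")
    }
    per$baseline <- bas$accuracy
    per$delta <- round_half_up(per$accuracy - per$baseline, 2L)
  }
  list(per_subject = per, mean = mean(per$accuracy),
       source_id = if (nrow(per) >= 2L) select_source(per) else
         per$subject_id,
       illiterate_ids = flag_illiterates(per, threshold_pct))
}

#' Export per-trial intermediate features
#'
#' Flattens the post-SE feature map `h1` or `h2` of every trial into one
#' row — the table behind embedding visualizations of the transferred and
#' source feature spaces. Deterministic in evaluation mode.
#'
#' @param classifier An `ssstn_classifier` or `ssstn_pretrain`.
#' @param dataset A `scalogram_set`, or an `N x C x F x T` image array with
#'   a `labels` attribute supplied via `labels`.
#' @param layer 1 or 2: which feature block to export.
#' @param labels Optional label vector when `dataset` is a bare array.
#' @return A tibble: `trial`, `subject_id`, `label`, then `f1..fD` feature
#'   columns.
#' @export
export_features <- function(classifier, dataset, layer = 2L,
                            labels = NULL) {
  if (inherits(classifier, "ssstn_pretrain")) classifier <- classifier$model
  if (!layer %in% c(1L, 2L)) abort_arg("`layer` must be 1 or 2.", "layer")
  subject_id <- NA_character_
  if (inherits(dataset, "scalogram_set")) {
    labels <- dataset$labels
    subject_id <- dataset$subject_id
  }
  x <- as_image_batch(dataset, classifier$spec)
  N <- dim(x)[4L]
  taps <- collect_taps(classifier, x)
  h <- taps[[c("h1", "h2")[layer]]]
  D <- prod(dim(h)[1:3])
  feat <- t(matrix(h, D, N))
  colnames(feat) <- paste0("f", seq_len(D))
  out <- tibble::tibble(trial = seq_len(N), subject_id = subject_id,
                        label = labels %||% rep(NA_integer_, N))
  dplyr::bind_cols(out, tibble::as_tibble(feat))
}
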