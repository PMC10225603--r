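# Phase orchestration: per-subject pretraining, source/illiterate
# identification, and generator training against frozen classifiers.

# Round-robin interleave of shuffled per-class index lists, chunked into
# batches: every batch is approximately class-balanced.
balanced_batches <- function(labels, batch_size) {
  per_class <- split(seq_along(labels), labels)
  per_class <- lapply(per_class, function(ix) ix[sample.int(length(ix))])
  ord <- unlist(lapply(seq_len(max(lengths(per_class))), function(j) {
    unlist(lapply(per_class, function(ix) if (j <= length(ix)) ix[j] else NULL))
  }), use.names = FALSE)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# Evaluation-mode class probabilities, chunked to bound im2col memory.
predict_proba <- function(model, images, chunk = 64L) {
  x <- as_image_batch(images, model$spec)
  N <- dim(x)[4L]
  out <- matrix(0, model$spec$K, N)
  for (start in seq.int(1L, N, by = chunk)) {
    ix <- start:min(N, start + chunk - 1L)
    fwd <- net_forward(model$layers, x[, , , ix, drop = FALSE], FALSE)
    out[, ix] <- apply(fwd$out, 2L, softmax_vec)
  }
  out
}

accuracy_pct <- function(model, images, labels) {
  p <- predict_proba(model, images)
  100 * mean(apply(p, 2L, which.max) == labels)
}

#' Pretrain a subject-specific classifier
#'
#' Minimizes the cross-entropy classification loss with Adam on
#' class-balanced batches, on a stratified split of the subject's
#' scalograms. Deterministic given `seed`.
#'
#' @param scalograms A `scalogram_set` for one subject.
#' @param spec Optional [classifier_spec()]; inferred from the data when
#'   `NULL`.
#' @param lr Learning rate (published operating point: 2e-4).
#' @param n_epochs Training epochs (published: 3000; reduced-scale runs
#'   use far fewer).
#' @param batch_size Batch size.
#' @param holdout Fraction of trials held out (stratified) to measure test
#'   accuracy.
#' @param seed Integer seed for the split, initialization, batching and
#'   dropout.
#' @param validate If TRUE, first trains on 90% of the training portion to
#'   log a validation accuracy, then refits on the full training portion.
#' @return An `ssstn_pretrain` object: the trained `model`, `subject_id`,
#'   `train_accuracy` and `test_accuracy` (percent), the per-epoch
#'   `loss_table` tibble, and the split indices.
#' @export
pretrain_classifier <- function(scalograms, spec = NULL, lr = 2e-4,
                                n_epochs = 200L, batch_size = 32L,
                                holdout = 0.25, seed = 1L,
                                validate = FALSE) {
  stopifnot(inherits(scalograms, "scalogram_set"))
  labels <- scalograms$labels
  if (length(unique(labels)) < 2L) {
    abort_arg("dataset must contain at least 2 classes.", "scalograms")
  }
  n_epochs <- check_count(n_epochs, "n_epochs")
  check_number(holdout, "holdout", lower = 0, upper = 1, strict_upper = TRUE)
  d <- dim(scalograms$images)
  spec <- spec %||% classifier_spec(d[2L], d[3L], d[4L], K = scalograms$K)
  x_all <- as_image_batch(scalograms, spec)

  split_ix <- with_seed(derive_seed(seed, "split"), {
    test <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      ix[sample.int(length(ix), round(holdout * length(ix)))]
    }), use.names = FALSE)
    list(test = sort(test), train = setdiff(seq_along(labels), test))
  })
  tr <- split_ix$train
  te <- split_ix$test

  fit_on <- function(ix, tag) {
    model <- build_classifier(spec, seed = derive_seed(seed, "init"))
    state <- adam_init(model$layers)
    losses <- numeric(n_epochs)
    step <- 0L
    with_seed(derive_seed(seed, "train", tag), {
      for (ep in seq_len(n_epochs)) {
        batches <- balanced_batches(labels[ix], batch_size)
        ep_loss <- 0
        for (b in batches) {
          xb <- x_all[, , , ix[b], drop = FALSE]
          fwd <- net_forward(model$layers, xb, training = TRUE)
          model$layers <- apply_buffer_updates(model$layers, fwd$buffers)
          p <- apply(fwd$out, 2L, softmax_vec)
          if (is.null(dim(p))) p <- matrix(p, nrow = spec$K)
          ep_loss <- ep_loss + classification_loss(p, labels[ix[b]]) *
            length(b)
          dlogits <- ce_logit_grad(p, labels[ix[b]])
          bwd <- net_backward(model$layers, fwd, dlogits)
          step <- step + 1L
          upd <- adam_step(model$layers, bwd$grads, state, lr, step)
          model$layers <- upd$layers
          state <- upd$state
        }
        losses[ep] <- ep_loss / length(ix)
      }
    })
    list(model = model, losses = losses)
  }

  validation_accuracy <- NA_real_
  if (validate && length(tr) >= 10L) {
    val <- with_seed(derive_seed(seed, "val"), {
      unlist(lapply(split(tr, labels[tr]), function(ix) {
        ix[sample.int(length(ix), max(1L, round(0.1 * length(ix))))]
      }), use.names = FALSE)
    })
    fit_v <- fit_on(setdiff(tr, val), "val")
    validation_accuracy <- accuracy_pct(
      fit_v$model, aperm(x_all[, , , val, drop = FALSE], c(4L, 3L, 1L, 2L)),
      labels[val])
  }
  fit <- fit_on(tr, "full")
  model <- fit$model
  as_nctf <- function(ix) aperm(x_all[, , , ix, drop = FALSE],
                                c(4L, 3L, 1L, 2L))
  structure(list(
    model = model, subject_id = scalograms$subject_id,
    train_accuracy = accuracy_pct(model, as_nctf(tr), labels[tr]),
    test_accuracy = accuracy_pct(model, as_nctf(te), labels[te]),
    validation_accuracy = validation_accuracy,
    loss_table = tibble::tibble(epoch = seq_len(n_epochs),
                                loss = fit$losses),
    split = split_ix, seed = seed), class = "ssstn_pretrain")
}

#' @export
#' @method print ssstn_pretrain
print.ssstn_pretrain <- function(x, ...) {
  cat(sprintf(
    "<ssstn_pretrain> subject %s: train %.2f%%, test %.2f%% (%d epochs)\n",
    x$subject_id, x$train_accuracy, x$test_accuracy, nrow(x$loss_table)))
  invisible(x)
}

# Coerce pretraining results to a (subject_id, accuracy) tibble.
accuracy_table <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("subject_id", "accuracy") %in% names(results)))
    return(tibble::as_tibble(results))
  }
  if (inherits(results, "ssstn_pretrain")) results <- list(results)
  stopifnot(is.list(results), length(results) >= 1L)
  tibble::tibble(
    subject_id = vapply(results, function(r) as.character(r$subject_id),
                        character(1L)),
    accuracy = vapply(results, function(r) r$test_accuracy, numeric(1L)))
}

#' Select the source subject (the "BCI expert")
#'
#' The subject with the highest held-out classification accuracy serves as
#' the source whose classifier and feature space define the transfer
#' target. Ties are broken by the lowest subject position in the table.
#'
#' @param results List of `ssstn_pretrain` objects, or a data frame with
#'   `subject_id` and `accuracy` columns.
#' @return The winning `subject_id`.
#' @export
select_source <- function(results) {
  tab <- accuracy_table(results)
  if (nrow(tab) < 2L) abort_arg("need at least 2 pretraining results.")
  tab$subject_id[which.max(tab$accuracy)]
}

#' Flag BCI-illiterate subjects
#'
#' Subjects whose accuracy falls strictly below the threshold
#' (conventionally 70%) are flagged as BCI illiterate — the transfer
#' targets the method is designed for.
#'
#' @inheritParams select_source
#' @param threshold_pct Accuracy threshold in percent (default 70).
#' @return Character vector of flagged `subject_id`s (possibly empty).
#' @export
flag_illiterates <- function(results, threshold_pct = 70) {
  tab <- accuracy_table(results)
  tab$subject_id[tab$accuracy < threshold_pct]
}

#' Bundle the frozen classifiers and loss weights for a transfer
#'
#' @param source,target Pretrained classifiers (`ssstn_pretrain` or
#'   `ssstn_classifier`) for the source (expert) and target (illiterate)
#'   subjects. Both stay frozen during generator training — enforced by
#'   checksum.
#' @param weights A [loss_weights()].
#' @param seed Integer seed for generator training.
#' @return A `transfer_bundle` object.
#' @export
transfer_bundle <- function(source, target, weights = loss_weights(),
                            seed = 1L) {
  get_model <- function(x) {
    if (inherits(x, "ssstn_pretrain")) x$model
    else if (inherits(x, "ssstn_classifier")) x
    else abort_arg("source/target must be pretrained classifiers.")
  }
  cs <- get_model(source)
  ct <- get_model(target)
  if (!identical(cs$spec, ct$spec)) {
    abort_arg("source and target classifiers must share one architecture.")
  }
  structure(list(source_classifier = cs, target_classifier = ct,
                 weights = weights, seed = check_count(seed, "seed", 0L)),
            class = "transfer_bundle")
}

# Evaluation-mode taps (h1, h2 in H,W,Cf,N layout) plus probabilities,
# with caches discarded; chunked.
collect_taps <- function(model, x, chunk = 64L) {
  N <- dim(x)[4L]
  h1 <- h2 <- NULL
  probs <- matrix(0, model$spec$K, N)
  for (start in seq.int(1L, N, by = chunk)) {
    ix <- start:min(N, start + chunk - 1L)
    fwd <- net_forward(model$layers, x[, , , ix, drop = FALSE], FALSE)
    if (is.null(h1)) {
      d1 <- dim(fwd$taps$h1); d2 <- dim(fwd$taps$h2)
      h1 <- array(0, dim = c(d1[1:3], N))
      h2 <- array(0, dim = c(d2[1:3], N))
    }
    h1[, , , ix] <- fwd$taps$h1
    h2[, , , ix] <- fwd$taps$h2
    probs[, ix] <- apply(fwd$out, 2L, softmax_vec)
  }
  list(h1 = h1, h2 = h2, probs = probs)
}

# Per-sample softmaxed flattened Gram per layer, as columns.
gram_softmaxes <- function(taps) {
  lapply(taps[c("h1", "h2")], function(h) {
    d <- dim(h)
    M <- d[1L] * d[2L]
    vapply(seq_len(d[4L]), function(n) {
      softmax_vec(as.numeric(gram(t(matrix(h[, , , n], M, d[3L])))))
    }, numeric(d[3L]^2))
  })
}

#' Train the style-transfer generator against frozen classifiers
#'
#' Each step samples a class-balanced batch of target-subject scalograms,
#' pairs every trial with a same-class source trial (pairing resampled
#' every epoch), pushes the generated images through the frozen source
#' classifier, and minimizes
#' `alpha * style + beta_w * content + gamma * semantic` by Adam on the
#' generator parameters only. The classifiers' parameters are
#' checksum-verified to be bit-identical before and after.
#'
#' @param bundle A [transfer_bundle()].
#' @param target_data,source_data `scalogram_set`s of the target and source
#'   subjects' *training* trials (test-session images must never enter).
#' @param lr Learning rate (published operating point: 0.003).
#' @param n_epochs Training epochs (published: 600; reduced-scale runs use
#'   fewer).
#' @param batch_size Batch size.
#' @param gen_spec Optional [generator_spec()]; default derived from the
#'   image dimensions.
#' @param seed Integer seed; defaults to the bundle's.
#' @return An `ssstn_transfer` object: the trained `generator`, the
#'   per-epoch `loss_table` tibble (style, content, semantic, total), the
#'   frozen-classifier checksums, and the bundle.
#' @export
train_generator <- function(bundle, target_data, source_data, lr = 0.003,
                            n_epochs = 60L, batch_size = 32L,
                            gen_spec = NULL, seed = bundle$seed) {
  stopifnot(inherits(bundle, "transfer_bundle"),
            inherits(target_data, "scalogram_set"),
            inherits(source_data, "scalogram_set"))
  if (target_data$K != source_data$K) {
    abort_arg("target and source datasets disagree on K.")
  }
  if (!all(dim(target_data$images)[-1L] == dim(source_data$images)[-1L])) {
    abort_arg("target and source images have different dimensions.")
  }
  n_epochs <- check_count(n_epochs, "n_epochs")
  cs <- bundle$source_classifier
  ct <- bundle$target_classifier
  w <- bundle$weights
  sum_before_s <- object_checksum(lapply(cs$layers, `[[`, "params"))
  sum_before_t <- object_checksum(lapply(ct$layers, `[[`, "params"))

  xt <- as_image_batch(target_data, cs$spec)
  xs <- as_image_batch(source_data, cs$spec)
  t_labels <- target_data$labels
  s_labels <- source_data$labels
  s_by_class <- split(seq_along(s_labels), s_labels)
  if (!all(as.character(sort(unique(t_labels))) %in% names(s_by_class))) {
    abort_arg("source data lacks trials for some target class.")
  }

  # constants: target-classifier features on x_T, source Gram softmaxes
  tap_t <- collect_taps(ct, xt)
  q_src <- gram_softmaxes(collect_taps(cs, xs))

  d <- dim(xt)
  gen_spec <- gen_spec %||%
    generator_spec(cs$spec$channels, cs$spec$n_freqs, cs$spec$n_times)
  gen <- build_generator(gen_spec, seed = derive_seed(seed, "gen_init"))
  state <- adam_init(gen$layers)

  tap_dims <- list(h1 = dim(tap_t$h1)[1:3], h2 = dim(tap_t$h2)[1:3])
  loss_tab <- tibble::tibble(epoch = integer(), style = numeric(),
                             content = numeric(), semantic = numeric(),
                             total = numeric())
  step <- 0L
  with_seed(derive_seed(seed, "gen_train"), {
    # class-matched random pairing of target and source trials, drawn
    # once per run so the per-epoch loss is a stationary objective
    pair <- vapply(t_labels, function(k) {
      pool <- s_by_class[[as.character(k)]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1L))
    for (ep in seq_len(n_epochs)) {
      batches <- balanced_batches(t_labels, batch_size)
      ep_style <- ep_content <- ep_semantic <- 0
      n_seen <- 0L
      for (b in batches) {
        nb <- length(b)
        xb <- xt[, , , b, drop = FALSE]
        gfwd <- net_forward(gen$layers, xb, training = TRUE)
        gen$layers <- apply_buffer_updates(gen$layers, gfwd$buffers)
        cfwd <- net_forward(cs$layers, gfwd$out, training = FALSE)
        p <- apply(cfwd$out, 2L, softmax_vec)
        if (is.null(dim(p))) p <- matrix(p, nrow = cs$spec$K)

        l_sem <- classification_loss(p, t_labels[b])
        dlogits <- w$gamma * ce_logit_grad(p, t_labels[b])

        l_style <- 0
        l_content <- 0
        dtaps <- list()
        for (lname in c("h1", "h2")) {
          tap <- cfwd$taps[[lname]]
          dd <- dim(tap)
          M <- dd[1L] * dd[2L]
          tgt <- (if (lname == "h1") tap_t$h1 else
            tap_t$h2)[, , , b, drop = FALSE]
          per_el <- dd[3L] * M
          l_content <- l_content + sum((tgt - tap)^2) / per_el / nb
          dtap <- w$beta_w * 2 * (tap - tgt) / per_el / nb
          qs <- q_src[[lname]]
          for (jj in seq_len(nb)) {
            hmat <- t(matrix(tap[, , , jj], M, dd[3L]))
            qv <- qs[, pair[b[jj]]]
            pvec <- softmax_vec(as.numeric(gram(hmat)))
            l_style <- l_style +
              sum(pvec * (log(pmax(pvec, EPS_LOG)) -
                            log(pmax(qv, EPS_LOG))))
            dh <- style_grad_one(hmat, qv)              # Cf x M
            dtap[, , , jj] <- dtap[, , , jj] +
              w$alpha * array(t(dh), dim = dd[1:3])
          }
          dtaps[[lname]] <- dtap
        }
        tot <- w$alpha * l_style + w$beta_w * l_content + w$gamma * l_sem
        if (!is.finite(tot)) {
          rlang::abort(sprintf(
            "non-finite generator loss at epoch %d (style %g, content %g, semantic %g)",
            ep, l_style, l_content, l_sem), class = "ssstn_numeric_error")
        }
        cbwd <- net_backward(cs$layers, cfwd, dlogits, dtaps)
        gbwd <- net_backward(gen$layers, gfwd, cbwd$dx)
        step <- step + 1L
        upd <- adam_step(gen$layers, gbwd$grads, state, lr, step)
        gen$layers <- upd$layers
        state <- upd$state
        ep_style <- ep_style + l_style
        ep_content <- ep_content + l_content * nb
        ep_semantic <- ep_semantic + l_sem * nb
        n_seen <- n_seen + nb
      }
      loss_tab <- dplyr::bind_rows(loss_tab, tibble::tibble(
        epoch = ep, style = ep_style,
        content = ep_content / n_seen, semantic = ep_semantic / n_seen,
        total = w$alpha * ep_style + w$beta_w * ep_content / n_seen +
          w$gamma * ep_semantic / n_seen))
    }
  })

  sum_after_s <- object_checksum(lapply(cs$layers, `[[`, "params"))
  sum_after_t <- object_checksum(lapply(ct$layers, `[[`, "params"))
  if (!identical(sum_before_s, sum_after_s) ||
      !identical(sum_before_t, sum_after_t)) {
    rlang::abort("frozen classifier parameters changed during training",
                 class = "ssstn_freeze_error")
  }
  structure(list(generator = gen, loss_table = loss_tab, bundle = bundle,
                 checksums = list(source = sum_after_s, target = sum_after_t),
                 seed = seed, variant = "full"),
            class = "ssstn_transfer")
}

#' @export
#' @method print ssstn_transfer
print.ssstn_transfer <- function(x, ...) {
  n <- nrow(x$loss_table)
  cat(sprintf(
    "<ssstn_transfer> %s: %d epochs, total loss %.4f -> %.4f\n",
    x$variant, n, x$loss_table$total[1L], x$loss_table$total[n]))
  invisible(x)
}

#' Run an ablation variant of generator training
#'
#' Sets exactly one loss weight to zero and reruns the identical training
#' loop: `no_content` drops the content term, `no_style` the style term,
#' `no_semantic` the semantic term; `full` reproduces [train_generator()]
#' exactly at equal seed.
#'
#' @param variant One of `"full"`, `"no_content"`, `"no_style"`,
#'   `"no_semantic"`.
#' @inheritParams train_generator
#' @return An `ssstn_transfer` object with the variant recorded.
#' @export
run_ablation <- function(variant, bundle, target_data, source_data,
                         lr = 0.003, n_epochs = 60L, batch_size = 32L,
                         gen_spec = NULL, seed = bundle$seed) {
  variants <- c("full", "no_content", "no_style", "no_semantic")
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% variants) {
    abort_arg(sprintf("unknown variant; must be one of %s.",
                      paste(variants, collapse = ", ")), "variant")
  }
  w <- bundle$weights
  w2 <- switch(variant,
    full = w,
    no_content = loss_weights(w$alpha, 0, w$gamma),
    no_style = loss_weights(0, w$beta_w, w$gamma),
    no_semantic = loss_weights(w$alpha, w$beta_w, 0))
  bundle$weights <- w2
  out <- train_generator(bundle, target_data, source_data, lr = lr,
                         n_epochs = n_epochs, batch_size = batch_size,
                         gen_spec = gen_spec, seed = seed)
  out$variant <- variant
  out
}
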