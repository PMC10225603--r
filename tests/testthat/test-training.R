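# Training orchestration on cheap toy scalograms: descent, determinism,
# the frozen-classifier invariant, source selection and illiteracy
# flagging against the published benchmark rows.

test_that("pretraining descends, reports accuracies, and is deterministic", {
  sc <- toy_scalogram_set(n_per_class = 10L, seed = 51L)
  r1 <- pretrain_classifier(sc, n_epochs = 15L, batch_size = 8L, seed = 3L)
  expect_true(r1$test_accuracy >= 0 && r1$test_accuracy <= 100)
  expect_lt(r1$loss_table$loss[15L], r1$loss_table$loss[1L])
  r2 <- pretrain_classifier(sc, n_epochs = 15L, batch_size = 8L, seed = 3L)
  expect_identical(r1$loss_table, r2$loss_table)
  expect_identical(r1$model$layers, r2$model$layers)
  # easily separable toy images are learned
  expect_gte(r1$train_accuracy, 90)
  # single-class data is rejected
  one <- sc
  one$labels <- rep(1L, length(one$labels))
  expect_error(pretrain_classifier(one, n_epochs = 2L), "class")
})

test_that("source selection takes the accuracy argmax with low-index ties", {
  se_cnn_2a <- published_accuracies("iv2a", "SE-CNN")
  expect_equal(select_source(se_cnn_2a), "3")
  se_cnn_2b <- published_accuracies("iv2b", "SE-CNN")
  expect_equal(select_source(se_cnn_2b), "5")
  expect_equal(se_cnn_2b$accuracy[se_cnn_2b$subject_id == "5"], 95.83)
  tie <- tibble::tibble(subject_id = c("4", "7"), accuracy = c(80, 80))
  expect_equal(select_source(tie), "4")
  expect_error(select_source(tie[1L, ]), "2")
})

test_that("illiteracy flagging applies the strict 70% threshold", {
  # the published backbone rows: IV-2a has subjects 2, 5 and 6 below 70%,
  # IV-2b only subject 2
  expect_equal(flag_illiterates(published_accuracies("iv2a", "SE-CNN")),
               c("2", "5", "6"))
  expect_equal(flag_illiterates(published_accuracies("iv2b", "SE-CNN")),
               "2")
  high <- tibble::tibble(subject_id = c("1", "2"), accuracy = c(90, 71))
  expect_equal(flag_illiterates(high), character(0))
  edge <- tibble::tibble(subject_id = "1", accuracy = 70)
  expect_equal(flag_illiterates(edge), character(0))   # strictly below
})

test_that("generator training leaves the classifiers bit-identical", {
  tgt <- toy_scalogram_set(10L, seed = 52L, subject_id = "t", sep = 0.4)
  src <- toy_scalogram_set(10L, seed = 53L, subject_id = "s")
  spec <- classifier_spec(2L, 8L, 10L, K = 2L, conv_channels = c(4L, 8L))
  cs <- pretrain_classifier(src, spec = spec, n_epochs = 10L, seed = 1L)
  ct <- pretrain_classifier(tgt, spec = spec, n_epochs = 10L, seed = 2L)
  before_s <- ssstn:::object_checksum(lapply(cs$model$layers, `[[`, "params"))
  before_t <- ssstn:::object_checksum(lapply(ct$model$layers, `[[`, "params"))
  bundle <- transfer_bundle(cs, ct, seed = 9L)
  gspec <- generator_spec(2L, 8L, 10L, enc_channels = c(4L, 6L, 8L))
  tfr <- train_generator(bundle, tgt, src, n_epochs = 8L, batch_size = 8L,
                         gen_spec = gspec)
  expect_identical(tfr$checksums$source, before_s)
  expect_identical(tfr$checksums$target, before_t)
  expect_equal(nrow(tfr$loss_table), 8L)
  expect_true(all(is.finite(tfr$loss_table$total)))
  # per-epoch rows satisfy the weighted decomposition
  w <- bundle$weights
  expect_equal(tfr$loss_table$total,
               w$alpha * tfr$loss_table$style +
                 w$beta_w * tfr$loss_table$content +
                 w$gamma * tfr$loss_table$semantic,
               tolerance = 1e-9)
  # identical seed reproduces the loss table bit-wise
  tfr2 <- train_generator(bundle, tgt, src, n_epochs = 8L, batch_size = 8L,
                          gen_spec = gspec)
  expect_identical(tfr$loss_table, tfr2$loss_table)
})

test_that("ablation variants zero exactly one weight and full matches", {
  tgt <- toy_scalogram_set(6L, seed = 54L, subject_id = "t", sep = 0.4)
  src <- toy_scalogram_set(6L, seed = 55L, subject_id = "s")
  spec <- classifier_spec(2L, 8L, 10L, K = 2L, conv_channels = c(4L, 8L))
  cs <- pretrain_classifier(src, spec = spec, n_epochs = 6L, seed = 1L)
  ct <- pretrain_classifier(tgt, spec = spec, n_epochs = 6L, seed = 2L)
  bundle <- transfer_bundle(cs, ct, seed = 4L)
  gspec <- generator_spec(2L, 8L, 10L, enc_channels = c(4L, 6L, 8L))
  full <- run_ablation("full", bundle, tgt, src, n_epochs = 4L,
                       batch_size = 8L, gen_spec = gspec)
  direct <- train_generator(bundle, tgt, src, n_epochs = 4L,
                            batch_size = 8L, gen_spec = gspec)
  expect_identical(full$loss_table, direct$loss_table)
  for (v in c("no_content", "no_style", "no_semantic")) {
    r <- run_ablation(v, bundle, tgt, src, n_epochs = 2L, batch_size = 8L,
                      gen_spec = gspec)
    w <- r$bundle$weights
    zeroed <- c(no_style = w$alpha, no_content = w$beta_w,
                no_semantic = w$gamma)[v]
    expect_equal(unname(zeroed), 0)
    expect_equal(r$variant, v)
  }
  expect_error(run_ablation("no_everything", bundle, tgt, src), "variant")
})

test_that("tidiers expose pretraining and transfer results as tibbles", {
  sc <- toy_scalogram_set(6L, seed = 56L)
  r <- pretrain_classifier(sc, n_epochs = 4L, batch_size = 8L, seed = 1L)
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_equal(g$n_epochs, 4L)
  expect_equal(g$subject_id, "toy")
})
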