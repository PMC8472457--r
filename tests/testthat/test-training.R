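make_pair <- function(sc, n = 60, stage = "seg", seed = 1) {
  lab <- if (stage == "seg") sc$liver_mask else sc$tissue_mask
  list(cube = sc$cube, labels = label_subsample(lab, n, seed))
}

test_that("vertical concatenation stacks rows and records provenance", {
  co <- tiny_cohort()
  s1 <- co$subjects[[1]]$scenes[[1]]
  s2 <- co$subjects[[2]]$scenes[[2]]
  set <- concat_training_set(list(
    list(cube = s1$cube, labels = s1$liver_mask),
    list(cube = s2$cube, labels = s2$liver_mask)))
  expect_equal(dim(set$cube$reflectance), c(96, 48, 100))
  expect_equal(dim(set$labels), c(96, 48))
  expect_equal(provenance_of(set, 1)$subject, "S1")
  expect_equal(provenance_of(set, 60)$subject, "S2")
  expect_equal(provenance_of(set, 60)$timepoint, "isch30")
  expect_error(provenance_of(set, 200), class = "lhsi_input_error")
  # single scene stacks to itself
  one <- concat_training_set(list(list(cube = s1$cube,
                                       labels = s1$liver_mask)))
  expect_identical(one$cube$reflectance, s1$cube$reflectance)
  # width mismatch rejected
  odd <- make_scene(seed = 1, shape = c(48, 64))
  expect_error(concat_training_set(list(
    list(cube = s1$cube, labels = s1$liver_mask),
    list(cube = odd$cube, labels = odd$liver_mask))),
    class = "lhsi_validation_error")
})

test_that("inverse-median-frequency weights satisfy their identities", {
  bal <- label_mask(matrix(rep(c(1L, -1L), 50), 10))
  w <- compute_class_weights(bal)
  expect_equal(w$w_pos, 1); expect_equal(w$w_neg, 1)
  # worked case: f_pos = 1/4 -> w_pos = 2, w_neg = 2/3
  m <- label_mask(matrix(c(rep(1L, 25), rep(-1L, 75)), 10))
  w <- compute_class_weights(m)
  expect_equal(w$w_pos, 2)
  expect_equal(w$w_neg, 2 / 3)
  expect_equal(w$m, 0.5)
  # exact identity w+ f+ + w- f- = 1 on randomized masks (0s ignored)
  set.seed(31)
  for (i in 1:20) {
    lab <- label_mask(matrix(sample(c(-1L, 0L, 1L), 400, TRUE,
                                    prob = c(runif(1, .1, .6), .2,
                                             runif(1, .1, .6))), 20))
    w <- tryCatch(compute_class_weights(lab),
                  lhsi_degenerate_labels_error = function(e) NULL)
    if (is.null(w)) next
    expect_equal(w$w_pos * w$f_pos + w$w_neg * w$f_neg, 1)
  }
  expect_error(compute_class_weights(label_mask(matrix(1L, 4, 4))),
               class = "lhsi_degenerate_labels_error")
})

test_that("an epoch visits every labelled pixel exactly once, never label 0", {
  co <- tiny_cohort()
  sc <- co$subjects[[1]]$scenes[[1]]
  set <- concat_training_set(list(make_pair(sc, n = 50)))
  st <- init_epoch(set, seed = 9)
  seen <- matrix(0L, nrow(set$labels), ncol(set$labels))
  repeat {
    b <- sample_batch(set, st, 16)
    if (is.null(b)) break
    st <- b$state
    expect_true(all(b$y %in% c(-1L, 1L)))
    seen[b$centers] <- seen[b$centers] + 1L
  }
  expect_true(all(seen[unclass(set$labels) != 0L] == 1L))
  expect_true(all(seen[unclass(set$labels) == 0L] == 0L))
  # fixed seed reproduces the batch sequence
  s1 <- init_epoch(set, seed = 9); s2 <- init_epoch(set, seed = 9)
  b1 <- sample_batch(set, s1, 16); b2 <- sample_batch(set, s2, 16)
  expect_identical(b1$centers, b2$centers)
  expect_identical(b1$X, b2$X)
})

test_that("training reduces the loss on a separable toy problem", {
  co <- tiny_cohort()
  set <- concat_training_set(lapply(
    co$subjects[[1]]$scenes[1:2], make_pair, n = 60))
  m <- build_model(architecture_spec(), seed = 1)
  fit <- train(m, set, train_config(learning_rate = 0.1, batch_size = 64,
                                    epochs = 3, seed = 2))
  expect_lt(tail(fit$trace, 1), fit$trace[1])
  expect_lt(tail(fit$trace, 1), 0.4)
})

test_that("training is deterministic and inert at zero learning rate", {
  co <- tiny_cohort()
  set <- concat_training_set(list(make_pair(co$subjects[[1]]$scenes[[1]],
                                            n = 40)))
  m <- build_model(architecture_spec(), seed = 3)
  f0 <- train(m, set, train_config(learning_rate = 0, batch_size = 40,
                                   epochs = 1, seed = 5))
  expect_identical(f0$model$params, m$params)
  fa <- train(m, set, train_config(learning_rate = 0.05, batch_size = 40,
                                   epochs = 2, seed = 5))
  fb <- train(m, set, train_config(learning_rate = 0.05, batch_size = 40,
                                   epochs = 2, seed = 5))
  expect_identical(fa$model$params, fb$model$params)
  expect_false(identical(fa$model$params, m$params))
})

test_that("a huge learning rate raises a divergence error", {
  co <- tiny_cohort()
  set <- concat_training_set(list(make_pair(co$subjects[[1]]$scenes[[1]],
                                            n = 40)))
  m <- build_model(architecture_spec(), seed = 3)
  expect_error(
    train(m, set, train_config(learning_rate = 50, batch_size = 40,
                               epochs = 3, seed = 5)),
    class = "lhsi_divergence_error")
  expect_error(
    train(m, set, train_config(batch_size = 1e6)),
    class = "lhsi_parameter_error")
})

test_that("LOPOCV trains one model per subject with no leakage", {
  co <- tiny_cohort(n = 3, size = 48, seed = 17)
  res <- lopocv(co, "segmentation",
                train_config(learning_rate = 0.1, batch_size = 64,
                             epochs = 1, seed = 4),
                n_train_px = 30, n_eval_px = 40)
  expect_length(res$models, 3)
  for (i in 1:3) {
    f <- res$folds[[i]]
    expect_false(f$held_out %in% f$trained_on)
    expect_length(f$trained_on, 2)
    # pooled predictions for a subject come only from its own fold
    expect_true(all(res$pooled$subject %in% paste0("S", 1:3)))
  }
  expect_setequal(unique(res$pooled$subject), paste0("S", 1:3))
  expect_error(lopocv(structure(list(subjects = co$subjects[1],
                                     timepoints = co$timepoints),
                                class = "phantom_cohort"), "segmentation"),
               class = "lhsi_parameter_error")
})
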