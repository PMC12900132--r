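test_that("subject-dependent splits follow the 9/6 and 16/8 trial rules", {
  fs <- tiny_fs()   # 2 subjects x 1 session x 15 trials
  splits <- make_subject_dependent_splits(fs, "seed")
  expect_length(splits, 2L)
  for (sp in splits) {
    expect_setequal(unique(sp$source$trial_id), 1:9)
    expect_setequal(unique(sp$target$trial_id), 10:15)
    expect_identical(unique(sp$source$subject_id), unique(sp$target$subject_id))
  }
  fs24 <- synth_generate(synth_spec(n_subjects = 1L, n_trials_per_session = 24L,
                                    n_segments_per_trial = 2L, n_channels = 4L,
                                    n_classes = 4L, seed = 1L))$data
  splits_iv <- make_subject_dependent_splits(fs24, "seed_iv")
  expect_length(splits_iv, 1L)
  expect_setequal(unique(splits_iv[[1]]$source$trial_id), 1:16)
  expect_setequal(unique(splits_iv[[1]]$target$trial_id), 17:24)
  expect_error(make_subject_dependent_splits(fs, "seed_iv"), "trials")
})

test_that("LOSO splits partition subjects", {
  fs <- synth_generate(synth_spec(n_subjects = 4L, n_segments_per_trial = 2L,
                                  n_channels = 4L, seed = 2L))$data
  splits <- make_loso_splits(fs)
  expect_length(splits, 4L)
  for (sp in splits) {
    s_subj <- unique(sp$source$subject_id)
    t_subj <- unique(sp$target$subject_id)
    expect_length(t_subj, 1L)
    expect_length(intersect(s_subj, t_subj), 0L)
    expect_setequal(union(s_subj, t_subj), 1:4)
  }
  one <- fs_subset(fs, fs$subject_id == 1L)
  expect_error(make_loso_splits(one), "two subjects")
})

test_that("training is reproducible and fits a separable task", {
  gen <- synth_generate(tiny_spec(subject_shift = 0.2, class_separation = 2,
                                  trial_jitter = 0.1))
  sp <- make_loso_splits(gen$data)[[1]]
  cfg <- train_config(epochs = 10L, seed = 31L)
  f1 <- train_model(sp, cfg)
  f2 <- train_model(sp, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$extractor$params$adjacency,
               f2$model$extractor$params$adjacency)
  # well-separated classes with mild shift are decoded nearly perfectly
  expect_gt(tail(f1$history$target_accuracy, 1), 0.95)
  # losses stayed finite and the reversal strength ramped upward
  expect_true(all(is.finite(f1$history$total)))
  expect_true(all(diff(f1$history$coeff) >= 0))
})

test_that("the adversarial model reduces to a source-only classifier", {
  gen <- synth_generate(tiny_spec())
  sp <- make_loso_splits(gen$data)[[1]]
  base <- train_config(epochs = 4L, seed = 13L, use_domain = FALSE,
                       use_individual = FALSE, lambda_cluster = 0)
  reduced <- train_config(epochs = 4L, seed = 13L, use_domain = TRUE,
                          hi = 0, lo = 0,           # reversal forced to zero
                          use_individual = FALSE, lambda_cluster = 0)
  f_base <- train_model(sp, base)
  f_red <- train_model(sp, reduced)
  # extractor and classifier trajectories coincide step for step
  expect_equal(f_red$model$extractor$params$adjacency,
               f_base$model$extractor$params$adjacency, tolerance = 1e-12)
  expect_equal(f_red$model$classifier$w, f_base$model$classifier$w,
               tolerance = 1e-12)
  expect_equal(f_red$history$cls, f_base$history$cls, tolerance = 1e-12)
  expect_equal(f_red$history$target_accuracy, f_base$history$target_accuracy)
})

test_that("target emotion labels never influence training", {
  gen <- synth_generate(tiny_spec())
  sp <- make_loso_splits(gen$data)[[1]]
  sp_corrupt <- sp
  set.seed(99)
  sp_corrupt$target$labels <- sample(0:2, n_segments(sp$target), TRUE)
  cfg <- train_config(epochs = 3L, seed = 7L)
  f1 <- train_model(sp, cfg)
  f2 <- train_model(sp_corrupt, cfg)
  expect_identical(f1$model$classifier$w, f2$model$classifier$w)
  expect_identical(f1$model$extractor$params$adjacency,
                   f2$model$extractor$params$adjacency)
  expect_identical(f1$history$total, f2$history$total)
})

test_that("the individual branch disables itself for single-subject splits", {
  fs1 <- fs_subset(tiny_fs(), tiny_fs()$subject_id == 1L)
  sp <- make_subject_dependent_splits(fs1, "seed")[[1]]
  expect_message(
    fit <- train_model(sp, train_config(epochs = 2L, use_individual = TRUE,
                                        seed = 3L)),
    "disabled")
  expect_false(fit$model$use_individual)
  expect_true(all(fit$history$individual == 0))
})

test_that("evaluation metrics are definitionally consistent", {
  gen <- synth_generate(tiny_spec())
  sp <- make_loso_splits(gen$data)[[1]]
  fit <- train_model(sp, train_config(epochs = 3L, seed = 5L))
  ev <- evaluate_model(fit, sp$target)
  expect_equal(sum(ev$confusion), n_segments(sp$target))
  expect_equal(ev$per_class, diag(ev$confusion_norm))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_true(all(abs(rowSums(ev$confusion_norm) - 1) < 1e-12 |
                    rowSums(ev$confusion) == 0))
  # a perfect predictor gives the identity row-normalized matrix
  mock <- fit$model
  perfect <- sp$target
  pred <- predict_classes(mock, perfect)$class
  perfect$labels <- pred
  ev2 <- evaluate_model(mock, perfect)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$confusion_norm[rowSums(ev2$confusion) > 0, ],
               diag(3)[rowSums(ev2$confusion) > 0, ], ignore_attr = TRUE)
  expect_error(evaluate_model(fit, fs_subset(sp$target, integer(0))), "empty")
})

test_that("uniform random predictions score at chance on balanced classes", {
  set.seed(77)
  n <- 3000L
  labels <- sample(0:2, n, TRUE)
  pred <- sample(0:2, n, TRUE)
  acc <- mean(pred == labels)
  # binomial error around 1/3
  expect_lt(abs(acc - 1 / 3), 4 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("protocol summaries aggregate per-split accuracies exactly", {
  gen <- synth_generate(tiny_spec())
  cfg <- train_config(epochs = 2L, seed = 9L)
  out_dir <- withr::local_tempdir()
  summ <- run_protocol(gen$data, "loso", cfg, out_dir = out_dir)
  expect_length(summ$fits, 2L)
  expect_equal(nrow(summ$per_split), 2L)
  expect_equal(summ$mean, mean(summ$per_split$accuracy), tolerance = 1e-12)
  expect_equal(summ$sd, sd(summ$per_split$accuracy), tolerance = 1e-12)
  expect_true(file.exists(file.path(out_dir, "per_split_accuracy.csv")))
  expect_true(file.exists(file.path(out_dir, "adjacency_split01.csv")))
  adj <- utils::read.csv(file.path(out_dir, "adjacency_split01.csv"),
                         row.names = 1)
  expect_identical(dim(as.matrix(adj)), c(6L, 6L))
})
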