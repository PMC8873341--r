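test_that("freeze plans enforce contiguity and group names", {
  p <- freeze_plan("only-output")
  expect_equal(unname(p$flags), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(freeze_plan("last-two-dense")$flags),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_error(freeze_plan(flags = c(conv1 = TRUE, conv2 = FALSE,
                                     dense = TRUE, output = TRUE)),
               "contiguous")
  expect_error(freeze_plan(flags = c(a = TRUE, b = TRUE, c = TRUE,
                                     d = TRUE)),
               "named")
})

test_that("frozen groups are bitwise invariant through training", {
  ep <- tiny_epochs()
  base <- build_network(tiny_spec(), 5)
  for (preset in freeze_plan_presets()) {
    m <- apply_freeze(base, freeze_plan(preset))
    fit <- train_network(m, ep, epochs = 4, shuffle_seed = 3)
    for (g in c("conv1", "conv2", "dense", "output")) {
      before <- group_params(base, g)
      after <- group_params(fit$model, g)
      if (m$trainable[[g]]) {
        expect_false(identical(before, after),
                     info = paste(preset, g, "should train"))
      } else {
        expect_identical(before, after)
      }
    }
  }
})

test_that("an all-frozen model refuses to train", {
  m <- build_network(tiny_spec(), 5)
  m$trainable[] <- FALSE
  expect_error(train_network(m, tiny_epochs(), epochs = 2),
               "no trainable")
})

test_that("series-level folds never leak a series across the split", {
  eps <- tiny_cohort_epochs(2)
  ep <- eps[[1]]
  for (kind in c("holdout_70_30", "leave_one_out", "kfold")) {
    sc <- split_scheme(kind, k = 3, rng_seed = 2)
    folds <- make_folds(ep, sc)
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0)
      expect_length(intersect(unique(ep$series[f$train]),
                              unique(ep$series[f$test])), 0)
      expect_setequal(c(f$train, f$test), seq_along(ep$labels))
    }
  }
})

test_that("a single series per class cannot be held out", {
  sched <- build_schedule(sessions = 1, series_per_session = 3)
  hemo <- hemodynamic_forward(sched, clean_profile(2))
  ep <- segment_epochs(hemo, window_s = 10, step_s = 5)
  expect_error(make_folds(ep, split_scheme("holdout_70_30")),
               "too few series")
})

test_that("k beyond the series count falls back to leave-one-series-out", {
  ep <- tiny_cohort_epochs(1)[[1]]
  expect_message(folds <- make_folds(ep, split_scheme("kfold", k = 10)),
                 "leave-one-series-out")
  expect_length(folds, length(unique(ep$series)))
})

test_that("window-level folds partition examples", {
  ep <- tiny_cohort_epochs(1)[[1]]
  folds <- make_folds(ep, split_scheme("kfold", k = 4, unit = "window"))
  expect_length(folds, 4)
  expect_setequal(unlist(lapply(folds, `[[`, "test")),
                  seq_along(ep$labels))
})

test_that("pretraining is deterministic and learns above chance", {
  eps <- lapply(c(3, 4), function(s) tiny_epochs(seed = s))
  spec <- tiny_spec()
  a <- pretrain_source(eps, spec, epochs = 10, rng_seed = 9)
  b <- pretrain_source(eps, spec, epochs = 10, rng_seed = 9)
  expect_identical(a$params, b$params)
  expect_error(pretrain_source(list(), spec), "empty")
  # held-out subject from the same clean population: above-chance transfer
  held <- tiny_epochs(seed = 5)
  held <- normalize_examples(held, "zscore")
  acc <- mean(predict_classes(model_from_checkpoint(a), held) ==
                held$labels)
  n <- length(held$labels)
  # binomial test against chance at 1/3
  expect_lt(binom.test(round(acc * n), n, p = 1 / 3,
                       alternative = "greater")$p.value, 0.05)
})

test_that("zero-budget fine-tuning equals the pretrained model's accuracy", {
  eps <- lapply(c(3, 4), function(s) tiny_epochs(seed = s))
  ckpt <- pretrain_source(eps, tiny_spec(), epochs = 8, rng_seed = 9)
  target <- tiny_epochs(seed = 6)
  sc <- split_scheme("holdout_70_30", rng_seed = 4)
  a0 <- finetune_target(ckpt, freeze_plan("last-two-dense"), target, 0, sc)
  # manual reference: evaluate checkpoint on the held-out fold
  folds <- make_folds(target, sc)
  tr <- normalize_examples(subset_epochs(target, folds[[1]]$train),
                           "zscore")
  te <- normalize_examples(subset_epochs(target, folds[[1]]$test),
                           "zscore", stats = tr$norm_stats)
  ref <- 100 * mean(predict_classes(model_from_checkpoint(ckpt), te) ==
                      te$labels)
  expect_equal(a0, ref)
})

test_that("fine-tuning beats scratch on a clean subject at a small budget", {
  eps <- lapply(3:5, function(s) tiny_epochs(seed = s))
  spec <- tiny_spec()
  ckpt <- pretrain_source(eps, spec, epochs = 12, rng_seed = 2)
  target <- tiny_epochs(seed = 9)
  sc <- split_scheme("holdout_70_30", rng_seed = 1)
  ft <- finetune_target(ckpt, freeze_plan("last-two-dense"), target, 5, sc,
                        rng_seed = 3)
  st <- train_scratch(spec, target, 5, sc, rng_seed = 3)
  expect_gte(ft, st)
  expect_true(ft >= 0 && ft <= 100)
})

test_that("label-shuffled targets stay near chance", {
  eps <- lapply(3:4, function(s) tiny_epochs(seed = s))
  ckpt <- pretrain_source(eps, tiny_spec(), epochs = 8, rng_seed = 2)
  target <- tiny_epochs(seed = 6)
  # permute labels within series blocks so folds stay class-complete
  set.seed(99)
  target$labels <- factor(sample(as.character(target$labels)),
                          levels = levels(target$labels))
  acc <- finetune_target(ckpt, freeze_plan("last-two-dense"), target, 10,
                         split_scheme("holdout_70_30", rng_seed = 1),
                         rng_seed = 5)
  # null sd for the pooled test windows at p = 1/3
  n_test <- length(make_folds(target, split_scheme("holdout_70_30",
                                                   rng_seed = 1))[[1]]$test)
  sd_null <- 100 * sqrt((1 / 3) * (2 / 3) / n_test)
  expect_lt(abs(acc - 100 / 3), 3 * sd_null + 1e-9)
})

test_that("the sweep returns complete deterministic tables", {
  eps <- tiny_cohort_epochs(4, master_seed = 8)
  spec <- tiny_spec(n_channels = 8)
  run <- function() {
    epoch_budget_sweep(eps, spec, budgets = c(5, 10),
                       n_source = 2, n_control = 1, n_baseline = 1,
                       pretrain_epochs = 6, master_seed = 21)
  }
  a <- run()
  expect_s3_class(a$control, "accuracy_table")
  expect_equal(dim(a$control$values), c(1, 2))
  expect_equal(dim(a$baseline$values), c(1, 2))
  expect_true(all(a$control$values >= 0 & a$control$values <= 100))
  b <- run()
  expect_identical(a$control$values, b$control$values)
  expect_identical(a$baseline$values, b$baseline$values)
  expect_error(epoch_budget_sweep(eps[1:2], spec, n_source = 2,
                                  n_control = 1, n_baseline = 1),
               "at least 3|split")
})

test_that("the freezing ablation covers every preset and is deterministic", {
  eps <- tiny_cohort_epochs(3, master_seed = 12)
  spec <- tiny_spec(n_channels = 8)
  ckpt <- pretrain_source(eps[1:2], spec, epochs = 6, rng_seed = 4)
  ab1 <- freezing_ablation(ckpt, eps[3], budget = 4, rng_seed = 6)
  ab2 <- freezing_ablation(ckpt, eps[3], budget = 4, rng_seed = 6)
  expect_setequal(ab1$plan, freeze_plan_presets())
  expect_identical(ab1, ab2)
  expect_true(attr(ab1, "winner") %in% ab1$plan)
  expect_true(all(diff(ab1$mean_accuracy) <= 0))
})
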