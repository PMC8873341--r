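## Transfer-learning protocol: source pretraining, freezing-schedule
## fine-tuning, scratch baseline, cross-validation and the epoch-budget
## sweep that produces subject x budget accuracy tables.

#' Freezing plans for fine-tuning
#'
#' A freeze plan maps the four parameter groups to trainability flags. The
#' trainable pattern must be contiguous from the output backwards (the
#' ablation unfreezes one block further towards the input at each step).
#' Presets: `"only-output"`, `"last-two-dense"` (dense + output, the
#' best-performing plan in the original ablation), `"unfreeze-through-conv2"`
#' and `"unfreeze-through-conv1"` (everything trainable).
#'
#' @param preset Preset name, or `NULL` when `flags` is given.
#' @param flags Named logical vector over `conv1`, `conv2`, `dense`,
#'   `output`.
#' @return A `freeze_plan` object.
#' @export
freeze_plan <- function(preset = c("last-two-dense", "only-output",
                                   "unfreeze-through-conv2",
                                   "unfreeze-through-conv1"),
                        flags = NULL) {
  groups <- c("conv1", "conv2", "dense", "output")
  if (is.null(flags)) {
    preset <- match.arg(preset)
    flags <- switch(preset,
      "only-output" = c(FALSE, FALSE, FALSE, TRUE),
      "last-two-dense" = c(FALSE, FALSE, TRUE, TRUE),
      "unfreeze-through-conv2" = c(FALSE, TRUE, TRUE, TRUE),
      "unfreeze-through-conv1" = c(TRUE, TRUE, TRUE, TRUE))
    names(flags) <- groups
  } else {
    preset <- "custom"
    if (!setequal(names(flags), groups)) {
      stop("`flags` must be named over: ", paste(groups, collapse = ", "))
    }
    flags <- flags[groups]
  }
  # contiguity from the output backwards: once trainable, stays trainable
  if (is.unsorted(as.integer(flags))) {
    stop("trainable pattern must be contiguous from the output backwards")
  }
  structure(list(preset = preset, flags = flags), class = "freeze_plan")
}

#' All preset freezing plans, in ablation order
#' @export
freeze_plan_presets <- function() {
  c("only-output", "last-two-dense", "unfreeze-through-conv2",
    "unfreeze-through-conv1")
}

#' Apply a freeze plan to a model handle
#'
#' Frozen groups are skipped by the optimizer entirely, so their parameters
#' are bitwise unchanged by any subsequent training call.
#'
#' @param model An `fnirs_cnn`.
#' @param plan A [freeze_plan()].
#' @return The model with updated trainability flags.
#' @export
apply_freeze <- function(model, plan) {
  stopifnot(inherits(model, "fnirs_cnn"), inherits(plan, "freeze_plan"))
  if (!setequal(names(plan$flags), names(model$trainable))) {
    stop("plan groups do not match model groups")
  }
  model$trainable[names(plan$flags)] <- plan$flags
  model
}

#' Describe a cross-validation scheme
#'
#' The grouping unit defaults to the series (all windows of one series stay
#' on the same side of every split), which prevents adjacent overlapping
#' windows from leaking across folds. `kfold` with more folds than series
#' falls back to leave-one-series-out with a message; a `"window"` unit is
#' available to fold over individual windows instead.
#'
#' @param kind `"holdout_70_30"`, `"leave_one_out"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param unit `"series"` or `"window"`.
#' @param rng_seed Seed for the fold shuffle.
#' @return A `split_scheme` object.
#' @export
split_scheme <- function(kind = c("holdout_70_30", "leave_one_out", "kfold"),
                         k = 10, unit = c("series", "window"),
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  structure(list(kind = kind, k = stop_if_not_count(k, "k"),
                 unit = unit, rng_seed = as.integer(rng_seed)),
            class = "split_scheme")
}

#' Build fold index lists for an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param scheme A [split_scheme()].
#' @return List of folds, each `list(train =, test =)` of example indices.
#'   Series-level folds are stratified by class where applicable.
#' @export
make_folds <- function(epochs, scheme) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(scheme, "split_scheme"))
  n <- length(epochs$labels)
  if (scheme$unit == "window") {
    ord <- with_seed(scheme$rng_seed, sample.int(n))
    folds <- switch(scheme$kind,
      holdout_70_30 = {
        ntr <- round(0.7 * n)
        list(list(train = sort(ord[seq_len(ntr)]),
                  test = sort(ord[-seq_len(ntr)])))
      },
      leave_one_out = lapply(seq_len(n), function(i) {
        list(train = setdiff(seq_len(n), i), test = i)
      }),
      kfold = {
        k <- min(scheme$k, n)
        assign_ <- rep_len(seq_len(k), n)[order(ord)]
        lapply(seq_len(k), function(f) {
          list(train = which(assign_ != f), test = which(assign_ == f))
        })
      })
    return(folds)
  }

  ser <- epochs$series
  uniq <- unique(ser)
  ser_class <- vapply(uniq, function(s) {
    as.character(epochs$labels[ser == s][1])
  }, character(1))
  split_series <- function(test_series) {
    list(train = which(!(ser %in% test_series)),
         test = which(ser %in% test_series))
  }
  switch(scheme$kind,
    holdout_70_30 = {
      test_series <- with_seed(scheme$rng_seed, unlist(
        lapply(split(uniq, ser_class), function(g) {
          g <- g[sample.int(length(g))]
          ntr <- max(1, min(length(g) - 1, round(0.7 * length(g))))
          g[-seq_len(ntr)]
        })))
      if (length(test_series) == 0) {
        stop("too few series per class to hold out a test set")
      }
      list(split_series(test_series))
    },
    leave_one_out = lapply(uniq, function(s) split_series(s)),
    kfold = {
      k <- scheme$k
      if (k > length(uniq)) {
        message(sprintf(
          "k = %d exceeds the %d series; using leave-one-series-out",
          k, length(uniq)))
        k <- length(uniq)
      }
      assign_ <- integer(length(uniq))
      with_seed(scheme$rng_seed, {
        for (g in split(seq_along(uniq), ser_class)) {
          assign_[g[sample.int(length(g))]] <- rep_len(seq_len(k), length(g))
        }
      })
      lapply(seq_len(k), function(f) split_series(uniq[assign_ == f]))
    })
}

#' Assert that no series leaks between the sides of any fold
#' @noRd
assert_no_leakage <- function(epochs, folds) {
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0) {
      stop("train and test example sets overlap")
    }
    common <- intersect(unique(epochs$series[f$train]),
                        unique(epochs$series[f$test]))
    if (length(common) > 0) {
      stop("series ", paste(common, collapse = ", "),
           " appear on both sides of a fold")
    }
  }
  invisible(TRUE)
}

#' Pretrain the network on pooled source subjects
#'
#' Pools the source subjects' epochs, z-scores them on their own
#' statistics, and trains a freshly initialized network. The returned
#' checkpoint carries the learned parameters, the spec and the per-epoch
#' training loss.
#'
#' @param source_sets Non-empty list of `epoch_set`s (the source subjects).
#' @param spec A [cnn_spec()].
#' @param epochs Pretraining epochs.
#' @param lr,batch_size Adam settings.
#' @param rng_seed Seed for initialization and batch order.
#' @return A `cnn_checkpoint`.
#' @export
pretrain_source <- function(source_sets, spec, epochs = 30,
                            lr = 1e-3, batch_size = 32, rng_seed = 1L) {
  if (length(source_sets) < 1) stop("source subset is empty")
  pooled <- bind_epoch_sets(source_sets)
  pooled <- normalize_examples(pooled, "zscore")
  model <- build_network(spec, rng_seed = derive_seed(rng_seed, 11))
  fit <- train_network(model, pooled, epochs = epochs, lr = lr,
                       batch_size = batch_size,
                       shuffle_seed = derive_seed(rng_seed, 12))
  structure(list(params = fit$model$params, spec = spec,
                 loss = fit$loss, epochs = epochs,
                 rng_seed = as.integer(rng_seed)),
            class = "cnn_checkpoint")
}

#' Restore a model handle from a checkpoint
#' @param checkpoint A `cnn_checkpoint`.
#' @export
model_from_checkpoint <- function(checkpoint) {
  model <- build_network(checkpoint$spec, rng_seed = 1L)
  model$params <- checkpoint$params
  model
}

## Shared fold-evaluation core: trains one model per fold up to
## max(budgets), records pooled test predictions at every budget, and
## returns the micro-averaged accuracy per budget.
eval_protocol <- function(target, budgets, split, model_factory,
                          lr = 1e-3, batch_size = 32, rng_seed = 1L) {
  budgets <- sort(unique(as.integer(budgets)))
  folds <- make_folds(target, split)
  assert_no_leakage(target, folds)
  pooled_ok <- stats::setNames(numeric(length(budgets)),
                               budgets)
  pooled_n <- 0
  correct <- matrix(0, nrow = length(budgets), ncol = 1)
  total <- 0
  skipped <- 0
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    tr <- subset_epochs(target, f$train)
    te <- subset_epochs(target, f$test)
    if (nlevels(droplevels(tr$labels)) < nlevels(target$labels)) {
      warning(sprintf("fold %d misses a class in training data; skipped", fi))
      skipped <- skipped + 1
      next
    }
    tr <- normalize_examples(tr, "zscore")
    te <- normalize_examples(te, "zscore", stats = tr$norm_stats)
    model <- model_factory(derive_seed(rng_seed, fi, 1))
    fit <- train_network(model, tr, epochs = max(budgets),
                         test = te, record_at = budgets,
                         lr = lr, batch_size = batch_size,
                         shuffle_seed = derive_seed(rng_seed, fi, 2))
    for (bi in seq_along(budgets)) {
      correct[bi, 1] <- correct[bi, 1] +
        sum(fit$test_pred[[bi]] == te$labels)
    }
    total <- total + length(te$labels)
  }
  if (total == 0) stop("every fold was skipped; no accuracy to report")
  acc <- 100 * correct[, 1] / total
  names(acc) <- budgets
  attr(acc, "n_test") <- total
  attr(acc, "skipped_folds") <- skipped
  acc
}

#' Fine-tune a pretrained network on one target subject
#'
#' Starts from the checkpoint parameters, applies the freeze plan, trains
#' for `budget` epochs on each fold's training windows and reports the
#' micro-averaged accuracy (percent of correct predictions pooled over the
#' folds' test windows). Folds whose training side misses a class are
#' skipped with a warning. `budget = 0` evaluates the pretrained model
#' as-is.
#'
#' @param checkpoint A [pretrain_source()] checkpoint.
#' @param plan A [freeze_plan()].
#' @param target An `epoch_set` of the target subject.
#' @param budget Training epochs (the epoch budget).
#' @param split A [split_scheme()].
#' @param lr,batch_size Adam settings.
#' @param rng_seed Seed for fold training.
#' @return Accuracy percent in `[0, 100]`.
#' @export
finetune_target <- function(checkpoint, plan, target, budget,
                            split = split_scheme("holdout_70_30"),
                            lr = 1e-3, batch_size = 32, rng_seed = 1L) {
  stopifnot(inherits(checkpoint, "cnn_checkpoint"))
  factory <- function(seed) {
    apply_freeze(model_from_checkpoint(checkpoint), plan)
  }
  if (budget == 0) {
    return(evaluate_checkpoint(checkpoint, target, split))
  }
  acc <- eval_protocol(target, budget, split, factory,
                       lr = lr, batch_size = batch_size, rng_seed = rng_seed)
  acc[[as.character(budget)]]
}

#' Evaluate a checkpoint on a target subject without training
#' @noRd
evaluate_checkpoint <- function(checkpoint, target, split) {
  folds <- make_folds(target, split)
  assert_no_leakage(target, folds)
  model <- model_from_checkpoint(checkpoint)
  correct <- 0; total <- 0
  for (f in folds) {
    tr <- normalize_examples(subset_epochs(target, f$train), "zscore")
    te <- normalize_examples(subset_epochs(target, f$test), "zscore",
                             stats = tr$norm_stats)
    correct <- correct + sum(predict_classes(model, te) == te$labels)
    total <- total + length(te$labels)
  }
  100 * correct / total
}

#' Train a randomly initialized network on one target subject
#'
#' The scratch baseline: identical protocol to [finetune_target()] but from
#' fresh initialization with every group trainable.
#'
#' @param spec A [cnn_spec()].
#' @inheritParams finetune_target
#' @return Accuracy percent in `[0, 100]`.
#' @export
train_scratch <- function(spec, target, budget,
                          split = split_scheme("holdout_70_30"),
                          lr = 1e-3, batch_size = 32, rng_seed = 1L) {
  factory <- function(seed) build_network(spec, rng_seed = seed)
  acc <- eval_protocol(target, budget, split, factory,
                       lr = lr, batch_size = batch_size, rng_seed = rng_seed)
  acc[[as.character(budget)]]
}

#' Subject x epoch-budget accuracy tables for both groups
#'
#' Runs the full study protocol on a cohort's epoch sets: the first
#' `n_source` subjects pretrain the network; of the remaining subjects, the
#' control group is fine-tuned from the checkpoint (under `plan`) and the
#' baseline group is trained from random initialization. Every target
#' subject is trained once per group membership up to `max(budgets)` with
#' accuracy recorded at each budget checkpoint, yielding one learning curve
#' per table row. Cell seeds derive deterministically from `master_seed`,
#' subject and group.
#'
#' @param epoch_sets List of `epoch_set`s, one per subject, in cohort order.
#' @param spec A [cnn_spec()].
#' @param budgets Epoch budgets (columns of the tables).
#' @param n_source,n_control,n_baseline Subject partition sizes (defaults
#'   16/5/5 for a 26-subject cohort). `assignment = "both"` instead
#'   evaluates every non-source subject under both protocols.
#' @param assignment `"disjoint"` or `"both"`.
#' @param plan Freeze plan for the control group.
#' @param split Within-subject evaluation split.
#' @param pretrain_epochs Source pretraining budget.
#' @param lr,batch_size Adam settings.
#' @param master_seed Master seed for the whole sweep.
#' @return List with `control` and `baseline` [accuracy_table()]s, the
#'   pretraining checkpoint and the subject assignment.
#' @export
epoch_budget_sweep <- function(epoch_sets, spec,
                               budgets = seq(10, 60, by = 10),
                               n_source = 16, n_control = 5, n_baseline = 5,
                               assignment = c("disjoint", "both"),
                               plan = freeze_plan("last-two-dense"),
                               split = split_scheme("holdout_70_30"),
                               pretrain_epochs = 30,
                               lr = 1e-3, batch_size = 32,
                               master_seed = 1L) {
  assignment <- match.arg(assignment)
  n <- length(epoch_sets)
  if (n < 3) stop("cohort must contain at least 3 subjects")
  if (assignment == "disjoint" && n < n_source + n_control + n_baseline) {
    stop(sprintf("cohort of %d cannot be split %d/%d/%d",
                 n, n_source, n_control, n_baseline))
  }
  budgets <- sort(unique(as.integer(budgets)))
  source_idx <- seq_len(n_source)
  if (assignment == "disjoint") {
    control_idx <- n_source + seq_len(n_control)
    baseline_idx <- n_source + n_control + seq_len(n_baseline)
  } else {
    control_idx <- baseline_idx <- setdiff(seq_len(n), source_idx)
  }
  if (length(control_idx) == 0 || length(baseline_idx) == 0) {
    stop("control and baseline groups must be non-empty")
  }

  checkpoint <- pretrain_source(epoch_sets[source_idx], spec,
                                epochs = pretrain_epochs, lr = lr,
                                batch_size = batch_size,
                                rng_seed = derive_seed(master_seed, 101))

  run_group <- function(idx, group_code, factory_for) {
    t(vapply(seq_along(idx), function(j) {
      si <- idx[j]
      seed <- derive_seed(master_seed, si, group_code)
      sc <- split
      sc$rng_seed <- derive_seed(seed, 3)
      eval_protocol(epoch_sets[[si]], budgets, sc, factory_for(seed),
                    lr = lr, batch_size = batch_size, rng_seed = seed)
    }, numeric(length(budgets))))
  }
  control_mat <- run_group(control_idx, 1L, function(seed) {
    function(s) apply_freeze(model_from_checkpoint(checkpoint), plan)
  })
  baseline_mat <- run_group(baseline_idx, 2L, function(seed) {
    function(s) build_network(spec, rng_seed = s)
  })

  ids_of <- function(idx) vapply(epoch_sets[idx],
                                 function(e) as.character(e$subject_id[1]),
                                 character(1))
  control <- accuracy_table(control_mat, subjects = ids_of(control_idx),
                            budgets = budgets, group = "control")
  baseline <- accuracy_table(baseline_mat, subjects = ids_of(baseline_idx),
                             budgets = budgets, group = "baseline")

  cm <- column_means(control, rounded = FALSE)
  if (length(cm) > 1 && any(diff(cm) < -1)) {
    warning(sprintf(
      "control accuracy drops after budget %s; likely past the overfitting point",
      names(cm)[which(diff(cm) < -1)[1]]))
  }
  list(control = control, baseline = baseline,
       checkpoint = checkpoint,
       assignment = list(source = source_idx, control = control_idx,
                         baseline = baseline_idx, mode = assignment),
       budgets = budgets, master_seed = as.integer(master_seed))
}

#' Freezing-schedule ablation
#'
#' Fine-tunes the checkpoint on each target subject under every preset
#' freeze plan at a fixed budget and ranks the plans by mean accuracy.
#'
#' @param checkpoint A [pretrain_source()] checkpoint.
#' @param targets Non-empty list of target `epoch_set`s.
#' @param budget Fine-tuning epoch budget.
#' @param split Evaluation split.
#' @param lr,batch_size Adam settings.
#' @param rng_seed Master seed.
#' @return Data frame (one row per plan, ranked by mean accuracy) with a
#'   `winner` attribute.
#' @export
freezing_ablation <- function(checkpoint, targets, budget = 30,
                              split = split_scheme("holdout_70_30"),
                              lr = 1e-3, batch_size = 32, rng_seed = 1L) {
  if (length(targets) < 1) stop("at least one target subject is required")
  plans <- freeze_plan_presets()
  means <- vapply(seq_along(plans), function(pi) {
    plan <- freeze_plan(plans[pi])
    mean(vapply(seq_along(targets), function(ti) {
      finetune_target(checkpoint, plan, targets[[ti]], budget, split,
                      lr = lr, batch_size = batch_size,
                      rng_seed = derive_seed(rng_seed, pi, ti))
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(plan = plans, mean_accuracy = means)
  out <- out[order(-out$mean_accuracy), ]
  rownames(out) <- NULL
  attr(out, "winner") <- out$plan[1]
  out
}
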