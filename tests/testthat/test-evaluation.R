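test_that("cross-entropy matches its closed forms", {
  expect_identical(cross_entropy(c(1, 0), 1), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(rep(1 / 8, 8), 3), log(8), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0, 1), 1), -log(1e-12))  # clamp
  expect_error(cross_entropy(c(0.5, 0.5), 3), "invalid class")
})

test_that("metrics match a hand-counted confusion matrix", {
  m <- compute_metrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, mean(c(1, 2 / 3)))   # macro
  expect_equal(m$recall, mean(c(0.5, 1)))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_identical(as.integer(m$confusion), c(1L, 0L, 1L, 2L))
  perfect <- compute_metrics(c("x", "y"), c("x", "y"))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall, perfect$f1),
               rep(1, 4))
  expect_error(compute_metrics(character(0), character(0)), "non-empty")
})

test_that("metrics agree with an independent brute-force tally", {
  classes <- c("a", "b", "c", "d")
  for (i in 1:200) {
    n <- withr::with_seed(i, sample(3:40, 1))
    truth <- withr::with_seed(i + 1, sample(classes, n, replace = TRUE))
    preds <- withr::with_seed(i + 2, sample(classes, n, replace = TRUE))
    m <- compute_metrics(preds, truth, class_names = classes)
    # brute force, loop per class
    prec <- rec <- numeric(4)
    for (k in seq_along(classes)) {
      cl <- classes[k]
      tp <- sum(preds == cl & truth == cl)
      prec[k] <- if (sum(preds == cl) > 0) tp / sum(preds == cl) else 0
      rec[k] <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    }
    expect_equal(m$accuracy, mean(preds == truth), tolerance = 1e-10)
    expect_equal(m$precision, mean(prec), tolerance = 1e-10)
    expect_equal(m$recall, mean(rec), tolerance = 1e-10)
    # confusion row sums = per-class truth counts
    expect_identical(as.integer(rowSums(m$confusion)),
                     as.integer(table(factor(truth, classes))))
    # micro averaging collapses to accuracy
    mi <- compute_metrics(preds, truth, "micro", class_names = classes)
    expect_equal(mi$precision, mi$accuracy)
    expect_equal(mi$recall, mi$accuracy)
  }
})

test_that("fold assignment is balanced, stratified and deterministic", {
  set <- random_event_set(10L, seed = 21, labels = "only")
  f <- kfold(set, 5L, seed = 1)
  expect_identical(as.integer(table(f)), rep(2L, 5))
  set2 <- abeta_set(n_per_class = 10L, seed = 23)
  f2 <- kfold(set2, 5L, seed = 2)
  labs <- vapply(set2$events, `[[`, "", "label")
  for (cl in unique(labs))
    expect_identical(as.integer(table(f2[labs == cl])), rep(2L, 5))
  expect_identical(kfold(set2, 5L, seed = 2), f2)
  expect_error(kfold(abeta_set(n_per_class = 3L), 5L), "fewer than k")
})

test_that("2-fold CV on separable peptide classes is accurate and accounted", {
  defs <- c(big = paste(rep("W", 20), collapse = ""),
            small = paste(rep("G", 20), collapse = ""))
  ds <- generate_dataset("peptide", 10L,
                         params = peptide_sim_params(sequence = defs[["big"]],
                                                     noise_sd = 0.01,
                                                     out_len = 60L),
                         class_defs = defs, seed = 25)
  pp <- preprocess_events(ds, 60L, standardize = "none")
  cv <- run_cv(pp, k = 2L, mcfg = tiny_mcfg(),
               tcfg = train_config(epochs_pretrain = 3L, epochs_finetune = 30L,
                                   batch_size = 8L, seed = 6L),
               variant = "pretrained", seed = 3L)
  expect_gt(cv$mean[["accuracy"]], 0.9)
  expect_identical(sum(cv$folds$n), length(pp))
  expect_equal(cv$mean[["accuracy"]], mean(cv$folds$accuracy))
})

test_that("experiment tables carry the full factorial design", {
  defs <- c(big = paste(rep("W", 12), collapse = ""),
            small = paste(rep("G", 12), collapse = ""))
  ds <- generate_dataset("peptide", 12L,
                         params = peptide_sim_params(sequence = defs[["big"]],
                                                     noise_sd = 0.05,
                                                     out_len = 36L),
                         class_defs = defs, seed = 27)
  pp <- preprocess_events(ds, 36L, standardize = "zscore")
  tcfg <- train_config(epochs_pretrain = 2L, epochs_finetune = 2L,
                       batch_size = 8L, seed = 7L)
  tab <- scarcity_experiment(pp, fractions = c(0.5, 1.0),
                             variants = c("pretrained", "scratch"),
                             seeds = 1:2, mcfg = tiny_mcfg(), tcfg = tcfg)
  expect_identical(nrow(tab), 2L * 2L * 2L)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$fold == 1L))
  # a fraction too small to keep both classes errors out
  expect_error(scarcity_experiment(pp, fractions = 0.01,
                                   variants = "scratch", seeds = 1,
                                   mcfg = tiny_mcfg(), tcfg = tcfg),
               "empty")
  sweep_tab <- mask_ratio_sweep(pp, ratios = c(0.15, 0.9), seeds = 1L,
                                mcfg = tiny_mcfg(), tcfg = tcfg)
  expect_identical(nrow(sweep_tab), 2L)
  expect_true(all(is.finite(sweep_tab$accuracy)))
})

test_that("embedding export is deterministic and dimensioned to d", {
  set <- abeta_set(n_per_class = 3L, seed = 29)
  mcfg <- tiny_mcfg()
  emb <- export_embeddings(set, stage = "random_init", mcfg = mcfg, seed = 4L)
  expect_identical(ncol(emb), 2L + mcfg$d)
  expect_identical(emb,
                   export_embeddings(set, stage = "random_init", mcfg = mcfg,
                                     seed = 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  tcfg <- train_config(epochs_pretrain = 1L, epochs_finetune = 1L,
                       batch_size = 4L, seed = 8L)
  ck <- finetune(set, mcfg, tcfg)
  export_embeddings(set, ck, stage = "finetuned", path = path)
  lines <- readLines(path)
  expect_match(lines[1], "^# stage=finetuned")
  expect_identical(length(lines), 2L + length(set))
})
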