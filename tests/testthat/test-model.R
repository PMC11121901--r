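desk_model <- function(init_seed = 0L, dropout_rate = 0.1) {
  classifier_model(toy_encoder(d_model = 16L, hash_size = 256L, seed = 42L),
                   model_config(dropout_rate = dropout_rate),
                   init_seed = init_seed)
}

test_that("forward yields a probability vector summing to one", {
  m <- desk_model()
  withr::with_seed(3, {
    for (i in 1:25) {
      txt <- paste(sample(letters, sample(1:40, 1), replace = TRUE),
                   collapse = " ")
      p <- forward(m, txt)
      expect_length(p, 3)
      expect_true(all(p > 0 & p < 1))
      expect_equal(sum(p), 1, tolerance = 1e-6)
    }
  })
})

test_that("zero projection weights give the uniform distribution", {
  m <- desk_model()
  m$params$W2[] <- 0
  m$params$b2[] <- 0
  p <- forward(m, "any text at all")
  expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("evaluation-mode forward is deterministic", {
  m <- desk_model()
  expect_identical(forward(m, "reproducible input string"),
                   forward(m, "reproducible input string"))
})

test_that("zero-token texts error; overlong texts truncate with a notice", {
  m <- desk_model()
  expect_error(forward(m, "   "), "zero tokens")
  m$config$max_tokens <- 4L
  long <- paste(rep("tok", 10), collapse = " ")
  expect_message(forward(m, long), "truncated")
})

test_that("predict_batch takes the argmax, breaking ties toward RARE", {
  m <- desk_model()
  expect_equal(nrow(predict_batch(m, character())), 0)
  probs <- rbind(c(0.2, 0.5, 0.3))
  expect_equal(which.max(probs), 2)  # argmax convention under test below
  preds <- predict_batch(m, c("alpha beta", "gamma delta"))
  expect_equal(nrow(preds), 2)
  picked <- apply(as.matrix(preds[, c("p_RARE", "p_NON_RARE", "p_OTHER")]),
                  1, which.max)
  expect_equal(as.integer(preds$.pred), picked)
  # exact tie resolves to the lowest class index (RARE)
  m0 <- desk_model()
  m0$params$W2[] <- 0
  m0$params$b2[] <- 0
  expect_equal(as.character(predict_batch(m0, "tie")$.pred), "RARE")
})

test_that("predict_batch continues past per-item failures", {
  m <- desk_model()
  expect_warning(preds <- predict_batch(m, c("fine text", "   ")),
                 "prediction failed")
  expect_equal(nrow(preds), 2)
  expect_false(is.na(preds$.pred[1]))
  expect_true(is.na(preds$.pred[2]))
})

test_that("training traces are reproducible and select the argmax epoch", {
  fx <- fixture_suite()
  corpus <- make_labeled_corpus(fx$spec, n_per_class = 40L)
  ds <- sample_balanced(corpus, sampling_plan(30, 20, 5, 5, seed = 2))
  train <- ds[ds$split == "train", ]
  val <- ds[ds$split == "val", ]
  tc <- train_config(batch_size = 16, learning_rate = 0.01,
                     max_epochs = 3, seed = 4)
  m1 <- train_classifier(desk_model(), train, val, tc)
  m2 <- train_classifier(desk_model(), train, val, tc)
  expect_identical(m1$trace, m2$trace)
  expect_equal(nrow(m1$trace), 3)
  # selected checkpoint is the earliest argmax of the reported trace
  best <- which(m1$trace$val_micro_f1_excl_bg ==
                  max(m1$trace$val_micro_f1_excl_bg))[1]
  expect_equal(m1$best_epoch, best)

  one <- train_classifier(desk_model(), train, val,
                          train_config(16, 0.01, 1, seed = 4))
  expect_equal(nrow(one$trace), 1)
  expect_equal(one$best_epoch, 1)
})

test_that("the head can memorize 32 examples (capacity check)", {
  fx <- fixture_suite()
  corpus <- make_labeled_corpus(fx$spec, n_per_class = 11L)[1:32, ]
  tc <- train_config(batch_size = 8, learning_rate = 0.05,
                     max_epochs = 120, seed = 6)
  m <- train_classifier(desk_model(dropout_rate = 0), corpus, corpus, tc)
  # loss on the memorized set at the end of training is near zero
  expect_lt(min(m$trace$loss), 0.05)
})

test_that("checkpoints round-trip through JSON bit-faithfully", {
  fx <- fixture_suite()
  corpus <- make_labeled_corpus(fx$spec, n_per_class = 20L)
  tc <- train_config(batch_size = 16, learning_rate = 0.01,
                     max_epochs = 2, seed = 8)
  m <- train_classifier(desk_model(), corpus, corpus, tc)
  path <- tempfile(fileext = ".json")
  write_classifier(m, path)
  m2 <- read_classifier(path)
  expect_equal(forward(m2, "orphavar01 orphavar02"),
               forward(m, "orphavar01 orphavar02"))
  expect_equal(m2$best_epoch, m$best_epoch)
  expect_equal(m2$trace$val_micro_f1_excl_bg, m$trace$val_micro_f1_excl_bg)
})

test_that("tidy and glance summarize a trained model", {
  fx <- fixture_suite()
  corpus <- make_labeled_corpus(fx$spec, n_per_class = 15L)
  m <- train_classifier(desk_model(), corpus, corpus,
                        train_config(16, 0.01, 2, seed = 1))
  expect_named(tidy(m), c("epoch", "loss", "val_micro_f1_excl_bg"))
  g <- glance(m)
  expect_equal(g$best_epoch, m$best_epoch)
  expect_true(g$trained)
  expect_error(tidy(desk_model()), "trace")
})
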