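test_that("confusion_matrix tabulates truth rows against prediction columns", {
  lv <- class_levels()
  truth <- rep(lv, each = 3)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm), setNames(c(3L, 3L, 3L), lv))
  expect_equal(sum(cm), 9)

  all_rare <- confusion_matrix(truth, rep("RARE", 9))
  expect_equal(unname(all_rare[, "RARE"]), c(3L, 3L, 3L))
  expect_equal(sum(all_rare[, -1]), 0)

  empty <- confusion_matrix(character(), character())
  expect_equal(sum(empty), 0)
  expect_error(confusion_matrix(c("RARE"), character()), "equal length")
})

test_that("class_metrics implements the one-vs-rest formulas with 0/0 = 0", {
  # harmonic-mean identity when precision == recall
  expect_equal(f1_score(0.7, 0.7), 0.7)
  # frozen oracle value: 2 * 0.69 * 0.54 / (0.69 + 0.54)
  expect_equal(f1_score(0.69, 0.54), 0.7452 / 1.23, tolerance = 1e-12)
  expect_equal(f1_score(0.69, 0.54), 0.6058537, tolerance = 1e-7)
  # degenerate convention
  expect_equal(f1_score(0, 0), 0)

  cm <- confusion_matrix(c("RARE", "RARE", "NON_RARE"),
                         c("NON_RARE", "NON_RARE", "NON_RARE"))
  rare <- class_metrics(cm, "RARE")
  expect_equal(rare$tp, 0)
  expect_equal(rare$fn, 2)
  expect_equal(rare$precision, 0)
  expect_equal(rare$recall, 0)
  expect_equal(rare$f1, 0)
})

test_that("per-class metrics match a naive recount on fuzzed label pairs", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      truth <- sample(class_levels(), n, replace = TRUE)
      pred <- sample(class_levels(), n, replace = TRUE)
      cm <- confusion_matrix(truth, pred)
      for (cl in class_levels()) {
        got <- class_metrics(cm, cl)
        want <- oracle_class_metrics(truth, pred, cl)
        expect_equal(got$tp, unname(want["tp"]))
        expect_equal(got$precision, unname(want["precision"]))
        expect_equal(got$recall, unname(want["recall"]))
        expect_equal(got$f1, unname(want["f1"]))
      }
    }
  })
})

test_that("micro equals accuracy when all classes are included", {
  withr::with_seed(37, {
    for (i in 1:200) {
      cm <- matrix(sample(0:30, 9, replace = TRUE), 3,
                   dimnames = list(truth = class_levels(),
                                   predicted = class_levels()))
      if (sum(cm) == 0) next
      class(cm) <- c("confusion_matrix", class(cm))
      av <- averaged_metrics(cm, exclude_background = FALSE)
      acc <- sum(diag(cm)) / sum(cm)
      micro <- av[av$average == "micro", ]
      expect_equal(micro$precision, acc)
      expect_equal(micro$recall, acc)
      expect_equal(micro$f1, acc)
    }
  })
})

test_that("background exclusion drops OTHER's tallies but keeps its errors", {
  # hand-built matrix: rows truth RARE/NON_RARE/OTHER
  cm <- matrix(c(8, 1, 1,
                 2, 6, 2,
                 3, 1, 6), 3, byrow = TRUE,
               dimnames = list(truth = class_levels(),
                               predicted = class_levels()))
  class(cm) <- c("confusion_matrix", class(cm))
  av <- averaged_metrics(cm, exclude_background = TRUE)
  # by hand: RARE tp=8 fp=2+3=5 fn=1+1=2; NON_RARE tp=6 fp=1+1=2 fn=2+2=4
  # micro: tp=14, fp=7, fn=6
  micro <- av[av$average == "micro", ]
  expect_equal(micro$precision, 14 / 21)
  expect_equal(micro$recall, 14 / 20)
  p_r <- c(8 / 13, 6 / 8)
  r_r <- c(8 / 10, 6 / 10)
  macro <- av[av$average == "macro", ]
  expect_equal(macro$precision, mean(p_r))
  expect_equal(macro$recall, mean(r_r))
  expect_equal(macro$f1, mean(2 * p_r * r_r / (p_r + r_r)))
  # correctly classified OTHER documents influence nothing
  cm2 <- cm
  cm2["OTHER", "OTHER"] <- 600L
  class(cm2) <- class(cm)
  expect_equal(averaged_metrics(cm2, exclude_background = TRUE), av)
})

test_that("a diagonal-only matrix scores 1 everywhere, either scope", {
  cm <- confusion_matrix(rep(class_levels(), times = c(5, 3, 7)),
                         rep(class_levels(), times = c(5, 3, 7)))
  for (ex in c(TRUE, FALSE)) {
    av <- averaged_metrics(cm, exclude_background = ex)
    expect_true(all(av$precision == 1 & av$recall == 1 & av$f1 == 1))
  }
})

test_that("f1 lies between min and max of precision and recall", {
  withr::with_seed(41, {
    p <- runif(500)
    r <- runif(500)
    f <- f1_score(p, r)
    expect_true(all(f <= pmax(p, r) + 1e-12))
    expect_true(all(f >= pmin(p, r) - 1e-12))
  })
})

test_that("evaluate_predictions builds the full report", {
  truth <- rep(class_levels(), times = c(4, 4, 4))
  # oracle predictor
  rep1 <- evaluate_predictions(truth, truth)
  expect_equal(rep1$accuracy, 1)
  # constant-OTHER predictor on a set with no OTHER examples
  truth2 <- rep(c("RARE", "NON_RARE"), each = 4)
  rep2 <- evaluate_predictions(truth2, rep("OTHER", 8))
  micro_ex <- rep2$averages[rep2$averages$scope == "without_background" &
                              rep2$averages$average == "micro", ]
  expect_equal(micro_ex$f1, 0)
  expect_error(evaluate_predictions(character(), character()), "empty")
})

test_that("a hand-built prediction set reproduces hand-computed values", {
  truth <- c("RARE", "RARE", "RARE", "NON_RARE", "NON_RARE", "OTHER",
             "OTHER", "OTHER")
  pred <- c("RARE", "NON_RARE", "RARE", "NON_RARE", "OTHER", "OTHER",
            "RARE", "OTHER")
  rep_ <- evaluate_predictions(truth, pred)
  expect_equal(rep_$accuracy, 5 / 8)
  pc <- rep_$per_class
  expect_equal(pc$precision[pc$class == "RARE"], 2 / 3)
  expect_equal(pc$recall[pc$class == "RARE"], 2 / 3)
  expect_equal(pc$precision[pc$class == "NON_RARE"], 1 / 2)
  expect_equal(pc$recall[pc$class == "NON_RARE"], 1 / 2)
  expect_equal(pc$recall[pc$class == "OTHER"], 2 / 3)
})

test_that("tidy, glance and serialization expose full-precision values", {
  truth <- rep(class_levels(), times = c(4, 4, 4))
  pred <- c("RARE", "RARE", "RARE", "NON_RARE",
            "NON_RARE", "NON_RARE", "NON_RARE", "OTHER",
            "OTHER", "OTHER", "OTHER", "RARE")
  rep_ <- evaluate_predictions(truth, pred)
  td <- tidy(rep_)
  expect_equal(nrow(td), 3)
  gl <- glance(rep_)
  expect_true(all(c("accuracy", "micro_f1_all", "macro_f1_excl_bg") %in%
                    names(gl)))
  expect_equal(gl$micro_f1_all, gl$accuracy)

  json <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_evaluation_report(rep_, json, tsv)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$accuracy, rep_$accuracy)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), 3 + 4)  # per-class rows + micro/macro x 2 scopes
})

test_that("autoplot returns ggplot objects", {
  truth <- rep(class_levels(), times = c(3, 3, 3))
  rep_ <- evaluate_predictions(truth, truth)
  expect_s3_class(autoplot(rep_), "ggplot")
})
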