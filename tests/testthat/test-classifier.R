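make_features <- function(ids, rt = 15) {
  tibble::tibble(subject_id = ids, vd_mean = 40, rvda_pct = 3,
                 fwhm = 12, fc = 20)
}
make_lateral <- function(ids, rt = 15) {
  tibble::tibble(subject_id = ids, rt_px = rt, rt_mm = rt * 0.05,
                 fovea_col = 300L)
}

test_that("assemble_features joins, validates and drops incomplete rows", {
  ids <- c("a", "b", "c")
  man <- tibble::tibble(subject_id = ids, label = c("normal", "mci", "ad"))
  out <- assemble_features(make_features(ids), make_lateral(ids), man)
  expect_equal(nrow(out), 3)

  lat_na <- make_lateral(ids); lat_na$rt_px[2] <- NA
  expect_warning(out2 <- assemble_features(make_features(ids), lat_na, man),
                 "dropped")
  expect_equal(out2$subject_id, c("a", "c"))

  dup <- make_features(c("a", "a", "c"))
  expect_error(assemble_features(dup, make_lateral(ids), man), "duplicate")

  man_bad <- man; man_bad$label[1] <- "healthy"
  expect_error(assemble_features(make_features(ids), make_lateral(ids),
                                 man_bad), "unknown labels")

  man_extra <- dplyr::bind_rows(man, tibble::tibble(subject_id = "zz",
                                                    label = "ad"))
  expect_error(assemble_features(make_features(ids), make_lateral(ids),
                                 man_extra), "zz")
})

test_that("confusion metrics reproduce the published formulas", {
  m <- confusion_metrics(1, 1, 0, 0)
  expect_equal(unlist(m[, c("accuracy", "specificity", "sensitivity",
                            "recall")]),
               c(accuracy = 100, specificity = 100, sensitivity = 100,
                 recall = 100))

  m2 <- confusion_metrics(90, 15, 9, 13)
  expect_equal(round(m2$accuracy, 2), 82.68)
  expect_equal(round(m2$specificity, 2), 62.50)
  expect_equal(round(m2$sensitivity, 2), 90.91)  # TP/(TP+FP), as published
  expect_equal(round(m2$recall, 2), 87.38)

  # zero denominators report NA, not 0
  z <- confusion_metrics(0, 5, 0, 0)
  expect_true(is.na(z$sensitivity))
  expect_true(is.na(z$recall))

  set.seed(19)
  for (i in 1:200) {
    cnt <- sample(0:50, 4, replace = TRUE)
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    tot <- sum(cnt)
    if (tot > 0) {
      expect_equal(m$accuracy, 100 * (cnt[1] + cnt[2]) / tot)
    }
    if (cnt[3] + cnt[2] > 0) {
      expect_equal(m$specificity, 100 * cnt[2] / (cnt[3] + cnt[2]))
    }
    if (cnt[1] + cnt[3] > 0) {
      expect_equal(m$sensitivity, 100 * cnt[1] / (cnt[1] + cnt[3]))
    }
    if (cnt[1] + cnt[4] > 0) {
      expect_equal(m$recall, 100 * cnt[1] / (cnt[1] + cnt[4]))
    }
  }
})

test_that("ROC endpoints, degenerate scores and symmetry behave", {
  pos <- c(rep(TRUE, 6), rep(FALSE, 6))
  perfect <- roc_auc(c(6:1 + 10, 6:1), pos)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[1], 0)
  expect_equal(utils::tail(perfect$roc$fpr, 1), 1)
  expect_equal(utils::tail(perfect$roc$tpr, 1), 1)

  expect_equal(roc_auc(rep(1, 12), pos)$auc, 0.5)

  set.seed(7)
  s <- rnorm(40); p <- rbinom(40, 1, 0.5) == 1
  expect_equal(roc_auc(-s, p)$auc, 1 - roc_auc(s, p)$auc)
})

test_that("trapezoid AUC agrees with pROC on random scores", {
  set.seed(100)
  s <- rnorm(60)
  p <- rbinom(60, 1, 0.5) == 1
  ours <- roc_auc(s, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(p),
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("every kernel separates well-separated 1-D classes", {
  tab <- separable_table(12, 12, "vd_mean")
  for (kern in octa_kernels()) {
    m <- train_svm(tab, "normal_vs_ad", "vd_mean", kern)
    ev <- evaluate(m, tab)
    expect_equal(ev$metrics$accuracy, 100,
                 info = paste("kernel:", kern))
  }
})

test_that("the RBF kernel solves XOR where the linear kernel cannot", {
  withr::with_seed(41, {
    n <- 15
    xor_tab <- tibble::tibble(
      f1 = c(rnorm(n, 2, .3), rnorm(n, -2, .3), rnorm(n, 2, .3),
             rnorm(n, -2, .3)),
      f2 = c(rnorm(n, 2, .3), rnorm(n, -2, .3), rnorm(n, -2, .3),
             rnorm(n, 2, .3)),
      label = c(rep("normal", 2 * n), rep("ad", 2 * n))
    )
  })
  rbf <- evaluate(train_svm(xor_tab, "normal_vs_ad", c("f1", "f2"),
                            "gaussian_rbf"), xor_tab)
  lin <- evaluate(train_svm(xor_tab, "normal_vs_ad", c("f1", "f2"),
                            "linear"), xor_tab)
  expect_equal(rbf$metrics$accuracy, 100)
  expect_lte(lin$metrics$accuracy, 75)
})

test_that("training fails cleanly on degenerate inputs", {
  tab <- separable_table(10, 10, "vd_mean")
  one_class <- tab[tab$label == "normal", ]
  expect_error(train_svm(one_class, "normal_vs_ad", "vd_mean"), "2 samples")
  expect_error(train_svm(tab, "normal_vs_ad", "nope"), "missing feature")
  expect_error(train_svm(tab, "normal_vs_ad", "vd_mean", "mystery"),
               "'arg' should be one of")
})

test_that("cross-validation is deterministic and bounded by resubstitution", {
  withr::with_seed(55, {
    accs <- replicate(10, {
      tab <- tibble::tibble(
        vd_mean = c(rnorm(24, 1), rnorm(16, -1)),
        label = c(rep("normal", 24), rep("ad", 16))
      )
      m <- train_svm(tab, "normal_vs_ad", "vd_mean", "linear")
      c(resub = evaluate(m, tab)$metrics$accuracy,
        cv = evaluate(m, tab, scheme = "cv", seed = 1317)$metrics$accuracy)
    })
  })
  expect_gte(mean(accs["resub", ]), mean(accs["cv", ]))

  tab <- separable_table(12, 10, "vd_mean", gap = 2, seed = 3)
  m <- train_svm(tab, "normal_vs_ad", "vd_mean", "gaussian_rbf")
  e1 <- evaluate(m, tab, scheme = "cv", seed = 1317)
  e2 <- evaluate(m, tab, scheme = "cv", seed = 1317)
  expect_identical(glance(e1), glance(e2))
})

test_that("model search reports every feature set with its winning kernel", {
  withr::with_seed(77, {
    n_pos <- 20; n_neg <- 16
    tab <- tibble::tibble(
      vd_mean = c(rnorm(n_pos, 45, 3), rnorm(n_neg, 30, 3)),
      rvda_pct = c(rnorm(n_pos, 3, .5), rnorm(n_neg, 6, .8)),
      fwhm = c(rnorm(n_pos, 12, 1), rnorm(n_neg, 18, 1.5)),
      fc = c(rnorm(n_pos, 20, 2), rnorm(n_neg, 28, 2)),
      rt_px = c(rnorm(n_pos, 16, 1.5), rnorm(n_neg, 11, 1.5)),
      label = c(rep("normal", n_pos), rep("ad", n_neg))
    )
  })
  rep1 <- search_models(tab, tasks = "normal_vs_ad",
                        kernels = c("linear", "gaussian_rbf"))
  expect_equal(nrow(rep1), 5 + 4 + 1)  # singles, VD pairs, baseline
  fitted <- rep1[rep1$features != "baseline_always_normal", ]
  expect_true(all(!is.na(fitted$kernel)))
  expect_true(all(fitted$kernel %in% c("linear", "gaussian_rbf")))
  expect_setequal(
    fitted$features,
    c("vd_mean", "rvda_pct", "fwhm", "fc", "rt_px",
      "rvda_pct+vd_mean", "fwhm+vd_mean", "fc+vd_mean", "rt_px+vd_mean")
  )

  # baseline accuracy equals the normal prevalence under imbalance
  base <- rep1[rep1$features == "baseline_always_normal", ]
  expect_equal(base$accuracy, 100 * 20 / 36)
  expect_equal(base$recall, 100)

  rep2 <- search_models(tab, tasks = "normal_vs_ad",
                        kernels = c("linear", "gaussian_rbf"))
  expect_identical(rep1, rep2)

  rep_all <- search_models(tab, tasks = "normal_vs_ad", kernels = "linear",
                           all_pairs = TRUE, include_baseline = FALSE)
  expect_equal(nrow(rep_all), 5 + 10)
})

test_that("tidy and glance methods return well-formed tibbles", {
  tab <- separable_table(10, 10, "vd_mean")
  m <- train_svm(tab, "normal_vs_ad", "vd_mean", "linear")
  g <- glance(m)
  expect_true(all(c("kernel", "C", "n_support_vectors") %in% names(g)))
  ev <- evaluate(m, tab)
  td <- tidy(ev)
  expect_equal(nrow(td), 6)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_s3_class(autoplot(ev), "ggplot")
})
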