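#' Supported binary screening tasks and kernels
#'
#' Tasks contrast the normal class against one disease grouping; kernels
#' span the families commonly compared for small-sample SVM screening.
#'
#' @return Character vector of names.
#' @export
octa_tasks <- function() c("normal_vs_ad", "normal_vs_mci", "normal_vs_admci")

#' @rdname octa_tasks
#' @export
octa_kernels <- function() {
  c("linear", "polynomial", "gaussian_rbf", "laplace_rbf", "sigmoid",
    "bessel", "anova_rbf")
}

#' @rdname octa_tasks
#' @export
octa_single_features <- function() {
  c("vd_mean", "rvda_pct", "fwhm", "fc", "rt_px")
}

# Subset a feature table to one binary task; normal is always the positive
# class.
.task_subset <- function(table, task) {
  task <- match.arg(task, octa_tasks())
  keep <- switch(task,
    normal_vs_ad = c("normal", "ad"),
    normal_vs_mci = c("normal", "mci"),
    normal_vs_admci = c("normal", "mci", "ad")
  )
  out <- table[table$label %in% keep, , drop = FALSE]
  out$class <- factor(ifelse(out$label == "normal", "normal", "disease"),
                      levels = c("normal", "disease"))
  out
}

# kernlab kernel object for a named kernel; d = feature dimension after
# standardisation (unit variance), so the RBF-family inverse width is 1/d.
.octa_kernel <- function(kernel, d) {
  switch(kernel,
    linear = kernlab::vanilladot(),
    polynomial = kernlab::polydot(degree = 2, scale = 1, offset = 1),
    gaussian_rbf = kernlab::rbfdot(sigma = 1 / d),
    laplace_rbf = kernlab::laplacedot(sigma = 1 / d),
    sigmoid = kernlab::tanhdot(scale = 1 / d, offset = 1),
    bessel = kernlab::besseldot(sigma = 1, order = 1, degree = 1),
    anova_rbf = kernlab::anovadot(sigma = 1, degree = 1),
    stop("unknown kernel: ", kernel, call. = FALSE)
  )
}

#' Train a soft-margin SVM on one or two features
#'
#' Fits a maximum-margin classifier for one screening task on a one- or
#' two-feature subset. Features are z-scored with training-set parameters
#' before fitting, and `C = 1` regularises the margin on that standardised
#' scale. The decision value is oriented so that positive means normal.
#'
#' @param table Feature table (from [assemble_features()] or
#'   [extract_cohort_features()]) with a `label` column.
#' @param task One of [octa_tasks()].
#' @param features Character vector of 1 or 2 feature column names.
#' @param kernel One of [octa_kernels()].
#' @param C Soft-margin cost (default 1).
#' @return An object of class `"octa_svm"`.
#' @export
train_svm <- function(table, task, features, kernel = "gaussian_rbf", C = 1) {
  if (!length(features) %in% c(1L, 2L)) {
    stop("features must name 1 or 2 columns", call. = FALSE)
  }
  if (!all(features %in% names(table))) {
    stop("missing feature columns: ",
         paste(setdiff(features, names(table)), collapse = ", "),
         call. = FALSE)
  }
  kernel <- match.arg(kernel, octa_kernels())
  dat <- .task_subset(table, task)
  if (any(table(dat$class) < 2)) {
    stop("need at least 2 samples of each class for task ", task,
         call. = FALSE)
  }
  x <- as.matrix(dat[, features, drop = FALSE])
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  fit <- kernlab::ksvm(xs, dat$class, type = "C-svc",
                       kernel = .octa_kernel(kernel, ncol(xs)),
                       C = C, scaled = FALSE)
  # orient decision values: positive decision must mean "normal"
  dec <- kernlab::predict(fit, xs, type = "decision")[, 1]
  pred <- kernlab::predict(fit, xs, type = "response")
  flip <- FALSE
  if (any(pred == "normal") && any(pred == "disease")) {
    flip <- mean(dec[pred == "normal"]) < mean(dec[pred == "disease"])
  }
  structure(
    list(fit = fit, task = task, features = features, kernel = kernel,
         C = C, center = centre, scale = scale_, flip = flip,
         n_train = nrow(dat), levels = levels(dat$class)),
    class = "octa_svm"
  )
}

#' @export
print.octa_svm <- function(x, ...) {
  cat("SVM (", x$kernel, ") for ", x$task, " on ",
      paste(x$features, collapse = " + "), "; C = ", x$C,
      ", n = ", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Predict classes and decision values
#'
#' @param object An `"octa_svm"`.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `.pred_class` (`normal`/`disease`) and `.decision`
#'   (signed margin distance; positive means normal).
#' @export
predict.octa_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dec <- kernlab::predict(object$fit, xs, type = "decision")[, 1]
  if (object$flip) dec <- -dec
  pred <- kernlab::predict(object$fit, xs, type = "response")
  tibble::tibble(.pred_class = factor(as.character(pred),
                                      levels = c("normal", "disease")),
                 .decision = dec)
}

#' Confusion-matrix screening metrics
#'
#' Computes the four headline percentages from confusion counts with the
#' normal class as positive:
#' accuracy \eqn{= (TP+TN)/(TP+FP+TN+FN)},
#' specificity \eqn{= TN/(FP+TN)},
#' sensitivity \eqn{= TP/(TP+FP)} (note: this is the positive predictive
#' value -- the definition is kept as published for comparability, and the
#' conventional sensitivity \eqn{TP/(TP+FN)} is reported separately as
#' `sensitivity_canonical`), and recall \eqn{= TP/(TP+FN)}.
#' A metric whose denominator is zero is returned as `NA`, never as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return One-row tibble with the counts and the metrics in percent.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = div(tp + tn, tp + fp + tn + fn),
    specificity = div(tn, fp + tn),
    sensitivity = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    sensitivity_canonical = div(tp, tp + fn)
  )
}

#' ROC curve and AUC from decision values
#'
#' Sweeps the decision-value threshold over all observed scores and returns
#' the stepwise ROC; the AUC is the trapezoid-rule area. Ties in scores are
#' handled by moving along both axes at once, which is what the trapezoid
#' rule requires.
#'
#' @param scores Numeric decision values, larger meaning more positive.
#' @param positive Logical vector, `TRUE` for the positive (normal) class.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(p), grp, max)
  fp <- tapply(cumsum(!p), grp, max)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thr <- c(Inf, tapply(s, grp, max))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = tibble::tibble(threshold = as.numeric(thr),
                            fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = auc)
}

# stratified fold assignment, deterministic under seed
.stratified_folds <- function(class, k, seed) {
  fold <- integer(length(class))
  withr::with_seed(seed, {
    for (cl in unique(class)) {
      idx <- which(class == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Evaluate a fitted SVM
#'
#' Under `"resubstitution"` the model scores its own training table. Under
#' `"cv"` the model's recipe (task, features, kernel, C) is refitted on
#' each of `k` stratified folds and scored on the held-out fold;
#' confusion counts and decision values are pooled across folds.
#'
#' @param model An `"octa_svm"`.
#' @param table Feature table with `label`.
#' @param scheme `"resubstitution"` or `"cv"`.
#' @param k Number of folds for `"cv"` (default 5).
#' @param seed Seed for the stratified fold assignment (default 1317).
#' @return An object of class `"octa_eval"`: confusion counts, metric
#'   tibble, ROC tibble, `auc`, `scheme`, `n`.
#' @export
evaluate <- function(model, table, scheme = c("resubstitution", "cv"),
                     k = 5, seed = 1317) {
  scheme <- match.arg(scheme)
  dat <- .task_subset(table, model$task)
  if (scheme == "resubstitution") {
    pred <- predict(model, dat)
    truth <- dat$class
    dec <- pred$.decision
    cls <- pred$.pred_class
  } else {
    fold <- .stratified_folds(dat$class, k, seed)
    dec <- numeric(nrow(dat))
    cls <- character(nrow(dat))
    for (f in seq_len(k)) {
      tr <- dat[fold != f, , drop = FALSE]
      te <- dat[fold == f, , drop = FALSE]
      m <- train_svm(tr, model$task, model$features, model$kernel, model$C)
      p <- predict(m, te)
      dec[fold == f] <- p$.decision
      cls[fold == f] <- as.character(p$.pred_class)
    }
    cls <- factor(cls, levels = c("normal", "disease"))
    truth <- dat$class
  }
  tp <- sum(truth == "normal" & cls == "normal")
  tn <- sum(truth == "disease" & cls == "disease")
  fp <- sum(truth == "disease" & cls == "normal")
  fn <- sum(truth == "normal" & cls == "disease")
  metrics <- confusion_metrics(tp, tn, fp, fn)
  ra <- roc_auc(dec, truth == "normal")
  structure(
    list(metrics = metrics, roc = ra$roc, auc = ra$auc, scheme = scheme,
         n = nrow(dat), task = model$task, features = model$features,
         kernel = model$kernel),
    class = "octa_eval"
  )
}

#' @export
print.octa_eval <- function(x, ...) {
  m <- x$metrics
  cat(x$task, "|", paste(x$features, collapse = "+"), "|", x$kernel, "|",
      x$scheme, "\n")
  cat(sprintf("  accuracy %.2f%%  specificity %s  sensitivity %s  recall %s  AUC %.3f\n",
              m$accuracy,
              ifelse(is.na(m$specificity), "NA", sprintf("%.2f%%", m$specificity)),
              ifelse(is.na(m$sensitivity), "NA", sprintf("%.2f%%", m$sensitivity)),
              ifelse(is.na(m$recall), "NA", sprintf("%.2f%%", m$recall)),
              x$auc))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.octa_eval <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    metric = c("accuracy", "specificity", "sensitivity", "recall",
               "sensitivity_canonical", "auc"),
    value = c(m$accuracy, m$specificity, m$sensitivity, m$recall,
              m$sensitivity_canonical, 100 * x$auc)
  )
}

#' @rdname tidiers
#' @export
glance.octa_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(task = x$task,
                   features = paste(x$features, collapse = "+"),
                   kernel = x$kernel, scheme = x$scheme, n = x$n),
    x$metrics,
    tibble::tibble(auc = x$auc)
  )
}

#' @rdname tidiers
#' @export
glance.octa_svm <- function(x, ...) {
  tibble::tibble(
    task = x$task, features = paste(x$features, collapse = "+"),
    kernel = x$kernel, C = x$C, n_train = x$n_train,
    n_support_vectors = kernlab::nSV(x$fit)
  )
}

#' One- and two-feature SVM model search
#'
#' For each task and feature set -- the five single features plus, by
#' default, the four pairs of the mean vessel density with each other
#' feature (`all_pairs = TRUE` expands to all ten unordered pairs) -- every
#' kernel is fitted and evaluated, and the best kernel by accuracy is kept
#' (ties broken by higher AUC, then by kernel name). The report has one row
#' per task and feature set, plus an always-normal baseline row per task
#' whose accuracy equals the normal-class prevalence, as a reference point
#' under class imbalance.
#'
#' @param table Feature table with `label`.
#' @param tasks Character vector of tasks (default all of [octa_tasks()]
#'   present in the data).
#' @param kernels Kernels to try (default [octa_kernels()]).
#' @param feature_sets Optional list of character vectors overriding the
#'   default feature sets.
#' @param all_pairs Use all 10 feature pairs instead of the 4 VD-paired
#'   sets.
#' @param scheme,k,seed Passed to [evaluate()].
#' @param C Soft-margin cost.
#' @param include_baseline Add the always-normal baseline row per task.
#' @return A tibble: `task`, `features`, `kernel`, `accuracy`,
#'   `sensitivity`, `specificity`, `recall`, `auc`, `n`. Feature sets whose
#'   every kernel fails to fit yield a row of `NA` metrics.
#' @export
search_models <- function(table, tasks = NULL, kernels = octa_kernels(),
                          feature_sets = NULL, all_pairs = FALSE,
                          scheme = "resubstitution", k = 5, seed = 1317,
                          C = 1, include_baseline = TRUE) {
  if (is.null(tasks)) {
    have <- unique(table$label)
    tasks <- c(
      if (all(c("normal", "ad") %in% have)) "normal_vs_ad",
      if (all(c("normal", "mci") %in% have)) "normal_vs_mci",
      if (all(c("normal", "mci", "ad") %in% have)) "normal_vs_admci"
    )
  }
  if (is.null(feature_sets)) {
    singles <- as.list(octa_single_features())
    others <- setdiff(octa_single_features(), "vd_mean")
    pairs <- if (all_pairs) {
      utils::combn(octa_single_features(), 2, simplify = FALSE)
    } else {
      lapply(others, function(f) c(f, "vd_mean"))
    }
    feature_sets <- c(singles, pairs)
  }
  rows <- list()
  for (task in tasks) {
    for (fs in feature_sets) {
      best <- NULL
      for (kern in kernels) {
        ev <- tryCatch({
          m <- train_svm(table, task, fs, kern, C = C)
          evaluate(m, table, scheme = scheme, k = k, seed = seed)
        }, error = function(e) NULL)
        if (is.null(ev)) next
        if (is.null(best) ||
            isTRUE(ev$metrics$accuracy > best$metrics$accuracy) ||
            (isTRUE(ev$metrics$accuracy == best$metrics$accuracy) &&
             (ev$auc > best$auc ||
              (ev$auc == best$auc && ev$kernel < best$kernel)))) {
          best <- ev
        }
      }
      rows[[length(rows) + 1L]] <- if (is.null(best)) {
        tibble::tibble(task = task, features = paste(fs, collapse = "+"),
                       kernel = NA_character_, accuracy = NA_real_,
                       sensitivity = NA_real_, specificity = NA_real_,
                       recall = NA_real_, auc = NA_real_, n = NA_integer_)
      } else {
        m <- best$metrics
        tibble::tibble(task = task, features = paste(fs, collapse = "+"),
                       kernel = best$kernel, accuracy = m$accuracy,
                       sensitivity = m$sensitivity,
                       specificity = m$specificity, recall = m$recall,
                       auc = best$auc, n = best$n)
      }
    }
    if (include_baseline) {
      dat <- .task_subset(table, task)
      n_pos <- sum(dat$class == "normal")
      n_neg <- sum(dat$class == "disease")
      bm <- confusion_metrics(tp = n_pos, tn = 0, fp = n_neg, fn = 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        task = task, features = "baseline_always_normal",
        kernel = NA_character_, accuracy = bm$accuracy,
        sensitivity = bm$sensitivity, specificity = bm$specificity,
        recall = bm$recall, auc = 0.5, n = nrow(dat)
      )
    }
  }
  dplyr::bind_rows(rows)
}
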