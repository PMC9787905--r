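# Classification bench: min-max scaling, task labelling, grid-searched
# AdaBoost / Extra Trees / Random Forest with stratified 80/20 evaluation.

#' Min-max scale features to [0, 1] using training ranges
#'
#' Ranges are fitted on the training rows only and applied unchanged to any
#' other rows, so held-out values may fall outside [0, 1] (no clipping).
#' A constant training column maps to 0 with a warning.
#'
#' @param x Numeric matrix or data.frame of feature columns.
#' @param ranges Optional fitted ranges (from a previous call's `ranges`
#'   element); default: fit on `x`.
#' @return List with `scaled` (same shape as `x`) and `ranges` (2 x p
#'   matrix of mins and maxs).
#' @examples
#' scaleMinMax(data.frame(a = c(2, 4, 6)))$scaled
#' @export
scaleMinMax <- function(x, ranges = NULL) {
  xm <- as.matrix(x)
  if (is.null(ranges)) {
    ranges <- apply(xm, 2, range)
    rownames(ranges) <- c("min", "max")
    if (any(ranges["max", ] - ranges["min", ] < 1e-24))
      warning("constant training column(s) scaled to 0: ",
              paste(colnames(xm)[ranges["max", ] - ranges["min", ] < 1e-24],
                    collapse = ", "), call. = FALSE)
  }
  span <- ranges["max", ] - ranges["min", ]
  span[span < 1e-24] <- 1
  scaled <- sweep(sweep(xm, 2, ranges["min", ], "-"), 2, span, "/")
  list(scaled = scaled, ranges = ranges)
}

#' Build class labels for one classification task
#'
#' * `PD_NONPD`: PD against the merged EL and S control groups.
#' * `PD_EL_S`: the three participant groups.
#' * `ON_OFF`: PD medication states; rows without an ON/OFF state (controls,
#'   DCIP-only patients) are excluded.
#' * `SEVERITY`: MDS-UPDRS Part III severity levels, restricted to mild and
#'   moderate (the only levels with recordings); labels come from
#'   `severity_level` or, if absent, from [binSeverity()] on `part3_total`.
#'
#' @param meta `data.frame` of per-recording metadata (`group`,
#'   `medication_state`, `severity_level` / `part3_total`).
#' @param task One of `"PD_NONPD"`, `"PD_EL_S"`, `"ON_OFF"`, `"SEVERITY"`.
#' @return Factor of labels with an NA for every excluded row; the number
#'   of excluded rows is reported in attribute `"excluded"`.
#' @examples
#' meta <- data.frame(group = c("PD", "EL", "S"),
#'                    medication_state = c("ON", NA, NA))
#' makeLabels(meta, "PD_NONPD")
#' @export
makeLabels <- function(meta, task = c("PD_NONPD", "PD_EL_S", "ON_OFF",
                                      "SEVERITY")) {
  task <- match.arg(task)
  n <- nrow(meta)
  lab <- switch(task,
    PD_NONPD = factor(ifelse(meta$group == "PD", "PD", "nonPD"),
                      levels = c("nonPD", "PD")),
    PD_EL_S = factor(meta$group, levels = gaitGroups()),
    ON_OFF = {
      st <- as.character(meta$medication_state)
      st[!(meta$group == "PD" & st %in% c("ON", "OFF"))] <- NA
      factor(st, levels = c("OFF", "ON"))
    },
    SEVERITY = {
      sev <- if ("severity_level" %in% names(meta) &&
                 !all(is.na(meta$severity_level)))
        as.character(meta$severity_level)
      else if ("part3_total" %in% names(meta))
        as.character(binSeverity(meta$part3_total[!is.na(meta$part3_total)]))[
          match(seq_len(n), which(!is.na(meta$part3_total)))]
      else stop("SEVERITY task needs severity_level or part3_total",
                call. = FALSE)
      sev[!(meta$group == "PD" & sev %in% c("mild", "moderate"))] <- NA
      factor(sev, levels = c("mild", "moderate"))
    })
  attr(lab, "excluded") <- sum(is.na(lab))
  lab
}

#' Configure a classification bench run
#'
#' @param task Classification task (see [makeLabels()]).
#' @param testType Walking test to use, or `NA` for all rows.
#' @param classifiers Subset of `"adaboost"`, `"extra_trees"`,
#'   `"random_forest"`.
#' @param testFraction Held-out fraction (default 0.20).
#' @param cvFolds Cross-validation folds for the grid search (default 5).
#' @param gridBudget Maximum candidate x fold evaluations (default 1000);
#'   the default grids use well under this.
#' @param seed Integer seed controlling the split, the folds and the tree
#'   ensembles.
#' @param selectFeatures Run the mixed-model + correlation feature selection
#'   on the training rows before fitting (default `TRUE`).
#' @param participantGrouped Split by participant rather than by recording,
#'   keeping all of a participant's rows on one side (default `FALSE`:
#'   recordings are independent samples, ON and OFF sessions included).
#' @return A `benchConfig` list.
#' @export
benchConfig <- function(task, testType = NA, classifiers = c("adaboost",
                        "extra_trees", "random_forest"),
                        testFraction = 0.20, cvFolds = 5, gridBudget = 1000,
                        seed = 1, selectFeatures = TRUE,
                        participantGrouped = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  stopifnot(testFraction > 0, testFraction < 1, cvFolds >= 2)
  structure(list(task = task, testType = testType, classifiers = classifiers,
                 testFraction = testFraction, cvFolds = cvFolds,
                 gridBudget = gridBudget, seed = seed,
                 selectFeatures = selectFeatures,
                 participantGrouped = participantGrouped),
            class = "benchConfig")
}

# ---------------------------------------------------------------------------
# classifiers

# Default hyperparameter grids; kept small so a full bench stays well under
# the candidate-evaluation budget.
.default_grids <- function() {
  list(
    adaboost = expand.grid(n_rounds = c(30, 60), max_depth = c(1, 2, 3)),
    extra_trees = expand.grid(num_trees = c(200, 500), mtry = c(2, 4),
                              min_node = c(1, 5)),
    random_forest = expand.grid(num_trees = c(200, 500), mtry = c(2, 4),
                                min_node = c(1, 5)))
}

# Multi-class AdaBoost (SAMME) over rpart base learners.
.ada_fit <- function(x, y, n_rounds, max_depth) {
  d <- data.frame(x, .y = y)
  n <- nrow(d); K <- nlevels(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, minsplit = 2, cp = 0,
                          xval = 0))
    pred <- predict(fit, d, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-10) {            # perfect learner: dominate the vote
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 1 - 1 / K) break    # no better than chance: stop boosting
    alpha <- log((1 - err) / err) + log(K - 1)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(learners)) {         # degenerate: majority-class model
    learners <- list(NULL)
    alphas <- 1
  }
  structure(list(learners = learners, alphas = alphas, levels = levels(y),
                 majority = names(which.max(table(y)))), class = "ada_samme")
}

.ada_predict <- function(model, x) {
  d <- data.frame(x)
  votes <- matrix(0, nrow(d), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (i in seq_along(model$learners)) {
    fit <- model$learners[[i]]
    if (is.null(fit)) {
      votes[, model$majority] <- votes[, model$majority] + model$alphas[i]
    } else {
      pred <- predict(fit, d, type = "class")
      votes[cbind(seq_len(nrow(d)), match(pred, model$levels))] <-
        votes[cbind(seq_len(nrow(d)), match(pred, model$levels))] +
        model$alphas[i]
    }
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

.fit_classifier <- function(method, x, y, params, seed) {
  x <- as.data.frame(x)
  if (method == "adaboost") {
    with_seed(seed, .ada_fit(x, y, params$n_rounds, params$max_depth))
  } else {
    ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      mtry = min(params$mtry, ncol(x)), min.node.size = params$min_node,
      splitrule = if (method == "extra_trees") "extratrees" else "gini",
      num.random.splits = 1,
      replace = method != "extra_trees",
      sample.fraction = if (method == "extra_trees") 1 else 0.632,
      seed = seed, num.threads = 1)
  }
}

.predict_classifier <- function(method, model, x) {
  x <- as.data.frame(x)
  if (method == "adaboost") .ada_predict(model, x)
  else predict(model, data = x, num.threads = 1)$predictions
}

# Stratified fold assignment (1..k) per observation.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Run one classification bench cell
#'
#' Stratified 80/20 train/test split under the config seed; mixed-model +
#' correlation feature selection and min-max scaling ranges are computed on
#' the training rows only; each classifier's hyperparameters are chosen by
#' stratified k-fold cross-validated accuracy on the training rows over the
#' documented default grid; the chosen model is refit on all training rows
#' and evaluated once on the held-out rows.
#'
#' @param table A [GaitSampleTable-class] or feature `data.frame` with
#'   metadata columns.
#' @param cfg A [benchConfig()].
#' @return A [BenchReport-class].
#' @examples
#' tab <- simulateFeatureTable(c(S = 10, PD = 10), seed = 1,
#'                             effect = c(step_length_m = 3))
#' runBench(tab, benchConfig("PD_NONPD", seed = 1,
#'                           classifiers = "random_forest"))
#' @export
runBench <- function(table, cfg) {
  stopifnot(inherits(cfg, "benchConfig"))
  df <- .as_sample_df(table)
  if (!is.na(cfg$testType))
    df <- df[df$test_type %in% cfg$testType, , drop = FALSE]
  lab <- makeLabels(df, cfg$task)
  keep <- !is.na(lab)
  if (sum(keep) == 0L || nlevels(droplevels(lab[keep])) < 2L)
    stopf("labeling for task %s left fewer than 2 classes (%d usable rows)",
          cfg$task, sum(keep))
  df <- df[keep, , drop = FALSE]
  y <- droplevels(lab[keep])

  grids <- .default_grids()
  n_evals <- sum(vapply(grids[cfg$classifiers], nrow, numeric(1))) *
    cfg$cvFolds
  if (n_evals > cfg$gridBudget)
    stopf("grid search would use %d candidate-fold evaluations (> budget %d)",
          n_evals, cfg$gridBudget)

  # stratified (optionally participant-grouped) 80/20 split
  test_idx <- with_seed(cfg$seed, {
    if (cfg$participantGrouped) {
      pid <- df$participant_id
      plab <- vapply(split(as.character(y), pid),
                     function(v) names(which.max(table(v))), character(1))
      test_pid <- unlist(lapply(split(names(plab), plab), function(ids)
        sample(ids, max(1, round(cfg$testFraction * length(ids))))))
      which(pid %in% test_pid)
    } else {
      unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        sample(idx, max(1, round(cfg$testFraction * length(idx))))
      }))
    }
  })
  train_idx <- setdiff(seq_len(nrow(df)), test_idx)
  y_train <- droplevels(y[train_idx]); y_test <- y[test_idx]
  if (nlevels(y_train) < 2L)
    stop("training partition lost a class; use a larger cohort",
         call. = FALSE)

  # feature selection on training rows only
  feats <- gaitFeatureNames()
  if (cfg$selectFeatures) {
    # the task label is the fixed factor of the screen
    dtr <- df[train_idx, , drop = FALSE]
    dtr$.bench_label <- y_train
    sel <- tryCatch({
      scr <- lmmScreen(dtr, ".bench_label", features = feats)
      suppressWarnings(selectFeatures(scr, correlationMatrix(dtr)))
    }, error = function(e) feats)
    if (length(sel) >= 1L) feats <- sel
  }

  sc <- scaleMinMax(df[train_idx, feats, drop = FALSE])
  x_train <- sc$scaled
  x_test <- scaleMinMax(df[test_idx, feats, drop = FALSE], sc$ranges)$scaled

  folds_k <- cfg$cvFolds
  min_class <- min(table(y_train))
  if (min_class < folds_k) {
    warning(sprintf(
      "class with %d training members < %d folds; reducing folds", min_class,
      folds_k), call. = FALSE)
    folds_k <- max(2L, min_class)
  }
  folds <- with_seed(sub_seed(cfg$seed, 1L), .stratified_folds(y_train,
                                                               folds_k))

  summary_rows <- list(); params <- list(); recall <- list()
  for (method in cfg$classifiers) {
    grid <- grids[[method]]
    cv_acc <- matrix(NA_real_, nrow(grid), folds_k)
    for (g in seq_len(nrow(grid))) {
      for (f in seq_len(folds_k)) {
        tr <- folds != f
        if (nlevels(droplevels(y_train[tr])) < 2L) next
        fit <- .fit_classifier(method, x_train[tr, , drop = FALSE],
                               droplevels(y_train[tr]), grid[g, ],
                               seed = sub_seed(cfg$seed, 100L + g * folds_k + f))
        pred <- .predict_classifier(method, fit,
                                    x_train[!tr, , drop = FALSE])
        cv_acc[g, f] <- mean(as.character(pred) ==
                               as.character(y_train[!tr]))
      }
    }
    means <- rowMeans(cv_acc, na.rm = TRUE)
    best <- which.max(means)
    final <- .fit_classifier(method, x_train, y_train, grid[best, ],
                             seed = sub_seed(cfg$seed, 7L))
    pred <- .predict_classifier(method, final, x_test)
    acc <- mean(as.character(pred) == as.character(y_test))
    summary_rows[[method]] <- data.frame(
      classifier = method, cv_mean = means[best],
      cv_sd = sd(cv_acc[best, ], na.rm = TRUE), holdout_accuracy = acc,
      n_train = length(train_idx), n_test = length(test_idx),
      stringsAsFactors = FALSE)
    params[[method]] <- as.list(grid[best, , drop = FALSE])
    recall[[method]] <- vapply(levels(y), function(lv) {
      idx <- y_test == lv
      if (!any(idx)) NA_real_
      else mean(as.character(pred[idx]) == lv)
    }, numeric(1))
  }
  new("BenchReport", task = cfg$task,
      testType = as.character(cfg$testType),
      summary = do.call(rbind, summary_rows), params = params,
      features = feats, recall = recall)
}
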