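#' Build a feature table for disease-onset classification
#'
#' Two feature modes are supported: \code{"predicted_states"} turns each
#' patient's nine predicted final states into binary features (collapse = 1);
#' \code{"average_values"} uses the mean of each biomarker's original
#' (pre-onset) readings.
#'
#' @param x A \code{\link{cohort}}.
#' @param predictions A table from \code{\link{predict_cohort}} (required for
#'   the predicted-states mode).
#' @param mode \code{"predicted_states"} or \code{"average_values"}.
#' @param panel Biomarker panel defining the feature columns and order.
#' @return A list with \code{features} (data frame, one row per patient, one
#'   column per biomarker) and \code{labels} (factor with levels
#'   control/case).
#' @export
featurize <- function(x, predictions = NULL,
                      mode = c("predicted_states", "average_values"),
                      panel = default_panel()) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "cohort"))
  bms <- names(panel)
  ids <- vapply(unclass(x), `[[`, character(1), "patient_id")
  labels <- factor(vapply(unclass(x), `[[`, character(1), "label"),
                   levels = c("control", "case"))
  feat <- matrix(NA_real_, nrow = length(ids), ncol = length(bms),
                 dimnames = list(ids, bms))
  if (mode == "predicted_states") {
    if (is.null(predictions)) {
      stop("predicted_states mode needs a prediction table", call. = FALSE)
    }
    for (i in seq_along(ids)) {
      sub <- predictions[predictions$patient_id == ids[i], ]
      dec <- stats::setNames(sub$decision, sub$biomarker)
      if (!all(bms %in% names(dec))) {
        stop(sprintf("patient %s is missing predictions for some biomarkers",
                     ids[i]), call. = FALSE)
      }
      feat[i, ] <- as.numeric(dec[bms] == "collapse")
    }
  } else {
    pats <- unclass(x)
    for (i in seq_along(ids)) {
      sm <- pats[[i]]$series
      if (!all(bms %in% names(sm))) {
        stop(sprintf("patient %s is missing some biomarker series", ids[i]),
             call. = FALSE)
      }
      feat[i, ] <- vapply(bms, function(b) mean(sm[[b]]$value), numeric(1))
    }
  }
  list(features = as.data.frame(feat), labels = labels)
}

# stratified train indices: round(train_fraction * n) per class
stratified_split <- function(labels, train_fraction) {
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    k <- round(train_fraction * length(idx))
    train <- c(train, sample(idx, k))
  }
  sort(train)
}

#' Hold-out decision-tree experiment
#'
#' Repeated stratified 75/25 hold-out evaluation of a depth-limited CART
#' decision tree.  Iteration j seeds the random split with
#' \code{seed_base + j}, so two runs with the same seed base (and the same
#' features) use identical splits -- which makes experiments on different
#' feature modes paired.  Reported per iteration: accuracy, recall
#' (sensitivity for the case class), specificity, PPV, NPV, and AUC from the
#' tree's class-probability scores.
#'
#' @param features Data frame of per-patient features.
#' @param labels Factor with levels control/case ("case" is positive).
#' @param n_iterations Number of shuffles (default 40).
#' @param train_fraction Training fraction (default 0.75).
#' @param max_depth Maximum tree depth (default 3).
#' @param seed_base Integer seed base.
#' @return An object of class \code{"incl_experiment"}: a list with
#'   \code{metrics} (one row per iteration) and \code{summary} (mean and sd
#'   per metric), plus the experiment settings.
#' @export
run_experiment <- function(features, labels, n_iterations = 40L,
                           train_fraction = 0.75, max_depth = 3L,
                           seed_base = 0L) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels),
            nlevels(labels) == 2L, all(table(labels) > 0),
            train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  dat <- cbind(.label = labels, features)
  metric_names <- c("accuracy", "recall", "specificity", "ppv", "npv", "auc")
  res <- matrix(NA_real_, nrow = n_iterations, ncol = length(metric_names),
                dimnames = list(NULL, metric_names))
  for (j in seq_len(n_iterations)) {
    set.seed(seed_base + j)
    train <- stratified_split(labels, train_fraction)
    test <- setdiff(seq_along(labels), train)
    fit <- rpart::rpart(.label ~ ., data = dat[train, ], method = "class",
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = 0, xval = 0))
    prob <- predict(fit, dat[test, ], type = "prob")[, "case"]
    pred_case <- prob >= 0.5
    truth_case <- labels[test] == "case"
    if (!any(truth_case) || all(truth_case)) next  # degenerate fold
    met <- binary_metrics(truth_case, pred_case)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth_case, predictor = prob, quiet = TRUE,
      levels = c(FALSE, TRUE), direction = "<")))
    res[j, ] <- c(met["accuracy"], met["sensitivity"], met["specificity"],
                  met["ppv"], met["npv"], auc)
  }
  metrics <- as.data.frame(res)
  metrics$iteration <- seq_len(n_iterations)
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(metrics[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(metrics[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(metrics = metrics, summary = summary,
                 n_iterations = n_iterations,
                 train_fraction = train_fraction, max_depth = max_depth,
                 seed_base = seed_base),
            class = "incl_experiment")
}

#' @export
print.incl_experiment <- function(x, ...) {
  cat(sprintf("<incl_experiment> %d stratified %d/%d hold-out shuffles, depth-%d tree\n",
              x$n_iterations, round(100 * x$train_fraction),
              round(100 * (1 - x$train_fraction)), x$max_depth))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %.3f (sd %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Paired comparison of two experiments
#'
#' Per-metric t-test across iterations of two experiments run with the same
#' seed base (hence identical splits); the default is a paired test, which
#' the shared splits make appropriate.
#'
#' @param table_a,table_b \code{"incl_experiment"} objects with equal
#'   iteration counts.
#' @param paired Use a paired t-test (default TRUE).
#' @return A named numeric vector of p-values (NA where a metric is constant
#'   or undefined).
#' @export
paired_comparison <- function(table_a, table_b, paired = TRUE) {
  stopifnot(inherits(table_a, "incl_experiment"),
            inherits(table_b, "incl_experiment"))
  if (nrow(table_a$metrics) != nrow(table_b$metrics)) {
    stop("experiments must have equal iteration counts", call. = FALSE)
  }
  metric_names <- c("accuracy", "recall", "specificity", "ppv", "npv", "auc")
  vapply(metric_names, function(m) {
    a <- table_a$metrics[[m]]; b <- table_b$metrics[[m]]
    ok <- stats::complete.cases(a, b)
    tryCatch(stats::t.test(a[ok], b[ok], paired = paired)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
}
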