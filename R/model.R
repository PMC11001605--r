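# Classifier, metric and report primitives: random forest scores via ranger,
# rank-based AUC, per-channel impurity importance, and mutual information
# between prediction label vectors.

#' Fit a random forest and score test epochs
#'
#' Probability random forest (impurity importance, library defaults
#' otherwise) trained on a balanced training set; returns the predicted
#' probability of the MW class for each test row.
#'
#' @param x_train,y_train training features and labels (both classes
#'   present, no missing values).
#' @param x_test test features.
#' @param num_trees forest size (default 100, the reference classifier
#'   library's default).
#' @param seed RNG seed for tree growing.
#' @return list with `scores` (P(MW) per test row) and `importance`
#'   (impurity decrease per feature).
#' @export
fit_predict_rf <- function(x_train, y_train, x_test, num_trees = 100,
                           seed = 1L) {
  if (length(unique(y_train)) < 2)
    stop("training data must contain both classes")
  df_train <- data.frame(.y = factor(y_train, levels = c("nonMW", "MW")),
                         x_train, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df_train,
                        probability = TRUE, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  pred <- stats::predict(fit, data.frame(x_test, check.names = FALSE),
                         num.threads = 1)$predictions
  list(scores = pred[, "MW"], importance = fit$variable.importance)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties: the probability
#' that a randomly chosen MW epoch is scored above a randomly chosen non-MW
#' epoch.
#'
#' @param scores numeric prediction scores.
#' @param labels vector with positives coded `"MW"` (or logical/0-1).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels == 1
         else labels == "MW"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean impurity importance per channel
#'
#' Groups per-feature impurity decreases by the channel of each feature
#' descriptor and averages.
#'
#' @param importance named or plain numeric vector, one value per feature
#'   column.
#' @param descriptors data.frame with a `channel` column, one row per
#'   feature column.
#' @return named numeric vector of mean importance per channel.
#' @export
channel_importance <- function(importance, descriptors) {
  if (length(importance) != nrow(descriptors))
    stop("importance length must match the descriptor table")
  means <- tapply(importance, descriptors$channel, mean)
  means[unique(descriptors$channel)]
}

#' Mutual information between two prediction label vectors
#'
#' Plug-in discrete mutual information from the contingency table, in bits.
#' Symmetric; equals the entropy of the vector when both inputs coincide.
#'
#' @param pred_a,pred_b equal-length label vectors.
#' @return mutual information in bits.
#' @export
prediction_mutual_information <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) stop("length mismatch")
  mi_discrete(pred_a, pred_b) / log(2)
}
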