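# Cross-validated prediction of clinical scores (support vector
# regression, leave-one-out) and diagnosis classification (linear SVC,
# stratified 10-fold), with label-permutation significance for the
# regression. Covariate (age) removal and all model fitting happen inside
# each training fold only, so no information leaks into the held-out
# subjects.

# One full LOOCV pass: per fold, regress age out of the features and the
# score with training-fold coefficients, fit a linear epsilon-SVR on the
# residuals, and add the training-fold age prediction back for the held
# out subject. Residualizing both sides makes an age-independent linear
# signal exactly recoverable in the noiseless limit.
svr_loocv_pass <- function(features, score, age, cost, epsilon) {
  n <- length(score)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    xa <- cbind(1, age[tr])
    beta <- solve(crossprod(xa), crossprod(xa, features[tr, , drop = FALSE]))
    gam <- solve(crossprod(xa), crossprod(xa, score[tr]))
    ftr <- features[tr, , drop = FALSE] - xa %*% beta
    str <- score[tr] - as.numeric(xa %*% gam)
    xte <- cbind(1, age[i])
    fte <- features[i, , drop = FALSE] - xte %*% beta
    fit <- e1071::svm(ftr, str, type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    pred[i] <- stats::predict(fit, fte) + as.numeric(xte %*% gam)
  }
  pred
}

#' Leave-one-out SVR prediction of a clinical score
#'
#' Linear epsilon-SVR predicting a clinical score from regional functional
#' features, evaluated by leave-one-out cross-validation. Age is regressed
#' out of the features and the score using coefficients estimated on the
#' training fold only; the held-out prediction adds the training-fold age
#' component back. Significance comes from label permutations of the whole LOOCV
#' loop, using negative rMSE as the statistic:
#' p = (1 + #\{perm rMSE <= observed rMSE\}) / (n_perm + 1).
#'
#' @param features subjects x regions numeric matrix.
#' @param score Clinical score per subject; missing values are dropped
#'   (with a message) together with their feature rows.
#' @param age Age covariate per subject.
#' @param n_perm Label permutations for the p value.
#' @param cost,epsilon Linear SVR hyperparameters (fixed, no tuning).
#' @param seed RNG seed (permutation order).
#' @return Object of class `prediction_result`: `predictions`, `rmse`,
#'   `mean_observed`, `p_perm`, `n_used`, `model_kind` = "SVR".
#' @export
svr_loocv <- function(features, score, age, n_perm = 1000L, cost = 1,
                      epsilon = 0.1, seed = 1L) {
  features <- as.matrix(features)
  keep <- which(!is.na(score))
  n_dropped <- length(score) - length(keep)
  if (n_dropped > 0)
    message(sprintf("dropping %d subject(s) with missing scores", n_dropped))
  features <- features[keep, , drop = FALSE]
  score <- score[keep]; age <- age[keep]
  if (length(score) < 10L) imgtx_stop("need at least 10 scored subjects")
  pred <- svr_loocv_pass(features, score, age, cost, epsilon)
  rmse <- sqrt(mean((pred - score)^2))
  p_perm <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      e <- 0L
      for (i in seq_len(n_perm)) {
        sp <- score[sample.int(length(score))]
        pp <- svr_loocv_pass(features, sp, age, cost, epsilon)
        if (sqrt(mean((pp - sp)^2)) <= rmse) e <- e + 1L
      }
      e
    })
    p_perm <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(predictions = pred, observed = score, rmse = rmse,
                 mean_observed = mean(score), p_perm = p_perm,
                 n_used = length(score), n_perm = n_perm,
                 model_kind = "SVR"),
            class = "prediction_result")
}

# Rank-based AUC (probability a positive outranks a negative).
rank_auc <- function(scores, labels_pos) {
  n1 <- sum(labels_pos); n0 <- sum(!labels_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold SVC classification of diagnosis
#'
#' Linear support-vector classification of the two diagnostic groups from
#' regional functional features, evaluated by stratified k-fold
#' cross-validation (10 folds by default). Reports the mean accuracy and
#' mean rank-based AUC over folds. If the smaller class has fewer subjects
#' than folds, the fold count shrinks with a warning.
#'
#' @param features subjects x regions numeric matrix.
#' @param labels Two-level group labels (cases first level by convention).
#' @param positive Level treated as the positive class for AUC.
#' @param n_folds Number of folds.
#' @param cost Linear SVC regularization parameter.
#' @param seed RNG seed (fold assignment).
#' @return Object of class `prediction_result` with `acc`, `auc`,
#'   `fold_acc`, `fold_auc`, `folds`, `model_kind` = "SVC".
#' @export
svc_cv10 <- function(features, labels, positive = "ASD", n_folds = 10L,
                     cost = 1, seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) imgtx_stop("labels must have exactly 2 levels")
  nmin <- min(table(labels))
  if (nmin < n_folds) {
    n_folds <- max(2L, nmin)
    warning(sprintf("small class: reducing to %d folds", n_folds), call. = FALSE)
  }
  with_seed(seed, {
    folds <- make_stratified_folds(labels, n_folds)
    fold_acc <- fold_auc <- numeric(n_folds)
    pred_all <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                        type = "C-classification", kernel = "linear",
                        cost = cost, scale = FALSE)
      pr <- stats::predict(fit, features[!tr, , drop = FALSE],
                           decision.values = TRUE)
      pred_all[!tr] <- pr
      fold_acc[f] <- mean(pr == labels[!tr])
      dv <- as.numeric(attr(pr, "decision.values"))
      # orient decision values toward the positive class
      if (!startsWith(colnames(attr(pr, "decision.values"))[1], positive))
        dv <- -dv
      fold_auc[f] <- rank_auc(dv, labels[!tr] == positive)
    }
    structure(list(acc = mean(fold_acc), auc = mean(fold_auc, na.rm = TRUE),
                   fold_acc = fold_acc, fold_auc = fold_auc, folds = folds,
                   predictions = pred_all, observed = labels,
                   model_kind = "SVC"),
              class = "prediction_result")
  })
}

#' @export
print.prediction_result <- function(x, ...) {
  if (x$model_kind == "SVR")
    cat(sprintf("<prediction_result> SVR LOOCV: rMSE = %.3f, mean observed = %.3f, p_perm = %s (n = %d)\n",
                x$rmse, x$mean_observed,
                ifelse(is.na(x$p_perm), "NA", format(x$p_perm, digits = 3)),
                x$n_used))
  else
    cat(sprintf("<prediction_result> SVC %d-fold: mean ACC = %.3f, mean AUC = %.3f\n",
                length(x$fold_acc), x$acc, x$auc))
  invisible(x)
}
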