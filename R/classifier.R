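#' Classifier configuration
#'
#' Settings for the per-subject state classifier: a multinomial logistic
#' model with an L2 (ridge) penalty. The objective minimized is
#' \deqn{-\sum_i \log p(y_i | x_i, W, b) + (penalty / 2) ||W||_2^2,}
#' i.e. `penalty` multiplies the squared Frobenius norm of the weight matrix
#' (intercepts unpenalized); the default 0.01 is a very light
#' regularization relative to the ~2000 training samples of a full session.
#'
#' @param penalty L2 regularization strength (> 0), default 0.01.
#' @param chance_level Theoretical chance accuracy, default 0.20 (five
#'   classes).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(penalty = 0.01, chance_level = 0.2) {
  if (penalty <= 0) stop("penalty must be > 0", call. = FALSE)
  if (chance_level <= 0 || chance_level >= 1)
    stop("chance_level must lie in (0, 1)", call. = FALSE)
  structure(list(penalty = penalty, chance_level = chance_level,
                 model = "multinomial logistic, L2 penalty"),
            class = "classifier_config")
}

#' Train a per-subject multinomial state classifier
#'
#' Fits an L2-penalized multinomial logistic regression (ridge,
#' `glmnet(alpha = 0)` at the single fixed lambda implied by the configured
#' penalty) of the five attention states on voxel patterns. The objective is
#' convex and the optimizer tolerance fixed, so refitting the same data gives
#' the same model.
#'
#' @param samples A [labeled_samples()] object with at least two distinct
#'   labels present.
#' @param config A [classifier_config()].
#' @return Object of class `subject_classifier`: `weights` (states x voxels),
#'   `intercepts`, `states`, `config`, `n_train`, `training_folds`.
#' @export
train_state_classifier <- function(samples, config = classifier_config()) {
  stopifnot(inherits(samples, "labeled_samples"),
            inherits(config, "classifier_config"))
  x <- samples$features
  y <- droplevels(samples$labels)
  if (nlevels(y) < 2L)
    stop("training requires at least 2 distinct state labels", call. = FALSE)
  n <- nrow(x)
  # glmnet scales its objective by 1/n; lambda = penalty / n makes
  # n * lambda * ||W||^2 / 2 match the documented (penalty/2)||W||^2 term.
  # A short descending lambda path provides warm starts (the target value is
  # tiny), which keeps convergence robust on weakly structured data.
  lam <- config$penalty / n
  fit <- glmnet::glmnet(
    x, y, family = "multinomial", alpha = 0,
    lambda = lam * c(10000, 1000, 100, 10, 1),
    standardize = FALSE, intercept = TRUE, thresh = 1e-10, maxit = 1e6,
    type.multinomial = "ungrouped")
  co <- glmnet::coef.glmnet(fit, s = lam, exact = FALSE)
  present <- levels(y)
  p <- ncol(x)
  all_states <- attention_states()
  weights <- matrix(0, length(all_states), p,
                    dimnames = list(all_states, NULL))
  intercepts <- stats::setNames(rep(-Inf, length(all_states)), all_states)
  for (s in present) {
    v <- as.numeric(co[[s]])
    intercepts[s] <- v[1]
    weights[s, ] <- v[-1]
  }
  structure(list(weights = weights, intercepts = intercepts,
                 states = all_states, present_states = present,
                 config = config, n_train = n,
                 training_folds = sprintf("blocks {%s}",
                                          paste(sort(unique(samples$blocks)),
                                                collapse = ","))),
            class = "subject_classifier")
}

#' @export
print.subject_classifier <- function(x, ...) {
  cat(sprintf(
    "<subject_classifier> %d states x %d voxels, penalty = %g, n = %d (%s)\n",
    length(x$present_states), ncol(x$weights), x$config$penalty, x$n_train,
    x$training_folds))
  invisible(x)
}

#' Class probabilities for new voxel patterns
#'
#' Softmax over the linear scores `intercept_k + x . w_k`. Absent training
#' classes receive probability 0. Rows sum to 1.
#'
#' @param classifier A [train_state_classifier()] result.
#' @param x Matrix (TRs x voxels) or single pattern vector.
#' @return Matrix of probabilities, one row per input row, columns in
#'   [attention_states()] order.
#' @export
predict_state_probs <- function(classifier, x) {
  stopifnot(inherits(classifier, "subject_classifier"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(classifier$weights))
    stop(sprintf("voxel count mismatch: input has %d, classifier expects %d",
                 ncol(x), ncol(classifier$weights)), call. = FALSE)
  z <- x %*% t(classifier$weights) +
    matrix(classifier$intercepts, nrow(x), length(classifier$states),
           byrow = TRUE)
  z <- z - apply(z, 1, max)          # log-sum-exp stabilization
  ez <- exp(z)
  pr <- ez / rowSums(ez)
  dimnames(pr) <- list(NULL, classifier$states)
  pr
}

# argmax with deterministic tie-breaking by column (state) order; ties logged
decide_states <- function(probs, states = colnames(probs)) {
  dec <- apply(probs, 1, which.max)
  n_ties <- sum(apply(probs, 1, function(r) sum(r == max(r)) > 1L))
  if (n_ties > 0L)
    message(sprintf(
      "decide_states: %d TR(s) had tied maxima; broken by state order (%s)",
      n_ties, paste(states, collapse = " < ")))
  factor(states[dec], levels = states)
}

#' Leave-one-block-out cross-validation of the state classifier
#'
#' Folds are the task blocks: each block is held out once, the classifier is
#' retrained on the remaining blocks, and every held-out TR is predicted
#' exactly once. Decisions are aggregated over all folds into a 5x5 confusion
#' matrix, per-condition accuracies, and per-condition chi-square tests
#' against chance ([accuracy_vs_chance_chisq()]).
#'
#' @inheritParams train_state_classifier
#' @param alpha Per-condition significance level used for the eligibility
#'   flag (default 0.001).
#' @return Object of class `accuracy_report`: `per_condition_accuracy`,
#'   `confusion_matrix` (true x predicted), `per_condition_chisq`,
#'   `per_condition_chisq_p`, `n_per_condition`, `eligible`, `chance_level`,
#'   and `predictions` (per-sample data.frame with block, trial id, true and
#'   predicted state and class probabilities).
#' @export
crossvalidate_by_block <- function(samples, config = classifier_config(),
                                   alpha = 0.001) {
  stopifnot(inherits(samples, "labeled_samples"))
  blocks <- sort(unique(samples$blocks))
  if (length(blocks) < 2L)
    stop("cross-validation needs >= 2 blocks; supply a multi-block session",
         call. = FALSE)
  states <- attention_states()
  n <- nrow(samples$features)
  pred <- factor(rep(NA_character_, n), levels = states)
  probs <- matrix(NA_real_, n, length(states),
                  dimnames = list(NULL, states))
  for (b in blocks) {
    held <- samples$blocks == b
    train <- labeled_samples(samples$features[!held, , drop = FALSE],
                             samples$labels[!held],
                             samples$blocks[!held],
                             samples$trial_ids[!held])
    clf <- train_state_classifier(train, config)
    pr <- predict_state_probs(clf, samples$features[held, , drop = FALSE])
    probs[held, ] <- pr
    pred[held] <- decide_states(pr)
  }
  confusion <- table(true = samples$labels, predicted = pred)
  confusion <- unclass(confusion)[states, states]
  n_per <- rowSums(confusion)
  acc <- ifelse(n_per > 0, diag(confusion) / n_per, NA_real_)
  chisq <- vapply(states, function(s) {
    if (n_per[s] == 0) return(c(NA_real_, NA_real_))
    unlist(accuracy_vs_chance_chisq(confusion[s, s], n_per[s],
                                    config$chance_level))
  }, numeric(2))
  report <- structure(list(
    per_condition_accuracy = acc,
    confusion_matrix = confusion,
    per_condition_chisq = chisq[1, ],
    per_condition_chisq_p = chisq[2, ],
    n_per_condition = n_per,
    chance_level = config$chance_level,
    eligible = NA,
    predictions = data.frame(
      sample = seq_len(n), block = samples$blocks,
      trial_id = samples$trial_ids,
      true = samples$labels, predicted = pred,
      correct = samples$labels == pred, probs)),
    class = "accuracy_report")
  report$eligible <- eligibility_check(report, alpha = alpha)
  report
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> leave-one-block-out cross-validation\n")
  print(round(100 * x$per_condition_accuracy, 1))
  cat(sprintf("chance = %g%%, eligible (meditation states): %s\n",
              100 * x$chance_level, x$eligible))
  invisible(x)
}

#' Chi-square goodness-of-fit test of accuracy against chance
#'
#' One-degree-of-freedom test of observed (correct, incorrect) counts against
#' the expectation `(chance, 1 - chance) * n_total`, without continuity
#' correction (immaterial at hundreds of samples per condition).
#'
#' @param n_correct Number of correct decisions (0..n_total).
#' @param n_total Number of decisions (> 0).
#' @param chance Chance probability in (0, 1).
#' @return List with `chisq` and `p` (upper tail of the 1-df chi-square
#'   distribution).
#' @export
accuracy_vs_chance_chisq <- function(n_correct, n_total, chance = 0.2) {
  if (chance <= 0 || chance >= 1)
    stop("chance must lie in (0, 1)", call. = FALSE)
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (n_correct < 0 || n_correct > n_total)
    stop("n_correct must lie in [0, n_total]", call. = FALSE)
  expected <- c(chance, 1 - chance) * n_total
  observed <- c(n_correct, n_total - n_correct)
  chisq <- sum((observed - expected)^2 / expected)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Per-subject eligibility rule for meditation decoding
#'
#' A subject's classifier qualifies for decoding the meditation period when
#' at least `n_required` of the three meditation-relevant conditions (Breath,
#' MW, Self) are classified above chance with a chi-square p-value below
#' `alpha`.
#'
#' @param report An [crossvalidate_by_block()] accuracy report.
#' @param alpha Significance threshold (default 0.001).
#' @param n_required How many of the three conditions must pass (default 2).
#' @return Logical flag.
#' @export
eligibility_check <- function(report, alpha = 0.001, n_required = 2L) {
  stopifnot(inherits(report, "accuracy_report"))
  need <- meditation_states()
  acc <- report$per_condition_accuracy[need]
  p <- report$per_condition_chisq_p[need]
  if (anyNA(acc) || anyNA(p))
    stop("report lacks Breath/MW/Self entries needed for eligibility",
         call. = FALSE)
  sum(acc > report$chance_level & p < alpha) >= n_required
}

#' Per-trial accuracy from cross-validated predictions
#'
#' Fraction of each trial's TR decisions that match the true condition; the
#' finest trial-level aggregation of TR decisions.
#'
#' @param report An [crossvalidate_by_block()] accuracy report.
#' @return data.frame with `trial_id`, `condition`, `n_trs`, `accuracy`.
#' @export
trial_accuracy <- function(report) {
  stopifnot(inherits(report, "accuracy_report"))
  pr <- report$predictions
  agg <- stats::aggregate(correct ~ trial_id + true, data = pr,
                          FUN = function(z) c(mean(z), length(z)))
  data.frame(trial_id = agg$trial_id, condition = agg$true,
             n_trs = agg$correct[, 2], accuracy = agg$correct[, 1])
}

#' Within-subject association of trial accuracy and attention ratings
#'
#' Pearson correlation between per-trial classification accuracy and the
#' subjective attention rating (1-4) over rated trials. MW trials are never
#' rated and so never enter. If either series is constant, the correlation is
#' undefined: the function returns `NA` with a logged explanation rather
#' than erroring, so group aggregation can skip the subject.
#'
#' @param trial_accuracy Numeric vector of per-trial accuracies.
#' @param ratings Paired integer ratings 1-4 (`NA` pairs are dropped).
#' @return List with `r` (Pearson correlation or `NA`) and `n_trials`.
#' @export
rating_accuracy_association <- function(trial_accuracy, ratings) {
  if (length(trial_accuracy) != length(ratings))
    stop("trial_accuracy and ratings must have equal length", call. = FALSE)
  keep <- !is.na(trial_accuracy) & !is.na(ratings)
  a <- trial_accuracy[keep]; r <- ratings[keep]
  if (length(a) < 3L)
    stop("need at least 3 rated trials", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(r) == 0) {
    message("rating_accuracy_association: zero variance in one series; ",
            "correlation undefined")
    return(list(r = NA_real_, n_trials = length(a)))
  }
  list(r = stats::cor(a, r), n_trials = length(a))
}
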