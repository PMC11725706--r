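#' Default posture feature specification
#'
#' Maps taxon feature records to the discriminant feature space: log10 body
#' mass, dimensionless COM (craniad offset over gleno-acetabular distance),
#' and forelimb/hindlimb length ratio. Supply any function mapping a record
#' data frame to a numeric matrix to use other features.
#'
#' @param records data frame with columns `mass_kg`, `com_per_ga`,
#'   `forelimb_m`, `hindlimb_m`.
#' @return Numeric matrix, one row per record.
#' @export
posture_features <- function(records) {
  cbind(log10_mass = log10(records$mass_kg),
        com_per_ga = records$com_per_ga,
        limb_ratio = records$forelimb_m / records$hindlimb_m)
}

#' Fit a two-class pooled-covariance linear discriminant
#'
#' Gaussian equal-covariance LDA from formulas: class means, pooled
#' (within-class) covariance, weight vector `w = solve(Sigma, mu1 - mu0)`
#' and midpoint intercept `c = w' (mu0 + mu1) / 2`. A record is classified
#' to class 1 iff `w'x - c + log(pi1/pi0) > 0`. Used here for the
#' bipedal (class 1) versus quadrupedal (class 0) posture vote.
#'
#' @param records labeled record data frame (see [posture_features()]) with
#'   a `posture` column, or a numeric feature matrix.
#' @param labels class labels (required when `records` is a matrix);
#'   coerced to factor, first level = class 0.
#' @param feature_spec function mapping records to a feature matrix
#'   (default [posture_features()]); ignored for matrix input.
#' @param priors `"frequency"` (class frequencies, default), `"equal"`, or
#'   a numeric length-2 vector summing to 1.
#' @param ridge non-negative scalar added to the pooled covariance diagonal
#'   (times its mean diagonal) to regularize near-singular fits.
#' @return Object of class `"lda_posture"`: `means` (2 x p), `cov`, `w`,
#'   `intercept`, `priors`, `levels`, `feature_spec`.
#' @export
fit_lda <- function(records, labels = NULL, feature_spec = posture_features,
                    priors = "frequency", ridge = 0) {
  if (is.matrix(records)) {
    x <- records
    if (is.null(labels)) stop("labels required for matrix input")
    feature_spec <- NULL
  } else {
    x <- feature_spec(records)
    labels <- labels %||% records$posture
  }
  if (ridge < 0) stop("ridge must be >= 0")
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("exactly two classes required")
  if (any(table(g) < 2L))
    stop("each class needs >= 2 records")
  if (!all(is.finite(x))) stop("features must be finite")
  n <- nrow(x)
  mu <- rbind(colMeans(x[g == levels(g)[1L], , drop = FALSE]),
              colMeans(x[g == levels(g)[2L], , drop = FALSE]))
  centered <- x - mu[as.integer(g), , drop = FALSE]
  Sigma <- crossprod(centered) / (n - 2L)
  if (ridge > 0) {
    scale <- mean(diag(Sigma))
    if (scale <= 0) scale <- 1
    Sigma <- Sigma + diag(ridge * scale, ncol(x))
  }
  ok <- tryCatch({chol(Sigma); TRUE},
                 error = function(e) FALSE)
  if (!ok)
    stop("pooled covariance is singular; refit with ridge > 0")
  w <- solve(Sigma, mu[2L, ] - mu[1L, ])
  intercept <- sum(w * (mu[1L, ] + mu[2L, ])) / 2
  pri <- if (is.numeric(priors)) {
    if (length(priors) != 2L || abs(sum(priors) - 1) > 1e-8)
      stop("numeric priors must be length 2 and sum to 1")
    priors
  } else if (match.arg(priors, c("frequency", "equal")) == "equal") {
    c(0.5, 0.5)
  } else {
    as.numeric(table(g) / n)
  }
  structure(list(means = mu, cov = Sigma, w = w, intercept = intercept,
                 priors = pri, levels = levels(g),
                 feature_spec = feature_spec),
            class = "lda_posture")
}

#' @export
print.lda_posture <- function(x, ...) {
  cat(sprintf("two-class LDA: %s (0) vs %s (1), %d features\n",
              x$levels[1L], x$levels[2L], length(x$w)))
  cat("w:", sprintf("%.4g", x$w), "  priors:",
      sprintf("%.3g", x$priors), "\n")
  invisible(x)
}

#' @export
coef.lda_posture <- function(object, ...) {
  c(object$w, intercept = -object$intercept +
      log(object$priors[2L] / object$priors[1L]))
}

#' Predict posture class and posterior probability
#'
#' Deterministic Gaussian equal-covariance posterior:
#' `p1 = plogis(w'x - c + log(pi1/pi0))`.
#'
#' @param object a fitted `"lda_posture"`.
#' @param newdata record data frame (run through the stored feature spec)
#'   or numeric feature matrix/vector.
#' @param ... unused.
#' @return Data frame: `label`, `posterior` (probability of class 1) and
#'   `score` (the discriminant including the prior term).
#' @export
predict.lda_posture <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    if (is.null(object$feature_spec))
      stop("model was fitted on a matrix; supply a feature matrix")
    object$feature_spec(newdata)
  } else if (is.null(dim(newdata))) {
    matrix(newdata, nrow = 1L)
  } else {
    as.matrix(newdata)
  }
  if (ncol(x) != length(object$w))
    stop("feature dimension mismatch: got ", ncol(x), ", expected ",
         length(object$w))
  score <- as.numeric(x %*% object$w) - object$intercept +
    log(object$priors[2L] / object$priors[1L])
  posterior <- stats::plogis(score)
  data.frame(label = object$levels[1L + (score > 0)],
             posterior = posterior, score = score)
}

#' Posture vote over repeated training sets
#'
#' Re-fits the discriminant once per training set and predicts the target
#' with each, tallying votes for the bipedal class — the structure of the
#' published repeated-training-set procedure (22 training datasets; the
#' composition of the originals lives in prior work, so any list of
#' training sets is accepted and a synthetic generator ships alongside).
#'
#' @param training_sets list of labeled record data frames (or of
#'   `list(x = matrix, labels = ...)`).
#' @param target one unlabeled record (data frame row or feature vector).
#' @param feature_spec passed to [fit_lda()].
#' @param bipedal_level label counted as the bipedal vote (default
#'   `"bipedal"`).
#' @param strict error on an unfittable training set (default `FALSE`:
#'   record an abstention with the reason).
#' @param ... further arguments to [fit_lda()] (priors, ridge).
#' @return List: `votes` (bipedal votes), `n_sets`, `posteriors` (per-set
#'   bipedal posterior, `NA` for abstentions), `abstentions` (reasons).
#' @export
vote_over_trainings <- function(training_sets, target,
                                feature_spec = posture_features,
                                bipedal_level = "bipedal", strict = FALSE,
                                ...) {
  if (!is.list(training_sets) || length(training_sets) == 0L)
    stop("need at least one training set")
  n <- length(training_sets)
  posteriors <- rep(NA_real_, n)
  votes <- 0L
  abst <- character(0)
  for (i in seq_len(n)) {
    ts <- training_sets[[i]]
    fit <- tryCatch(
      if (is.data.frame(ts)) fit_lda(ts, feature_spec = feature_spec, ...)
      else fit_lda(ts$x, labels = ts$labels, ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (strict) stop("training set ", i, " unfittable: ",
                       conditionMessage(fit))
      abst <- c(abst, sprintf("set %d: %s", i, conditionMessage(fit)))
      next
    }
    pr <- predict(fit, target)
    p_biped <- if (fit$levels[2L] == bipedal_level) pr$posterior
               else 1 - pr$posterior
    posteriors[i] <- p_biped
    if (p_biped > 0.5) votes <- votes + 1L
  }
  list(votes = votes, n_sets = n, posteriors = posteriors,
       abstentions = abst)
}
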