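test_that("1-D equal-prior LDA puts the boundary at the midpoint of means", {
  x <- matrix(c(-1.2, -1.0, -0.8, -1.1, 0.8, 1.0, 1.2, 1.1), ncol = 1)
  g <- factor(rep(c("quadrupedal", "bipedal"), each = 4),
              levels = c("quadrupedal", "bipedal"))
  fit <- fit_lda(x, labels = g, priors = "equal")
  m0 <- mean(x[1:4]); m1 <- mean(x[5:8])
  boundary <- (m0 + m1) / 2
  eps <- 1e-9
  expect_equal(predict(fit, boundary + eps)$label, "bipedal")
  expect_equal(predict(fit, boundary - eps)$label, "quadrupedal")
  expect_equal(predict(fit, boundary)$posterior, 0.5, tolerance = 1e-9)
})

test_that("well-separated Gaussian classes are classified perfectly", {
  # 6 pooled-SD separation, n = 50 per class
  rec <- make_posture_features(
    n_per_class = 50,
    means = rbind(c(1.5, 0.35, 0.90), c(1.5 + 6 * 0.2, 0.35, 0.90)),
    cov = diag(c(0.04, 0.004, 0.01)), seed = 10)
  fit <- fit_lda(rec)
  pred <- predict(fit, rec)
  expect_equal(mean(pred$label == rec$posture), 1.0)
  # a target at the bipedal prototype is called bipedal with confidence
  proto <- rec[rec$posture == "bipedal", ]
  target <- proto[1, ]
  target$mass_kg <- 10^mean(log10(proto$mass_kg))
  target$com_per_ga <- mean(proto$com_per_ga)
  target$forelimb_m <- mean(proto$forelimb_m / proto$hindlimb_m) * 0.32
  target$hindlimb_m <- 0.32
  p <- predict(fit, target)
  expect_equal(p$label, "bipedal")
  expect_gt(p$posterior, 0.99)
})

test_that("identical class means leave the posterior at the priors", {
  rec <- make_posture_features(
    n_per_class = c(1500, 500),
    means = rbind(c(1.4, 0.3, 0.7), c(1.4, 0.3, 0.7)),
    cov = diag(c(0.04, 0.004, 0.01)), seed = 11)
  fit <- fit_lda(rec, priors = "frequency")
  pred <- predict(fit, rec)
  # prior for class 1 (bipedal) is 0.25
  expect_lt(max(abs(pred$posterior - 0.25)), 0.05)
})

test_that("posteriors match the reference LDA implementation to 1e-6", {
  rec <- make_posture_features(n_per_class = 60, seed = 12)
  fit <- fit_lda(rec, priors = "frequency")
  x <- posture_features(rec)
  oracle <- MASS::lda(x, grouping = factor(rec$posture))
  test <- make_posture_features(n_per_class = 50, seed = 13)
  xt <- posture_features(test)
  p_mine <- predict(fit, test)$posterior
  p_oracle <- predict(oracle, xt)$posterior[, fit$levels[2]]
  expect_lt(max(abs(p_mine - p_oracle)), 1e-6)
  expect_equal(predict(fit, test)$label,
               as.character(predict(oracle, xt)$class))
})

test_that("affine feature rescaling leaves predicted labels unchanged", {
  rec <- make_posture_features(n_per_class = 40, seed = 14)
  x <- posture_features(rec)
  g <- rec$posture
  fit1 <- fit_lda(x, labels = g)
  A <- diag(c(10, 0.2, 3))
  b <- c(-5, 2, 0.7)
  x2 <- sweep(x %*% A, 2, b, `+`)
  fit2 <- fit_lda(x2, labels = g)
  t1 <- posture_features(make_posture_features(n_per_class = 30, seed = 15))
  t2 <- sweep(t1 %*% A, 2, b, `+`)
  expect_equal(predict(fit1, t1)$label, predict(fit2, t2)$label)
  expect_equal(predict(fit1, t1)$posterior, predict(fit2, t2)$posterior,
               tolerance = 1e-8)
})

test_that("large-sample fits recover the generating parameters", {
  mu <- rbind(c(1.5, 0.35, 0.90), c(1.2, 0.25, 0.55))
  Sg <- diag(c(0.04, 0.004, 0.01))
  rec <- make_posture_features(n_per_class = 5000, means = mu, cov = Sg,
                               seed = 16)
  fit <- fit_lda(rec)
  # class means within 3 standard errors
  se <- sqrt(diag(Sg) / 5000)
  expect_true(all(abs(fit$means[1, ] - mu[1, ]) < 3 * se))
  expect_true(all(abs(fit$means[2, ] - mu[2, ]) < 3 * se))
  # pooled covariance within 5% Frobenius norm
  expect_lt(norm(fit$cov - Sg, "F") / norm(Sg, "F"), 0.05)
})

test_that("overlapping classes approach the Bayes error of the mixture", {
  # 1 pooled-SD separation in one dimension: Bayes accuracy pnorm(0.5)
  mu <- rbind(c(1.5, 0.35, 0.90), c(1.5 + 0.2, 0.35, 0.90))
  rec <- make_posture_features(n_per_class = 2500, means = mu,
                               cov = diag(c(0.04, 0.004, 0.01)), seed = 17)
  fit <- fit_lda(rec)
  acc <- mean(predict(fit, rec)$label == rec$posture)
  expect_lt(abs(acc - pnorm(0.5)), 0.02)
})

test_that("degenerate fits are rejected with actionable errors", {
  x <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4), ncol = 2)  # second col = first
  g <- c("a", "a", "b", "b")
  expect_error(fit_lda(x, labels = g), "ridge")
  expect_silent(fit_lda(x, labels = g, ridge = 1e-6))
  expect_error(fit_lda(x[1:3, ], labels = c("a", "a", "b")), ">= 2 records")
  fit <- fit_lda(make_posture_features(n_per_class = 10, seed = 18))
  expect_error(predict(fit, matrix(1, 1, 2)), "dimension mismatch")
})

test_that("the voting harness tallies per-training-set predictions", {
  rec <- make_posture_features(n_per_class = 30, seed = 19)
  # identical training sets vote identically
  v <- vote_over_trainings(rep(list(rec), 5),
                           rec[rec$posture == "bipedal", ][1, ])
  expect_true(v$votes %in% c(0L, 5L))
  expect_equal(length(unique(round(v$posteriors, 12))), 1L)
  expect_error(vote_over_trainings(list(), rec[1, ]), "at least one")

  # 22 seeded resampled training sets; target at the bipedal mean
  mu <- rbind(c(1.5, 0.35, 0.90), c(1.2, 0.25, 0.55))
  sets <- lapply(1:22, function(i)
    make_posture_features(n_per_class = 40, means = mu, seed = 200 + i))
  target <- data.frame(taxon = "proto", mass_kg = 10^mu[2, 1],
                       com_per_ga = mu[2, 2],
                       forelimb_m = mu[2, 3] * 0.32, hindlimb_m = 0.32)
  v22 <- vote_over_trainings(sets, target)
  expect_equal(v22$n_sets, 22L)
  expect_gte(v22$votes, 20L)

  # an unfittable set becomes an abstention unless strict
  broken <- c(sets[1:3], list(rec[1:3, ]))
  v4 <- vote_over_trainings(broken, target)
  expect_equal(length(v4$abstentions), 1L)
  expect_error(vote_over_trainings(broken, target, strict = TRUE),
               "unfittable")
})

test_that("the shipped feature fixture carries both published record sets", {
  f <- load_fixture_yaml(paleomech_example("riojasuchus_features.yaml"))
  recs <- f$records
  expect_equal(length(recs), 2L)
  this_model <- recs[[1]]
  expect_equal(this_model$mass_kg, 24.56)
  expect_equal(this_model$com_craniad_m / this_model$ga_m, 0.0986 / 0.355)
  alt <- recs[[2]]
  expect_equal(alt$mass_kg, 13.55)
  expect_equal(alt$ga_m, 0.400)
})
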