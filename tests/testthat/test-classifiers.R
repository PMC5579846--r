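make_gaussian_classes <- function(n, mu, sd = 1, seed = 1) {
  set.seed(seed)
  K <- nrow(mu)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n * ncol(mu), 0, sd), n), 2, mu[k, ], "+")))
  list(x = x, y = rep(letters[seq_len(K)], each = n))
}

test_that("Gaussian MAP recovers parameters and reduces to nearest mean", {
  mu <- rbind(c(0, 0), c(3, 1))
  d <- make_gaussian_classes(5000, mu, sd = 1, seed = 51)
  model <- bdm_fit(d$x, d$y)
  se <- 1 / sqrt(5000)
  for (k in 1:2)
    expect_true(all(abs(model$models[[k]]$mean - mu[k, ]) < 3 * se))

  # shared spherical covariance + equal priors == nearest class mean
  d2 <- make_gaussian_classes(40, rbind(c(0, 0), c(4, 0), c(0, 4)), seed = 52)
  m2 <- bdm_fit(d2$x, d2$y)
  # overwrite with exactly shared spherical covariances
  for (k in 1:3) m2$models[[k]]$chol <- chol(diag(2))
  test <- matrix(rnorm(100, 1, 2), 50, 2)
  centers <- t(vapply(m2$models, `[[`, numeric(2), "mean"))
  nearest <- m2$classes[apply(test, 1, function(p)
    which.min(colSums((t(centers) - p)^2)))]
  expect_identical(bdm_predict(m2, test), nearest)
})

test_that("degenerate class covariance is ridged into a finite model", {
  x <- rbind(c(1, 2), c(1, 2), c(5, 6), c(5.1, 6.2))
  y <- c("a", "a", "b", "b")
  model <- bdm_fit(x, y)   # class a has zero covariance
  expect_true(all(is.finite(model$models[[1]]$chol)))
  expect_identical(bdm_predict(model, rbind(c(1, 2), c(5, 6))), c("a", "b"))
  expect_error(bdm_fit(x[c(1, 3, 4), ], y[c(1, 3, 4)]), "fewer than 2")
})

test_that("1-D two-class boundary sits at the midpoint and shifts with priors", {
  # equal priors, equal variance: boundary at the midpoint of the means
  model <- structure(list(
    classes = c("a", "b"),
    models = list(list(mean = 0, chol = matrix(1), prior = 0.5),
                  list(mean = 2, chol = matrix(1), prior = 0.5)),
    M = 1L), class = "bdm_model")
  eps <- 1e-6
  expect_identical(bdm_predict(model, matrix(1 - eps)), "a")
  expect_identical(bdm_predict(model, matrix(1 + eps)), "b")
  # doubling one prior moves the boundary by sigma^2 ln 2 / delta-mu
  model$models[[1]]$prior <- 2 / 3
  model$models[[2]]$prior <- 1 / 3
  shift <- log(2) / 2
  expect_identical(bdm_predict(model, matrix(1 + shift - eps)), "a")
  expect_identical(bdm_predict(model, matrix(1 + shift + eps)), "b")
})

test_that("k-NN matches an exhaustive recount of the 7 nearest neighbors", {
  set.seed(53)
  train_x <- matrix(rnorm(400), 100, 4)
  train_y <- sample(c("u", "v", "w"), 100, replace = TRUE)
  test_x <- matrix(rnorm(400), 100, 4)
  got <- knn_predict(train_x, train_y, test_x, k = 7)
  oracle <- vapply(seq_len(nrow(test_x)), function(i) {
    d <- sqrt(colSums((t(train_x) - test_x[i, ])^2))
    nn <- order(d)[1:7]
    tabv <- table(train_y[nn])
    top <- names(tabv)[tabv == max(tabv)]
    if (length(top) == 1) return(top)
    md <- vapply(top, function(cl) mean(d[nn][train_y[nn] == cl]), numeric(1))
    sort(top[md == min(md)])[1]
  }, character(1))
  expect_identical(got, oracle)

  # k = 1 on a training point returns that point's class
  expect_identical(knn_predict(train_x, train_y, train_x[3, , drop = FALSE], 1),
                   train_y[3])
  expect_error(knn_predict(train_x, train_y, test_x, k = 101), "exceeds")
})

test_that("one-vs-one SVM trains K(K-1)/2 machines and separates a toy", {
  d <- make_gaussian_classes(30, rbind(c(0, 0), c(5, 0), c(0, 5)),
                             sd = 0.5, seed = 54)
  model <- svm_train(d$x, d$y)
  expect_length(model$machines, 3L)
  expect_identical(svm_predict(model, d$x), d$y)
  expect_identical(svm_predict(model, d$x, fusion = "confidence"), d$y)
  expect_error(svm_train(d$x[1:30, ], d$y[1:30]), "at least 2 classes")
  cfg <- classifier_config()
  expect_equal(cfg$C, 40)
  expect_equal(cfg$gamma, 0.2)
  expect_equal(cfg$k, 7L)
})

test_that("hidden layer sizing rounds half up on the two-bound average", {
  expect_identical(hidden_neuron_count(19), 21L)
  expect_identical(hidden_neuron_count(6), 7L)
  expect_identical(hidden_neuron_count(2), 3L)   # 2.5 rounds up
  expect_error(hidden_neuron_count(1), "at least 2")
})

test_that("adaptive stopping fires exactly when 10 epochs stop improving", {
  flat <- rep(0.5, 20)
  fired_at <- which(vapply(seq_along(flat), function(i)
    ann_should_stop(flat[1:i]), logical(1)))[1]
  expect_identical(fired_at, 11L)
  # a steadily improving error never triggers the rule
  improving <- seq(1, 0.01, length.out = 40)
  expect_false(any(vapply(11:40, function(i)
    ann_should_stop(improving[1:i]), logical(1))))
})

test_that("perceptron training is deterministic and learns a margin toy", {
  d <- make_gaussian_classes(50, rbind(c(0, 0), c(3, 3)), sd = 0.5, seed = 55)
  cfg <- classifier_config(seed = 7)
  m1 <- ann_train(d$x, d$y, cfg)
  m2 <- ann_train(d$x, d$y, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_gte(mean(ann_predict(m1, d$x) == d$y), 0.95)
  expect_identical(m1$H, hidden_neuron_count(2))
})

test_that("perceptron forward pass matches a hand computation", {
  model <- structure(list(
    classes = c("a", "b"),
    W1 = rbind(c(0.1, 1, -1), c(-0.2, 0.5, 0.5)),   # 2 hidden, bias first
    W2 = rbind(c(0, 2, -1), c(0.3, -1, 2)),
    M = 2L, H = 2L), class = "ann_model")
  x <- c(0.4, -0.3)
  h <- 1 / (1 + exp(-(model$W1 %*% c(1, x))))
  o <- 1 / (1 + exp(-(model$W2 %*% c(1, h))))
  expect_true(all(o > 0 & o < 1))
  expect_identical(ann_predict(model, matrix(x, 1)),
                   model$classes[which.max(o)])
})

test_that("all four classifiers separate an easy task and sit at chance on noise", {
  # feature scale mimics the pipeline's classifier input: [0, 1]-normalized
  # features after PCA, where the pinned SVM and perceptron settings operate
  set.seed(56)
  M <- 30
  mu <- matrix(runif(3 * M, 0.2, 0.8), 3)
  d <- make_gaussian_classes(100, mu, sd = 0.08, seed = 56)
  cfg <- classifier_config(seed = 2)
  idx <- sample(300, 150)
  # labels shuffled over the whole set: the truth used for scoring is then
  # independent of the features, so accuracy must sit at chance (1/K)
  ysh <- sample(d$y)
  for (cl in c("bdm", "knn", "svm", "ann")) {
    model <- oimotion:::fit_classifier(cl, d$x[idx, ], d$y[idx], cfg)
    acc <- mean(oimotion:::predict_classifier(cl, model, d$x[-idx, ]) ==
                  d$y[-idx])
    expect_gte(acc, 0.9)
    msh <- oimotion:::fit_classifier(cl, d$x[idx, ], ysh[idx], cfg)
    accsh <- mean(oimotion:::predict_classifier(cl, msh, d$x[-idx, ]) ==
                    ysh[-idx])
    expect_lt(abs(accsh - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 150))
  }
})
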