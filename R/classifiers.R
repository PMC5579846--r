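## The four classifiers of the evaluation pipeline, with pinned
## hyperparameters: Gaussian MAP ("Bayesian decision making"), k-NN (k = 7),
## one-vs-one RBF SVM (C = 40, gamma = 0.2), and a single-hidden-layer
## sigmoid perceptron trained by online back-propagation with an adaptive
## stopping rule.  All tie-breaks are deterministic (class declaration
## order) for reproducibility.

#' Classifier configuration with pinned defaults
#'
#' @param k Neighbors for k-NN (default 7).
#' @param C SVM penalty (default 40).
#' @param gamma RBF kernel width (default 0.2).
#' @param learning_rate Online back-propagation step (default 0.3).
#' @param init_range Uniform weight initialization interval (default
#'   `c(0, 0.2)`).
#' @param stop_delta,stop_window Adaptive stopping rule: stop at epoch `i`
#'   when the smallest of the last `stop_window` epoch errors fails to
#'   undercut the error `stop_window` epochs earlier by `stop_delta`
#'   (defaults 0.01 and 10).
#' @param max_epochs Safety cap on training epochs (default 1000).
#' @param seed Seed for weight initialization and per-epoch shuffling.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(k = 7L, C = 40, gamma = 0.2,
                              learning_rate = 0.3, init_range = c(0, 0.2),
                              stop_delta = 0.01, stop_window = 10L,
                              max_epochs = 1000L, seed = 1L) {
  stopifnot(k >= 1L, C > 0, gamma > 0, length(init_range) == 2L,
            stop_window >= 1L, max_epochs > stop_window)
  structure(list(k = as.integer(k), C = C, gamma = gamma,
                 learning_rate = learning_rate, init_range = init_range,
                 stop_delta = stop_delta, stop_window = as.integer(stop_window),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "classifier_config")
}

## ---- Gaussian MAP (BDM) ---------------------------------------------------

#' Fit a Gaussian maximum a posteriori classifier
#'
#' Per class, the maximum-likelihood mean vector and covariance matrix
#' (normalized by n) are estimated; priors are the empirical class
#' frequencies. A covariance whose Cholesky factorization fails is ridged by
#' `eps * (trace / M)` on the diagonal, with `eps = 1e-6` escalated tenfold
#' until positive definite.
#'
#' @param x Numeric matrix (rows = training vectors).
#' @param y Class labels (coerced to character).
#' @return An object of class `bdm_model`.
#' @export
bdm_fit <- function(x, y) {
  x <- as.matrix(x); y <- as.character(y)
  classes <- sort(unique(y))
  M <- ncol(x)
  models <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    n <- nrow(xi)
    if (n < 2L) stop("class '", cl, "' has fewer than 2 training rows")
    mu <- colMeans(xi)
    cc <- sweep(xi, 2L, mu, "-")
    S <- crossprod(cc) / n
    eps <- 1e-6
    repeat {
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(ch) && all(diag(ch) > 0)) break
      base <- sum(diag(S)) / M
      if (base <= 0) base <- 1       # all-zero covariance: absolute ridge
      S <- S + diag(eps * base, M)
      eps <- eps * 10
    }
    list(mean = mu, chol = ch, prior = n / nrow(x))
  })
  structure(list(classes = classes, models = models, M = M),
            class = "bdm_model")
}

#' Classify with a Gaussian MAP model
#'
#' Picks the class maximizing log prior + Gaussian log density; ties resolve
#' to the earlier class in sorted order.
#'
#' @param model A [bdm_fit()] model.
#' @param x Numeric matrix of test rows.
#' @return Character vector of predicted labels.
#' @export
bdm_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$M)
    stop("test rows have ", ncol(x), " columns; model expects ", model$M)
  scores <- vapply(model$models, function(m) {
    z <- forwardsolve(t(m$chol), t(sweep(x, 2L, m$mean, "-")))
    -0.5 * colSums(z * z) - sum(log(diag(m$chol))) + log(m$prior)
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  model$classes[apply(scores, 1L, which.max)]
}

## ---- k-nearest neighbors --------------------------------------------------

#' k-nearest-neighbor classification
#'
#' Euclidean distances, majority vote over the `k` nearest training rows.
#' Vote ties are broken by the smallest mean distance among the tied
#' classes' voting neighbors, then by class order.
#'
#' @param train_x,train_y Training matrix and labels.
#' @param test_x Test matrix.
#' @param k Number of neighbors; must not exceed `nrow(train_x)`.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 7L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  n <- nrow(train_x)
  if (k > n) stop("k = ", k, " exceeds the number of training rows (", n, ")")
  ## squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  apply(d2, 1L, function(dr) {
    nn <- order(dr)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    md <- vapply(top, function(cl) mean(sqrt(dr[nn[train_y[nn] == cl]])),
                 numeric(1))
    sort(top[md == min(md)])[1L]
  })
}

## ---- one-vs-one RBF SVM ---------------------------------------------------

#' Train a one-vs-one RBF-kernel SVM ensemble
#'
#' Fits one binary soft-margin SVM with Gaussian RBF kernel
#' `exp(-gamma * |x - y|^2)` per unordered class pair — `K(K-1)/2` machines
#' for `K` classes. Binary machines come from libsvm (via e1071) with
#' feature scaling disabled (features are already normalized upstream).
#'
#' @param x,y Training matrix and labels (at least 2 classes).
#' @param C Penalty parameter (default 40).
#' @param gamma RBF width (default 0.2).
#' @return An object of class `svm_ovo_model`.
#' @export
svm_train <- function(x, y, C = 40, gamma = 0.2) {
  x <- as.matrix(x); y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("SVM training needs at least 2 classes")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    e1071::svm(x[idx, , drop = FALSE], factor(y[idx], levels = pr),
               type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = FALSE)
  })
  structure(list(classes = classes, pairs = pairs, machines = machines,
                 M = ncol(x)),
            class = "svm_ovo_model")
}

#' Classify with a one-vs-one SVM ensemble
#'
#' Each binary machine casts one vote; the class with most votes wins.
#' Vote ties are broken by the largest sum of absolute decision values
#' accumulated when voted for, then by class order.
#'
#' @param model A [svm_train()] model.
#' @param x Test matrix.
#' @param fusion `"vote"` (pairwise max-vote, default) or `"confidence"`
#'   (the single machine with the largest absolute decision value decides).
#' @return Character vector of predicted labels.
#' @export
svm_predict <- function(model, x, fusion = c("vote", "confidence")) {
  fusion <- match.arg(fusion)
  x <- as.matrix(x)
  n <- nrow(x)
  K <- length(model$classes)
  votes <- matrix(0L, n, K, dimnames = list(NULL, model$classes))
  score <- matrix(0, n, K, dimnames = list(NULL, model$classes))
  for (j in seq_along(model$machines)) {
    pr <- model$pairs[[j]]
    pred <- predict(model$machines[[j]], x, decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    ## the machine's own label is the vote (libsvm orients the decision
    ## value toward its internal first label, which depends on row order);
    ## |dv| still measures the vote's confidence
    win <- as.character(pred)
    for (cl in pr) {
      hit <- win == cl
      votes[hit, cl] <- votes[hit, cl] + 1L
      score[hit, cl] <- score[hit, cl] + abs(dv[hit])
    }
  }
  if (fusion == "confidence") {
    return(model$classes[apply(score, 1L, which.max)])
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[which.max(score[i, top])]
    model$classes[[top[[1L]]]]
  }, character(1))
}

## ---- single-hidden-layer perceptron ---------------------------------------

#' Hidden-layer size rule
#'
#' The nearest integer (half rounded up) to
#' `0.5 * (log2(2 K) + 2 K - 1)` for `K` classes: the average of an
#' optimistic (`log2(2K)` intersecting hyperplanes) and a pessimistic
#' (`2K - 1` parallel hyperplanes) neuron count, assuming two linearly
#' separable subclasses per class.
#'
#' @param K Number of classes, `K >= 2`.
#' @return Integer neuron count.
#' @export
hidden_neuron_count <- function(K) {
  if (K < 2L) stop("K must be at least 2")
  as.integer(floor(0.5 * (log2(2 * K) + 2 * K - 1) + 0.5))
}

#' Adaptive stopping rule on the epoch error sequence
#'
#' Fires at epoch `i` when `min(E[i - w + 1], ..., E[i]) > E[i - w] - delta`
#' with window `w`: none of the last `w` epochs improved on the error `w`
#' epochs back by at least `delta`.
#'
#' @param errors Numeric vector of epoch errors so far.
#' @param delta Required improvement (default 0.01).
#' @param window Look-back window (default 10).
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
ann_should_stop <- function(errors, delta = 0.01, window = 10L) {
  i <- length(errors)
  if (i < window + 1L) return(FALSE)
  min(errors[(i - window + 1L):i]) > errors[i - window] - delta
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the single-hidden-layer perceptron
#'
#' Architecture: `M` inputs, `hidden_neuron_count(K)` sigmoid hidden units,
#' `K` sigmoid outputs with one-hot targets. Training is online (per-sample)
#' back-propagation on the squared error, with the sample order reshuffled
#' every epoch from the seeded stream. Weights (including biases) start
#' uniform in `init_range`. Training ends when [ann_should_stop()] fires on
#' the per-epoch mean summed squared error, or at `max_epochs`.
#'
#' @param x,y Training matrix and labels.
#' @param config A [classifier_config()].
#' @return An object of class `ann_model` with the weight matrices and the
#'   epoch error trajectory.
#' @export
ann_train <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x); y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  M <- ncol(x); n <- nrow(x)
  H <- hidden_neuron_count(K)
  targets <- outer(y, classes, "==") * 1        # n x K one-hot
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  W1 <- matrix(runif(H * (M + 1L), config$init_range[1L], config$init_range[2L]),
               H, M + 1L)
  W2 <- matrix(runif(K * (H + 1L), config$init_range[1L], config$init_range[2L]),
               K, H + 1L)
  lr <- config$learning_rate
  errors <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    sse <- 0
    for (i in sample.int(n)) {
      a1 <- c(1, x[i, ])
      h <- sigmoid(W1 %*% a1)
      a2 <- c(1, h)
      o <- sigmoid(W2 %*% a2)
      e <- as.numeric(o) - targets[i, ]
      sse <- sse + sum(e * e)
      d2 <- e * as.numeric(o) * (1 - as.numeric(o))
      d1 <- (crossprod(W2[, -1L, drop = FALSE], d2)) * as.numeric(h) * (1 - as.numeric(h))
      W2 <- W2 - lr * tcrossprod(d2, a2)
      W1 <- W1 - lr * tcrossprod(as.numeric(d1), a1)
    }
    err <- sse / n
    if (!is.finite(err))
      stop("training diverged (non-finite error) at epoch ", epoch)
    errors <- c(errors, err)
    if (ann_should_stop(errors, config$stop_delta, config$stop_window)) break
  }
  structure(list(classes = classes, W1 = W1, W2 = W2, errors = errors,
                 M = M, H = H),
            class = "ann_model")
}

#' Classify with a trained perceptron
#'
#' Forward pass; the output neuron with the largest activation decides, with
#' ties resolved by class order.
#'
#' @param model An [ann_train()] model.
#' @param x Test matrix.
#' @return Character vector of predicted labels.
#' @export
ann_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$M)
    stop("test rows have ", ncol(x), " columns; model expects ", model$M)
  h <- sigmoid(model$W1 %*% t(cbind(1, x)))
  o <- sigmoid(model$W2 %*% rbind(1, h))
  model$classes[apply(o, 2L, which.max)]
}

## ---- uniform front-end used by the evaluation harness ---------------------

fit_classifier <- function(name, x, y, config) {
  switch(name,
    bdm = bdm_fit(x, y),
    knn = list(train_x = as.matrix(x), train_y = as.character(y),
               k = config$k),
    svm = svm_train(x, y, C = config$C, gamma = config$gamma),
    ann = ann_train(x, y, config),
    stop("unknown classifier '", name,
         "'; allowed: bdm, knn, svm, ann"))
}

predict_classifier <- function(name, model, x) {
  switch(name,
    bdm = bdm_predict(model, x),
    knn = knn_predict(model$train_x, model$train_y, x, model$k),
    svm = svm_predict(model, x),
    ann = ann_predict(model, x))
}
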