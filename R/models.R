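#' Fit a TF-IDF n-gram vectorizer
#'
#' Bag-of-n-grams (orders a subset of 1..3) with smoothed inverse document
#' frequency `log((1 + N) / (1 + df)) + 1` and L2 row normalisation. The
#' vocabulary and document frequencies are learned from the training texts
#' only; n-grams unseen at fit time contribute nothing at transform time.
#'
#' @param texts Character vector of normalised training sentences.
#' @param ngram_orders Integer vector of n-gram orders, subset of 1:3
#'   (default `1:3`).
#' @return An object of class `tfidf_vectorizer`.
#' @export
fit_tfidf <- function(texts, ngram_orders = 1:3) {
  stopifnot(length(texts) > 0, all(ngram_orders %in% 1:3))
  docs <- lapply(texts, function(tx) text_ngrams(tokenize_text(tx), ngram_orders))
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (!length(vocab)) stop("no features in training texts", call. = FALSE)
  df <- table(factor(unlist(lapply(docs, unique), use.names = FALSE),
                     levels = vocab))
  n <- length(texts)
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  structure(list(vocab = vocab, idf = idf, ngram_orders = ngram_orders,
                 n_docs = n),
            class = "tfidf_vectorizer")
}

text_ngrams <- function(tokens, orders) {
  nt <- length(tokens)
  unlist(lapply(orders, function(k) {
    if (nt < k) return(character(0))
    if (k == 1L) return(tokens)
    vapply(seq_len(nt - k + 1L),
           function(i) paste(tokens[i:(i + k - 1L)], collapse = " "), "")
  }), use.names = FALSE)
}

#' Transform texts to a TF-IDF matrix
#'
#' @param vectorizer A fitted [fit_tfidf()] object.
#' @param texts Character vector of normalised sentences.
#' @return A sparse `dgCMatrix` (rows = texts, columns = learned
#'   vocabulary), L2-normalised per row; all-unseen texts give zero rows.
#' @export
transform_tfidf <- function(vectorizer, texts) {
  stopifnot(inherits(vectorizer, "tfidf_vectorizer"))
  vocab <- vectorizer$vocab
  triplets <- lapply(seq_along(texts), function(i) {
    grams <- text_ngrams(tokenize_text(texts[i]), vectorizer$ngram_orders)
    j <- match(grams, vocab)
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    cnt <- table(j)
    cbind(i = i, j = as.integer(names(cnt)), x = as.numeric(cnt))
  })
  trip <- do.call(rbind, triplets)
  if (is.null(trip)) trip <- cbind(i = integer(0), j = integer(0), x = numeric(0))
  x <- trip[, "x"] * vectorizer$idf[trip[, "j"]]
  m <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = x,
                            dims = c(length(texts), length(vocab)))
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  methods::as(m, "CsparseMatrix")
}

default_hyperparameters <- function(family) {
  switch(family,
    logistic_regression = list(C = 100),
    svm_linear = list(C = 10),
    random_forest = list(n_trees = 10L)
  )
}

#' Train a TF-IDF n-gram text classifier
#'
#' Baseline families with their study hyperparameters: ridge-penalised
#' (l2) logistic regression with `C = 100` (fit with glmnet at
#' `lambda = 1 / (C * n)`), linear-kernel SVM with `C = 10` (one-vs-rest
#' for more than two classes), and a random forest with 10 trees (Gini
#' splitting). The fitted object is a pure prediction function; anything
#' else exposing a compatible `predict(object, texts)` method (e.g. a
#' fine-tuned transformer adapter) slots into evaluation and ablation
#' unchanged.
#'
#' @param texts Character vector of normalised training sentences.
#' @param labels Character vector of training labels (at least two distinct
#'   classes).
#' @param family `"logistic_regression"`, `"svm_linear"` or
#'   `"random_forest"`.
#' @param hyperparameters Named list overriding the family defaults
#'   (`C` for the linear models, `n_trees` for the forest).
#' @param ngram_orders n-gram orders for the vectorizer (default `1:3`).
#' @param seed Integer seed; the full train/predict path is deterministic
#'   given it.
#' @return An object of class `text_classifier`.
#' @export
train_text_classifier <- function(texts, labels,
                                  family = c("logistic_regression",
                                             "svm_linear", "random_forest"),
                                  hyperparameters = list(),
                                  ngram_orders = 1:3, seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(texts) == length(labels), length(texts) > 0)
  y <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(y) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  vectorizer <- fit_tfidf(texts, ngram_orders)
  x <- transform_tfidf(vectorizer, texts)
  fit <- withr::with_seed(seed, switch(family,
    logistic_regression = {
      # ridge logistic regression at lambda = 1 / (C * n); glmnet converges
      # reliably only along a decreasing warm-start path, so fit a path down
      # to the target and predict at the target
      lam <- 1 / (hp$C * nrow(x))
      path <- exp(seq(log(lam * 1e5), log(lam), length.out = 30))
      f <- glmnet::glmnet(
        x, y, family = if (nlevels(y) == 2L) "binomial" else "multinomial",
        alpha = 0, lambda = path, standardize = FALSE
      )
      f$target_lambda <- lam
      f
    },
    svm_linear = fit_svm_ovr(x, y, cost = hp$C),
    random_forest = {
      xd <- as_dense_features(x)
      randomForest::randomForest(x = xd, y = y, ntree = hp$n_trees)
    }
  ))
  structure(
    list(vectorizer = vectorizer, fit = fit, family = family,
         classes = levels(y), hyperparameters = hp, seed = as.integer(seed),
         fingerprint = rlang::hash(list(texts, labels, family, hp, seed))),
    class = "text_classifier"
  )
}

as_dense_features <- function(x) {
  xd <- as.matrix(x)
  colnames(xd) <- paste0("f", seq_len(ncol(xd)))
  xd
}

# Linear SVM; one-vs-rest for K > 2 classes. libsvm decision-value signs
# depend on label encounter order, so each binary machine's sign is
# calibrated on its own training scores.
fit_svm_ovr <- function(x, y, cost) {
  xd <- as_dense_features(x)
  if (nlevels(y) == 2L) {
    return(list(kind = "binary",
                fit = e1071::svm(xd, y, kernel = "linear", cost = cost,
                                 scale = FALSE)))
  }
  machines <- lapply(levels(y), function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    if (length(unique(yb)) < 2L) return(NULL)
    f <- e1071::svm(xd, yb, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(f, xd, decision.values = TRUE),
               "decision.values")[, 1L]
    sgn <- if (mean(dv[yb == "pos"]) >= mean(dv[yb == "neg"])) 1 else -1
    list(fit = f, sgn = sgn)
  })
  names(machines) <- levels(y)
  list(kind = "ovr", machines = machines)
}

predict_svm_ovr <- function(model, xd, classes) {
  if (model$kind == "binary") {
    return(as.character(stats::predict(model$fit, xd)))
  }
  scores <- vapply(classes, function(cl) {
    m <- model$machines[[cl]]
    if (is.null(m)) return(rep(-Inf, nrow(xd)))
    dv <- attr(stats::predict(m$fit, xd, decision.values = TRUE),
               "decision.values")[, 1L]
    m$sgn * dv
  }, numeric(nrow(xd)))
  if (nrow(xd) == 1L) scores <- matrix(scores, nrow = 1L)
  classes[max.col(scores, ties.method = "first")]
}

#' @export
predict.text_classifier <- function(object, newdata, ...) {
  x <- transform_tfidf(object$vectorizer, newdata)
  switch(object$family,
    logistic_regression = {
      p <- stats::predict(object$fit, x, type = "class",
                          s = object$fit$target_lambda)
      as.character(drop(p))
    },
    svm_linear = predict_svm_ovr(object$fit, as_dense_features(x),
                                 object$classes),
    random_forest = as.character(stats::predict(object$fit,
                                                newdata = as_dense_features(x)))
  )
}

#' @export
print.text_classifier <- function(x, ...) {
  cat("<text_classifier>", x$family, "| classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("  vocabulary:", length(x$vectorizer$vocab), "n-grams | seed:",
      x$seed, "\n")
  invisible(x)
}

#' Grid search with k-fold cross-validation
#'
#' Selects the hyperparameter point with the best mean cross-validated
#' weighted F1. The vectorizer is refit within each fold so document
#' frequencies never leak from held-out folds. Exact ties go to the earlier
#' grid point.
#'
#' @param texts,labels Training data.
#' @param family Classifier family (see [train_text_classifier()]).
#' @param grid List of named hyperparameter lists.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and fits.
#' @param ngram_orders n-gram orders for the vectorizer.
#' @return A list with `best` (the winning hyperparameter list) and
#'   `scores` (tibble of mean weighted F1 per grid point).
#' @export
grid_search_cv <- function(texts, labels, family, grid, k = 5L, seed = 1L,
                           ngram_orders = 1:3) {
  stopifnot(length(grid) >= 1L, k >= 2L)
  n <- length(texts)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  class_set <- sort(unique(labels))
  mean_f1 <- vapply(seq_along(grid), function(g) {
    f1s <- vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      m <- train_text_classifier(texts[tr], labels[tr], family = family,
                                 hyperparameters = grid[[g]],
                                 ngram_orders = ngram_orders, seed = seed)
      pred <- stats::predict(m, texts[!tr])
      compute_metrics(labels[!tr], pred, class_set)$weighted_avg[["f1"]]
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(mean_f1)
  list(best = grid[[best]],
       scores = tibble::tibble(grid_point = seq_along(grid),
                               mean_weighted_f1 = mean_f1))
}
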