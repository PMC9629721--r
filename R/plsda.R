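# Partial least squares discriminant analysis (PLS-DA) on texture feature
# tables: NIPALS PLS2 against one-hot class indicators, argmax decision
# rule, and exact leave-one-out cross-validated misclassification.

#' One-hot class-indicator matrix
#'
#' @param labels character/factor vector with at least two distinct values.
#' @return n x n_classes 0/1 matrix, columns ordered by sorted class name.
#' @export
one_hot <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least two distinct classes", call. = FALSE)
  }
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Fit a PLS-DA model (NIPALS PLS2)
#'
#' Constant features are removed (recorded in the model), X is centred and
#' optionally scaled to unit variance (autoscaling, the default, because
#' GLCM measures live on disparate scales), Y is the centred one-hot
#' indicator matrix. Components are extracted by NIPALS with X deflation;
#' training scores are mutually orthogonal.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param labels class labels, length `nrow(X)`.
#' @param ncomp number of latent components (default 3).
#' @param scale autoscale features to unit variance (default TRUE).
#' @return an object of class `pls_model` with weights `W`, X-loadings
#'   `P`, Y-loadings `Q`, scores `T`, regression coefficients `B`,
#'   centring/scaling vectors, class list and bookkeeping.
#' @export
pls_fit <- function(X, labels, ncomp = 3, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  }
  if (anyNA(X)) stop("X contains undefined values", call. = FALSE)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  Y <- one_hot(labels)
  if (nrow(X) < ncol(Y)) {
    stop("fewer samples than classes", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  constant <- sds <= .Machine$double.eps^0.5 * pmax(1, abs(colMeans(X)))
  dropped <- colnames(X)[constant]
  X <- X[, !constant, drop = FALSE]
  if (ncol(X) == 0L) stop("all features are constant", call. = FALSE)
  ncomp <- as.integer(ncomp)
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > max_rank) {
    stop(sprintf("ncomp = %d exceeds achievable rank %d", ncomp, max_rank),
         call. = FALSE)
  }
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  n <- nrow(Xc); pft <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, pft, ncomp); P <- matrix(0, pft, ncomp)
  Q <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(500L)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_new <- Xd %*% w
      q <- crossprod(Yd, t_new)[, 1] / sum(t_new^2)
      u <- (Yd %*% q) / sum(q^2)
      if (sum((t_new - t_old)^2) < 1e-24 * max(1, sum(t_new^2))) break
      t_old <- t_new
    }
    t_a <- as.numeric(t_new)
    p_a <- crossprod(Xd, t_a)[, 1] / sum(t_a^2)
    q_a <- crossprod(Yd, t_a)[, 1] / sum(t_a^2)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; Tm[, a] <- t_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    Yd <- Yd - tcrossprod(t_a, q_a)
  }
  # rotated weights: T = Xc %*% R with R = W (P'W)^-1
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  rownames(W) <- rownames(P) <- rownames(R) <- rownames(B) <- colnames(Xc)
  structure(list(W = W, P = P, Q = Q, T = Tm, R = R, B = B,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, classes = colnames(Y),
                 ncomp = ncomp, scaled = scale,
                 dropped_features = dropped,
                 train_labels = labels,
                 feature_names = colnames(Xc)),
            class = "pls_model")
}

#' Predict classes from a PLS-DA model
#'
#' New samples are aligned to the training features by name (extra columns
#' ignored if they were dropped as constant in training; genuinely missing
#' or unknown columns are an error), processed with the training centring
#' and scaling, and classified by the argmax of the predicted indicator
#' values. Exact ties are broken by the first class in sorted order and
#' flagged.
#'
#' @param object a [pls_fit()] model.
#' @param newdata numeric matrix with named columns.
#' @param method decision rule: "max" (argmax of predicted indicators,
#'   default) or "centroid" (nearest class centroid in latent score space,
#'   more robust to within-class contamination).
#' @param ... unused.
#' @return a list with `class` (character), `indicators` (matrix),
#'   `scores` (latent variable scores) and `ties` (logical).
#' @export
predict.pls_model <- function(object, newdata, method = c("max", "centroid"),
                              ...) {
  method <- match.arg(method)
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) == length(object$feature_names)) {
      colnames(X) <- object$feature_names
    } else {
      stop("newdata must have named columns", call. = FALSE)
    }
  }
  missing <- setdiff(object$feature_names, colnames(X))
  extra <- setdiff(colnames(X),
                   c(object$feature_names, object$dropped_features))
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  Xc <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  Yhat <- sweep(Xc %*% object$B, 2, object$y_center, "+")
  colnames(Yhat) <- object$classes
  scores <- Xc %*% object$R
  if (method == "centroid") {
    dists <- vapply(object$classes, function(cl) {
      ctr <- colMeans(object$T[object$train_labels == cl, , drop = FALSE])
      rowSums(sweep(scores, 2, ctr)^2)
    }, numeric(nrow(scores)))
    dists <- matrix(dists, nrow = nrow(scores),
                    dimnames = list(NULL, object$classes))
    ties <- apply(dists, 1, function(r) sum(r == min(r)) > 1L)
    cls <- object$classes[apply(dists, 1, which.min)]
  } else {
    ties <- apply(Yhat, 1, function(r) sum(r == max(r)) > 1L)
    cls <- object$classes[apply(Yhat, 1, which.max)]
  }
  if (any(ties)) {
    message(sum(ties), " tied prediction(s); first class in sorted order used")
  }
  list(class = cls, indicators = Yhat, scores = scores, ties = ties)
}

#' Leave-one-out cross-validated misclassification
#'
#' For each sample the model is refit from scratch on the remaining n - 1
#' samples (centring, scaling and constant-feature removal are all redone
#' inside the fold) and the held-out sample predicted. A fold that would
#' lose an entire class is an error, not a silent skip.
#'
#' @param X feature matrix (samples x features).
#' @param labels class labels.
#' @param ncomp number of components (default 3).
#' @param scale autoscaling flag passed to [pls_fit()].
#' @param method decision rule passed to [predict.pls_model()].
#' @return an object of class `cv_result` with `predicted`, `truth`,
#'   `misclassification_rate`, `confusion` (table), `n` and `granularity`
#'   (= 1/n).
#' @export
loo_misclassification <- function(X, labels, ncomp = 3, scale = TRUE,
                                  method = "max") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  classes <- sort(unique(labels))
  if (n < length(classes) + 1L) {
    stop("need at least one more sample than classes", call. = FALSE)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < length(classes)) {
      stop(sprintf("fold %d would lose class '%s' entirely", i, labels[i]),
           call. = FALSE)
    }
    fit <- pls_fit(X[-i, , drop = FALSE], tr_lab, ncomp = ncomp,
                   scale = scale)
    pred[i] <- predict(fit, X[i, , drop = FALSE], method = method)$class
  }
  wrong <- sum(pred != labels)
  structure(list(predicted = pred, truth = labels,
                 misclassification_rate = wrong / n,
                 confusion = table(truth = labels, predicted = pred),
                 n = n, granularity = 1 / n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out CV: %d/%d misclassified (rate %.4f, granularity 1/%d)\n",
              round(x$misclassification_rate * x$n), x$n,
              x$misclassification_rate, x$n))
  print(x$confusion)
  invisible(x)
}
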