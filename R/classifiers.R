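#' Train a two-class classifier
#'
#' The three classifiers used to score feature subsets. `decision_tree` is
#' binary CART (Gini impurity, grown to purity, deterministic tie-breaking
#' on the lowest feature index then lowest midpoint threshold) with native
#' missing-value routing: rows missing the split feature go to the child
#' minimising impurity, and that direction is reused at prediction.
#' `lda` is a two-class linear discriminant with pooled covariance plus a
#' small ridge for singular cases. `svm_poly` is a C-SVC with polynomial
#' kernel `(1 + x.y)^degree` trained by SMO. Each fitted model exposes a
#' continuous positive-class score for ROC analysis (tree: leaf
#' positive-class fraction; lda: discriminant value; svm: decision margin).
#'
#' @param spec One of `"decision_tree"`, `"lda"`, `"svm_poly"`.
#' @param X Numeric matrix (rows = subjects). Missing values are only
#'   supported by the tree; `lda`/`svm_poly` mean-impute them from the
#'   training columns.
#' @param y Labels coercible to 0/1 (1 = positive class, TBI).
#' @param ... Classifier options: `max_depth` (tree, 0 = unlimited),
#'   `ridge` (lda, default 1e-6), `degree`, `cost` (svm, defaults 3 and 1).
#' @return A `tbi_classifier` with a `predict` giving scores in the
#'   positive direction; `predict(model, X) > model$threshold` is the
#'   positive call.
#' @export
train_classifier <- function(spec = c("decision_tree", "lda", "svm_poly"),
                             X, y, ...) {
  spec <- match.arg(spec)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  if (any(tabulate(y + 1L, 2L) < 2L)) {
    stop("need >= 2 training samples per class")
  }
  opts <- list(...)
  model <- switch(spec,
    decision_tree = {
      tree <- cart_fit(X, y, max_depth = opts$max_depth %||% 0L)
      list(tree = tree, threshold = 0.5)
    },
    lda = fit_lda(impute_train(X), y, ridge = opts$ridge %||% 1e-6),
    svm_poly = fit_svm_poly(impute_train(X), y,
                            degree = opts$degree %||% 3,
                            cost = opts$cost %||% 1)
  )
  structure(c(model, list(spec = spec)), class = "tbi_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

impute_train <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  attr(X, "impute_means") <- mu
  X
}

fit_lda <- function(X, y, ridge = 1e-6) {
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  S0 <- stats::cov(X[y == 0, , drop = FALSE]) * (n0 - 1)
  S1 <- stats::cov(X[y == 1, , drop = FALSE]) * (n1 - 1)
  Sp <- (S0 + S1) / (n0 + n1 - 2)
  Sp <- Sp + diag(ridge * max(1, mean(diag(Sp))), ncol(X))
  w <- solve(Sp, mu1 - mu0)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  list(w = w, b = b, threshold = 0,
       impute_means = attr(X, "impute_means"))
}

poly_kernel <- function(A, B, degree) (1 + tcrossprod(A, B))^degree

# minimal SMO for the two-class C-SVC dual; data sets here are tiny
fit_svm_poly <- function(X, y, degree = 3, cost = 1, tol = 1e-3,
                         max_sweeps = 200) {
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  K <- poly_kernel(X, X, degree)
  alpha <- numeric(n)
  b <- 0
  E <- -ys                      # decision is 0 at alpha = 0
  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    ai_old <- alpha[i]
    aj_old <- alpha[j]
    if (ys[i] != ys[j]) {
      L <- max(0, aj_old - ai_old)
      H <- min(cost, cost + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - cost)
      H <- min(cost, ai_old + aj_old)
    }
    if (L >= H) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= -1e-12) return(FALSE)
    aj <- aj_old - ys[j] * (E[i] - E[j]) / eta
    aj <- min(H, max(L, aj))
    if (abs(aj - aj_old) < 1e-8) return(FALSE)
    ai <- ai_old + ys[i] * ys[j] * (aj_old - aj)
    b1 <- b - E[i] - ys[i] * (ai - ai_old) * K[i, i] -
      ys[j] * (aj - aj_old) * K[i, j]
    b2 <- b - E[j] - ys[i] * (ai - ai_old) * K[i, j] -
      ys[j] * (aj - aj_old) * K[j, j]
    b_new <- if (ai > 0 && ai < cost) b1 else
      if (aj > 0 && aj < cost) b2 else (b1 + b2) / 2
    # incremental error-cache update
    E <<- E + ys[i] * (ai - ai_old) * K[, i] +
      ys[j] * (aj - aj_old) * K[, j] + (b_new - b)
    b <<- b_new
    alpha[i] <<- ai
    alpha[j] <<- aj
    TRUE
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- 0
    for (i in seq_len(n)) {
      if ((ys[i] * E[i] < -tol && alpha[i] < cost) ||
          (ys[i] * E[i] > tol && alpha[i] > 0)) {
        # second-choice heuristic, then deterministic fallback over all j
        cand <- unique(c(which.max(abs(E - E[i])), seq_len(n)))
        for (j in cand) {
          if (take_step(i, j)) {
            changed <- changed + 1
            break
          }
        }
      }
    }
    if (changed == 0) break
  }
  sv <- alpha > 1e-8
  list(sv_x = X[sv, , drop = FALSE], sv_coef = (alpha * ys)[sv], b = b,
       degree = degree, threshold = 0,
       impute_means = attr(X, "impute_means"))
}

#' Positive-class score of a fitted classifier
#'
#' @param object A `tbi_classifier`.
#' @param newdata Numeric matrix of test rows.
#' @param ... Unused.
#' @return Numeric score vector; `score > object$threshold` is the
#'   positive (TBI) call.
#' @export
predict.tbi_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$spec != "decision_tree" && anyNA(newdata)) {
    mu <- object$impute_means
    for (j in seq_len(ncol(newdata))) {
      newdata[is.na(newdata[, j]), j] <- mu[j]
    }
  }
  switch(object$spec,
    decision_tree = cart_score(object$tree, newdata),
    lda = as.numeric(newdata %*% object$w + object$b),
    svm_poly = as.numeric(poly_kernel(newdata, object$sv_x,
                                      object$degree) %*% object$sv_coef +
                            object$b)
  )
}
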