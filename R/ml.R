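# Internal ML primitives for the consensus feature-selection pipeline.
# A bagged-CART random forest (Gini importance) and a linear SVM
# (L2-regularized squared hinge) are implemented here because the panel
# pipeline only needs importances/coefficients and deterministic fits;
# LASSO is delegated to glmnet.

#' Deterministic stratified fold assignment
#'
#' Samples of each class are shuffled with the supplied seed and dealt
#' cyclically into `k` folds, so every fold has (near-)balanced class
#' composition and the assignment is reproducible.
#'
#' @param y binary vector (logical, factor or 0/1).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (min(table(y)) < k) stop("need at least k samples in every class")
  fold <- integer(length(y))
  rng <- .rng_local(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- rng$shuffle(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Localized RNG helper: runs callbacks under a private seed without
# disturbing the caller's .Random.seed.
.rng_local <- function(seed) {
  run <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    seed <<- sample.int(.Machine$integer.max, 1L)  # advance for next call
    f()
  }
  list(
    shuffle = function(x) run(function() x[sample.int(length(x))]),
    with = run
  )
}

# Gini impurity of a binary count pair.
.gini <- function(n0, n1) {
  n <- n0 + n1
  if (n == 0) return(0)
  p0 <- n0 / n
  1 - p0 * p0 - (1 - p0) * (1 - p0)
}

# Best split of one feature at a node; returns decrease (weighted by node
# fraction of the root sample) and threshold, or NULL if unsplittable.
.best_split_feature <- function(x, y01, n_root) {
  ord <- order(x)
  xs <- x[ord]; ys <- y01[ord]
  n <- length(xs)
  c1 <- cumsum(ys)
  c0 <- seq_len(n) - c1
  tot1 <- c1[n]; tot0 <- n - tot1
  cut_ok <- which(diff(xs) > 0)
  if (length(cut_ok) == 0L) return(NULL)
  g_node <- .gini(tot0, tot1)
  nl <- cut_ok
  gl <- 1 - (c0[cut_ok] / nl)^2 - (c1[cut_ok] / nl)^2
  nr <- n - nl
  r0 <- tot0 - c0[cut_ok]; r1 <- tot1 - c1[cut_ok]
  gr <- 1 - (r0 / nr)^2 - (r1 / nr)^2
  dec <- (n / n_root) * (g_node - (nl / n) * gl - (nr / n) * gr)
  best <- which.max(dec)
  if (dec[best] <= 0) return(NULL)
  list(decrease = dec[best],
       threshold = (xs[cut_ok[best]] + xs[cut_ok[best] + 1L]) / 2)
}

#' Random-forest Gini feature importance
#'
#' Bagged CART classification trees with `mtry` features sampled per node;
#' importance of a feature is the total Gini impurity decrease it
#' contributes, averaged over trees. Only importances are returned — the
#' consensus pipeline ranks features, it does not predict with the forest.
#'
#' @param X sample x feature numeric matrix.
#' @param y binary labels (logical or coercible to 2-level factor).
#' @param ntree number of trees (default 100).
#' @param mtry features tried per node (default `floor(sqrt(p))`).
#' @param min_node minimum node size to attempt a split (default 2).
#' @param max_depth maximum tree depth (default 12).
#' @param seed integer seed (fits are deterministic given the seed).
#' @return named numeric importance vector along `colnames(X)`.
#' @export
rf_importance <- function(X, y, ntree = 100L, mtry = NULL, min_node = 2L,
                          max_depth = 12L, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.integer(as.factor(y)) - 1L
  if (length(unique(y01)) < 2L) stop("y must contain two classes")
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  imp <- numeric(p)
  rng <- .rng_local(seed)
  grow <- function(idx, depth, env) {
    ys <- y01[idx]
    if (length(idx) < min_node || depth >= max_depth ||
        sum(ys) == 0L || sum(ys) == length(ys)) return(invisible())
    feats <- env$feat_draw(p, mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- .best_split_feature(X[idx, f], ys, env$n_root)
      if (!is.null(sp) && (is.null(best) || sp$decrease > best$decrease)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(invisible())
    imp[best_f] <<- imp[best_f] + best$decrease
    left <- idx[X[idx, best_f] <= best$threshold]
    right <- idx[X[idx, best_f] > best$threshold]
    grow(left, depth + 1L, env)
    grow(right, depth + 1L, env)
    invisible()
  }
  rng$with(function() {
    for (t in seq_len(ntree)) {
      boot <- sample.int(n, n, replace = TRUE)
      env <- list(n_root = length(boot),
                  feat_draw = function(p, m) sample.int(p, m))
      grow(boot, 0L, env)
    }
  })
  stats::setNames(imp / ntree, colnames(X))
}

#' Linear SVM coefficients
#'
#' Solves the primal L2-regularized squared-hinge SVM
#' `min 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (x_i w + b))^2`
#' by BFGS on standardized features (the objective is smooth and convex).
#' Coefficients are returned on the standardized scale, which is the scale
#' on which the |coefficient| feature ranking is meaningful.
#'
#' @param X sample x feature matrix.
#' @param y binary labels.
#' @param C cost parameter (default 1).
#' @param maxit BFGS iteration cap.
#' @return named coefficient vector along `colnames(X)` (intercept
#'   excluded).
#' @export
svm_linear_coef <- function(X, y, C = 1, maxit = 200L) {
  X <- as.matrix(X)
  yy <- as.integer(as.factor(y))
  if (length(unique(yy)) < 2L) stop("y must contain two classes")
  yy <- ifelse(yy == 2L, 1, -1)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  p <- ncol(Z)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - yy * (drop(Z %*% w) + b))
    0.5 * sum(w * w) + C * sum(m * m)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - yy * (drop(Z %*% w) + b))
    gw <- w - 2 * C * drop(crossprod(Z, yy * m))
    gb <- -2 * C * sum(yy * m)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  stats::setNames(fit$par[seq_len(p)], colnames(X))
}

#' Ridge-penalized logistic regression (IRLS)
#'
#' Small deterministic classifier used to evaluate panels: logistic
#' regression with an L2 penalty on standardized features, fit by
#' iteratively reweighted least squares. Handles p = 1 and separable data
#' (the penalty keeps coefficients finite).
#'
#' @param X sample x feature matrix.
#' @param y binary labels; the second factor level is the positive class.
#' @param lambda ridge penalty (default 1e-2).
#' @param maxit,tol IRLS controls.
#' @return object of class `ridge_logistic` with `predict` support
#'   returning positive-class probabilities.
#' @export
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  yy <- as.integer(as.factor(y)) - 1L
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, mu, "-"), 2, sdv, "/"))
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    prob <- 1 / (1 + exp(-eta))
    w <- pmax(prob * (1 - prob), 1e-8)
    zresp <- eta + (yy - prob) / w
    A <- crossprod(Z * w, Z) + pen
    bnew <- drop(solve(A, crossprod(Z * w, zresp)))
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  structure(list(beta = beta, mu = mu, sd = sdv,
                 levels = levels(as.factor(y))),
            class = "ridge_logistic")
}

#' @rdname ridge_logistic
#' @param object fitted `ridge_logistic`.
#' @param newdata sample x feature matrix.
#' @param ... unused.
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  Z <- cbind(1, sweep(sweep(as.matrix(newdata), 2, object$mu, "-"),
                      2, object$sd, "/"))
  drop(1 / (1 + exp(-(Z %*% object$beta))))
}
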