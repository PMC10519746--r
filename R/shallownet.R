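#' Shallow-network hyperparameter specification
#'
#' One fully connected hidden layer with ReLU activation and a softmax
#' cross-entropy loss, Glorot-initialised and trained with L-BFGS. These
#' defaults mirror a "wide" shallow network: 100 hidden nodes, 1000
#' iteration cap, five-fold cross-validation for the reported CV accuracy.
#'
#' @param hidden_units Hidden-layer width (default 100).
#' @param max_iterations L-BFGS iteration cap (default 1000).
#' @param tol Relative convergence tolerance of the optimiser
#'   (default 1e-6).
#' @param cv_folds Cross-validation folds for the reported CV accuracy
#'   (default 5; set 0 to skip CV).
#' @param feature_set Feature subset the classifier consumes:
#'   `"hybrid"`, `"conventional"` or `"fractal"` (see [feature_set()]).
#' @return An object of class `shallow_net_spec`.
#' @export
shallow_net_spec <- function(hidden_units = 100L, max_iterations = 1000L,
                             tol = 1e-6, cv_folds = 5L,
                             feature_set = c("hybrid", "conventional",
                                             "fractal")) {
  feature_set <- match.arg(feature_set)
  stopifnot(hidden_units >= 1L, max_iterations >= 1L, tol > 0,
            cv_folds == 0L || cv_folds >= 2L)
  structure(list(hidden_units = as.integer(hidden_units),
                 max_iterations = as.integer(max_iterations),
                 tol = tol, cv_folds = as.integer(cv_folds),
                 feature_set = feature_set),
            class = "shallow_net_spec")
}

# parameter packing ----------------------------------------------------------
.net_unpack <- function(theta, d, h, k) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- theta[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.net_loss_grad <- function(theta, X, Yind, d, h, k) {
  par <- .net_unpack(theta, d, h, k)
  n <- nrow(X)
  Z1 <- sweep(X %*% par$W1, 2, par$b1, `+`)
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, `+`)
  Z2 <- Z2 - apply(Z2, 1, max)
  expZ <- exp(Z2)
  P <- expZ / rowSums(expZ)
  loss <- -mean(log(pmax(P[Yind], 1e-300)))

  dZ2 <- P
  dZ2[Yind] <- dZ2[Yind] - 1
  dZ2 <- dZ2 / n
  gW2 <- crossprod(A1, dZ2)
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(par$W2)
  dZ1 <- dA1 * (Z1 > 0)
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

#' Train a shallow softmax network
#'
#' Standardises the predictors with training statistics (z-score), draws
#' Glorot-uniform initial weights under the given seed, and minimises the
#' mean softmax cross-entropy with L-BFGS. Works for two or more classes;
#' the binary levels of the hierarchical classifier and the flat multiclass
#' baselines share this trainer.
#'
#' @param x Numeric matrix or data.frame of predictors (rows = samples).
#' @param y Factor (or coercible) of class labels; every level must occur.
#' @param spec A [shallow_net_spec()].
#' @param seed Integer seed (weight initialisation and CV folds).
#' @return An object of class `shallow_net` with the fitted weights,
#'   standardisation statistics, class levels and `cv_accuracy` (fraction;
#'   `NA` when `cv_folds = 0`).
#' @export
train_shallow_net <- function(x, y, spec = shallow_net_spec(), seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  if (any(table(y) == 0L)) stop("every class must be present")
  stopifnot(nrow(x) == length(y))

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)

  fit1 <- .fit_net(Xs, y, spec, seed)
  cv_acc <- NA_real_
  if (spec$cv_folds >= 2L) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed) + 1L)
    fold <- sample(rep_len(seq_len(spec$cv_folds), nrow(Xs)))
    hits <- 0L
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      m <- .fit_net(Xs[tr, , drop = FALSE], y[tr], spec, seed + f)
      pr <- .net_predict_class(m, Xs[!tr, , drop = FALSE])
      hits <- hits + sum(pr == y[!tr])
    }
    cv_acc <- hits / nrow(Xs)
  }

  structure(list(theta = fit1$theta, levels = levels(y),
                 d = ncol(x), h = spec$hidden_units, k = nlevels(y),
                 center = center, scale = scale_,
                 feature_names = colnames(x),
                 spec = spec, seed = seed,
                 converged = fit1$converged, cv_accuracy = cv_acc),
            class = "shallow_net")
}

.fit_net <- function(Xs, y, spec, seed) {
  d <- ncol(Xs); h <- spec$hidden_units
  y <- droplevels(as.factor(y)); k <- nlevels(y)
  n <- nrow(Xs)
  Yind <- cbind(seq_len(n), as.integer(y))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  glorot <- function(fan_in, fan_out, n_par) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n_par, -lim, lim)
  }
  theta0 <- c(glorot(d, h, d * h), numeric(h),
              glorot(h, k, h * k), numeric(k))
  env <- new.env()
  fn <- function(th) {
    r <- .net_loss_grad(th, Xs, Yind, d, h, k)
    env$grad <- r$grad
    r$loss
  }
  gr <- function(th) env$grad
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = spec$max_iterations,
                                     factr = spec$tol / .Machine$double.eps))
  list(theta = opt$par, converged = opt$convergence == 0,
       levels = levels(y), d = d, h = h, k = k)
}

.net_predict_prob <- function(model, Xs) {
  par <- .net_unpack(model$theta, model$d, model$h, model$k)
  A1 <- pmax(sweep(Xs %*% par$W1, 2, par$b1, `+`), 0)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, `+`)
  Z2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Z2)
  P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}

#' Predict from a trained shallow network
#'
#' @param object A `shallow_net`.
#' @param newdata Matrix or data.frame with the training columns.
#' @param type `"class"` for labels, `"prob"` for the softmax posterior
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels or a probability matrix.
#' @export
predict.shallow_net <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  P <- .net_predict_prob(object, Xs)
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

.net_predict_class <- function(model, Xs) {
  P <- .net_predict_prob(model, Xs)
  factor(model$levels[max.col(P, ties.method = "first")],
         levels = model$levels)
}

#' Train one binary level of the hierarchical classifier
#'
#' Thin wrapper over [train_shallow_net()] that enforces a binary problem,
#' as solved at each node of the classification tree.
#'
#' @inheritParams train_shallow_net
#' @return A `shallow_net` with two output classes.
#' @export
train_level <- function(x, y, spec = shallow_net_spec(), seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) {
    stop(sprintf("train_level: expected exactly 2 classes, got %d",
                 nlevels(y)))
  }
  train_shallow_net(x, y, spec, seed)
}
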