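gpr_kernels <- c("exponential", "sq_exponential", "matern52",
                 "rational_quadratic")

# covariance from a Euclidean distance matrix
gpr_kfun <- function(r, kernel, l, alpha = 1) {
  switch(kernel,
    exponential = exp(-r / l),                       # Matern nu = 1/2
    sq_exponential = exp(-r^2 / (2 * l^2)),
    matern52 = {
      z <- sqrt(5) * r / l
      (1 + z + z^2 / 3) * exp(-z)
    },
    rational_quadratic = (1 + r^2 / (2 * alpha * l^2))^(-alpha),
    stop("unknown kernel: ", kernel)
  )
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Gaussian process regression with marginal-likelihood hyperparameters
#'
#' Constant-mean GP with an isotropic kernel on standardised features and an
#' observation-noise term. Hyperparameters (length-scale, signal SD, noise
#' SD, and the shape parameter of the rational-quadratic kernel) are chosen
#' by maximising the log marginal likelihood with L-BFGS-B on the log scale,
#' unless fixed values are supplied.
#'
#' @param x Feature matrix (or data frame) of training inputs.
#' @param y Numeric targets.
#' @param kernel One of `"exponential"` (Matern 1/2), `"sq_exponential"`,
#'   `"matern52"`, `"rational_quadratic"`.
#' @param hyperparams Optional fixed list (`l`, `sf`, `sn`, `alpha`); when
#'   supplied no optimisation is done. `sn = 0` gives an interpolating GP
#'   (a small jitter keeps the Cholesky stable).
#' @param maxit Optimiser iteration cap.
#' @return Object of class `gpr_model`.
#' @export
gpr_fit <- function(x, y, kernel = "exponential", hyperparams = NULL,
                    maxit = 40) {
  kernel <- match.arg(kernel, gpr_kernels)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ybar <- mean(y)
  yc <- y - ybar
  sy <- max(sd(y), 1e-8)
  n <- length(y)
  jitter <- 1e-12 * sy^2

  r <- cross_dist(xs, xs)

  chol_jittered <- function(K, jit) {
    for (i in 0:6) {
      L <- tryCatch(chol(K + diag(jit * 100^i, nrow(K))), error = function(e) NULL)
      if (!is.null(L)) return(L)
    }
    stop("kernel matrix is numerically singular")
  }

  nll <- function(theta) {
    l <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    alpha <- if (kernel == "rational_quadratic") exp(theta[4]) else 1
    K <- sf^2 * gpr_kfun(r, kernel, l, alpha)
    diag(K) <- diag(K) + sn^2 + 100 * jitter
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }

  if (is.null(hyperparams)) {
    theta0 <- c(log(1), log(sy), log(0.1 * sy))
    lower <- c(log(1e-3), log(1e-4 * sy), log(1e-6 * sy))
    upper <- c(log(1e3), log(1e3 * sy), log(10 * sy))
    if (kernel == "rational_quadratic") {
      theta0 <- c(theta0, 0); lower <- c(lower, log(1e-2)); upper <- c(upper, log(1e3))
    }
    opt <- optim(theta0, nll, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = maxit, factr = 1e9))
    th <- opt$par
    hp <- list(l = exp(th[1]), sf = exp(th[2]), sn = exp(th[3]),
               alpha = if (kernel == "rational_quadratic") exp(th[4]) else 1)
  } else {
    hp <- modifyList(list(l = 1, sf = sy, sn = 0.1 * sy, alpha = 1), hyperparams)
  }

  K <- hp$sf^2 * gpr_kfun(r, kernel, hp$l, hp$alpha)
  diag(K) <- diag(K) + hp$sn^2
  L <- chol_jittered(K, jitter)
  alpha_vec <- backsolve(L, forwardsolve(t(L), yc))

  structure(list(kernel = kernel, hyperparams = hp, x = xs, alpha = alpha_vec,
                 center = ctr, scale = scl, ybar = ybar,
                 x_range = apply(x, 2, range)),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  hp <- x$hyperparams
  cat("<gpr_model> kernel = ", x$kernel, ", n = ", nrow(x$x),
      ", l = ", format(hp$l, digits = 3), ", sf = ", format(hp$sf, digits = 3),
      ", sn = ", format(hp$sn, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Posterior-mean prediction from a GPR model
#'
#' Vectorised and chunked so whole-image pixel sets can be pushed through.
#' Inputs outside the training range are still finite (the posterior reverts
#' towards the prior mean); their count is attached as the `extrapolated`
#' attribute.
#'
#' @param object A `gpr_model`.
#' @param newdata Matrix or data frame with the training feature columns.
#' @param chunk Rows per prediction block.
#' @param ... Unused.
#' @export
predict.gpr_model <- function(object, newdata, chunk = 4000L, ...) {
  xq <- as.matrix(newdata)
  if (ncol(xq) != ncol(object$x)) {
    stop("feature dimension mismatch: model has ", ncol(object$x),
         ", newdata has ", ncol(xq))
  }
  xs <- sweep(sweep(xq, 2, object$center), 2, object$scale, "/")
  hp <- object$hyperparams
  out <- numeric(nrow(xs))
  idx <- split(seq_len(nrow(xs)), ceiling(seq_len(nrow(xs)) / chunk))
  for (ii in idx) {
    ks <- hp$sf^2 * gpr_kfun(cross_dist(xs[ii, , drop = FALSE], object$x),
                             object$kernel, hp$l, hp$alpha)
    out[ii] <- drop(ks %*% object$alpha) + object$ybar
  }
  extra <- vapply(seq_len(ncol(xq)), function(j) {
    sum(xq[, j] < object$x_range[1, j] | xq[, j] > object$x_range[2, j])
  }, 1L)
  attr(out, "extrapolated") <- sum(extra)
  out
}

model_frame <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop("feature dimension mismatch: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  as.matrix(data[, features, drop = FALSE])
}

#' Train a regression model with k-fold cross-validation
#'
#' Trains one of the regression-learning estimators on a tabular dataset from
#' [build_datasets()] and reports cross-validated metrics. Folds are assigned
#' at the row level by default, so replicate rows of one phantom can inform
#' each other across folds (matching an app-level protocol where the
#' replicate structure is invisible to the learner); `grouped = TRUE`
#' assigns whole phantoms to folds for an honest generalisation estimate.
#' The final model is refit on all rows. Resubstitution metrics are reported
#' alongside the CV metrics.
#'
#' @param data Dataset tibble from [build_datasets()] (or any tibble with
#'   attributes `features` and `target`, or pass them explicitly).
#' @param kind `"gpr_exponential"`, `"gpr_sq_exponential"`, `"gpr_matern52"`,
#'   `"gpr_rational_quadratic"` or `"linear"`.
#' @param seed Integer seed for the fold assignment.
#' @param folds Number of CV folds.
#' @param grouped Assign folds by phantom `id` instead of by row.
#' @param features,target Optional overrides of the dataset attributes.
#' @return Object of class `ept_reg_model` with the refit `model`, the
#'   out-of-fold predictions (`cv`), and `metrics` (CV and resubstitution).
#' @export
train_cv_model <- function(data, kind = "gpr_exponential", seed = 1L,
                           folds = 5L, grouped = FALSE,
                           features = attr(data, "features"),
                           target = attr(data, "target")) {
  kinds <- c(paste0("gpr_", gpr_kernels), "linear")
  kind <- match.arg(kind, kinds)
  stopifnot(!is.null(features), !is.null(target))
  n <- nrow(data)
  if (n < folds) stop("fewer rows (", n, ") than folds (", folds, ")")
  x <- model_frame(data, features)
  y <- data[[target]]

  set.seed(seed)
  if (grouped) {
    ids <- sort(unique(data$id))
    id_fold <- setNames(sample(rep(seq_len(folds), length.out = length(ids))), ids)
    fold <- unname(id_fold[as.character(data$id)])
  } else if (all(c("id", "replicate") %in% names(data))) {
    # key the assignment to (id, replicate) so it is invariant to row order
    ord <- order(data$id, data$replicate)
    fold <- integer(n)
    fold[ord] <- sample(rep(seq_len(folds), length.out = n))
  } else {
    fold <- sample(rep(seq_len(folds), length.out = n))
  }

  fit_fun <- if (kind == "linear") {
    function(x, y) lm.fit(cbind(1, x), y)
  } else {
    kernel <- sub("^gpr_", "", kind)
    function(x, y) gpr_fit(x, y, kernel = kernel)
  }
  pred_fun <- function(model, x) {
    if (kind == "linear") drop(cbind(1, x) %*% model$coefficients)
    else as.numeric(predict(model, x))
  }

  cv_pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    m <- fit_fun(x[tr, , drop = FALSE], y[tr])
    cv_pred[!tr] <- pred_fun(m, x[!tr, , drop = FALSE])
  }
  final <- fit_fun(x, y)
  resub_pred <- pred_fun(final, x)

  cv_m <- regression_metrics(y, cv_pred)
  rs_m <- regression_metrics(y, resub_pred)
  structure(list(
    kind = kind, model = final, features = features, target = target,
    folds = folds, grouped = grouped, seed = seed,
    cv = tibble::tibble(row = seq_len(n), fold = fold, obs = y, pred = cv_pred),
    metrics = list(rmse = cv_m$rmse, r2 = cv_m$r2,
                   rmse_resub = rs_m$rmse, r2_resub = rs_m$r2, n = n)
  ), class = "ept_reg_model")
}

#' @export
print.ept_reg_model <- function(x, ...) {
  cat("<ept_reg_model> ", x$kind, ", ", x$metrics$n, " rows, ", x$folds,
      "-fold CV (", if (x$grouped) "phantom" else "row", "-level)\n",
      "  CV RMSE = ", format(x$metrics$rmse, digits = 4),
      ", CV R2 = ", format(x$metrics$r2, digits = 4),
      "  (resub ", format(x$metrics$rmse_resub, digits = 4), " / ",
      format(x$metrics$r2_resub, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
predict.ept_reg_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else model_frame(newdata, object$features)
  if (ncol(x) != length(object$features)) {
    stop("feature dimension mismatch")
  }
  if (object$kind == "linear") {
    drop(cbind(1, x) %*% object$model$coefficients)
  } else {
    predict(object$model, x, ...)
  }
}

#' @method glance ept_reg_model
#' @export
glance.ept_reg_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, rmse = x$metrics$rmse, r2 = x$metrics$r2,
                 rmse_resub = x$metrics$rmse_resub,
                 r2_resub = x$metrics$r2_resub,
                 folds = x$folds, grouped = x$grouped, n = x$metrics$n)
}

#' @method tidy ept_reg_model
#' @export
tidy.ept_reg_model <- function(x, ...) x$cv
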