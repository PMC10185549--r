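# one-hidden-layer network machinery ----------------------------------------
# weights vector layout: W1 (h x (d+1), row-major by unit), then w2 (h+1)

nnf_unpack <- function(w, d, h) {
  list(W1 = matrix(w[seq_len(h * (d + 1))], nrow = h, byrow = TRUE),
       w2 = w[h * (d + 1) + seq_len(h + 1)])
}

nnf_forward <- function(w, X1, h) {
  p <- nnf_unpack(w, ncol(X1) - 1, h)
  H <- tanh(X1 %*% t(p$W1))
  list(H = H, yhat = drop(cbind(H, 1) %*% p$w2))
}

# Jacobian of predictions wrt weights (n x p), analytic
nnf_jacobian <- function(w, X1, h) {
  d <- ncol(X1) - 1
  p <- nnf_unpack(w, d, h)
  H <- tanh(X1 %*% t(p$W1))
  dH <- 1 - H^2
  J <- matrix(0, nrow(X1), length(w))
  for (j in seq_len(h)) {
    cols <- (j - 1) * (d + 1) + seq_len(d + 1)
    J[, cols] <- (p$w2[j] * dH[, j]) * X1
  }
  J[, h * (d + 1) + seq_len(h + 1)] <- cbind(H, 1)
  J
}

# Levenberg-Marquardt on the residual vector, optional L2 decay,
# optional early stopping on a validation set
nnf_train_lm <- function(w, X1, y, h, decay = 0, val = NULL, max_iter = 150,
                         patience = 12) {
  lambda <- 1e-2
  res <- function(w) nnf_forward(w, X1, h)$yhat - y
  obj <- function(w) sum(res(w)^2) + decay * sum(w^2)
  best_w <- w; best_val <- Inf; stall <- 0
  f <- obj(w)
  for (it in seq_len(max_iter)) {
    r <- res(w)
    J <- nnf_jacobian(w, X1, h)
    g <- drop(crossprod(J, r)) + decay * w
    Hm <- crossprod(J) + diag(decay, length(w))
    ok <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(Hm + diag(lambda, length(w)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + step
        f_new <- obj(w_new)
        if (is.finite(f_new) && f_new < f) {
          w <- w_new; f <- f_new; lambda <- max(lambda / 5, 1e-12); ok <- TRUE
          break
        }
      }
      lambda <- min(lambda * 10, 1e12)
    }
    if (!is.null(val)) {
      v <- sqrt(mean((nnf_forward(w, val$X1, h)$yhat - val$y)^2))
      if (v < best_val - 1e-9) { best_val <- v; best_w <- w; stall <- 0 }
      else stall <- stall + 1
      if (stall >= patience) break
    }
    if (!ok) break
  }
  if (is.null(val)) w else best_w
}

nnf_train_cg <- function(w, X1, y, h, val = NULL, chunks = 15, maxit = 40) {
  fn <- function(w) 0.5 * sum((nnf_forward(w, X1, h)$yhat - y)^2)
  gr <- function(w) {
    r <- nnf_forward(w, X1, h)$yhat - y
    drop(crossprod(nnf_jacobian(w, X1, h), r))
  }
  best_w <- w; best_val <- Inf; stall <- 0
  for (ch in seq_len(chunks)) {
    w <- optim(w, fn, gr, method = "CG", control = list(maxit = maxit))$par
    if (!is.null(val)) {
      v <- sqrt(mean((nnf_forward(w, val$X1, h)$yhat - val$y)^2))
      if (v < best_val - 1e-9) { best_val <- v; best_w <- w; stall <- 0 }
      else stall <- stall + 1
      if (stall >= 3) break
    }
  }
  if (is.null(val)) w else best_w
}

#' Train a one-hidden-layer neural fit
#'
#' Feed-forward network with one tanh hidden layer and a linear output,
#' trained on standardised features and targets. Rows are split 70/15/15
#' into training, validation and test sets. Three trainers are provided:
#' `"lm"` (Levenberg--Marquardt on the residual vector with an analytic
#' Jacobian, early-stopped on validation RMSE), `"bayes_reg"`
#' (Levenberg--Marquardt with an L2 weight penalty whose strength is picked
#' on the validation split), and `"scg"` (conjugate-gradient descent with
#' validation-based stopping).
#'
#' @param data Dataset tibble from [build_datasets()].
#' @param hidden Hidden layer width (the study explored 10, 17 and 50).
#' @param algorithm `"lm"`, `"bayes_reg"` or `"scg"`.
#' @param seed Integer seed (weight init and split).
#' @param splits Fractions for train/validation/test.
#' @param features,target Optional overrides of the dataset attributes.
#' @return Object of class `nnf_model` with per-split `metrics` and
#'   `predictions`.
#' @export
train_nnf <- function(data, hidden = 17L, algorithm = c("lm", "bayes_reg", "scg"),
                      seed = 1L, splits = c(0.7, 0.15, 0.15),
                      features = attr(data, "features"),
                      target = attr(data, "target")) {
  algorithm <- match.arg(algorithm)
  stopifnot(!is.null(features), !is.null(target),
            abs(sum(splits) - 1) < 1e-9, hidden >= 1)
  x <- model_frame(data, features)
  y <- data[[target]]
  n <- nrow(x); d <- ncol(x)

  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  ybar <- mean(y); ysd <- max(sd(y), 1e-12)
  Xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ys <- (y - ybar) / ysd

  set.seed(seed)
  split_id <- sample(cut(seq_len(n) / n, c(0, cumsum(splits)),
                         labels = c("training", "validation", "test")))
  parts <- lapply(levels(split_id), function(s) {
    i <- split_id == s
    list(X1 = cbind(Xs[i, , drop = FALSE], 1), y = ys[i], idx = which(i))
  })
  names(parts) <- levels(split_id)

  p <- hidden * (d + 1) + hidden + 1
  w0 <- rnorm(p, 0, 0.5)
  tr <- parts$training; va <- parts$validation

  w <- switch(algorithm,
    lm = nnf_train_lm(w0, tr$X1, tr$y, hidden, val = va),
    scg = nnf_train_cg(w0, tr$X1, tr$y, hidden, val = va),
    bayes_reg = {
      grid <- 10^seq(-5, 0, length.out = 6)
      fits <- lapply(grid, function(dc) {
        nnf_train_lm(w0, tr$X1, tr$y, hidden, decay = dc, max_iter = 80)
      })
      val_rmse <- vapply(fits, function(wf) {
        sqrt(mean((nnf_forward(wf, va$X1, hidden)$yhat - va$y)^2))
      }, 1)
      fits[[which.min(val_rmse)]]
    }
  )

  preds <- dplyr::bind_rows(lapply(names(parts), function(s) {
    pp <- parts[[s]]
    tibble::tibble(split = s, row = pp$idx,
                   obs = pp$y * ysd + ybar,
                   pred = nnf_forward(w, pp$X1, hidden)$yhat * ysd + ybar)
  }))
  metrics <- preds |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(rmse = regression_metrics(.data$obs, .data$pred)$rmse,
                     r2 = regression_metrics(.data$obs, .data$pred)$r2,
                     n = dplyr::n(), .groups = "drop")

  structure(list(algorithm = algorithm, hidden = hidden, weights = w,
                 features = features, target = target,
                 scaling = list(center = ctr, scale = scl, ybar = ybar, ysd = ysd),
                 metrics = metrics, predictions = preds, seed = seed,
                 converged = all(is.finite(w))),
            class = "nnf_model")
}

#' @export
print.nnf_model <- function(x, ...) {
  cat("<nnf_model> ", x$algorithm, ", hidden = ", x$hidden, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
predict.nnf_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else model_frame(newdata, object$features)
  if (ncol(x) != length(object$features)) stop("feature dimension mismatch")
  s <- object$scaling
  X1 <- cbind(sweep(sweep(x, 2, s$center), 2, s$scale, "/"), 1)
  nnf_forward(object$weights, X1, object$hidden)$yhat * s$ysd + s$ybar
}

#' @method glance nnf_model
#' @export
glance.nnf_model <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "split",
                     values_from = c("rmse", "r2", "n"))
}

#' @method tidy nnf_model
#' @export
tidy.nnf_model <- function(x, ...) x$metrics
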