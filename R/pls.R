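#' Fit a single-response partial least squares (PLS1) model by NIPALS
#'
#' Predictors are autoscaled (centred, unit variance) and the response
#' standardised internally; the preprocessing record is stored and inverted
#' on prediction. Components are extracted by NIPALS deflation:
#' `w_a = X_a' y_a / ||X_a' y_a||`, `t_a = X_a w_a`,
#' `p_a = X_a' t_a / (t_a' t_a)`, `c_a = y_a' t_a / (t_a' t_a)`, then `X_a`
#' and `y_a` are deflated. The response variance captured by component a is
#' `SSY_a = c_a^2 (t_a' t_a)`. Requested components beyond the rank of X are
#' dropped with a warning.
#'
#' @param x Sample x gene numeric matrix (or data frame of predictors).
#' @param y Numeric response, one value per row of `x`.
#' @param ncomp Number of latent components.
#' @return Object of class `pls1_fit`: weights `W` (unit columns), scores
#'   `T` (mutually orthogonal), loadings `P`, y-loadings `c`, `ssy`,
#'   standardized coefficients, fitted values and the preprocessing record.
#' @export
fit_pls1 <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%04d", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x), is.numeric(y))
  if (anyNA(x) || anyNA(y)) abort("x and y must not contain missing values.")
  if (sd(y) == 0) abort("response has zero variance.")
  n <- nrow(x); p <- ncol(x)
  x_center <- colMeans(x)
  x_scale <- matrixStats::colSds(x)
  x_scale[x_scale == 0] <- 1       # constant predictors carry no weight
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y); y_scale <- sd(y)
  ys <- (y - y_center) / y_scale

  A <- min(ncomp, n - 1, p)
  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  cvec <- ssy <- numeric(A)
  Xa <- xs; ya <- ys
  a_used <- 0L
  for (a in seq_len(A)) {
    wv <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- drop(Xa %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(Xa, tv)) / tt
    cv <- sum(ya * tv) / tt
    Xa <- Xa - tcrossprod(tv, pv)
    ya <- ya - cv * tv
    W[, a] <- wv; Tm[, a] <- tv; P[, a] <- pv
    cvec[a] <- cv; ssy[a] <- cv^2 * tt
    a_used <- a + 0L
  }
  if (a_used == 0L) abort("no informative component could be extracted.")
  if (a_used < ncomp) {
    warn(sprintf("only %d informative component(s); requested %d.", a_used, ncomp))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  cvec <- cvec[seq_len(a_used)]; ssy <- ssy[seq_len(a_used)]
  rownames(W) <- rownames(P) <- colnames(x)
  # regression vector on the standardized scale: R = W (P'W)^-1, beta = R c
  R <- W %*% solve(crossprod(P, W))
  beta_std <- drop(R %*% cvec)
  fitted_std <- drop(xs %*% beta_std)
  fitted <- y_center + y_scale * fitted_std
  structure(list(W = W, scores = Tm, P = P, y_loadings = cvec, ncomp = a_used,
                 ssy = ssy, beta_std = setNames(beta_std, colnames(x)),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 genes = colnames(x), fitted = fitted, y = y,
                 x_std = xs),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 (NIPALS): %d component(s), %d predictors, n = %d\n",
              x$ncomp, length(x$genes), length(x$y)))
  ss_tot <- sum(((x$y - x$y_center) / x$y_scale)^2)
  cat(sprintf("  response variance explained per component: %s\n",
              paste(sprintf("%.1f%%", 100 * x$ssy / ss_tot), collapse = " ")))
  invisible(x)
}

#' Predict from a PLS1 fit
#'
#' @param object A `pls1_fit`.
#' @param newdata Sample x gene matrix with the model's predictors (matched
#'   by column name when present).
#' @param ... Unused.
#' @return Numeric predictions on the original response scale.
#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$genes, colnames(newdata))
    if (length(missing)) abort("newdata lacks model predictors; see predict_phenotype() for partially overlapping external data.")
    newdata <- newdata[, object$genes, drop = FALSE]
  } else if (ncol(newdata) != length(object$genes)) {
    abort("newdata has the wrong number of columns.")
  }
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  drop(object$y_center + object$y_scale * (xs %*% object$beta_std))
}

#' Leave-one-out RRMSEP curve and component selection
#'
#' For each number of components up to `a_max`, every sample is predicted
#' from a model fit (preprocessing included) on the remaining samples; RMSEP
#' is the root mean squared error of those predictions and RRMSEP divides it
#' by `sd(y)`, so 1.0 is the no-skill reference. The chosen component count
#' is the elbow: the smallest A whose relative improvement to A + 1 is below
#' `improvement` (or where RRMSEP increases).
#'
#' @param x,y As in [fit_pls1()] (n >= 3 samples).
#' @param a_max Largest component count assessed.
#' @param improvement Relative-improvement cutoff of the elbow rule.
#' @return Tibble of class `rrmsep_curve` (`ncomp`, `rmsep`, `rrmsep`) with
#'   attribute `chosen`.
#' @export
loo_rrmsep_select <- function(x, y, a_max = 10, improvement = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) abort("leave-one-out selection needs at least 3 samples.")
  a_max <- min(a_max, n - 2, ncol(x))
  pred <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(fit_pls1(x[-i, , drop = FALSE], y[-i], ncomp = a_max))
    for (a in seq_len(min(a_max, fit$ncomp))) {
      sub <- fit
      sub$beta_std <- drop(fit$W[, 1:a, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:a, drop = FALSE], fit$W[, 1:a, drop = FALSE])) %*%
        fit$y_loadings[1:a])
      pred[i, a] <- predict.pls1_fit(sub, x[i, , drop = FALSE])
    }
  }
  # folds that ran out of rank fall back to the deepest available component
  for (a in seq_len(a_max)) {
    if (anyNA(pred[, a]) && a > 1) pred[is.na(pred[, a]), a] <- pred[is.na(pred[, a]), a - 1]
  }
  rmsep <- sqrt(colMeans((pred - y)^2))
  rrmsep <- rmsep / sd(y)
  chosen <- a_max
  for (a in seq_len(a_max - 1)) {
    rel_gain <- (rrmsep[a] - rrmsep[a + 1]) / rrmsep[a]
    # stop at the elbow, or once error is at the noise floor already
    if (rel_gain < improvement || rrmsep[a] <= 0.05) { chosen <- a; break }
  }
  out <- tibble::tibble(ncomp = seq_len(a_max), rmsep = rmsep, rrmsep = rrmsep)
  class(out) <- c("rrmsep_curve", class(out))
  attr(out, "chosen") <- as.integer(chosen)
  out
}
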