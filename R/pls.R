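#' Fit a PLS 3D-QSAR model (NIPALS)
#'
#' Partial least squares regression of an activity vector on a field
#' descriptor matrix, computed by the NIPALS algorithm with mean-centering
#' of X and y and no column scaling (the CoMFA convention: field columns
#' share the kcal/mol scale, so autoscaling would inflate noise points).
#' Components are extracted by deflation, so the models for 1..ncomp latent
#' variables are nested and all returned. At the maximum number of
#' components on a full-rank matrix the model coincides with ordinary
#' least squares.
#'
#' @param X descriptor matrix (rows = molecules); attributes
#'   \code{field_index}/\code{lattice} from \code{\link{assemble_X}} are
#'   carried into the model for map export.
#' @param y activity vector (pKi), length = nrow(X), non-constant.
#' @param ncomp maximum number of latent variables (default 5).
#' @return object of class \code{qsar_pls} with per-component weights
#'   \code{W}, loadings \code{P}, scores \code{T}, y-loadings \code{q},
#'   cumulative coefficient matrix \code{B} (one column per component
#'   count), centering vectors, fitted values and \code{r2} per component.
#' @export
qsar_pls <- function(X, y, ncomp = 5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (n < 3) stop("need at least 3 molecules")
  if (stats::sd(y) == 0) stop("constant y: nothing to model")
  if (ncomp > min(n - 1, p))
    stop("ncomp = ", ncomp, " exceeds min(rows - 1, columns) = ",
         min(n - 1, p))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  k_eff <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X deflated to noise floor: stop early
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pk <- crossprod(Xd, t_) / tt
    qk <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(pk)
    yd <- yd - t_ * qk
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- t_; q[k] <- qk
    k_eff <- k
  }
  if (k_eff == 0L) stop("X carries no covariance with y (all-zero weights)")
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  Tm <- Tm[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]
  # cumulative regression coefficients per component count
  R <- W %*% solve(t(P) %*% W)   # projection weights (p x k)
  B <- sapply(seq_len(k_eff), function(k)
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
  B <- matrix(B, nrow = p)
  fitted_all <- y_mean + Xc %*% B
  tss <- sum(yc^2)
  r2 <- 1 - colSums((y - fitted_all)^2) / tss
  structure(list(ncomp = k_eff, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, scores = Tm, q = q, B = B,
                 coefficients = B[, k_eff], fitted = fitted_all[, k_eff],
                 fitted_by_ncomp = fitted_all, r2 = r2, y = y,
                 field_index = attr(X, "field_index"),
                 lattice = attr(X, "lattice"),
                 call = match.call()),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("PLS 3D-QSAR model: %d molecules, %d descriptors, %d component(s)\n",
              length(x$y), length(x$coefficients), x$ncomp))
  cat(sprintf("r2 (by components): %s\n",
              paste(sprintf("%.3f", x$r2), collapse = " ")))
  invisible(x)
}

#' @export
summary.qsar_pls <- function(object, ...) {
  res <- object$y - object$fitted
  out <- list(ncomp = object$ncomp, r2 = object$r2,
              sdec = sqrt(mean(res^2)),
              n = length(object$y), p = length(object$coefficients))
  class(out) <- "summary.qsar_pls"
  out
}

#' @export
print.summary.qsar_pls <- function(x, ...) {
  cat(sprintf("PLS 3D-QSAR model (%d x %d), %d component(s)\n",
              x$n, x$p, x$ncomp))
  cat(sprintf("  r2 at %d comps: %.4f   SDEC: %.4f\n",
              x$ncomp, x$r2[x$ncomp], x$sdec))
  cat("  r2 path:", paste(sprintf("%.3f", x$r2), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.qsar_pls <- function(object, ncomp = object$ncomp, ...) {
  object$B[, ncomp]
}

#' Predict activities from a fitted PLS model
#'
#' @param object a \code{qsar_pls}.
#' @param newdata matrix whose columns match the model's retained columns
#'   (apply the frozen pretreatment mask first); defaults to training fits.
#' @param ncomp number of components to use.
#' @param ... unused.
#' @return numeric vector of predicted pKi.
#' @export
predict.qsar_pls <- function(object, newdata = NULL,
                             ncomp = object$ncomp, ...) {
  if (is.null(newdata)) return(object$fitted_by_ncomp[, ncomp])
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("column mismatch: model has ", length(object$x_mean),
         " descriptors, newdata has ", ncol(newdata))
  as.numeric(object$y_mean +
               sweep(newdata, 2, object$x_mean) %*% object$B[, ncomp])
}

#' @export
fitted.qsar_pls <- function(object, ...) object$fitted

#' @export
residuals.qsar_pls <- function(object, ...) object$y - object$fitted

#' @method plot qsar_pls
#' @export
plot.qsar_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "observed pKi",
                 ylab = "recalculated pKi",
                 main = sprintf("PLS model, %d component(s), r2 = %.3f",
                                x$ncomp, x$r2[x$ncomp]), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Cross-validate a PLS model
#'
#' Leave-one-out or leave-some-out (random groups) cross-validation; every
#' fold refits the PLS model from scratch on the retained descriptor
#' columns (the pretreatment itself stays frozen, mirroring how the model
#' would meet genuinely new compounds). q2 = 1 - PRESS / sum((y - mean(y))^2)
#' with the full-sample mean; SDEP = sqrt(PRESS / n). LSO statistics are
#' averaged over \code{repeats} random partitions.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param ncomp maximum components; statistics are returned for 1..ncomp.
#' @param scheme \code{"loo"} or \code{"lso"}.
#' @param groups number of LSO groups (default 5).
#' @param repeats number of random LSO partitions averaged.
#' @param seed RNG seed for the LSO partitions.
#' @return list with per-component \code{q2} and \code{sdep}, plus
#'   \code{scheme}, \code{groups}, \code{repeats}, \code{seed}.
#' @export
cross_validate <- function(X, y, ncomp = 5, scheme = c("loo", "lso"),
                           groups = 5, repeats = 20, seed = 1) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (scheme == "loo" && n < 4) stop("LOO needs at least 4 molecules")
  if (scheme == "lso" && groups > n) stop("more groups than molecules")
  ncomp <- min(ncomp, n - 2, ncol(X))
  tss <- sum((y - mean(y))^2)
  press_for <- function(fold_of) {
    press <- numeric(ncomp)
    for (g in unique(fold_of)) {
      hold <- fold_of == g
      fit <- qsar_pls(X[!hold, , drop = FALSE], y[!hold],
                      ncomp = min(ncomp, sum(!hold) - 1))
      for (k in seq_len(ncomp)) {
        kk <- min(k, fit$ncomp)
        pred <- predict(fit, X[hold, , drop = FALSE], ncomp = kk)
        press[k] <- press[k] + sum((y[hold] - pred)^2)
      }
    }
    press
  }
  if (scheme == "loo") {
    press <- press_for(seq_len(n))
    q2 <- 1 - press / tss
    sdep <- sqrt(press / n)
  } else {
    q2m <- matrix(0, repeats, ncomp)
    sdepm <- matrix(0, repeats, ncomp)
    with_seed(seed, {
      for (r in seq_len(repeats)) {
        fold_of <- sample(rep_len(seq_len(groups), n))
        press <- press_for(fold_of)
        q2m[r, ] <- 1 - press / tss
        sdepm[r, ] <- sqrt(press / n)
      }
    })
    q2 <- colMeans(q2m)
    sdep <- colMeans(sdepm)
  }
  list(q2 = q2, sdep = sdep, scheme = scheme,
       groups = if (scheme == "lso") groups else n,
       repeats = if (scheme == "lso") repeats else 1L,
       seed = seed, ncomp = ncomp)
}

#' Y-scrambling validation
#'
#' Refits the model after permuting the activities (sampling without
#' replacement) and averages r2, LOO q2 and LSO q2 over the permutations.
#' A real structure-activity relation shows scrambled statistics far below
#' the true model's. FFD selection is not re-run inside the scramble (the
#' scrambled statistics then bound the optimistic bias of the fixed
#' descriptor set).
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param ncomp components for the refits.
#' @param n_perm number of permutations (>= 10; default 100).
#' @param seed RNG seed.
#' @param lso_groups,lso_repeats LSO settings inside the scramble.
#' @param perms optional list of explicit permutations (testing hook,
#'   overrides \code{n_perm}).
#' @return list with averages \code{r2_ys}, \code{q2_ys_loo},
#'   \code{q2_ys_lso} and the per-iteration \code{trace}.
#' @export
y_scramble <- function(X, y, ncomp = 5, n_perm = 100, seed = 1,
                       lso_groups = 5, lso_repeats = 1, perms = NULL) {
  if (is.null(perms)) {
    if (n_perm < 10) stop("n_perm must be at least 10")
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(i)
      sample(length(y))))
  }
  ncomp <- min(ncomp, nrow(X) - 2, ncol(X))
  trace <- do.call(rbind, lapply(seq_along(perms), function(i) {
    yp <- y[perms[[i]]]
    fit <- qsar_pls(X, yp, ncomp = ncomp)
    loo <- cross_validate(X, yp, ncomp = ncomp, scheme = "loo")
    lso <- cross_validate(X, yp, ncomp = ncomp, scheme = "lso",
                          groups = lso_groups, repeats = lso_repeats,
                          seed = seed + i)
    data.frame(perm = i, r2 = fit$r2[fit$ncomp],
               q2_loo = max(loo$q2), q2_lso = max(lso$q2))
  }))
  list(r2_ys = mean(trace$r2), q2_ys_loo = mean(trace$q2_loo),
       q2_ys_lso = mean(trace$q2_lso), trace = trace,
       n_perm = length(perms), seed = seed)
}

#' External prediction report
#'
#' Predicts an external set with a fitted model and reports the per-compound
#' absolute error of prediction (AEP, pKi units), their mean (AAEP) and the
#' predictive q2, q2_pred = 1 - sum((yhat - y)^2) / sum((y - ybar_TR)^2),
#' whose denominator is anchored on the training-set mean.
#'
#' @param model a \code{qsar_pls}.
#' @param X_new external descriptor matrix (same frozen pretreatment).
#' @param y_new optional observed activities.
#' @param ncomp components to use.
#' @return object of class \code{prediction_report}: \code{predicted},
#'   and, when \code{y_new} is given, \code{aep}, \code{aaep},
#'   \code{q2_pred}.
#' @export
prediction_report <- function(model, X_new, y_new = NULL,
                              ncomp = model$ncomp) {
  yhat <- predict(model, X_new, ncomp = ncomp)
  out <- list(predicted = yhat, ncomp = ncomp)
  if (!is.null(y_new)) {
    y_new <- as.numeric(y_new)
    if (length(y_new) != length(yhat))
      stop("y_new length mismatch")
    out$observed <- y_new
    out$aep <- abs(yhat - y_new)
    out$aaep <- mean(out$aep)
    out$q2_pred <- 1 - sum((yhat - y_new)^2) /
      sum((y_new - model$y_mean)^2)
  }
  structure(out, class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("External prediction (%d compounds, %d comps)\n",
              length(x$predicted), x$ncomp))
  if (!is.null(x$aaep))
    cat(sprintf("  AAEP: %.3f pKi units   q2_pred: %.3f\n",
                x$aaep, x$q2_pred))
  invisible(x)
}
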