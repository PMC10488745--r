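#' Clamp field energies to a symmetric cutoff
#'
#' Every entry is clamped into [-cutoff, +cutoff] (kcal/mol). Idempotent.
#'
#' @param X descriptor matrix.
#' @param cutoff positive cutoff CO, kcal/mol.
#' @export
apply_cutoff <- function(X, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  X[] <- pmin(pmax(X, -cutoff), cutoff)
  X
}

#' Zero out small field energies
#'
#' Entries with |x| < z become 0 (kcal/mol). z = 0 is the identity;
#' idempotent.
#'
#' @param X descriptor matrix.
#' @param z zeroing threshold Z, >= 0.
#' @export
apply_zeroing <- function(X, z) {
  if (!is.numeric(z) || z < 0) stop("zeroing threshold must be >= 0")
  X[abs(X) < z] <- 0
  X
}

#' Drop low-variance descriptor columns
#'
#' Columns whose sample standard deviation (n-1 denominator) falls below
#' \code{min_sd} are removed; near-constant columns (including the
#' few-level discrete ones) go with them. The returned mask records the
#' survivors so coefficient maps can be re-expanded with zeros at dropped
#' points, and so the same mask can be frozen and applied to prediction
#' sets.
#'
#' @param X descriptor matrix with >= 2 rows.
#' @param min_sd minimum standard deviation SD, >= 0.
#' @return list with \code{X} (filtered matrix, attributes preserved and
#'   index subset) and \code{mask} (logical, length = original columns).
#' @export
sd_filter <- function(X, min_sd) {
  if (nrow(X) < 2) stop("sd_filter needs at least 2 rows")
  if (!is.numeric(min_sd) || min_sd < 0) stop("min_sd must be >= 0")
  sds <- apply(X, 2, stats::sd)
  mask <- sds >= min_sd & is.finite(sds)
  Xf <- subset_columns(X, mask)
  list(X = Xf, mask = mask)
}

# keep field_index / lattice attributes in step with a column subset
subset_columns <- function(X, mask) {
  idx <- attr(X, "field_index"); lat <- attr(X, "lattice")
  Xf <- X[, mask, drop = FALSE]
  if (!is.null(idx)) attr(Xf, "field_index") <- idx[mask, , drop = FALSE]
  if (!is.null(lat)) attr(Xf, "lattice") <- lat
  Xf
}

#' Pretreatment parameter set
#'
#' @param cutoff energy cutoff CO, kcal/mol (> 0); entries clamp to +-CO.
#' @param zeroing zeroing threshold Z, kcal/mol (>= 0); |x| < Z becomes 0.
#' @param min_sd minimum column standard deviation SD (>= 0).
#' @return object of class \code{pretreatment_params}.
#' @export
pretreatment_params <- function(cutoff = 5, zeroing = 0.01, min_sd = 0.05) {
  stopifnot(cutoff > 0, zeroing >= 0, min_sd >= 0)
  structure(list(cutoff = cutoff, zeroing = zeroing, min_sd = min_sd),
            class = "pretreatment_params")
}

#' Apply the full pretreatment chain
#'
#' Fixed operator order: cutoff, then zeroing, then SD filter. Applying the
#' chain twice equals applying it once. Pretreatment is fitted on the
#' training block only; use the returned mask (and the same cutoff/zeroing)
#' on any prediction set so no information leaks from it.
#'
#' @param X raw descriptor matrix.
#' @param params a \code{\link{pretreatment_params}}.
#' @return list with \code{X}, \code{mask} and \code{params}.
#' @export
pretreat <- function(X, params = pretreatment_params()) {
  stopifnot(inherits(params, "pretreatment_params"))
  X <- apply_cutoff(X, params$cutoff)
  X <- apply_zeroing(X, params$zeroing)
  out <- sd_filter(X, params$min_sd)
  out$params <- params
  out
}

#' Apply a frozen pretreatment to new data
#'
#' @param X_new matrix with the same raw columns as the training block.
#' @param fit result of \code{\link{pretreat}}.
#' @export
pretreat_apply <- function(X_new, fit) {
  if (ncol(X_new) != length(fit$mask))
    stop("column count mismatch: expected ", length(fit$mask),
         ", got ", ncol(X_new))
  X_new <- apply_cutoff(X_new, fit$params$cutoff)
  X_new <- apply_zeroing(X_new, fit$params$zeroing)
  subset_columns(X_new, fit$mask)
}

#' Variable pretreatment optimization (VPO)
#'
#' Exhaustive grid search over (cutoff, zeroing, min_sd) triples maximizing
#' the cross-validated q2 of a PLS model fitted on the pretreated matrix.
#' The default grid scans cutoffs 1..5 kcal/mol in steps of 1, zeroing
#' 0.005..0.05 in steps of 0.005, and SD thresholds 0.01..0.1 in steps of
#' 0.01. Ties break toward smaller cutoff, then smaller zeroing, then larger
#' SD (the sparser model). A triple that empties the matrix is recorded with
#' q2 = -Inf and never aborts the scan.
#'
#' @param X_raw raw descriptor matrix.
#' @param y activity vector.
#' @param cutoffs,zeroings,sds grid values.
#' @param ncomp maximum number of PLS components (best by CV is used).
#' @param objective \code{"q2_loo"} or \code{"q2_lso"}.
#' @param groups,repeats,seed LSO settings (ignored for LOO).
#' @return list with \code{best} (a \code{pretreatment_params}),
#'   \code{q2} of the optimum, and \code{surface} (data.frame of the full
#'   scan).
#' @export
vpo_search <- function(X_raw, y,
                       cutoffs = seq(1, 5, by = 1),
                       zeroings = seq(0.005, 0.05, by = 0.005),
                       sds = seq(0.01, 0.1, by = 0.01),
                       ncomp = 5,
                       objective = c("q2_loo", "q2_lso"),
                       groups = 5, repeats = 5, seed = 1) {
  objective <- match.arg(objective)
  stopifnot(length(cutoffs) > 0, length(zeroings) > 0, length(sds) > 0,
            all(cutoffs > 0), all(zeroings > 0), all(sds > 0),
            nrow(X_raw) == length(y))
  grid <- expand.grid(cutoff = cutoffs, zeroing = zeroings, min_sd = sds)
  q2 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pp <- pretreatment_params(grid$cutoff[g], grid$zeroing[g], grid$min_sd[g])
    pt <- pretreat(X_raw, pp)
    if (ncol(pt$X) == 0L || all(apply(pt$X, 2, stats::sd) == 0)) {
      q2[g] <- -Inf
      next
    }
    nc <- min(ncomp, nrow(pt$X) - 2L, ncol(pt$X))
    q2[g] <- tryCatch({
      cv <- if (objective == "q2_loo")
        cross_validate(pt$X, y, ncomp = nc, scheme = "loo")
      else
        cross_validate(pt$X, y, ncomp = nc, scheme = "lso",
                       groups = groups, repeats = repeats, seed = seed)
      max(cv$q2)
    }, error = function(e) -Inf)
  }
  grid$q2 <- q2
  # argmax with documented tie-break: smaller CO, smaller Z, larger SD
  ord <- order(-grid$q2, grid$cutoff, grid$zeroing, -grid$min_sd)
  best <- grid[ord[1], ]
  list(best = pretreatment_params(best$cutoff, best$zeroing, best$min_sd),
       q2 = best$q2, surface = grid)
}
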