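#' Fractional-factorial-design variable selection
#'
#' GOLPE-style FFD selection: a two-level design over the real descriptor
#' columns plus a fraction of inert dummy variables is generated (about
#' \code{design_mult} times as many design rows as variables); each design
#' row fits a PLS model on the included real columns and records its
#' cross-validated SDEP. A variable's effect is
#' mean SDEP(rows excluding it) - mean SDEP(rows including it): positive
#' means removing it hurts prediction. Dummies never touch the matrix, so
#' their effect distribution estimates pure design noise; a real column is
#' retained when its effect exceeds the dummy mean + 2 standard deviations
#' (clearly helpful). Columns inside the dummy band are uncertain and are
#' dropped by default (\code{keep_uncertain = FALSE}); columns below the
#' band are detrimental and always dropped.
#'
#' @param X descriptor matrix (>= 10 columns).
#' @param y activity vector.
#' @param ncomp PLS components for the per-row fits.
#' @param dummy_ratio fraction of dummies relative to real columns, in
#'   (0, 0.5].
#' @param design_mult design rows per variable (default 2).
#' @param cv_scheme \code{"loo"} or \code{"lso"} for the per-row SDEP.
#' @param groups LSO groups.
#' @param seed RNG seed; the whole selection is deterministic under it.
#' @param keep_uncertain retain columns whose effect sits inside the dummy
#'   noise band?
#' @return object of class \code{ffd_result}: \code{keep} (logical mask over
#'   real columns, dummies never appear), \code{effects},
#'   \code{dummy_effects}, \code{threshold}, \code{design}, \code{sdep}.
#' @export
ffd_select <- function(X, y, ncomp = 5, dummy_ratio = 0.2, design_mult = 2,
                       cv_scheme = c("loo", "lso"), groups = 5, seed = 1,
                       keep_uncertain = FALSE) {
  cv_scheme <- match.arg(cv_scheme)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 10)
    stop("FFD design infeasible with ", p,
         " columns (< 10); skip FFD for such small models")
  if (!(dummy_ratio > 0 && dummy_ratio <= 0.5))
    stop("dummy_ratio must be in (0, 0.5]")
  nd <- max(2L, ceiling(dummy_ratio * p))
  nv <- p + nd
  nrows <- ceiling(design_mult * nv)
  with_seed(seed, {
    D <- matrix(stats::runif(nrows * nv) > 0.5, nrows, nv)
    # every variable must be included and excluded at least twice,
    # and every row must keep at least 2 real columns
    for (j in seq_len(nv)) {
      while (sum(D[, j]) < 2 || sum(!D[, j]) < 2)
        D[, j] <- stats::runif(nrows) > 0.5
    }
    for (i in seq_len(nrows)) {
      while (sum(D[i, seq_len(p)]) < 2)
        D[i, seq_len(p)] <- stats::runif(p) > 0.5
    }
    sdep <- vapply(seq_len(nrows), function(i) {
      cols <- which(D[i, seq_len(p)])
      Xi <- X[, cols, drop = FALSE]
      nc <- min(ncomp, nrow(Xi) - 2, ncol(Xi))
      cv <- tryCatch(
        cross_validate(Xi, y, ncomp = nc, scheme = cv_scheme,
                       groups = groups, repeats = 1, seed = seed + i),
        error = function(e) NULL)
      if (is.null(cv)) NA_real_ else cv$sdep[length(cv$sdep)]
    }, numeric(1))
  })
  ok <- is.finite(sdep)
  effect <- vapply(seq_len(nv), function(j)
    mean(sdep[ok & !D[, j]]) - mean(sdep[ok & D[, j]]), numeric(1))
  eff_real <- effect[seq_len(p)]
  eff_dummy <- effect[(p + 1):nv]
  thr_hi <- mean(eff_dummy) + 2 * stats::sd(eff_dummy)
  thr_lo <- mean(eff_dummy) - 2 * stats::sd(eff_dummy)
  keep <- eff_real > thr_hi
  if (keep_uncertain) keep <- keep | (eff_real >= thr_lo)
  names(keep) <- colnames(X)
  structure(list(keep = keep, effects = eff_real,
                 dummy_effects = eff_dummy,
                 threshold = c(lower = thr_lo, upper = thr_hi),
                 design = D, sdep = sdep, dummy_ratio = dummy_ratio,
                 seed = seed, keep_uncertain = keep_uncertain),
            class = "ffd_result")
}

#' @export
print.ffd_result <- function(x, ...) {
  cat(sprintf(
    "FFD selection: %d/%d columns retained (%d dummies, noise band [%.4g, %.4g])\n",
    sum(x$keep), length(x$keep), length(x$dummy_effects),
    x$threshold[1], x$threshold[2]))
  invisible(x)
}
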