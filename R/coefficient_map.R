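#' Back-project PLS coefficients onto the lattice
#'
#' Produces one full-lattice coefficient grid per field kind from a fitted
#' model, re-inserting zeros at the points the pretreatment dropped. The
#' sign convention is: a positive coefficient at a point means that a
#' larger field value there increases the predicted activity (for the
#' steric field, bulk is favourable; for the electrostatic field under a
#' positive probe charge, positive potential is favourable). The grids are
#' exportable with \code{\link{write_grid_map}} for isocontour inspection.
#'
#' @param model a \code{qsar_pls} fitted on a matrix that carried a
#'   \code{field_index} attribute (from \code{\link{assemble_X}}, possibly
#'   subset by pretreatment), or supply \code{index}/\code{lattice}.
#' @param index optional data.frame (kind, ix, iy, iz) for the model's
#'   retained columns.
#' @param lattice optional \code{mif_lattice}.
#' @param ncomp component count for the coefficients.
#' @return named list (one element per field kind) of numeric vectors of
#'   length \code{n_points(lattice)}, in the package's x-fastest order,
#'   with attribute \code{lattice}; class \code{coef_map}.
#' @export
coefficient_map <- function(model, index = NULL, lattice = NULL,
                            ncomp = model$ncomp) {
  stopifnot(inherits(model, "qsar_pls"))
  if (is.null(index)) index <- model$field_index
  if (is.null(lattice)) lattice <- model$lattice
  if (is.null(index) || is.null(lattice))
    stop("no field index/lattice stored in the model; pass them explicitly")
  b <- model$B[, ncomp]
  if (length(b) != nrow(index))
    stop("coefficient count (", length(b),
         ") does not match index rows (", nrow(index), ")")
  d <- lattice$dims
  if (any(index$ix >= d[1] | index$iy >= d[2] | index$iz >= d[3]))
    stop("index/lattice mismatch: grid indices outside lattice dims")
  np <- n_points(lattice)
  out <- lapply(split(seq_len(nrow(index)), index$kind), function(rows) {
    g <- numeric(np)
    lin <- 1L + index$ix[rows] + d[1] * (index$iy[rows] + d[2] * index$iz[rows])
    g[lin] <- b[rows]
    g
  })
  # keep the STE/ELE presentation order stable
  ord <- intersect(c("STE", "ELE"), names(out))
  out <- out[ord]
  attr(out, "lattice") <- lattice
  class(out) <- "coef_map"
  out
}

#' @export
print.coef_map <- function(x, ...) {
  lat <- attr(x, "lattice")
  cat(sprintf("<PLS coefficient map: %s on %d-point lattice>\n",
              paste(names(x), collapse = " + "), n_points(lat)))
  for (k in names(x))
    cat(sprintf("  %s: |coef| max %.4g, %d nonzero points\n",
                k, max(abs(x[[k]])), sum(x[[k]] != 0)))
  invisible(x)
}

#' Write a coefficient map's grids to cube/dx files
#'
#' @param map a \code{coef_map}.
#' @param prefix output path prefix; files are named
#'   \code{<prefix>_<KIND>.<format>}.
#' @param format \code{"cube"} or \code{"dx"}.
#' @return invisible character vector of paths written.
#' @export
write_coef_map <- function(map, prefix, format = c("cube", "dx")) {
  format <- match.arg(format)
  lat <- attr(map, "lattice")
  paths <- vapply(names(map), function(k) {
    path <- paste0(prefix, "_", gsub("[^A-Za-z0-9]", "", k), ".", format)
    write_grid_map(lat, map[[k]], path, format)
    path
  }, character(1))
  invisible(paths)
}
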