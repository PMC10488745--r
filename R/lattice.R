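#' Build the common field lattice over an aligned series
#'
#' The lattice is the regular 3-D grid on which every molecular interaction
#' field is sampled; all molecules of a series share it, so field columns are
#' comparable across molecules. The origin is the elementwise minimum over
#' all heavy-atom coordinates minus the margin, snapped down to a multiple of
#' the spacing; the far corner covers the elementwise maximum plus the margin.
#'
#' @param molecules list of \code{qsar_mol} (or poses), all in one frame.
#' @param spacing grid spacing GS, Angstrom (> 0).
#' @param margin extra space around the series, Angstrom (>= 0).
#' @return object of class \code{mif_lattice}: \code{origin}, \code{spacing},
#'   \code{dims} (nx, ny, nz).
#' @export
build_lattice <- function(molecules, spacing = 1, margin = 5) {
  if (inherits(molecules, "qsar_mol") || inherits(molecules, "qsar_pose"))
    molecules <- list(molecules)
  if (!length(molecules)) stop("empty molecule list")
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(molecules, function(m)
    coords(as_qsar_mol(m), heavy_only = TRUE)))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - origin) / spacing)) + 1L)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims),
            class = "mif_lattice")
}

#' Number of lattice points
#' @param lattice a \code{mif_lattice}.
#' @export
n_points <- function(lattice) prod(lattice$dims)

#' Lattice point coordinates
#'
#' Points are linearized x-fastest: index i = ix + nx*(iy + ny*iz) (0-based
#' grid indices, 1-based vector index). Format writers convert to each file
#' format's native order.
#'
#' @param lattice a \code{mif_lattice}.
#' @return matrix n_points x 3 of Cartesian coordinates, Angstrom.
#' @export
lattice_points <- function(lattice) {
  d <- lattice$dims; s <- lattice$spacing; o <- lattice$origin
  ix <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  iz <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(x = o[1] + ix * s, y = o[2] + iy * s, z = o[3] + iz * s)
}

#' Grid indices of each lattice point
#'
#' @param lattice a \code{mif_lattice}.
#' @return integer matrix n_points x 3 of 0-based (ix, iy, iz), in the
#'   package's x-fastest linear order.
#' @export
lattice_index <- function(lattice) {
  d <- lattice$dims
  cbind(ix = rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        iy = rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        iz = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' @export
print.mif_lattice <- function(x, ...) {
  cat(sprintf(
    "<lattice %d x %d x %d, spacing %.3g A, origin (%.3g, %.3g, %.3g): %d points>\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3], n_points(x)))
  invisible(x)
}
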