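#' Write a scalar field on a lattice as a Gaussian cube or OpenDX map
#'
#' Values are supplied in the package's x-fastest linear order (see
#' \code{\link{lattice_points}}); the writer converts to each format's
#' native z-fastest order. Cube files use Bohr for lengths (the format's
#' convention); OpenDX files stay in Angstrom. The maps are what molecular
#' viewers contour, e.g. positive/negative PLS-coefficient isosurfaces.
#'
#' @param lattice a \code{mif_lattice}.
#' @param values numeric vector, one value per lattice point.
#' @param path output file.
#' @param format \code{"cube"} or \code{"dx"}.
#' @export
write_grid_map <- function(lattice, values, path, format = c("cube", "dx")) {
  format <- match.arg(format)
  np <- n_points(lattice)
  if (length(values) != np)
    stop("values length mismatch: expected ", np, ", got ", length(values))
  d <- lattice$dims
  # x-fastest -> z-fastest reorder
  arr <- array(values, dim = d)
  vz <- as.vector(aperm(arr, c(3, 2, 1)))  # now z fastest, x slowest
  if (format == "cube") {
    b <- 1 / 0.52917721067  # Angstrom -> Bohr
    o <- lattice$origin * b; s <- lattice$spacing * b
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("mifqsar grid map", "scalar field on regular lattice"), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 1L, o[1], o[2], o[3]), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[1], s, 0, 0), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[2], 0, s, 0), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[3], 0, 0, s), con)
    # one placeholder atom (cube requires an atom block)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1L, 0, o[1], o[2], o[3]),
               con)
    idx <- seq_along(vz)
    rows <- split(vz, ceiling(idx / 6))
    writeLines(vapply(rows, function(r)
      paste(sprintf("%13.5E", r), collapse = ""), character(1)), con)
  } else {
    o <- lattice$origin; s <- lattice$spacing
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]), con)
    writeLines(sprintf("delta %.6f 0 0", s), con)
    writeLines(sprintf("delta 0 %.6f 0", s), con)
    writeLines(sprintf("delta 0 0 %.6f", s), con)
    writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf(
      "object 3 class array type double rank 0 items %d data follows", np),
      con)
    idx <- seq_along(vz)
    rows <- split(vz, ceiling(idx / 3))
    writeLines(vapply(rows, function(r)
      paste(sprintf("%.6e", r), collapse = " "), character(1)), con)
    writeLines("attribute \"dep\" string \"positions\"", con)
  }
  invisible(path)
}

#' Read a grid map written by \code{\link{write_grid_map}}
#'
#' @param path cube or dx file.
#' @param format \code{"cube"} or \code{"dx"}; guessed from the extension.
#' @return list with \code{lattice} and \code{values} (x-fastest order).
#' @export
read_grid_map <- function(path, format = c("auto", "cube", "dx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), cube = "cube", dx = "dx",
                     stop("cannot guess grid format of ", path))
  lines <- readLines(path)
  if (format == "cube") {
    b <- 0.52917721067
    h <- read_nums(lines[3]); natoms <- as.integer(h[1])
    origin <- h[2:4] * b
    hx <- read_nums(lines[4]); hy <- read_nums(lines[5]); hz <- read_nums(lines[6])
    d <- as.integer(c(hx[1], hy[1], hz[1]))
    spacing <- hx[2] * b
    data_start <- 7 + abs(natoms)
    vz <- read_nums(paste(lines[data_start:length(lines)], collapse = " "))
  } else {
    cl <- grep("gridpositions counts", lines, value = TRUE)[1]
    d <- as.integer(utils::tail(read_nums(cl), 3))
    origin <- read_nums(grep("^origin", lines, value = TRUE)[1])
    deltas <- grep("^delta", lines, value = TRUE)
    spacing <- max(read_nums(deltas[1]))
    i0 <- grep("data follows", lines) + 1
    i1 <- grep("^attribute", lines) - 1
    if (!length(i1)) i1 <- length(lines)
    vz <- read_nums(paste(lines[i0:i1], collapse = " "))
  }
  np <- prod(d)
  if (length(vz) != np)
    stop("grid data length ", length(vz), " != ", np, " points")
  arr <- array(vz, dim = rev(d))            # file order: z fastest
  values <- as.vector(aperm(arr, c(3, 2, 1)))  # back to x fastest
  lattice <- structure(list(origin = origin, spacing = spacing, dims = d),
                       class = "mif_lattice")
  list(lattice = lattice, values = values)
}

read_nums <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  v[!is.na(v)]
}
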