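#' Construct a molecule
#'
#' The basic unit of alignment, RMSD and field computation: an ordered set of
#' atoms with Cartesian coordinates (Angstrom), elements and partial charges
#' (elementary charge units), optionally carrying an activity (pKi = -log Ki)
#' and a free-text pharmacology label (e.g. AG/IA/PA/FA).
#'
#' @param name molecule identifier.
#' @param elements character vector of chemical symbols.
#' @param coords numeric matrix, n_atoms x 3, Angstrom.
#' @param charges numeric vector of partial charges; defaults to zeros.
#' @param activity optional pKi value.
#' @param role optional pharmacology label.
#' @return an object of class \code{qsar_mol}.
#' @export
molecule <- function(name, elements, coords, charges = NULL,
                     activity = NULL, role = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  elements <- as.character(elements)
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)")
  if (any(!nzchar(elements)) || anyNA(elements))
    stop("every atom needs a non-empty element symbol")
  if (any(!is.finite(coords)))
    stop("coordinates must be finite")
  if (is.null(charges)) charges <- rep(0, length(elements))
  if (length(charges) != length(elements))
    stop("length(charges) must equal number of atoms")
  is_h <- toupper(elements) == "H"
  if (all(is_h))
    stop("molecule '", name, "' has no heavy atom")
  structure(
    list(name = as.character(name),
         atoms = data.frame(element = elements,
                            x = coords[, 1], y = coords[, 2], z = coords[, 3],
                            charge = as.numeric(charges), is_h = is_h,
                            stringsAsFactors = FALSE),
         activity = if (is.null(activity)) NA_real_ else as.numeric(activity),
         role = role),
    class = "qsar_mol")
}

#' Atom coordinates of a molecule
#'
#' @param mol a \code{qsar_mol}.
#' @param heavy_only drop hydrogens first?
#' @return numeric matrix n x 3.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  stopifnot(inherits(mol, "qsar_mol"))
  a <- mol$atoms
  if (heavy_only) a <- a[!a$is_h, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Number of atoms
#' @param mol a \code{qsar_mol}.
#' @param heavy_only count heavy atoms only?
#' @export
n_atoms <- function(mol, heavy_only = FALSE) {
  stopifnot(inherits(mol, "qsar_mol"))
  if (heavy_only) sum(!mol$atoms$is_h) else nrow(mol$atoms)
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy)%s>\n", x$name,
              nrow(x$atoms), sum(!x$atoms$is_h),
              if (is.finite(x$activity))
                sprintf(", pKi %.2f", x$activity) else ""))
  invisible(x)
}

#' Wrap a molecule as a docking pose
#'
#' A pose is a molecule conformation tagged with its provenance (engine /
#' scoring-function label, stage) and an optional engine score. The score is
#' opaque: it is only used to order candidate poses, never interpreted.
#'
#' @param mol a \code{qsar_mol}.
#' @param source_label free-text origin of the pose.
#' @param score optional engine score.
#' @return an object of class \code{qsar_pose}.
#' @export
pose <- function(mol, source_label = "", score = NA_real_) {
  stopifnot(inherits(mol, "qsar_mol"))
  structure(list(molecule = mol, source_label = source_label,
                 score = as.numeric(score)),
            class = "qsar_pose")
}

#' @export
print.qsar_pose <- function(x, ...) {
  cat(sprintf("<pose of %s [%s]%s>\n", x$molecule$name, x$source_label,
              if (is.finite(x$score)) sprintf(", score %.3f", x$score) else ""))
  invisible(x)
}

# accept either a pose or a bare molecule where a pose is expected
as_qsar_mol <- function(x) {
  if (inherits(x, "qsar_pose")) x$molecule
  else if (inherits(x, "qsar_mol")) x
  else stop("expected a qsar_mol or qsar_pose")
}

# run expr with a private, restored RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
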