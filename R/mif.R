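#' Default probe table
#'
#' Eight probe pseudo-atoms: CR (alkyl carbon), CB (aromatic carbon), NC=O
#' (amide nitrogen), NR (amine nitrogen), O=C (carbonyl oxygen), OH2 (water
#' oxygen), HNCO (amide hydrogen) and ELE (a bare +1 point charge producing
#' only the electrostatic field). Lennard-Jones parameters are given as
#' Rmin/2 (Angstrom) and epsilon (kcal/mol) in the AMBER convention; charges
#' in elementary units. These are declared package defaults in the spirit of
#' common force-field values (e.g. a TIP3P-like water oxygen), overridable
#' through \code{\link{probe_spec}}.
#'
#' @return named list of \code{probe_spec} objects.
#' @export
default_probes <- function() {
  list(
    "CR"   = probe_spec("CR",   1.9080, 0.1094,  1.000),
    "CB"   = probe_spec("CB",   1.8500, 0.0860,  1.000),
    "NC=O" = probe_spec("NC=O", 1.8240, 0.1700, -0.500),
    "NR"   = probe_spec("NR",   1.8240, 0.1700, -0.700),
    "O=C"  = probe_spec("O=C",  1.6612, 0.2100, -0.500),
    "OH2"  = probe_spec("OH2",  1.7683, 0.1521, -0.834),
    "HNCO" = probe_spec("HNCO", 0.6000, 0.0157,  0.400),
    "ELE"  = probe_spec("ELE",  0.0000, 0.0000,  1.000, fields = "ELE")
  )
}

#' Define a field probe
#'
#' @param name probe label.
#' @param lj_rmin Rmin/2 of the probe, Angstrom.
#' @param lj_epsilon well depth, kcal/mol (>= 0).
#' @param charge probe charge, elementary units.
#' @param fields which fields the probe produces: the electrostatic-only ELE
#'   probe produces \code{"ELE"}, every other probe both \code{"STE"} and
#'   \code{"ELE"}.
#' @return object of class \code{probe_spec}.
#' @export
probe_spec <- function(name, lj_rmin, lj_epsilon, charge,
                       fields = c("STE", "ELE")) {
  stopifnot(lj_epsilon >= 0)
  fields <- match.arg(fields, c("STE", "ELE"), several.ok = TRUE)
  structure(list(name = name, lj_rmin = lj_rmin, lj_epsilon = lj_epsilon,
                 charge = charge, fields = fields),
            class = "probe_spec")
}

# per-element Lennard-Jones parameters (Rmin/2 in Angstrom, epsilon kcal/mol),
# AMBER-style generic values; config-overridable via the `vdw` argument of
# compute_mif.
default_vdw_table <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "F", "P", "S", "CL", "BR", "I"),
    rmin    = c(1.4870, 1.9080, 1.8240, 1.6612, 1.75, 2.10, 2.00, 1.948,
                2.22, 2.35),
    eps     = c(0.0157, 0.1094, 0.1700, 0.2100, 0.061, 0.20, 0.25, 0.265,
                0.32, 0.40),
    stringsAsFactors = FALSE)
}

#' Compute molecular interaction fields on a lattice
#'
#' The probe is placed at every lattice point and its interaction energy with
#' the molecule is summed over atoms. The steric field is a 12-6
#' Lennard-Jones potential in the epsilon/Rmin parameterization with
#' Lorentz-Berthelot combination (Rmin_ij = Rmin/2_i + Rmin/2_probe,
#' eps_ij = sqrt(eps_i eps_probe)):
#' STE = sum_i eps_ij [ (Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6 ].
#' The electrostatic field is Coulombic,
#' ELE = sum_i 332.0636 q_i q_probe / (eps(r) r),
#' with a constant dielectric eps(r) = 1 by default or the distance-dependent
#' eps(r) = r. Distances below 0.01 Angstrom are clamped to 0.01. Energies
#' are kcal/mol. No per-point energy clamping happens here; that belongs to
#' pretreatment so the raw fields stay reusable across cutoff scans.
#'
#' @param mol a \code{qsar_mol} (charges may be zero).
#' @param lattice a \code{mif_lattice}.
#' @param probe a \code{probe_spec} or a probe name from
#'   \code{\link{default_probes}}.
#' @param dielectric \code{"constant"} or \code{"distance"}.
#' @param vdw per-element Lennard-Jones table (columns element, rmin, eps).
#' @return named list of \code{mif_field} objects (one row of values per
#'   molecule call), keyed by field kind ("STE", "ELE").
#' @export
compute_mif <- function(mol, lattice, probe = "OH2",
                        dielectric = c("constant", "distance"),
                        vdw = default_vdw_table()) {
  dielectric <- match.arg(dielectric)
  if (is.character(probe)) {
    probes <- default_probes()
    if (!probe %in% names(probes)) stop("unknown probe: ", probe)
    probe <- probes[[probe]]
  }
  stopifnot(inherits(probe, "probe_spec"))
  mol <- as_qsar_mol(mol)
  pts <- lattice_points(lattice)
  xyz <- coords(mol)
  el <- toupper(mol$atoms$element)
  row <- match(el, vdw$element)
  if ("STE" %in% probe$fields && anyNA(row))
    stop("no van der Waals parameters for element '",
         mol$atoms$element[which(is.na(row))[1]], "'")
  # n_points x n_atoms distance matrix; clamp below 0.01 A
  d2 <- outer(rowSums(pts^2), rep(1, nrow(xyz))) +
    outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * pts %*% t(xyz)
  r <- sqrt(pmax(d2, 1e-4))
  out <- list()
  if ("STE" %in% probe$fields) {
    rmin_ij <- vdw$rmin[row] + probe$lj_rmin
    eps_ij <- sqrt(vdw$eps[row] * probe$lj_epsilon)
    s6 <- sweep(1 / r, 2, rmin_ij, `*`)^6
    ste <- (s6^2 - 2 * s6) %*% eps_ij
    out$STE <- field_block(probe, "STE", as.numeric(ste), lattice, mol$name)
  }
  if ("ELE" %in% probe$fields) {
    denom <- if (dielectric == "distance") r^2 else r
    ele <- (332.0636 / denom) %*% (mol$atoms$charge * probe$charge)
    out$ELE <- field_block(probe, "ELE", as.numeric(ele), lattice, mol$name)
  }
  out
}

field_block <- function(probe, kind, values, lattice, mol_names) {
  values <- matrix(values, nrow = length(mol_names), byrow = TRUE)
  rownames(values) <- mol_names
  structure(list(probe = probe$name, kind = kind, values = values,
                 lattice = lattice),
            class = "mif_field")
}

#' Compute fields for a whole series
#'
#' Convenience wrapper around \code{\link{compute_mif}} stacking one row per
#' molecule into per-kind field blocks.
#'
#' @param molecules list of \code{qsar_mol}.
#' @inheritParams compute_mif
#' @return named list of \code{mif_field} blocks ("STE", "ELE"), each with a
#'   molecules x lattice-points value matrix.
#' @export
compute_mif_series <- function(molecules, lattice, probe = "OH2",
                               dielectric = c("constant", "distance"),
                               vdw = default_vdw_table()) {
  dielectric <- match.arg(dielectric)
  per_mol <- lapply(molecules, compute_mif, lattice = lattice, probe = probe,
                    dielectric = dielectric, vdw = vdw)
  kinds <- names(per_mol[[1]])
  out <- lapply(kinds, function(k) {
    b <- per_mol[[1]][[k]]
    b$values <- do.call(rbind, lapply(per_mol, function(p) p[[k]]$values))
    rownames(b$values) <- vapply(molecules, function(m)
      as_qsar_mol(m)$name, character(1))
    b
  })
  names(out) <- kinds
  out
}

#' @export
print.mif_field <- function(x, ...) {
  cat(sprintf("<%s field, probe %s: %d molecule(s) x %d points>\n",
              x$kind, x$probe, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Assemble the QSAR descriptor matrix from field blocks
#'
#' Selects the steric block, the electrostatic block, or their column-wise
#' concatenation [STE | ELE]. The returned matrix carries a column index
#' mapping every column to (field kind, 0-based grid indices ix, iy, iz);
#' the mapping is invertible, which is what lets PLS coefficients be
#' projected back onto the lattice.
#'
#' @param field_blocks named list of \code{mif_field} ("STE", "ELE") sharing
#'   one lattice and molecule ordering.
#' @param field_selection \code{"STE"}, \code{"ELE"} or \code{"BOTH"}.
#' @return numeric matrix with attributes \code{field_index} (data.frame:
#'   kind, ix, iy, iz) and \code{lattice}.
#' @export
assemble_X <- function(field_blocks, field_selection = c("BOTH", "STE", "ELE")) {
  field_selection <- match.arg(field_selection)
  want <- if (field_selection == "BOTH") c("STE", "ELE") else field_selection
  missing <- setdiff(want, names(field_blocks))
  if (length(missing))
    stop("field block(s) not available: ", paste(missing, collapse = ", "))
  blocks <- field_blocks[want]
  lat <- blocks[[1]]$lattice
  for (b in blocks) {
    if (!identical(b$lattice$dims, lat$dims) ||
        max(abs(b$lattice$origin - lat$origin)) > 1e-9 ||
        abs(b$lattice$spacing - lat$spacing) > 1e-9)
      stop("field blocks do not share one lattice")
    if (nrow(b$values) != nrow(blocks[[1]]$values))
      stop("field blocks do not share molecule ordering")
  }
  X <- do.call(cbind, lapply(blocks, function(b) b$values))
  gi <- lattice_index(lat)
  idx <- do.call(rbind, lapply(want, function(k)
    data.frame(kind = k, ix = gi[, 1], iy = gi[, 2], iz = gi[, 3],
               stringsAsFactors = FALSE)))
  colnames(X) <- paste0(idx$kind, "_", idx$ix, "_", idx$iy, "_", idx$iz)
  attr(X, "field_index") <- idx
  attr(X, "lattice") <- lat
  X
}
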