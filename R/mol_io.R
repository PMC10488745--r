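#' Read molecules from SDF, MOL2 or PDB
#'
#' Atom order is preserved exactly as in the file; hydrogens are retained but
#' flagged. Partial charges are taken from the file where the format carries
#' them (MOL2); SDF and PDB carry none, so charges are zero-filled with a
#' warning. No charge assignment is attempted: charges are expected to have
#' been computed upstream.
#'
#' @param path file path.
#' @param format one of \code{"sdf"}, \code{"mol2"}, \code{"pdb"}; guessed
#'   from the file extension when missing.
#' @return a list of \code{\link{molecule}} objects.
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "mol2", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "sdf", mol2 = "mol2", pdb = "pdb",
                     stop("cannot guess format from extension of ", path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, warn = FALSE)) == 0L)
    stop("empty file: ", path)
  switch(format,
         sdf  = read_sdf(path),
         mol2 = read_mol2(path),
         pdb  = read_pdb(path))
}

check_elements <- function(elements, where) {
  known <- c("H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG",
             "AL", "SI", "P", "S", "CL", "K", "CA", "BR", "I", "SE", "ZN",
             "FE", "MN", "CU")
  bad <- which(!(toupper(elements) %in% known))
  if (length(bad))
    stop("unknown element '", elements[bad[1]], "' at atom index ", bad[1],
         " in ", where)
}

read_sdf <- function(path) {
  sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e) stop("SDF parse error in ", path, ": ",
                                            conditionMessage(e)))
  if (length(sdfs) == 0L) stop("no molecules in ", path)
  warning("SDF carries no partial charges; zero-filling charges for ", path)
  lapply(seq_along(ChemmineR::SDFset2SDF(sdfs)), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    check_elements(elements, path)
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || !nzchar(nm)) nm <- sprintf("mol%d", i)
    molecule(nm, elements, ab[, 1:3, drop = FALSE])
  })
}

read_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("MOL2 parse error in ", path, ": ",
                                         conditionMessage(e)))
  mols <- if (inherits(m, "mol2")) list(m) else m
  lapply(mols, function(mm) {
    at <- mm$atom
    elements <- sub("\\..*$", "", at$elety)
    check_elements(elements, path)
    ch <- at$charge
    if (is.null(ch) || all(is.na(ch))) {
      warning("no charges in MOL2 ", path, "; zero-filling")
      ch <- rep(0, nrow(at))
    }
    molecule(mm$name, elements, cbind(at$x, at$y, at$z), ch)
  })
}

read_pdb <- function(path) {
  p <- tryCatch(bio3d::read.pdb(path),
                error = function(e) stop("PDB parse error in ", path, ": ",
                                         conditionMessage(e)))
  at <- p$atom
  elements <- trimws(at$elesy)
  # fall back to first letter of atom name when the element column is blank
  blank <- !nzchar(elements) | is.na(elements)
  elements[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  check_elements(elements, path)
  warning("PDB coordinate records carry no partial charges; zero-filling for ",
          path)
  nm <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  list(molecule(nm, elements, cbind(at$x, at$y, at$z)))
}

#' Write molecules to SDF, MOL2 or PDB
#'
#' The inverse of \code{\link{read_molecules}}: a read-write-read round trip
#' preserves atom count, order, elements and coordinates to the precision the
#' format carries (1e-4 Angstrom for SDF/MOL2, 1e-3 for PDB's fixed columns).
#' PDB output holds a single molecule per file.
#'
#' @param mols a list of \code{qsar_mol} (or a single one).
#' @param path output path.
#' @param format \code{"sdf"}, \code{"mol2"} or \code{"pdb"}.
#' @export
write_molecules <- function(mols, path, format = c("auto", "sdf", "mol2", "pdb")) {
  if (inherits(mols, "qsar_mol")) mols <- list(mols)
  stopifnot(all(vapply(mols, inherits, logical(1), "qsar_mol")))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol2 = "mol2", pdb = "pdb",
                     stop("cannot guess format from extension of ", path))
  switch(format,
         sdf  = write_sdf(mols, path),
         mol2 = write_mol2(mols, path),
         pdb  = write_pdb(mols, path))
  invisible(path)
}

write_sdf <- function(mols, path) {
  sdfl <- lapply(mols, function(m) {
    n <- nrow(m$atoms)
    ab <- cbind(as.matrix(m$atoms[, c("x", "y", "z")]),
                matrix(0, n, 12))
    rownames(ab) <- paste(m$atoms$element, seq_len(n), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    bb <- matrix(0, 0, 7,
                 dimnames = list(NULL, paste0("C", 1:7)))
    methods::new("SDF",
                 header = c(Molecule_Name = m$name, Source = "mifqsar",
                            Comment = "", Counts_Line = sprintf(
                              "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L)),
                 atomblock = ab, bondblock = bb, datablock = character(0))
  })
  sdfset <- methods::as(sdfl[[1]], "SDFset")
  if (length(sdfl) > 1) {
    cid <- paste0("CMP", seq_along(sdfl))
    sdfset <- methods::new("SDFset", SDF = sdfl, ID = cid)
  }
  # ChemmineR warns on cbind-ing the empty bond block; harmless here
  suppressWarnings(ChemmineR::write.SDF(sdfset, file = path))
}

write_mol2 <- function(mols, path) {
  lines <- unlist(lapply(mols, function(m) {
    n <- nrow(m$atoms)
    c("@<TRIPOS>MOLECULE", m$name,
      sprintf("%d 0 1", n), "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
      sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
              seq_len(n), paste0(m$atoms$element, seq_len(n)),
              m$atoms$x, m$atoms$y, m$atoms$z, m$atoms$element,
              1L, "LIG", m$atoms$charge))
  }))
  writeLines(lines, path)
}

write_pdb <- function(mols, path) {
  if (length(mols) != 1L)
    stop("PDB output holds one molecule per file; got ", length(mols))
  m <- mols[[1]]
  n <- nrow(m$atoms)
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n),
    substr(paste0(m$atoms$element, seq_len(n)), 1, 4),
    "LIG", 1L, m$atoms$x, m$atoms$y, m$atoms$z, m$atoms$element)
  writeLines(c(lines, "END"), path)
}

#' Read an activity table
#'
#' CSV with columns \code{name,pKi}; extra columns are carried through.
#'
#' @param path CSV path.
#' @return data.frame with at least \code{name} and \code{pKi}.
#' @export
read_activities <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("name", "pKi") %in% names(d)))
    stop("activity table needs columns 'name' and 'pKi'")
  if (!is.numeric(d$pKi)) stop("pKi column is not numeric in ", path)
  d
}

#' Read an RMSD assessment table
#'
#' CSV with complex IDs in the first column (\code{Code}) and one column of
#' RMSD values (Angstrom) per docking engine / scoring-function pair. Missing
#' cells become \code{NA} and are reported, never silently dropped.
#'
#' @param path CSV path.
#' @param stage assessment stage label (ECRD, RCRD, ECCD or RCCD).
#' @return an \code{assessment_table}: RMSD matrix (complexes x engines) with
#'   a per-engine docking-accuracy row available through
#'   \code{\link{docking_accuracy}}.
#' @export
read_assessment_table <- function(path, stage = "RCCD") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L) stop("assessment table needs a Code column plus engines")
  codes <- as.character(d[[1]])
  vals <- d[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & nzchar(trimws(v)) & is.na(v2))
      if (length(bad))
        stop("non-numeric RMSD cell at row '", codes[bad[1]], "', column '",
             names(vals)[j], "'")
      vals[[j]] <- v2
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- codes
  if (any(m < 0, na.rm = TRUE)) stop("negative RMSD in ", path)
  n_missing <- sum(is.na(m))
  assessment_table(m, stage = stage, n_missing = n_missing)
}

#' Construct an assessment table
#'
#' @param rmsd numeric matrix, complexes x engines, Angstrom.
#' @param stage stage label.
#' @param params \code{\link{da_params}} used for the DA row.
#' @param n_missing count of missing cells (informational).
#' @return object of class \code{assessment_table} with the per-engine DA row
#'   recomputed from the RMSD columns.
#' @export
assessment_table <- function(rmsd, stage = "RCCD", params = da_params(),
                             n_missing = sum(is.na(rmsd))) {
  stopifnot(is.matrix(rmsd))
  da <- apply(rmsd, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_real_ else docking_accuracy(col, params)
  })
  structure(list(stage = stage, rmsd = rmsd, da = da, params = params,
                 n_missing = n_missing),
            class = "assessment_table")
}

#' @export
print.assessment_table <- function(x, digits = 3, ...) {
  cat(sprintf("Assessment table, stage %s: %d complexes x %d engines",
              x$stage, nrow(x$rmsd), ncol(x$rmsd)))
  if (x$n_missing) cat(sprintf(" (%d missing cells)", x$n_missing))
  cat("\n\n")
  out <- rbind(round(x$rmsd, digits),
               `DA (%)` = round(100 * x$da, 2))
  print(out)
  invisible(x)
}

#' Write an assessment table to CSV
#'
#' Writes the RMSD matrix in the dialect \code{\link{read_assessment_table}}
#' reads (the DA row is derived, so it is not stored).
#'
#' @param tab an \code{assessment_table}.
#' @param path output CSV path.
#' @export
write_assessment_table <- function(tab, path) {
  stopifnot(inherits(tab, "assessment_table"))
  d <- data.frame(Code = rownames(tab$rmsd), tab$rmsd,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
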