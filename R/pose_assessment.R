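#' Docking-accuracy thresholds
#'
#' Two RMSD thresholds classify a pose: at or below \code{a} Angstrom the
#' pose counts as correctly docked, between \code{a} and \code{b} as
#' partially docked, above \code{b} as mis-docked. The docking-accuracy
#' statistic credits correct poses fully and partial poses half.
#'
#' @param a lower threshold, Angstrom (default 2).
#' @param b upper threshold, Angstrom (default 3).
#' @param inclusive are comparisons at the thresholds inclusive (<=)? The
#'   default is inclusive; no printed benchmark RMSD lies exactly on a
#'   threshold, so both readings give the same reference values.
#' @return object of class \code{da_params}.
#' @export
da_params <- function(a = 2, b = 3, inclusive = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (!(a > 0 && b > a)) stop("need 0 < a < b")
  structure(list(a = a, b = b, inclusive = isTRUE(inclusive)),
            class = "da_params")
}

#' Heavy-atom RMSD between two poses
#'
#' Root-mean-square deviation over mapped heavy atoms, with no superposition:
#' docked poses already share the receptor frame, so deviations are measured
#' in place. Hydrogens are excluded.
#'
#' @param reference,candidate \code{qsar_pose} or \code{qsar_mol}.
#' @param atom_map optional 2-column integer matrix pairing heavy-atom
#'   indices (reference, candidate) counted over heavy atoms only; identity
#'   by default.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(reference, candidate, atom_map = NULL) {
  r <- coords(as_qsar_mol(reference), heavy_only = TRUE)
  c_ <- coords(as_qsar_mol(candidate), heavy_only = TRUE)
  if (nrow(r) == 0L) stop("no heavy atoms in reference")
  if (is.null(atom_map)) {
    if (nrow(r) != nrow(c_))
      stop("heavy-atom count mismatch (", nrow(r), " vs ", nrow(c_),
           ") and no atom_map given")
    atom_map <- cbind(seq_len(nrow(r)), seq_len(nrow(r)))
  }
  atom_map <- as.matrix(atom_map)
  stopifnot(ncol(atom_map) == 2L)
  d <- r[atom_map[, 1], , drop = FALSE] - c_[atom_map[, 2], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Classify a pose from its RMSD
#'
#' rmsd <= a: docked; a < rmsd <= b: partially docked; rmsd > b: mis-docked
#' (strict inequalities at the thresholds when \code{params$inclusive} is
#' FALSE). The three classes partition [0, Inf) exactly.
#'
#' @param rmsd numeric vector of RMSD values, Angstrom (>= 0).
#' @param params \code{\link{da_params}}.
#' @return factor with levels docked, partially_docked, misdocked.
#' @export
classify_pose <- function(rmsd, params = da_params()) {
  if (any(rmsd < 0)) stop("negative RMSD")
  le <- if (params$inclusive) `<=` else `<`
  lab <- ifelse(le(rmsd, params$a), "docked",
                ifelse(le(rmsd, params$b), "partially_docked", "misdocked"))
  factor(lab, levels = c("docked", "partially_docked", "misdocked"))
}

#' Docking accuracy of an RMSD set
#'
#' DA = f_a + 0.5 (f_b - f_a), where f_t is the fraction of RMSD values at
#' or below threshold t: correctly docked poses count fully, partially
#' docked poses half, mis-docked poses not at all.
#'
#' @param rmsds non-empty numeric vector of RMSD values, Angstrom. Missing
#'   cells must be removed by the caller.
#' @param params \code{\link{da_params}}.
#' @return fraction in [0, 1].
#' @export
docking_accuracy <- function(rmsds, params = da_params()) {
  if (!length(rmsds)) stop("empty RMSD list")
  if (anyNA(rmsds)) stop("missing RMSD values; drop them before calling")
  if (any(rmsds < 0)) stop("negative RMSD")
  le <- if (params$inclusive) `<=` else `<`
  fa <- mean(le(rmsds, params$a))
  fb <- mean(le(rmsds, params$b))
  fa + 0.5 * (fb - fa)
}

#' Randomize a molecule conformation
#'
#' Produces a randomized, physically plausible starting conformation for
#' re-docking assessments: the molecule is centered at the origin, given a
#' uniformly random rigid rotation and, when rotatable-bond annotations are
#' present (attribute \code{rotatable}, a 2-column matrix of atom indices
#' with the molecule's \code{bonds} attribute giving connectivity), each
#' rotatable torsion is resampled uniformly. Candidate torsions producing a
#' heavy-atom clash (nonbonded pair closer than 0.7 x the sum of van der
#' Waals radii) are rejected and resampled. Bond lengths and angles are
#' untouched (rigid transforms and torsion rotations only).
#'
#' @param mol a \code{qsar_mol}.
#' @param seed integer seed; the result is a pure function of it.
#' @param max_tries clash-rejection budget per torsion.
#' @return a new \code{qsar_mol}.
#' @export
randomize_conformation <- function(mol, seed, max_tries = 50L) {
  stopifnot(inherits(mol, "qsar_mol"))
  with_seed(seed, {
    xyz <- coords(mol)
    bonds <- attr(mol, "bonds")
    rot <- attr(mol, "rotatable")
    if (!is.null(bonds) && !is.null(rot) && nrow(rot) > 0) {
      for (k in seq_len(nrow(rot))) {
        for (try in seq_len(max_tries)) {
          cand <- rotate_torsion(xyz, bonds, rot[k, 1], rot[k, 2],
                                 stats::runif(1, -pi, pi))
          if (!has_clash(cand, mol$atoms$element, mol$atoms$is_h, bonds)) {
            xyz <- cand
            break
          }
        }
      }
    }
    ctr <- colMeans(xyz)
    xyz <- sweep(xyz, 2, ctr)
    xyz <- xyz %*% t(random_rotation())
    molecule(mol$name, mol$atoms$element, xyz, mol$atoms$charge,
             mol$activity, mol$role)
  })
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotate the atoms on the j-side of bond i-j about the i->j axis
rotate_torsion <- function(xyz, bonds, i, j, angle) {
  side <- bond_side(bonds, nrow(xyz), i, j)
  axis <- xyz[j, ] - xyz[i, ]
  axis <- axis / sqrt(sum(axis^2))
  R <- axis_rotation(axis, angle)
  moved <- sweep(xyz[side, , drop = FALSE], 2, xyz[j, ])
  xyz[side, ] <- sweep(moved %*% t(R), 2, xyz[j, ], `+`)
  xyz
}

axis_rotation <- function(u, th) {
  c_ <- cos(th); s <- sin(th); C <- 1 - c_
  matrix(c(c_ + u[1]^2 * C, u[1] * u[2] * C - u[3] * s, u[1] * u[3] * C + u[2] * s,
           u[2] * u[1] * C + u[3] * s, c_ + u[2]^2 * C, u[2] * u[3] * C - u[1] * s,
           u[3] * u[1] * C - u[2] * s, u[3] * u[2] * C + u[1] * s, c_ + u[3]^2 * C),
         3, 3, byrow = TRUE)
}

# atoms reachable from j without crossing bond i-j
bond_side <- function(bonds, n, i, j) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); seen[i] <- TRUE; seen[j] <- TRUE
  queue <- j; side <- j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; queue <- c(queue, w); side <- c(side, w)
    }
  }
  setdiff(side, j)
}

has_clash <- function(xyz, elements, is_h, bonds) {
  heavy <- which(!is_h)
  if (length(heavy) < 2) return(FALSE)
  rv <- vdw_radius(elements[heavy])
  bonded <- matrix(FALSE, nrow(xyz), nrow(xyz))
  bonded[bonds] <- TRUE
  bonded <- bonded | t(bonded)
  # 1-3 neighbours excluded too
  one3 <- bonded %*% bonded > 0
  d <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  lim <- 0.7 * outer(rv, rv, `+`)
  excl <- bonded[heavy, heavy] | one3[heavy, heavy]
  any(d < lim & !excl & upper.tri(d))
}

vdw_radius <- function(elements) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, F = 1.47, S = 1.8,
           CL = 1.75, BR = 1.85, I = 1.98, P = 1.8)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Run one assessment stage over pose sets
#'
#' The four-level harness (ECRD, RCRD, ECCD, RCCD) around external docking
#' engines: for each engine and complex the engine's top-ranked candidate
#' pose (rank 1 by \code{score}; or the minimum-RMSD pose when
#' \code{pose_selection = "min_rmsd"}) is compared with the reference by
#' heavy-atom RMSD, and the docking-accuracy row is derived per engine.
#' Top-rank selection is the default because DA measures the scoring
#' function's ability; min-RMSD selection would inflate it.
#'
#' @param pose_sets named list: engine -> named list: complex -> list of
#'   candidate poses (ordered by rank unless scores say otherwise).
#' @param references named list: complex -> reference pose/molecule.
#' @param stage stage label (ECRD, RCRD, ECCD or RCCD).
#' @param params \code{\link{da_params}}.
#' @param pose_selection \code{"top_ranked"} or \code{"min_rmsd"}.
#' @return an \code{\link{assessment_table}}.
#' @export
run_assessment_stage <- function(pose_sets, references,
                                 stage = c("RCCD", "ECRD", "RCRD", "ECCD"),
                                 params = da_params(),
                                 pose_selection = c("top_ranked", "min_rmsd")) {
  stage <- match.arg(stage)
  pose_selection <- match.arg(pose_selection)
  keep <- vapply(pose_sets, function(ps) length(ps) > 0, logical(1))
  if (any(!keep)) {
    warning("excluding engines with zero complexes: ",
            paste(names(pose_sets)[!keep], collapse = ", "))
    pose_sets <- pose_sets[keep]
  }
  if (!length(pose_sets)) stop("no engines with poses")
  complexes <- names(references)
  m <- matrix(NA_real_, length(complexes), length(pose_sets),
              dimnames = list(complexes, names(pose_sets)))
  for (eng in names(pose_sets)) {
    for (cx in intersect(complexes, names(pose_sets[[eng]]))) {
      cands <- pose_sets[[eng]][[cx]]
      if (!length(cands)) next
      rms <- vapply(cands, function(p)
        tryCatch(heavy_atom_rmsd(references[[cx]], p),
                 error = function(e) NA_real_), numeric(1))
      if (all(is.na(rms))) next  # per-cell error marker stays NA
      sel <- if (pose_selection == "min_rmsd") which.min(rms) else {
        sc <- vapply(cands, function(p)
          if (inherits(p, "qsar_pose")) p$score else NA_real_, numeric(1))
        if (all(is.finite(sc))) order(sc)[1] else 1L
      }
      m[cx, eng] <- rms[sel]
    }
  }
  assessment_table(m, stage = stage, params = params)
}
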