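#' Generate a pre-aligned congeneric series
#'
#' Builds the statistical object a field-based QSAR assumes: a series of
#' molecules sharing one rigid scaffold (identical coordinates across the
#' series, i.e. pre-aligned by construction) that differ only in
#' single-atom pseudo-substituents placed at fixed attachment sites. Each
#' substituent draws its element (hence van der Waals radius) from
#' {C, N, O, F, Br} and its partial charge uniformly from [-0.5, 0.5], so
#' the steric and electrostatic fields vary across the series only around
#' the sites. Single atoms rather than multi-atom groups keep the
#' field-to-activity mapping low rank, which is what makes planted-weight
#' recovery provable; chemical realism is not the goal.
#'
#' @param n_molecules series size (>= 6, so cross-validation has folds).
#' @param n_sites number of substituent attachment sites (>= 1).
#' @param seed integer seed; the series is a pure function of it.
#' @return object of class \code{synthetic_series}: \code{molecules} (list
#'   of \code{qsar_mol}), \code{sites} (site coordinates), \code{seed}.
#' @export
make_aligned_series <- function(n_molecules = 24, n_sites = 3, seed = 1) {
  if (n_molecules < 6)
    stop("need at least 6 molecules for cross-validation folds")
  stopifnot(n_sites >= 1)
  # rigid scaffold: benzene-like ring + short amino-ketone tail, ~10 heavy atoms
  ring <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
  tail <- rbind(c(2.78, 0.00, 0.55),
                c(3.90, 0.85, 0.60),
                c(5.05, 0.25, 0.95),
                c(3.95, 2.05, 0.30))
  scaffold_xyz <- rbind(ring, tail)
  scaffold_el <- c(rep("C", 7), "C", "N", "O")
  scaffold_q <- c(rep(-0.05, 6), 0.10, 0.15, -0.40, -0.45)
  # fixed attachment sites: octahedron vertices around the scaffold centroid,
  # pairwise >= 6.5 A apart so each site's field factor stays identifiable
  ctr <- colMeans(scaffold_xyz)
  r_site <- 4.6
  site_pool <- t(ctr + t(rbind(c(-r_site, 0, 0), c(0, r_site, 0),
                               c(r_site, 0, 0), c(0, -r_site, 0),
                               c(0, 0, r_site), c(0, 0, -r_site))))
  if (n_sites > nrow(site_pool)) {
    extra <- n_sites - nrow(site_pool)
    ang <- 2 * pi * seq_len(extra) / extra
    site_pool <- rbind(site_pool,
                       t(ctr + t(cbind(6.5 * cos(ang), 6.5 * sin(ang), 0))))
  }
  sites <- site_pool[seq_len(n_sites), , drop = FALSE]
  elements_pool <- c("C", "N", "O", "F", "Br")
  mols <- with_seed(seed, lapply(seq_len(n_molecules), function(i) {
    sub_el <- sample(elements_pool, n_sites, replace = TRUE)
    sub_q <- stats::runif(n_sites, -0.5, 0.5)
    molecule(sprintf("synth%02d", i),
             c(scaffold_el, sub_el),
             rbind(scaffold_xyz, sites),
             c(scaffold_q, sub_q))
  }))
  structure(list(molecules = mols, sites = sites, seed = seed,
                 n_scaffold = nrow(scaffold_xyz)),
            class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat(sprintf(
    "<synthetic aligned series: %d molecules, %d scaffold atoms, %d sites, seed %d>\n",
    length(x$molecules), x$n_scaffold, nrow(x$sites), x$seed))
  invisible(x)
}

#' Plant a linear field-activity relation into a series
#'
#' Computes the probe fields of the series on the lattice and selects
#' \code{weight_sparsity} planted descriptor columns, assigning them
#' weights of alternating sign \code{+-effect_size}. The noiseless signal
#' is scaled linearly into the pKi window [4.2, 6.0] typical of cathinone
#' training sets, then N(0, noise_sd) noise is added in pKi units. The
#' returned ground-truth weights are on the post-scaling (pKi) scale, so
#' recovery tests can compare coefficient-map signs and magnitudes
#' directly.
#'
#' Column choice is constrained so that recovery is well posed. Candidate
#' columns must carry genuine variation that survives the standard
#' pretreatment (values within \code{max_abs} kcal/mol so the default
#' cutoff cannot clamp the signal away, sample SD at least
#' \code{min_col_sd}). Because every column near one substituent site is
#' driven by that site's single latent factor (the substituent radius for
#' the steric field, its charge for the electrostatic field), at most one
#' weight is planted per (site, field kind) bucket — planting two opposing
#' weights on one factor would cancel unidentifiably. Within a bucket the
#' highest-SD candidate is planted. \code{weight_sparsity} therefore
#' cannot exceed the number of non-empty buckets (up to 2 per site for
#' BOTH fields); the default plants one weight per site.
#'
#' @param series a \code{synthetic_series}.
#' @param lattice a \code{mif_lattice} (default built over the series).
#' @param probe probe name or \code{probe_spec}.
#' @param field_selection descriptor block ("BOTH", "STE", "ELE").
#' @param weight_sparsity number of planted columns (default: one per
#'   site).
#' @param effect_size magnitude of the planted weights (pre-scaling).
#' @param noise_sd activity noise, pKi units.
#' @param seed integer seed.
#' @param max_abs,min_col_sd the candidate-column guards described above.
#' @param site_radius how far (Angstrom) a grid point may sit from its
#'   nearest site to count as that site's bucket.
#' @return list with \code{activities}, \code{weights} (full-length sparse
#'   vector on the pKi scale), \code{columns} (planted indices), \code{X}
#'   (raw descriptor matrix), \code{lattice}, \code{molecules} (series
#'   molecules with activities attached), \code{noise_sd}, \code{seed}.
#' @export
plant_activity <- function(series, lattice = NULL, probe = "OH2",
                           field_selection = "BOTH", weight_sparsity = NULL,
                           effect_size = 1, noise_sd = 0.1, seed = 1,
                           max_abs = 5, min_col_sd = 0.1, site_radius = 6) {
  stopifnot(inherits(series, "synthetic_series"))
  if (is.null(lattice))
    lattice <- build_lattice(series$molecules, spacing = 1, margin = 5)
  n_sites <- nrow(series$sites)
  if (is.null(weight_sparsity)) weight_sparsity <- n_sites
  blocks <- compute_mif_series(series$molecules, lattice, probe = probe)
  X <- assemble_X(blocks, field_selection = field_selection)
  idx <- attr(X, "field_index")
  sds <- apply(X, 2, stats::sd)
  maxabs <- apply(abs(X), 2, max)
  cand <- which(is.finite(sds) & sds >= min_col_sd & maxabs <= max_abs)
  if (!length(cand)) stop("no candidate columns with nonzero variation")
  # nearest site of each candidate column's grid point
  pts <- lattice_points(lattice)
  lin <- 1L + idx$ix[cand] +
    lattice$dims[1] * (idx$iy[cand] + lattice$dims[2] * idx$iz[cand])
  dsite <- sapply(seq_len(n_sites), function(s)
    sqrt(rowSums(sweep(pts[lin, , drop = FALSE], 2, series$sites[s, ])^2)))
  dsite <- matrix(dsite, ncol = n_sites)
  nearest <- max.col(-dsite)
  near_enough <- dsite[cbind(seq_along(cand), nearest)] <= site_radius
  # buckets in deterministic order: all sites with STE, then all with ELE
  kinds <- intersect(c("STE", "ELE"), unique(idx$kind))
  cols <- integer(0)
  for (k in kinds) {
    for (s in seq_len(n_sites)) {
      if (length(cols) >= weight_sparsity) break
      in_bucket <- cand[near_enough & nearest == s & idx$kind[cand] == k]
      if (!length(in_bucket)) next
      cols <- c(cols, in_bucket[which.max(sds[in_bucket])])
    }
  }
  if (length(cols) < weight_sparsity)
    stop("only ", length(cols), " plantable (site x field) buckets for ",
         weight_sparsity, " weights; add sites or fields")
  with_seed(seed, {
    cols <- sort(cols[seq_len(weight_sparsity)])
    w <- rep_len(c(1, -1), weight_sparsity) * effect_size
    signal <- as.numeric(X[, cols, drop = FALSE] %*% w)
    rng <- range(signal)
    if (diff(rng) < 1e-12) {
      # zero effect size: activities are pure noise around the window centre
      a <- 0
      y0 <- rep(5.1, length(signal))
    } else {
      a <- 1.8 / diff(rng)            # map signal span onto pKi window 4.2-6.0
      y0 <- 4.2 + a * (signal - rng[1])
    }
    y <- y0 + stats::rnorm(length(y0), 0, noise_sd)
    w_full <- numeric(ncol(X))
    w_full[cols] <- a * w
    mols <- mapply(function(m, act) { m$activity <- act; m },
                   series$molecules, y, SIMPLIFY = FALSE)
    list(activities = y, noiseless = y0, weights = w_full, columns = cols,
         X = X, lattice = lattice, molecules = mols,
         noise_sd = noise_sd, seed = seed, scale = a)
  })
}

#' Perturb a molecule into a pose of controlled RMSD
#'
#' \code{rigid_translation} shifts every atom along one random unit vector
#' by \code{target_rmsd}, which makes the heavy-atom RMSD equal the target
#' exactly. \code{random_displacement} draws an independent Gaussian
#' displacement per atom and rescales it so the heavy-atom RMSD equals the
#' target exactly (hydrogens move with the same scaling). Used to exercise
#' the docking-accuracy harness end to end without a docking engine.
#'
#' @param mol a \code{qsar_mol}.
#' @param target_rmsd desired heavy-atom RMSD, Angstrom (>= 0).
#' @param mode perturbation mode.
#' @param seed integer seed.
#' @param source_label label recorded on the pose.
#' @return a \code{qsar_pose}.
#' @export
perturb_pose <- function(mol, target_rmsd,
                         mode = c("rigid_translation", "random_displacement"),
                         seed = 1, source_label = "synthetic") {
  mode <- match.arg(mode)
  stopifnot(inherits(mol, "qsar_mol"), target_rmsd >= 0)
  xyz <- coords(mol)
  heavy <- !mol$atoms$is_h
  new_xyz <- with_seed(seed, {
    if (target_rmsd == 0) {
      xyz
    } else if (mode == "rigid_translation") {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      sweep(xyz, 2, u * target_rmsd, `+`)
    } else {
      disp <- matrix(stats::rnorm(length(xyz)), ncol = 3)
      achieved <- sqrt(mean(rowSums(disp[heavy, , drop = FALSE]^2)))
      xyz + disp * (target_rmsd / achieved)
    }
  })
  pose(molecule(mol$name, mol$atoms$element, new_xyz, mol$atoms$charge,
                mol$activity, mol$role),
       source_label = source_label)
}
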