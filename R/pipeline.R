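#' Configure a full 3D-QSAR run
#'
#' @param molecules list of aligned \code{qsar_mol} with charges.
#' @param activities numeric pKi vector (or data.frame with name/pKi,
#'   matched by molecule name).
#' @param probes probe names to model (see \code{\link{default_probes}}).
#' @param fields descriptor blocks per probe: subset of
#'   \code{c("STE", "ELE", "BOTH")}.
#' @param spacing,margin lattice geometry, Angstrom.
#' @param dielectric \code{"constant"} or \code{"distance"}.
#' @param pretreatment a \code{\link{pretreatment_params}}, or the string
#'   \code{"vpo"} to grid-search it per model.
#' @param vpo list of arguments forwarded to \code{\link{vpo_search}} when
#'   \code{pretreatment = "vpo"}.
#' @param ffd run FFD variable selection after pretreatment?
#' @param ffd_args list of arguments forwarded to \code{\link{ffd_select}}.
#' @param ncomp maximum latent variables (default 5); the reported PC is
#'   the argmax of LOO q2 over 1..ncomp.
#' @param lso_groups,lso_repeats leave-some-out settings.
#' @param n_scramble Y-scrambling permutations.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it, so a rerun with the same config is bit-identical.
#' @param out_dir optional directory: coefficient maps (cube) and the
#'   statistics table (CSV) are written there.
#' @return a \code{run_config} list.
#' @export
run_config <- function(molecules, activities, probes = "OH2",
                       fields = c("STE", "ELE", "BOTH"),
                       spacing = 1, margin = 5,
                       dielectric = "constant",
                       pretreatment = pretreatment_params(),
                       vpo = list(), ffd = FALSE, ffd_args = list(),
                       ncomp = 5, lso_groups = 5, lso_repeats = 20,
                       n_scramble = 100, seed = 42, out_dir = NULL) {
  if (is.data.frame(activities)) {
    nm <- vapply(molecules, function(m) m$name, character(1))
    activities <- activities$pKi[match(nm, activities$name)]
  }
  stopifnot(length(molecules) == length(activities),
            all(is.finite(activities)))
  fields <- match.arg(fields, c("STE", "ELE", "BOTH"), several.ok = TRUE)
  structure(list(molecules = molecules, activities = as.numeric(activities),
                 probes = probes, fields = fields, spacing = spacing,
                 margin = margin, dielectric = dielectric,
                 pretreatment = pretreatment, vpo = vpo,
                 ffd = isTRUE(ffd), ffd_args = ffd_args, ncomp = ncomp,
                 lso_groups = lso_groups, lso_repeats = lso_repeats,
                 n_scramble = n_scramble, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full 3D-QSAR pipeline
#'
#' Orchestrates the stages end to end for every probe x field combination:
#' lattice construction, molecular interaction fields, pretreatment
#' (optionally grid-searched), optional FFD variable selection, PLS fitting
#' with LOO/LSO cross-validation, Y-scrambling, and PLS-coefficient maps.
#' The statistics table mirrors the conventional model-summary layout:
#' columns GS (grid spacing), PC (chosen components), CO, Z, SD
#' (pretreatment), r2, q2_LOO, q2_LSO, r2_YS, q2_YS_LOO, q2_YS_LSO, with
#' provenance columns (seed, repeats) appended after. Every number in the
#' table is recomputable by calling the stage functions directly with the
#' logged seeds: the pipeline is pure composition, no hidden state.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{qsar3d_run}: \code{stats} (data.frame),
#'   \code{models}, \code{maps}, \code{lattice}, \code{config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  lattice <- build_lattice(cf$molecules, spacing = cf$spacing,
                           margin = cf$margin)
  y <- cf$activities
  rows <- list(); models <- list(); maps <- list()
  task <- 0L
  for (probe in cf$probes) {
    blocks <- compute_mif_series(cf$molecules, lattice, probe = probe,
                                 dielectric = cf$dielectric)
    for (field in cf$fields) {
      task <- task + 1L
      tseed <- (cf$seed + task * 7919L) %% 2147483647L
      need <- if (field == "BOTH") c("STE", "ELE") else field
      if (!all(need %in% names(blocks))) next  # e.g. STE from the ELE-only probe
      X_raw <- assemble_X(blocks, field_selection = field)
      pp <- if (identical(cf$pretreatment, "vpo")) {
        do.call(vpo_search, c(list(X_raw = X_raw, y = y, ncomp = cf$ncomp,
                                   seed = tseed), cf$vpo))$best
      } else cf$pretreatment
      pt <- pretreat(X_raw, pp)
      X <- pt$X
      if (ncol(X) == 0L)
        stop("pretreatment stage emptied the descriptor matrix for probe ",
             probe, ", field ", field)
      if (cf$ffd) {
        sel <- do.call(ffd_select,
                       c(list(X = X, y = y, ncomp = cf$ncomp, seed = tseed),
                         cf$ffd_args))
        if (sum(sel$keep) >= 2) X <- subset_columns(X, sel$keep)
      }
      nc <- min(cf$ncomp, nrow(X) - 2, ncol(X))
      loo <- cross_validate(X, y, ncomp = nc, scheme = "loo")
      pc <- which.max(loo$q2)
      fit <- qsar_pls(X, y, ncomp = nc)
      lso <- cross_validate(X, y, ncomp = nc, scheme = "lso",
                            groups = cf$lso_groups,
                            repeats = cf$lso_repeats, seed = tseed)
      ys <- y_scramble(X, y, ncomp = nc, n_perm = cf$n_scramble,
                       seed = tseed, lso_groups = cf$lso_groups)
      key <- paste(probe, field, sep = "_")
      map <- coefficient_map(fit, ncomp = pc)
      rows[[key]] <- data.frame(
        probe = probe, field = field, GS = cf$spacing, PC = pc,
        CO = pp$cutoff, Z = pp$zeroing, SD = pp$min_sd,
        r2 = fit$r2[pc], q2_LOO = loo$q2[pc], q2_LSO = lso$q2[pc],
        r2_YS = ys$r2_ys, q2_YS_LOO = ys$q2_ys_loo,
        q2_YS_LSO = ys$q2_ys_lso,
        seed = tseed, lso_repeats = cf$lso_repeats,
        n_scramble = cf$n_scramble, n_vars = ncol(X),
        stringsAsFactors = FALSE)
      models[[key]] <- fit
      maps[[key]] <- map
    }
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  if (!is.null(cf$out_dir)) {
    dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats, file.path(cf$out_dir, "statistics.csv"),
                     row.names = FALSE)
    for (key in names(maps))
      write_coef_map(maps[[key]], file.path(cf$out_dir, key), "cube")
  }
  structure(list(stats = stats, models = models, maps = maps,
                 lattice = lattice, config = cf),
            class = "qsar3d_run")
}

#' @export
print.qsar3d_run <- function(x, digits = 3, ...) {
  cat(sprintf("3D-QSAR run: %d model(s) on %d molecules\n",
              nrow(x$stats), length(x$config$molecules)))
  show <- x$stats[, c("probe", "field", "GS", "PC", "CO", "Z", "SD",
                      "r2", "q2_LOO", "q2_LSO", "r2_YS",
                      "q2_YS_LOO", "q2_YS_LSO")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round, digits)
  print(show)
  invisible(x)
}
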