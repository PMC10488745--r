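test_that("heavy-atom RMSD matches hand-computed deviations and skips hydrogens", {
  ref <- tri_mol()
  expect_equal(heavy_atom_rmsd(ref, ref), 0)
  expect_equal(heavy_atom_rmsd(ref, tri_mol(shift = c(3, 0, 0))), 3)
  # per-atom deviations {1, 1, 3} -> sqrt((1 + 1 + 9) / 3)
  cand <- molecule("c", c("C", "C", "C"),
                   rbind(c(0, 0, 1), c(1, 0, 1), c(2, 0, 3)))
  expect_equal(heavy_atom_rmsd(
    molecule("r", c("C", "C", "C"),
             rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), cand),
    sqrt(11 / 3))
  # moving only the hydrogen changes nothing
  h_moved <- molecule("h", c("C", "C", "C", "H"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(9, 9, 9)))
  expect_equal(heavy_atom_rmsd(ref, h_moved), 0)
})

test_that("RMSD needs matching heavy atoms or an explicit map", {
  ref <- tri_mol()
  two <- molecule("two", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(heavy_atom_rmsd(ref, two), "mismatch")
  expect_equal(heavy_atom_rmsd(ref, two, atom_map = cbind(1:2, 1:2)), 0)
  h_only <- expect_error(
    heavy_atom_rmsd(molecule("x", c("C", "H"), rbind(c(0, 0, 0), c(1, 0, 0))),
                    two, atom_map = cbind(1, 1)), NA)
})

test_that("RMSD is invariant under a common rigid transform", {
  set.seed(5)
  ref <- tri_mol()
  cand <- tri_mol(shift = c(0.4, -0.2, 1.1))
  base <- heavy_atom_rmsd(ref, cand)
  for (i in 1:10) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                  2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
                3, 3, byrow = TRUE)
    tr <- rnorm(3)
    xf <- function(m) molecule(m$name, m$atoms$element,
                               sweep(coords(m) %*% t(R), 2, tr, `+`),
                               m$atoms$charge)
    expect_equal(heavy_atom_rmsd(xf(ref), xf(cand)), base, tolerance = 1e-9)
  }
})

test_that("pose classification partitions RMSD space at the two thresholds", {
  p <- da_params()
  expect_equal(as.character(classify_pose(1.943, p)), "docked")
  expect_equal(as.character(classify_pose(2.5, p)), "partially_docked")
  expect_equal(as.character(classify_pose(3.5, p)), "misdocked")
  expect_error(classify_pose(-0.1, p), "negative")
  # exhaustive partition: every value falls in exactly one class
  set.seed(1)
  r <- c(runif(200, 0, 6), 0, 2, 3, 2 + 1e-12, 3 + 1e-12)
  cls <- classify_pose(r, p)
  expect_false(anyNA(cls))
  expect_equal(as.character(classify_pose(2, p)), "docked")       # inclusive
  expect_equal(as.character(classify_pose(3, p)), "partially_docked")
  strict <- da_params(inclusive = FALSE)
  expect_equal(as.character(classify_pose(2, strict)), "partially_docked")
})

test_that("docking accuracy reproduces the benchmark columns and edge cases", {
  vina5 <- c(2.843, 2.224, 1.943, 1.971, 2.941, 2.365, 1.984, 1.965, 2.695,
             2.657, 3.625, 3.954, 3.625, 3.695)
  expect_equal(docking_accuracy(vina5), 0.5)
  t6 <- read_assessment_table(extdata("table6_rccd.csv"))
  expect_equal(round(docking_accuracy(t6$rmsd[, "Vina"]), 4), 0.6364)
  expect_equal(docking_accuracy(rep(1, 5)), 1)
  expect_equal(docking_accuracy(rep(5, 5)), 0)
  expect_error(docking_accuracy(numeric(0)), "empty")
})

test_that("docking accuracy is monotone non-increasing in every entry", {
  set.seed(7)
  for (i in 1:20) {
    r <- runif(10, 0, 5)
    da0 <- docking_accuracy(r)
    j <- sample(10, 1)
    r[j] <- r[j] + runif(1, 0, 3)
    expect_lte(docking_accuracy(r), da0)
  }
})

test_that("conformation randomization is centered, deterministic and rigid-preserving", {
  hex <- hexagon_mol()
  r1 <- randomize_conformation(hex, seed = 7)
  expect_lt(sqrt(sum(colMeans(coords(r1))^2)), 1e-9)
  r2 <- randomize_conformation(hex, seed = 7)
  expect_identical(coords(r1), coords(r2))
  expect_false(isTRUE(all.equal(coords(r1), coords(randomize_conformation(hex, seed = 8)))))
  # all pairwise C-C distances preserved to 1e-3
  expect_equal(as.matrix(dist(coords(r1))), as.matrix(dist(coords(hex))),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("torsion resampling keeps bond lengths while changing dihedrals", {
  # butane-like chain with one rotatable central bond
  chain <- molecule("chain", rep("C", 4),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0),
                          c(3.8, 1.3, 0.2)))
  attr(chain, "bonds") <- cbind(1:3, 2:4)
  attr(chain, "rotatable") <- matrix(c(2, 3), 1)
  r <- randomize_conformation(chain, seed = 3)
  d0 <- sqrt(rowSums((coords(chain)[1:3, ] - coords(chain)[2:4, ])^2))
  d1 <- sqrt(rowSums((coords(r)[1:3, ] - coords(r)[2:4, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  # 1-4 distance (the torsion-dependent one) should generally move
  d14 <- function(x) sqrt(sum((x[1, ] - x[4, ])^2))
  expect_false(isTRUE(all.equal(d14(coords(r)), d14(coords(chain)),
                                tolerance = 1e-6)))
})

test_that("the assessment harness reproduces oracle DA for generated poses", {
  ref <- hexagon_mol()
  refs <- list(c1 = ref)
  mk_engine <- function(targets, seed0) {
    lapply(seq_along(targets), function(i)
      list(perturb_pose(ref, targets[i], "rigid_translation", seed = seed0 + i)))
  }
  targets <- c(1, 1, 2.5, 4)
  poses <- mk_engine(targets, 100)
  refs4 <- setNames(rep(list(ref), 4), paste0("c", 1:4))
  names(poses) <- paste0("c", 1:4)
  tab <- run_assessment_stage(list(engine = poses), refs4, stage = "RCCD")
  expect_equal(unname(tab$da["engine"]), 2 / 4 + 0.5 * (3 / 4 - 2 / 4))
  # candidate identical to reference
  tab0 <- run_assessment_stage(list(e = list(c1 = list(pose(ref)))),
                               list(c1 = ref), stage = "ECRD")
  expect_equal(unname(tab0$rmsd["c1", "e"]), 0)
  expect_equal(unname(tab0$da["e"]), 1)
})

test_that("engines without complexes are excluded with a warning", {
  ref <- hexagon_mol()
  refs <- list(c1 = ref)
  good <- list(c1 = list(pose(ref)))
  expect_warning(
    tab <- run_assessment_stage(list(ok = good, empty = list()), refs),
    "empty")
  expect_equal(colnames(tab$rmsd), "ok")
})

test_that("top-ranked selection differs from min-RMSD selection by design", {
  ref <- hexagon_mol()
  # rank-1 pose (best score) is worse than the rank-2 pose
  p_bad <- perturb_pose(ref, 4, "rigid_translation", seed = 1)
  p_good <- perturb_pose(ref, 0.5, "rigid_translation", seed = 2)
  p_bad$score <- -10; p_good$score <- -5
  sets <- list(e = list(c1 = list(p_bad, p_good)))
  top <- run_assessment_stage(sets, list(c1 = ref), pose_selection = "top_ranked")
  best <- run_assessment_stage(sets, list(c1 = ref), pose_selection = "min_rmsd")
  expect_equal(unname(top$rmsd["c1", "e"]), 4, tolerance = 1e-9)
  expect_equal(unname(best$rmsd["c1", "e"]), 0.5, tolerance = 1e-9)
})
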