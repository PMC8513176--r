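test_that("coarse models inherit template coordinates and bridge gaps at bond length", {
  tmpl <- make_ideal_chain(10, "helix", seed = 2)
  sq <- structure_sequence(tmpl)
  idal <- global_align(sq, sq)
  out <- build_coarse_model(idal, tmpl)
  expect_equal(ca_coords(out$structure), ca_coords(tmpl))
  expect_equal(kabsch_rmsd(ca_coords(out$structure), ca_coords(tmpl))$rmsd, 0,
               tolerance = 1e-9)
  # a 3-residue insertion between anchors 15.2 A apart: near-ideal spacing
  far <- cirperm:::chain_from_xyz(rbind(c(0, 0, 0), c(15.2, 0, 0)), "AV")
  aln <- structure(list(rows = c("AGGGV", "A---V"), aligned_columns = 2,
                        score = 0, scheme = scoring_scheme("nw")),
                   class = "seq_alignment")
  mod <- build_coarse_model(aln, far)$structure
  d <- sqrt(rowSums(diff(ca_coords(mod))^2))
  expect_true(all(abs(d - 3.8) < 0.4))
  # determinism
  expect_equal(build_coarse_model(aln, far)$energy,
               build_coarse_model(aln, far)$energy)
  bad <- structure(list(rows = c("AGGGV", "A---A"), aligned_columns = 2,
                        score = 0, scheme = scoring_scheme("nw")),
                   class = "seq_alignment")
  expect_error(build_coarse_model(bad, far), "mismatch")
})

test_that("surrogate energy vanishes on ideal chains and counts clashes", {
  straight <- make_ideal_chain(10, "straight", seed = 1)
  expect_equal(surrogate_energy(straight), 0)
  # one far-in-sequence residue 2 A from residue 1: exactly one clash
  xyz <- rbind(ca_coords(straight), c(-2, 0, 0))
  clash_d <- sqrt(rowSums(sweep(xyz[1:8, , drop = FALSE], 2, xyz[11, ])^2))
  expect_equal(sum(clash_d < 4), 1)
  e <- surrogate_energy(xyz)
  bond_tail <- (sqrt(sum((xyz[11, ] - xyz[10, ])^2)) - 3.8)^2
  expect_equal(e - bond_tail, 10)
  # rigid-motion invariance
  withr::with_seed(9, {
    for (i in 1:5) {
      R <- cirperm:::rot_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
      moved <- sweep(xyz %*% t(R), 2, stats::rnorm(3, sd = 20), `+`)
      expect_equal(surrogate_energy(moved), e, tolerance = 1e-9)
    }
  })
})

test_that("hinge frames partition the proportions with the documented tie rule", {
  td <- make_two_domain(40, 60, seed = 3)
  fr <- split_by_hinge(td$model, td$junction, 0)
  expect_equal(fr$small_serials, 1:40)
  expect_false(fr$small_is_cterm)
  even <- make_two_domain(50, 50, seed = 4)
  fr2 <- split_by_hinge(even$model, even$junction, 0)
  expect_true(fr2$small_is_cterm)
  expect_equal(fr2$small_serials, 51:100)
  expect_equal(sqrt(sum(fr2$axis_r^2)), 1, tolerance = 1e-9)
  # plane residual: both centroids lie on the plane through the hinge
  for (fx in list(fr, fr2)) {
    expect_lt(abs(sum((fx$com_small - fx$hinge) * fx$normal)), 1e-9)
    expect_lt(abs(sum((fx$com_large - fx$hinge) * fx$normal)), 1e-9)
  }
  # equivariance: rotating the model rotates the axis
  R <- cirperm:::rot_about_axis(c(0, 1, 1), 63)
  xyz <- ca_coords(td$model) %*% t(R)
  rot <- cirperm:::chain_from_xyz(xyz, structure_sequence(td$model))
  fr3 <- split_by_hinge(rot, td$junction, 0)
  expect_equal(fr3$axis_r, as.numeric(R %*% fr$axis_r), tolerance = 1e-9)
  # with a linker, the hinge sits on its middle residue
  pr <- make_cp_pair(30, linker = "GGSGG", seed = 5)
  frl <- split_by_hinge(pr$s, pr$junction, 5)
  expect_equal(frl$hinge, unname(ca_coords(pr$s)[pr$junction + 3, ]),
               ignore_attr = TRUE)
})

test_that("hinge refinement is a rigid, energy-non-increasing grid search", {
  td <- make_two_domain(22, 14, seed = 6)
  fr <- split_by_hinge(td$model, td$junction, 0)
  e_in <- surrogate_energy(td$model)
  ref <- hinge_refine(td$model, fr)
  expect_equal(attr(ref, "n_snapshots"), 162)
  expect_lte(attr(ref, "energy"), e_in)
  # intra-proportion distances preserved; large proportion untouched
  d0 <- stats::dist(ca_coords(td$model)[fr$small_serials, ])
  d1 <- stats::dist(ca_coords(ref)[fr$small_serials, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)
  expect_equal(ca_coords(ref)[fr$large_serials, ],
               ca_coords(td$model)[fr$large_serials, ])
  # chosen energy equals the independently recomputed grid minimum
  expect_equal(attr(ref, "energy"), oracle_grid_min(td$model, fr),
               tolerance = 1e-9)
})

test_that("a rigged energy recovers its planted optimal pose", {
  td <- make_two_domain(20, 12, seed = 7)
  fr <- split_by_hinge(td$model, td$junction, 0)
  # rig: energy minimized exactly at the pose reached by (40, 120)
  target <- cirperm:::apply_pose(ca_coords(td$model)[fr$small_serials, ],
                                 fr, 40, 120)
  rig <- function(s) {
    sum((ca_coords(s)[fr$small_serials, ] - target)^2)
  }
  ref <- hinge_refine(td$model, fr, energy_fn = rig)
  expect_equal(attr(ref, "pose"), list(theta = 40, phi = 120))
  expect_equal(attr(ref, "energy"), 0, tolerance = 1e-12)
  # ties break toward the lexicographically smallest pose
  flat <- function(s) 1
  tie <- hinge_refine(td$model, fr, energy_fn = flat)
  expect_equal(attr(tie, "pose"), list(theta = 0, phi = 0))
})

test_that("Kabsch superposition matches the quaternion oracle", {
  withr::with_seed(31, {
    A <- matrix(stats::rnorm(15), 5, 3)
    expect_equal(kabsch_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)
    for (i in 1:20) {
      A <- matrix(stats::rnorm(15, sd = 5), 5, 3)
      R <- cirperm:::rot_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
      B <- sweep(A %*% t(R), 2, stats::rnorm(3, sd = 10), `+`)
      expect_lt(kabsch_rmsd(A, B)$rmsd, 1e-9)
      # random clouds: SVD solution equals the closed-form quaternion one
      C <- matrix(stats::rnorm(15, sd = 5), 5, 3)
      expect_equal(kabsch_rmsd(A, C)$rmsd, quaternion_rmsd(A, C),
                   tolerance = 1e-9)
      # proper rotation only
      expect_equal(det(kabsch_rmsd(A, C)$rotation), 1, tolerance = 1e-9)
    }
  })
  expect_error(kabsch_rmsd(matrix(0, 4, 3), matrix(0, 5, 3)), "matched")
})

test_that("alignment ratio is aligned residues over target size", {
  expect_equal(alignment_ratio(214, 214), 100)
  expect_equal(alignment_ratio(0, 100), 0)
  expect_equal(alignment_ratio(53, 106), 50)
  expect_error(alignment_ratio(1, 0), "positive")
})
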