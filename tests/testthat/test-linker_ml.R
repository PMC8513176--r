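test_that("feature values are inverse-square sums with the sequence window excluded", {
  # residue 1 (ALA at origin) vs residue of interest 7, 10 A apart:
  # sequence separation 6 -> contributes 1/100
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0),
               c(400, 0, 0), c(500, 0, 0), c(10, 0, 0))
  s <- cirperm:::chain_from_xyz(xyz, "AGGGGGV")
  f <- compute_features(s, 7)
  expect_equal(unname(f["A"]), 0.01)
  expect_equal(sum(f), 0.01)
  # same spatial neighbor but separation 3: excluded, all zero
  xyz2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(10, 0, 0))
  f2 <- compute_features(cirperm:::chain_from_xyz(xyz2, "AGGV"), 4)
  expect_equal(sum(f2), 0)
  # nothing within 20 A: zero vector
  lonely <- make_ideal_chain(20, "straight", seed = 1)
  expect_equal(sum(compute_features(lonely, 10)), 0)
})

test_that("features are rigid-motion invariant and monotone in neighbors", {
  pr <- make_cp_pair(26, linker = "GGSGG", seed = 4)
  s <- pr$s
  i <- pr$junction + 2
  f <- compute_features(s, i)
  R <- cirperm:::rot_about_axis(c(1, 2, 3), 37)
  xyz <- ca_coords(s) %*% t(R)
  xyz <- sweep(xyz, 2, c(5, -3, 11), `+`)
  s2 <- cirperm:::chain_from_xyz(xyz, structure_sequence(s))
  expect_equal(compute_features(s2, i), f, tolerance = 1e-9)
  # adding a qualifying tryptophan neighbor raises F[W], touches nothing else
  far <- rbind(xyz, ca_coords(s)[i, ] + c(8, 0, 0))
  s3 <- cirperm:::chain_from_xyz(rbind(ca_coords(s),
                                       ca_coords(s)[i, ] + c(8, 0, 0)),
                                 paste0(structure_sequence(s), "W"))
  f3 <- compute_features(s3, i)
  expect_gt(f3["W"], f["W"])
  expect_equal(f3[setdiff(aa_alphabet(), "W")], f[setdiff(aa_alphabet(), "W")])
  # moving that neighbor farther lowers its contribution
  s4 <- cirperm:::chain_from_xyz(rbind(ca_coords(s),
                                       ca_coords(s)[i, ] + c(15, 0, 0)),
                                 paste0(structure_sequence(s), "W"))
  expect_lt(compute_features(s4, i)["W"], f3["W"])
})

test_that("class compositions are Laplace-smoothed conditional frequencies", {
  sch <- estimate_composition(class_scheme(), c("GGGG", "SS"))
  comp <- sch$composition
  # neutral counts: G 4 + 1, S 2 + 1, P/T/Y 1 each -> total 11
  expect_equal(unname(comp["neutral", "G"]), 5 / 11)
  expect_equal(unname(comp["neutral", "S"]), 3 / 11)
  expect_equal(sum(comp["neutral", ]), 1)
  expect_equal(sum(comp["hydrophilic", ]), 1)
  expect_true(all(comp[cbind(unname(sch$classes), aa_alphabet())] > 0))
})

test_that("restoration multiplies class probability by within-class proportion", {
  sch <- class_scheme()
  sch$composition <- matrix(0, 3, 20,
                            dimnames = list(c("hydrophilic", "hydrophobic", "neutral"),
                                            aa_alphabet()))
  for (cl in rownames(sch$composition)) {
    members <- names(sch$classes)[sch$classes == cl]
    sch$composition[cl, members] <- 1 / length(members)
  }
  pe <- restore_aa_probs(c(hydrophilic = 0.8, hydrophobic = 0.1, neutral = 0.1), sch)
  expect_equal(sum(pe), 1)
  # uniform within-class composition -> uniform within class
  hyd <- names(sch$classes)[sch$classes == "hydrophilic"]
  expect_equal(unname(pe[hyd]), rep(0.8 / 7, 7))
  # random valid inputs stay normalized
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- stats::runif(3); p <- p / sum(p)
      names(p) <- c("hydrophilic", "hydrophobic", "neutral")
      expect_equal(sum(restore_aa_probs(p, sch)), 1, tolerance = 1e-9)
    }
  })
  expect_error(restore_aa_probs(c(hydrophilic = 0.9, hydrophobic = 0.9,
                                  neutral = 0.1), sch), "sum to 1")
})

test_that("the vote ensemble is deterministic, normalized, and constant on one class", {
  tr <- make_ml_training_set(25, separation = 4, seed = 3)
  sch <- estimate_composition(class_scheme(), c("GGSGG", "RKDE", "AVLI"))
  e1 <- train_ensemble(tr[, aa_alphabet()], tr$class, sch, seed = 7,
                       n_tree = 20, n_net = 5)
  e2 <- train_ensemble(tr[, aa_alphabet()], tr$class, sch, seed = 7,
                       n_tree = 20, n_net = 5)
  probe <- make_ml_training_set(10, separation = 4, seed = 8)
  p1 <- predict_class_probs(e1, probe[, aa_alphabet()])
  p2 <- predict_class_probs(e2, probe[, aa_alphabet()])
  expect_equal(p1, p2)
  expect_equal(unname(rowSums(as.matrix(p1))), rep(1, nrow(p1)))
  # vote fractions are multiples of 1/n_minor
  expect_true(all(abs(as.matrix(p1) * e1$n_minor -
                        round(as.matrix(p1) * e1$n_minor)) < 1e-9))
  # single-class training set: constant predictor with a warning
  one <- tr[tr$class == "neutral", ]
  expect_warning(
    ec <- train_ensemble(one[, aa_alphabet()], one$class, sch, seed = 1,
                         n_tree = 5, n_net = 2),
    "single-class")
  pc <- predict_class_probs(ec, probe[, aa_alphabet()])
  expect_equal(unname(as.matrix(pc)[, "neutral"]), rep(1, nrow(pc)))
  expect_error(train_ensemble(tr[0, aa_alphabet()], character(0), sch), "empty")
})

test_that("probability profiles from a coarse model are valid distributions", {
  db <- make_linker_db(8, 4, seed = 6)
  feats <- purrr::map(db$pair, function(p) {
    compute_features_tbl(p$s, p$junction + seq_len(nchar(p$linker)))
  }) |> dplyr::bind_rows()
  labels <- unlist(purrr::map(db$linker, aa_classes))
  sch <- estimate_composition(class_scheme(), db$linker)
  ens <- train_ensemble(feats[, aa_alphabet()], labels, sch, seed = 2,
                        n_tree = 15, n_net = 3)
  pr <- db$pair[[1]]
  prof <- aa_probability_profile(pr$s, pr$junction + seq_len(nchar(pr$linker)), ens)
  expect_s3_class(prof, "aa_profile")
  expect_equal(nrow(prof), nchar(pr$linker))
  expect_equal(unname(rowSums(unclass(prof))), rep(1, nrow(prof)), tolerance = 1e-9)
  expect_true(all(prof >= 0))
  td <- tidy(prof)
  expect_equal(nrow(td), 20 * nrow(prof))
})
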