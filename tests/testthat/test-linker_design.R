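test_that("length estimate follows the logarithmic fit with clamping", {
  expect_equal(estimate_linker_length(5), 0)   # raw -17.4, clamped
  expect_equal(estimate_linker_length(15), 7)  # round(6.54)
  expect_error(estimate_linker_length(20), "iterative")
  expect_error(estimate_linker_length(25), "iterative")
  expect_error(estimate_linker_length(0), "positive")
  expect_error(estimate_linker_length(-3), "positive")
  grid <- seq(0.5, 19.5, by = 0.25)
  l <- vapply(grid, estimate_linker_length, integer(1))
  expect_true(all(diff(l) >= 0))
  expect_true(all(l >= 0))
})

test_that("rounding is half away from zero", {
  rha <- cirperm:::round_half_away
  expect_equal(rha(c(0.5, 1.5, 2.5, -0.5, -2.5, 2.49)),
               c(1, 2, 3, -1, -3, 2))
})

test_that("temporary linkers are propensity-driven and seeded", {
  tab <- stats::setNames(rep(0, 20), aa_alphabet()); tab["G"] <- 1
  expect_equal(sample_temporary_linkers(4, tab, 3, seed = 1),
               rep("GGGG", 3))
  t1 <- sample_temporary_linkers(6, propensity_table(), 10, seed = 5)
  t2 <- sample_temporary_linkers(6, propensity_table(), 10, seed = 5)
  expect_equal(t1, t2)
  expect_true(all(nchar(t1) == 6))
  bad <- stats::setNames(rep(0.1, 20), aa_alphabet())
  expect_error(sample_temporary_linkers(4, bad, 3), "sum to 1")
  # empirical law: single-position draws track the table (chi-square)
  tab2 <- propensity_table(c("GGGGGGSSSP"))
  draws <- sample_temporary_linkers(1, tab2, 4000, seed = 9)
  obs <- table(factor(draws, levels = aa_alphabet()))
  expect_gt(stats::chisq.test(obs, p = tab2)$p.value, 0.01)
})

test_that("candidate sampling follows the per-position probabilities", {
  point <- matrix(0, 3, 20, dimnames = list(NULL, aa_alphabet()))
  point[1, "V"] <- 1; point[2, "L"] <- 1; point[3, "G"] <- 1
  prof <- structure(point, class = c("aa_profile", "matrix", "array"))
  expect_equal(sample_candidate_sequences(prof, 4, seed = 1),
               rep("VLG", 4))
  # 70/30 valine/leucine position: frequency tracks the probability
  mix <- matrix(0, 1, 20, dimnames = list(NULL, aa_alphabet()))
  mix[1, "V"] <- 0.7; mix[1, "L"] <- 0.3
  prof2 <- structure(mix, class = c("aa_profile", "matrix", "array"))
  draws <- sample_candidate_sequences(prof2, 2000, seed = 3)
  expect_equal(mean(draws == "V"), 0.7, tolerance = 0.05)
})

test_that("the design protocol pools t'*k candidates and ranks by energy", {
  db <- make_linker_db(8, 4, seed = 12)
  feats <- purrr::map(db$pair, function(p) {
    compute_features_tbl(p$s, p$junction + seq_len(nchar(p$linker)))
  }) |> dplyr::bind_rows()
  labels <- unlist(purrr::map(db$linker, aa_classes))
  sch <- estimate_composition(class_scheme(), db$linker)
  ens <- train_ensemble(feats[, aa_alphabet()], labels, sch, seed = 3,
                        n_tree = 15, n_net = 3)
  pr <- db$pair[[1]]
  cfg <- design_config(t = 12, t_prime = 4, k = 3, m_models = 1,
                       n_report = 5, seed = 21)
  des <- design_linkers(pr$q, pr$site, ens, cfg, l = nchar(pr$linker),
                        table = propensity_table(db$linker))
  pool <- attr(des, "pool")
  expect_equal(nrow(pool), cfg$t_prime * cfg$k)
  expect_equal(nrow(des), cfg$n_report)
  expect_true(all(diff(des$energy) >= 0))
  expect_true(all(des$sequence %in% pool$sequence))
  expect_true(all(nchar(des$sequence) == nchar(pr$linker)))
  # n_report = 1 returns the pool minimum
  cfg1 <- design_config(t = 12, t_prime = 4, k = 3, m_models = 1,
                        n_report = 1, seed = 21)
  one <- design_linkers(pr$q, pr$site, ens, cfg1, l = nchar(pr$linker),
                        table = propensity_table(db$linker))
  expect_equal(one$energy[1], min(pool$energy))
  # deterministic under seed
  des2 <- design_linkers(pr$q, pr$site, ens, cfg, l = nchar(pr$linker),
                         table = propensity_table(db$linker))
  expect_equal(tibble::as_tibble(des), tibble::as_tibble(des2))
})

test_that("coarse screening keeps the t' lowest-energy models", {
  # a rigged backend whose energy is a deterministic hash of the linker
  db <- make_linker_db(4, 2, seed = 13)
  pr <- db$pair[[1]]
  seen <- new.env(); seen$rows <- list()
  rig <- function(aln, template) {
    out <- build_coarse_model(aln, template)
    lseq <- aln$rows[1]
    out$energy <- sum(utf8ToInt(gsub("-", "", lseq))) %% 97
    seen$rows[[length(seen$rows) + 1]] <- out$energy
    out
  }
  sch <- estimate_composition(class_scheme(), db$linker)
  tr <- make_ml_training_set(15, separation = 4, seed = 2)
  ens <- train_ensemble(tr[, aa_alphabet()], tr$class, sch, seed = 2,
                        n_tree = 5, n_net = 2)
  cfg <- design_config(t = 10, t_prime = 3, k = 2, m_models = 1,
                       n_report = 3, seed = 5)
  des <- design_linkers(pr$q, pr$site, ens, cfg, l = 4, backend = rig)
  coarse <- attr(des, "coarse")
  expect_equal(nrow(coarse), cfg$t)
  # the kept coarse models are the t' smallest of the t built (sort oracle)
  expect_equal(sort(coarse$energy[coarse$kept]),
               sort(coarse$energy)[seq_len(cfg$t_prime)])
  expect_true(all(des$energy == sort(des$energy)))
  expect_equal(nrow(attr(des, "pool")), cfg$t_prime * cfg$k)
})

test_that("zero-length designs degrade to a direct connection", {
  pr <- make_cp_pair(24, linker = "", seed = 14)
  tr <- make_ml_training_set(15, separation = 4, seed = 2)
  sch <- estimate_composition(class_scheme(), c("GGS"))
  ens <- train_ensemble(tr[, aa_alphabet()], tr$class, sch, seed = 2,
                        n_tree = 5, n_net = 2)
  des <- design_linkers(pr$q, pr$site, ens,
                        design_config(t = 5, t_prime = 2, k = 2,
                                      m_models = 1, n_report = 3, seed = 1),
                        l = 0)
  expect_equal(nrow(des), 1)
  expect_equal(des$sequence, "")
  expect_true(is.finite(des$energy))
})

test_that("iterative length estimation recovers a planted optimum", {
  pr <- make_cp_pair(120, site = 50, linker = "", seed = 15)
  tab <- propensity_table()
  cfg <- design_config(t = 3, t_prime = 1, k = 1, m_models = 1, seed = 2)
  # rig the backend so energy is minimized exactly at 23 linker residues
  rig <- function(aln, template) {
    out <- build_coarse_model(aln, template)
    l_here <- sum(strsplit(aln$rows[2], "")[[1]] == "-")
    out$energy <- (l_here - 23)^2
    out
  }
  est <- estimate_linker_length_long(pr$q, pr$site, tab, cfg, backend = rig)
  expect_equal(as.integer(est), 23)
  scan <- attr(est, "scan")
  expect_true(all(seq(20, 24, 1) %in% scan$l))
  # constant-energy backend: smallest scanned length wins the tie
  flat <- function(aln, template) {
    out <- build_coarse_model(aln, template)
    out$energy <- 1
    out
  }
  est2 <- estimate_linker_length_long(pr$q, pr$site, tab, cfg, backend = flat)
  expect_equal(as.integer(est2), 16)
})
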