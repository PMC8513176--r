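# Deterministic synthetic fixtures: ideal CA traces, CP pairs with
# planted bridging linkers, separable training sets, and the scaled
# independent-test harness. These emulate the study inputs (curated CP
# pairs and in-silico permutants) so the whole protocol runs on toys.

random_sequence <- function(n, seed = NULL, prob = NULL) {
  draw <- function() paste(sample(aa_alphabet(), n, replace = TRUE,
                                  prob = prob), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

chain_from_xyz <- function(xyz, seq) {
  n <- nrow(xyz)
  stopifnot(nchar(seq) == n)
  new_structure(tibble(
    serial = seq_len(n), resname = aa_one_to_three(strsplit(seq, "")[[1]]),
    atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    eleno = seq_len(n), occ = 1
  ))
}

#' Idealized CA-trace chain
#'
#' Builds a single-chain CA trace with exact 3.8 Angstrom consecutive
#' spacing in one of three geometries: `straight` (a line), `helix`
#' (alpha-helical rise/twist, clash-free), or `ring` (a closed circle
#' whose termini are one bond apart — the close-termini geometry required
#' for direct in-silico circular permutation).
#'
#' @param n Residue count, `>= 2`.
#' @param geometry `"straight"`, `"helix"` or `"ring"`.
#' @param seq Amino-acid sequence (length `n`); random (seeded) if NULL.
#' @param seed Seed for the random sequence.
#' @return A `cpm_structure` (CA-only).
#' @export
make_ideal_chain <- function(n, geometry = c("straight", "helix", "ring"),
                             seq = NULL, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 2)
  if (is.null(seq)) seq <- random_sequence(n, seed)
  i <- seq_len(n) - 1
  xyz <- switch(geometry,
    straight = cbind(3.8 * i, 0, 0),
    helix = {
      r <- 2.3; step <- 100 * pi / 180
      rise <- sqrt(3.8^2 - (2 * r * sin(step / 2))^2)
      cbind(r * cos(i * step), r * sin(i * step), rise * i)
    },
    ring = {
      R <- 3.8 / (2 * sin(pi / n))
      ang <- 2 * pi * i / n
      cbind(R * cos(ang), R * sin(ang), 0)
    }
  )
  chain_from_xyz(xyz, seq)
}

#' Two-domain fixture for hinge refinement
#'
#' Two helical domains joined end-to-end, the second rigidly rotated away
#' from the first by seeded random angles — a toy whose optimal relative
#' domain orientation is recoverable by the hinge search.
#'
#' @param n1,n2 Residue counts of the two domains.
#' @param seed Seed for the sequence and the perturbing rotation.
#' @return List: `model` (a `cpm_structure`), `junction` (= `n1`).
#' @export
make_two_domain <- function(n1 = 20, n2 = 15, seed = 1) {
  n <- n1 + n2
  seqs <- random_sequence(n, seed)
  base <- make_ideal_chain(n, "helix", seq = seqs)
  xyz <- ca_coords(base)
  withr::with_seed(seed + 1, {
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, 20, 160)
  })
  hinge <- (xyz[n1, ] + xyz[n1 + 1, ]) / 2
  R <- rot_about_axis(axis, angle)
  seg2 <- seq(n1 + 1, n)
  xyz[seg2, ] <- sweep(sweep(xyz[seg2, , drop = FALSE], 2, hinge) %*% t(R),
                       2, hinge, `+`)
  list(model = chain_from_xyz(xyz, seqs), junction = n1)
}

#' Synthetic CP pair with a planted bridging linker
#'
#' Builds a protein Q as a closed ring (close termini), then its circular
#' permutant S: Q's coordinates rotated at the CP site, with a planted
#' linker of known sequence bridging the joined native termini on a
#' circular arc. The CP-aware residue correspondence and the ground-truth
#' linker are returned, so linker determination can be checked exactly.
#'
#' @param l_q Residue count of Q.
#' @param site CP site on Q (defaults to mid-chain).
#' @param linker Planted linker sequence ("" for none).
#' @param seed Seed for Q's sequence.
#' @return List: `q`, `s` (`cpm_structure`s), `alignment`
#'   ([cp_alignment()] of Q vs S), `linker` (the planted sequence),
#'   `site`, `junction` (serial of the last residue of S's first native
#'   segment).
#' @export
make_cp_pair <- function(l_q = 30, site = NULL, linker = "GGSGG", seed = 1) {
  if (is.null(site)) site <- floor(l_q / 2) + 1L
  q <- make_ideal_chain(l_q, "ring", seed = seed)
  perm <- make_pseudo_cp_template(q, site)
  lk <- nchar(linker)
  junction <- l_q - site + 1L
  xyz_p <- ca_coords(perm)
  seq_s <- insert_linker(structure_sequence(perm), linker, junction)
  if (lk > 0) {
    bridge <- arc_place(xyz_p[junction, ], xyz_p[junction + 1, ], lk)
    xyz_s <- rbind(xyz_p[seq_len(junction), , drop = FALSE], bridge,
                   xyz_p[seq(junction + 1, l_q), , drop = FALSE])
  } else {
    xyz_s <- xyz_p
  }
  s <- chain_from_xyz(xyz_s, seq_s)
  qs <- seq_len(l_q)
  ss <- ifelse(qs >= site, qs - site + 1L, junction + lk + qs)
  aln <- cp_alignment(tibble(q = qs, s = ss), l_q, l_q + lk)
  list(q = q, s = s, alignment = aln, linker = linker,
       site = as.integer(site), junction = junction)
}

#' Linearly separable synthetic training set
#'
#' Three Gaussian clusters in the 20-dimensional feature space, one per
#' amino-acid class, with controllable separation (0 = pure noise).
#' Features are truncated at zero to respect the non-negativity of the
#' inverse-square-distance features.
#'
#' @param n_per_class Cases per class.
#' @param separation Distance between cluster means.
#' @param seed Integer seed.
#' @param sd Within-cluster standard deviation.
#' @return Tibble: 20 feature columns ([aa_alphabet()]) plus `class`.
#' @export
make_ml_training_set <- function(n_per_class = 100, separation = 5, seed = 1,
                                 sd = 1) {
  withr::with_seed(seed, {
    dirs <- list(c(1, rep(0, 19)), c(0, 1, rep(0, 18)), c(0, 0, 1, rep(0, 17)))
    rows <- purrr::imap(.class_levels, function(cl, k) {
      mu <- 2 + separation * dirs[[k]]
      X <- matrix(stats::rnorm(n_per_class * 20, sd = sd), ncol = 20)
      X <- pmax(sweep(X, 2, mu, `+`), 0)
      colnames(X) <- aa_alphabet()
      mutate(as_tibble(X), class = cl)
    })
    bind_rows(rows)[sample(3 * n_per_class), ]
  })
}

#' Synthetic linker database for the independent-test harness
#'
#' A set of CP-pair fixtures grouped by source entry (several permutants
#' may share a parent protein), each with a planted, known linker whose
#' composition is glycine/serine-rich — emulating a curated database of
#' termini linkers.
#'
#' @param n_entries Number of linker entries.
#' @param n_groups Number of source groups.
#' @param seed Integer seed.
#' @return Tibble with columns `entry`, `group`, `pair` (list of
#'   [make_cp_pair()] fixtures), `linker`, `protein_seq`.
#' @export
make_linker_db <- function(n_entries = 30, n_groups = 10, seed = 1) {
  withr::with_seed(seed, {
    groups <- sort(rep_len(seq_len(n_groups), n_entries))
    linker_prob <- stats::setNames(rep(0.25 / 18, 20), aa_alphabet())
    linker_prob["G"] <- 0.55; linker_prob["S"] <- 0.20
    specs <- tibble(
      entry = seq_len(n_entries),
      group = groups,
      l_q = sample(24:32, n_entries, replace = TRUE),
      l_lk = sample(3:5, n_entries, replace = TRUE),
      seed_q = sample.int(1e6, n_entries)
    )
    # entries of a group share the parent sequence seed
    specs$seed_q <- specs$seed_q[match(specs$group, specs$group)]
    specs$l_q <- specs$l_q[match(specs$group, specs$group)]
    specs$linker <- vapply(specs$l_lk, function(n) {
      paste(sample(aa_alphabet(), n, replace = TRUE, prob = linker_prob),
            collapse = "")
    }, character(1))
    specs$site <- vapply(specs$l_q, function(L) sample(seq(5, L - 5), 1),
                         integer(1))
  })
  pairs <- purrr::pmap(specs[, c("l_q", "site", "linker", "seed_q")],
                       function(l_q, site, linker, seed_q) {
                         make_cp_pair(l_q, site, linker, seed = seed_q)
                       })
  tibble(entry = specs$entry, group = specs$group, pair = pairs,
         linker = specs$linker,
         protein_seq = vapply(pairs, function(p) structure_sequence(p$q),
                              character(1)))
}

#' Multi-round independent test of the linker design protocol
#'
#' A grouped cross-validation harness: per round, the linker groups are
#' split 90/10 into training and test sets; test proteins sharing at
#' least `identity_cutoff` percent sequence identity with any training
#' protein are discarded; the vote ensemble, class compositions and
#' propensity table are estimated from the training linkers (features
#' taken at the known linker positions of the training permutant
#' structures); and every surviving test linker is redesigned at its
#' known length. Reported per case: the BLOSUM45 similarity between the
#' designed and known linker and the backend energy difference
#' (designed minus known).
#'
#' @param db A [make_linker_db()] tibble.
#' @param rounds Number of rounds.
#' @param test_frac Fraction of groups held out per round.
#' @param identity_cutoff Percent identity above which a test protein is
#'   discarded.
#' @param cfg A [design_config()] (scaled-down defaults recommended:
#'   `t = 20, t_prime = 5, k = 3, m_models = 2`).
#' @param seed Integer seed.
#' @param backend Modeling backend.
#' @return Tibble with one row per redesigned test case: `round`,
#'   `entry`, `designed`, `known`, `similarity`, `energy_designed`,
#'   `energy_known`, `energy_delta`.
#' @export
run_independent_test <- function(db, rounds = 10, test_frac = 0.1,
                                 identity_cutoff = 15,
                                 cfg = design_config(t = 20, t_prime = 5,
                                                     k = 3, m_models = 2,
                                                     n_report = 5),
                                 seed = 1, backend = surrogate_backend()) {
  groups <- unique(db$group)
  n_test <- max(1, round(test_frac * length(groups)))
  if (length(groups) < 2) abort("too few groups to split")
  purrr::map(seq_len(rounds), function(rd) {
    test_groups <- withr::with_seed(seed + rd, sample(groups, n_test))
    train <- filter(db, !.data$group %in% test_groups)
    test <- filter(db, .data$group %in% test_groups)
    # identity filter against the training proteins
    keep <- vapply(test$protein_seq, function(sq) {
      ids <- vapply(unique(train$protein_seq),
                    function(tr) sequence_identity(sq, tr), numeric(1))
      all(ids < identity_cutoff)
    }, logical(1))
    test <- test[keep, ]
    if (nrow(test) == 0) return(tibble())
    # train on the known linkers of the training set
    feats <- purrr::map(train$pair, function(p) {
      serials <- p$junction + seq_len(nchar(p$linker))
      compute_features_tbl(p$s, serials, cfg$d_r)
    }) |> bind_rows()
    labels <- unlist(purrr::map(train$linker, aa_classes))
    scheme <- estimate_composition(class_scheme(), train$linker)
    predictor <- train_ensemble(feats[, aa_alphabet()], labels, scheme,
                                seed = seed + rd, n_tree = 25, n_net = 5)
    prop <- propensity_table(train$linker)
    purrr::pmap(test[, c("entry", "pair", "linker")],
                function(entry, pair, linker) {
      des <- design_linkers(pair$q, pair$site, predictor, cfg,
                            l = nchar(linker), table = prop,
                            backend = backend)
      best <- des[1, ]
      e_known <- model_with_linker(
        cp_sequence(structure_sequence(pair$q), pair$site), linker,
        pair$junction, make_pseudo_cp_template(renumber(pair$q), pair$site),
        backend, default_schemes(), m_models = cfg$m_models)$energy
      tibble(round = rd, entry = entry,
             designed = best$sequence, known = linker,
             similarity = sequence_similarity(best$sequence, linker),
             energy_designed = best$energy, energy_known = e_known,
             energy_delta = best$energy - e_known)
    }) |> bind_rows()
  }) |> bind_rows()
}
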