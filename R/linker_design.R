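# The six-step linker design protocol: length estimation, propensity-
# guided temporary linkers, coarse-model screening, per-position
# probability prediction, probability-guided sampling, and energy-ranked
# final selection.

#' Linker design configuration
#'
#' All the protocol knobs. Defaults follow the published protocol
#' (`t = 200` temporary linkers, `t' = 20` kept coarse models, `k = 10`
#' sequences sampled per coarse model, `m = 10` models per candidate, 30
#' reported candidates, 20 Angstrom feature radius).
#'
#' @param t Temporary linkers built in step 1.
#' @param t_prime Coarse models kept after energy screening.
#' @param k Sequences sampled per coarse model.
#' @param m_models Models built per candidate in step 5.
#' @param n_report Candidates reported.
#' @param d_r Feature radius, Angstrom.
#' @param seed Integer seed for every random draw of the protocol.
#' @return A `design_config` list.
#' @export
design_config <- function(t = 200, t_prime = 20, k = 10, m_models = 10,
                          n_report = 30, d_r = 20, seed = 1) {
  stopifnot(t >= t_prime, t_prime >= 1, k >= 1, m_models >= 1, n_report >= 1)
  structure(list(t = t, t_prime = t_prime, k = k, m_models = m_models,
                 n_report = n_report, d_r = d_r, seed = as.integer(seed)),
            class = "design_config")
}

#' Amino-acid propensity table for temporary linkers
#'
#' Background amino-acid frequencies used to sample the temporary
#' (placeholder) linkers of protocol step 1. Estimated from a supplied
#' set of known linker sequences (with Laplace smoothing), or uniform if
#' none is given.
#'
#' @param linkers Optional character vector of known linker sequences.
#' @param laplace Smoothing pseudo-count.
#' @return Named numeric 20-vector summing to 1, in [aa_alphabet()]
#'   order.
#' @export
propensity_table <- function(linkers = NULL, laplace = 1) {
  if (is.null(linkers) || length(linkers) == 0) {
    return(stats::setNames(rep(1 / 20, 20), aa_alphabet()))
  }
  aa <- unlist(strsplit(paste(linkers, collapse = ""), ""))
  counts <- table(factor(aa, levels = aa_alphabet())) + laplace
  p <- as.numeric(counts) / sum(counts)
  stats::setNames(p, aa_alphabet())
}

check_propensity <- function(table) {
  if (!setequal(names(table), aa_alphabet())) abort("propensity table must cover the 20 amino acids")
  if (any(table < 0) || abs(sum(table) - 1) > 1e-9) {
    abort("propensity table must be non-negative and sum to 1")
  }
  table[aa_alphabet()]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate linker length from the termini distance
#'
#' For termini closer than 20 Angstrom, the linker length follows the
#' logarithmic fit `l = Round(21.8 * ln(b) - 52.5)`, clamped at 0
#' (rounding half away from zero). Beyond 20 Angstrom the fit does not
#' hold and the iterative estimator
#' [estimate_linker_length_long()] must be used instead.
#'
#' @param b Termini CA-CA distance, Angstrom; `0 < b < 20`.
#' @return Integer linker length `l >= 0`.
#' @export
estimate_linker_length <- function(b) {
  if (!is.numeric(b) || length(b) != 1 || b <= 0) abort("termini distance must be positive")
  if (b >= 20) abort("use iterative estimator: the length fit only holds below 20 Angstrom")
  max(0L, as.integer(round_half_away(21.8 * log(b) - 52.5)))
}

#' Sample temporary linkers from a propensity table
#'
#' @param l Linker length (residues), `>= 1`.
#' @param table A [propensity_table()].
#' @param t Number of linkers.
#' @param seed Integer seed.
#' @return Character vector of `t` sequences of length `l`.
#' @export
sample_temporary_linkers <- function(l, table, t, seed = 1) {
  stopifnot(l >= 1, t >= 1)
  table <- check_propensity(table)
  withr::with_seed(seed, {
    vapply(seq_len(t), function(i) {
      paste(sample(aa_alphabet(), l, replace = TRUE, prob = table),
            collapse = "")
    }, character(1))
  })
}

#' Sample candidate sequences from a probability profile
#'
#' Draws an amino acid per linker position from the per-position
#' probabilities (e.g. if valine has probability 0.70 at position 1, the
#' sampled residue is valine 70% of the time), `k` times.
#'
#' @param profile An `aa_profile` (positions x 20).
#' @param k Number of sequences.
#' @param seed Integer seed.
#' @return Character vector of `k` sequences of `nrow(profile)` residues.
#' @export
sample_candidate_sequences <- function(profile, k, seed = 1) {
  m <- unclass(profile)
  stopifnot(ncol(m) == 20, k >= 1)
  withr::with_seed(seed, {
    vapply(seq_len(k), function(i) {
      paste(vapply(seq_len(nrow(m)), function(p) {
        sample(colnames(m), 1, prob = m[p, ])
      }, character(1)), collapse = "")
    }, character(1))
  })
}

insert_linker <- function(seq, linker, after) {
  paste0(substr(seq, 1, after), linker,
         substr(seq, after + 1, nchar(seq)))
}

# build (align + model) a target sequence carrying a linker against the
# pseudo-CP template, m times, keeping the lowest-energy model
model_with_linker <- function(target_seq, linker, junction, template,
                              backend, schemes, m_models = 1) {
  full <- insert_linker(target_seq, linker, junction)
  aln <- align_best(full, structure_sequence(template), schemes)
  best <- NULL
  for (i in seq_len(m_models)) {
    out <- backend(aln, template)
    if (is.null(best) || out$energy < best$energy) best <- out
  }
  best$alignment <- aln
  best
}

#' Iterative linker-length estimation for distant termini
#'
#' For proteins whose termini are 20 Angstrom apart or more. Starting at
#' `l = 20` and increasing by 5 up to one fifth of the target size, `t`
#' propensity-sampled temporary linkers are built and modeled per length
#' and the per-length minimum energy recorded; the neighborhood
#' `l - 4 .. l + 4` of the best coarse length is then scanned the same
#' way, and the overall lowest-energy length returned (ties toward the
#' smallest length).
#'
#' @param template A renumbered `cpm_structure` (the native protein).
#' @param site CP site on the template.
#' @param table A [propensity_table()].
#' @param cfg A [design_config()].
#' @param backend Modeling backend, see [surrogate_backend()].
#' @param schemes Alignment schemes.
#' @return Integer linker length, with attribute `scan` (tibble `l`,
#'   `energy`).
#' @export
estimate_linker_length_long <- function(template, site, table = propensity_table(),
                                        cfg = design_config(),
                                        backend = surrogate_backend(),
                                        schemes = default_schemes()) {
  template <- renumber(template)
  L <- n_residues(template)
  pseudo <- make_pseudo_cp_template(template, site)
  target_seq <- cp_sequence(structure_sequence(template), site)
  junction <- L - site + 1L
  lmax <- max(20L, floor(L / 5))
  coarse <- seq(20L, lmax, by = 5L)
  energy_of_l <- function(l, seed_off) {
    temps <- sample_temporary_linkers(l, table, cfg$t, cfg$seed + seed_off)
    min(vapply(temps, function(lk) {
      model_with_linker(target_seq, lk, junction, pseudo, backend, schemes)$energy
    }, numeric(1)))
  }
  scan <- tibble(l = coarse,
                 energy = vapply(seq_along(coarse),
                                 function(i) energy_of_l(coarse[i], i),
                                 numeric(1)))
  l_best <- scan$l[order(scan$energy, scan$l)[1]]
  fine <- setdiff(seq(max(1L, l_best - 4L), l_best + 4L), scan$l)
  if (length(fine) > 0) {
    scan <- bind_rows(scan, tibble(
      l = fine,
      energy = vapply(seq_along(fine),
                      function(i) energy_of_l(fine[i], 1000 + i),
                      numeric(1))))
  }
  scan <- arrange(scan, .data$l)
  out <- scan$l[order(scan$energy, scan$l)[1]]
  attr(out, "scan") <- scan
  out
}

#' Design termini linkers for a circular permutant
#'
#' The full six-step protocol. (1) `t` temporary linkers sampled from the
#' propensity table are inserted at the junction of the native termini,
#' modeled against the pseudo-CP template, and the `t'` lowest-energy
#' coarse models kept. (2) For each coarse model, the feature vector of
#' every linker position feeds the vote ensemble; the three class
#' probabilities are restored to 20 amino-acid probabilities. (3) `k`
#' sequences are sampled per coarse model from the per-position
#' probabilities, pooling `t' * k` candidates. (5) Each candidate is
#' re-inserted, re-aligned, and modeled `m` times, keeping its lowest
#' energy. (6) Candidates are ranked by energy (ties by provenance) and
#' the top `n_report` returned.
#'
#' @param template A renumbered `cpm_structure` (the native protein).
#' @param site CP site on the template.
#' @param predictor A trained [train_ensemble()] whose scheme carries
#'   compositions.
#' @param cfg A [design_config()].
#' @param l Linker length; if `NULL`, estimated from the termini distance
#'   ([estimate_linker_length()] below 20 Angstrom, the iterative
#'   estimator otherwise).
#' @param table A [propensity_table()].
#' @param target_seq Target CPM sequence without the linker; defaults to
#'   the circular permutation of the template sequence.
#' @param backend Modeling backend (see [surrogate_backend()]).
#' @param schemes Alignment schemes competing under the selection rule.
#' @return A `linker_designs` tibble: `rank`, `sequence`, `energy`,
#'   `coarse_id`, `sample_id`, with attributes `pool` (all `t' * k`
#'   candidates), `coarse` (the step-1 screening energies), `config`,
#'   `l`, `junction`, `models` (list of the reported models' structures).
#' @export
design_linkers <- function(template, site, predictor, cfg = design_config(),
                           l = NULL, table = propensity_table(),
                           target_seq = NULL,
                           backend = surrogate_backend(),
                           schemes = default_schemes()) {
  template <- renumber(template)
  L <- n_residues(template)
  pseudo <- make_pseudo_cp_template(template, site)
  if (is.null(target_seq)) target_seq <- cp_sequence(structure_sequence(template), site)
  junction <- L - site + 1L
  if (is.null(l)) {
    b <- termini_distance(template)
    l <- if (b < 20) {
      estimate_linker_length(b)
    } else {
      as.integer(estimate_linker_length_long(template, site, table, cfg,
                                             backend, schemes))
    }
  }
  if (l == 0) {
    aln <- align_best(target_seq, structure_sequence(pseudo), schemes)
    out <- backend(aln, pseudo)
    res <- tibble(rank = 1L, sequence = "", energy = out$energy,
                  coarse_id = NA_integer_, sample_id = NA_integer_)
    return(structure(res, pool = res, config = cfg, l = 0L,
                     junction = junction, models = list(out$structure),
                     class = c("linker_designs", class(tibble()))))
  }
  # step 1: temporary linkers -> coarse models, keep t' lowest energies
  temps <- sample_temporary_linkers(l, table, cfg$t, cfg$seed)
  coarse <- purrr::map(temps, function(lk) {
    model_with_linker(target_seq, lk, junction, pseudo, backend, schemes)
  })
  energies <- vapply(coarse, function(x) x$energy, numeric(1))
  keep <- order(energies, seq_along(energies))[seq_len(cfg$t_prime)]
  coarse_tbl <- tibble(id = seq_along(energies), linker = temps,
                       energy = energies, kept = seq_along(energies) %in% keep)
  # steps 2-4: per coarse model, probability profile -> k samples
  pool <- purrr::imap(keep, function(ci, ki) {
    mod <- coarse[[ci]]$structure
    serials <- junction + seq_len(l)
    prof <- aa_probability_profile(mod, serials, predictor, cfg$d_r)
    seqs <- sample_candidate_sequences(prof, cfg$k, cfg$seed + 7919 * ki)
    tibble(coarse_id = ki, sample_id = seq_len(cfg$k), sequence = seqs)
  }) |> bind_rows()
  # step 5: energy of each candidate
  pool <- pool |>
    mutate(energy = purrr::map_dbl(.data$sequence, function(sq) {
      model_with_linker(target_seq, sq, junction, pseudo, backend, schemes,
                        m_models = cfg$m_models)$energy
    }))
  # step 6: rank
  ranked <- pool |>
    arrange(.data$energy, .data$coarse_id, .data$sample_id) |>
    mutate(rank = row_number()) |>
    select("rank", "sequence", "energy", "coarse_id", "sample_id")
  top <- ranked[seq_len(min(cfg$n_report, nrow(ranked))), ]
  models <- purrr::map(top$sequence, function(sq) {
    model_with_linker(target_seq, sq, junction, pseudo, backend, schemes,
                      m_models = cfg$m_models)$structure
  })
  structure(top, pool = ranked, coarse = coarse_tbl, config = cfg,
            l = as.integer(l), junction = junction, models = models,
            class = c("linker_designs", class(tibble())))
}
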