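# End-to-end orchestration: the three working modes (primary CP
# modeling, highly modified CPM modeling, linker design) and run reports.

new_report <- function(mode, ...) {
  structure(c(list(mode = mode), list(...)), class = "cirperm_report")
}

#' @export
print.cirperm_report <- function(x, ...) {
  cat(sprintf("<cirperm_report> mode %d, CP site %d\n", x$mode, x$cp_site))
  cat(sprintf("  alignment: %d columns aligned, identity %.1f%%, similarity %.1f%%\n",
              x$aligned_columns, x$identity, x$similarity))
  if (!is.null(x$linker) && nzchar(x$linker)) {
    cat(sprintf("  linker: %s (%d residues)\n", x$linker, nchar(x$linker)))
  }
  if (!is.null(x$pose)) {
    cat(sprintf("  refinement: %d snapshots, best pose theta=%d phi=%d, energy %.3f\n",
                x$n_snapshots, x$pose$theta, x$pose$phi, x$energy))
  }
  if (!is.null(x$evaluation)) {
    cat(sprintf("  vs reference: alignment ratio %.1f%%, RMSD %.2f A\n",
                x$evaluation$alignment_ratio, x$evaluation$rmsd))
  }
  invisible(x)
}

#' Glance at a run report
#' @param x A `cirperm_report`.
#' @param ... Unused.
#' @return One-row tibble of the headline numbers.
#' @export
glance.cirperm_report <- function(x, ...) {
  tibble(mode = x$mode, cp_site = x$cp_site,
         aligned_columns = x$aligned_columns,
         identity = x$identity, similarity = x$similarity,
         linker = x$linker %||% "",
         energy = x$energy %||% NA_real_,
         rmsd = if (!is.null(x$evaluation)) x$evaluation$rmsd else NA_real_)
}

run_mode_common <- function(template, cp_site, target_seq, linker, refine,
                            seed, reference, schemes, backend, mode) {
  if (is.character(template)) template <- parse_structure(template)
  template <- renumber(template)
  L <- n_residues(template)
  pseudo <- make_pseudo_cp_template(template, cp_site)
  junction <- L - cp_site + 1L
  linker <- linker %||% ""
  if (is.null(target_seq)) {
    target_seq <- cp_sequence(structure_sequence(template), cp_site)
  }
  full <- if (nzchar(linker)) insert_linker(target_seq, linker, junction) else target_seq
  aln <- align_best(full, structure_sequence(pseudo), schemes)
  if (similarity_percent(aln) < 20) {
    warn("target shares very low similarity with the template; the model is unreliable")
  }
  coarse <- backend(aln, pseudo)
  model <- coarse$structure
  out <- list(model = model, energy = coarse$energy,
              trace = NULL, pose = NULL, n_snapshots = 0L)
  if (refine && junction >= 1 && junction + nchar(linker) < n_residues(model)) {
    frame <- split_by_hinge(model, junction, nchar(linker))
    refined <- hinge_refine(model, frame)
    out <- list(model = refined, energy = attr(refined, "energy"),
                trace = attr(refined, "trace"), pose = attr(refined, "pose"),
                n_snapshots = attr(refined, "n_snapshots"))
  }
  ev <- if (!is.null(reference)) {
    if (is.character(reference)) reference <- parse_structure(reference)
    evaluate_model(out$model, renumber(reference))
  }
  new_report(mode, cp_site = as.integer(cp_site), seed = as.integer(seed),
             target_sequence = target_seq, linker = linker,
             aligned_columns = aln$aligned_columns,
             identity = identity_percent(aln),
             similarity = similarity_percent(aln),
             alignment = aln, model = out$model, energy = out$energy,
             trace = out$trace, pose = out$pose,
             n_snapshots = out$n_snapshots, evaluation = ev)
}

#' Mode 1: structure modeling for a primary circular permutant
#'
#' The target sequence is derived from the template according to the CP
#' site (a pure circular permutation, with an optional already-designed
#' linker inserted at the junction of the native termini). Pipeline:
#' renumber, pseudo-CP template, alignment, coarse model, CP-site-hinged
#' refinement over the 162-pose grid.
#'
#' @param template A `cpm_structure`, or a path to / text of a PDB file.
#' @param cp_site CP site (1-based residue serial on the renumbered
#'   template); 1 gives conventional co-linear modeling.
#' @param linker Optional designed linker sequence.
#' @param refine Run the hinge refinement.
#' @param seed Integer seed (echoed in the report; mode 1 is
#'   deterministic).
#' @param reference Optional known CPM structure for evaluation.
#' @param schemes Alignment schemes.
#' @param backend Modeling backend.
#' @return A `cirperm_report`.
#' @export
run_mode1 <- function(template, cp_site, linker = "", refine = TRUE,
                      seed = 1, reference = NULL,
                      schemes = default_schemes(),
                      backend = surrogate_backend()) {
  run_mode_common(template, cp_site, NULL, linker, refine, seed, reference,
                  schemes, backend, mode = 1L)
}

#' Mode 2: structure modeling for a highly modified circular permutant
#'
#' Like mode 1, but the target CPM sequence is supplied by the user and
#' may carry substitutions and indels in addition to the permutation; it
#' is aligned against the pseudo-CP template under every configured
#' scheme and the alignment with the most aligned residues is used.
#'
#' @inheritParams run_mode1
#' @param target_seq The CPM sequence (with any linker already included).
#' @return A `cirperm_report`.
#' @export
run_mode2 <- function(template, cp_site, target_seq, refine = TRUE,
                      seed = 1, reference = NULL,
                      schemes = default_schemes(),
                      backend = surrogate_backend()) {
  if (is.null(target_seq) || !nzchar(target_seq)) abort("mode 2 requires the CPM sequence")
  run_mode_common(template, cp_site, target_seq, "", refine, seed, reference,
                  schemes, backend, mode = 2L)
}

#' Mode 3: linker design
#'
#' Delegates to [design_linkers()]; reports the ranked candidates
#' (default 30) with their energies and models.
#'
#' @inheritParams run_mode1
#' @param predictor A trained [train_ensemble()].
#' @param cfg A [design_config()].
#' @param table A [propensity_table()].
#' @param l Linker length override (NULL = estimate from the termini
#'   distance).
#' @return A `cirperm_report` with a `candidates` tibble.
#' @export
run_mode3 <- function(template, cp_site, predictor, cfg = design_config(),
                      table = propensity_table(), l = NULL, seed = NULL,
                      backend = surrogate_backend(),
                      schemes = default_schemes()) {
  if (is.character(template)) template <- parse_structure(template)
  template <- renumber(template)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  des <- design_linkers(template, cp_site, predictor, cfg, l = l,
                        table = table, backend = backend, schemes = schemes)
  new_report(3L, cp_site = as.integer(cp_site), seed = cfg$seed,
             target_sequence = cp_sequence(structure_sequence(template), cp_site),
             linker = des$sequence[1],
             aligned_columns = NA_integer_, identity = NA_real_,
             similarity = NA_real_, candidates = des,
             model = attr(des, "models")[[1]], energy = des$energy[1],
             trace = NULL, pose = NULL, n_snapshots = 0L, evaluation = NULL)
}

# ---- plotting ------------------------------------------------------------

#' Plot the hinge-refinement energy landscape
#'
#' Tile plot of snapshot energy over the (theta, phi) grid, with the
#' chosen pose marked.
#'
#' @param report A `cirperm_report` from a refined run.
#' @return A ggplot.
#' @export
plot_refinement_trace <- function(report) {
  tr <- report$trace
  if (is.null(tr)) abort("report has no refinement trace")
  ggplot2::ggplot(tr, ggplot2::aes(.data$phi, .data$theta, fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = as_tibble(report$pose),
                        ggplot2::aes(.data$phi, .data$theta),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "axial angle phi (deg)", y = "in-plane angle theta (deg)",
                  fill = "energy")
}

#' @rdname plot_refinement_trace
#' @param object A `cirperm_report`.
#' @param ... Unused.
#' @export
autoplot.cirperm_report <- function(object, ...) plot_refinement_trace(object)

#' Plot a per-position amino-acid probability profile
#'
#' @param object An `aa_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aa_profile <- function(object, ...) {
  ggplot2::ggplot(tidy.aa_profile(object),
                  ggplot2::aes(.data$position, .data$aa, fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "linker position", y = "amino acid", fill = "p")
}

#' Plot ranked linker candidates by energy
#'
#' @param object A `linker_designs` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linker_designs <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$rank, .data$energy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "candidate rank", y = "backend energy")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
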