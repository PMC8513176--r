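# CP-pair linker determination, solvent-exposure detection and in-silico
# circular permutant synthesis.

#' Circular-permutation-aware residue correspondence
#'
#' Holds the aligned residue pairs between two proteins Q and S related
#' by circular permutation. Because of the CP wrap, when the pairs are
#' ordered by Q serial the S serials form at most two strictly increasing
#' runs.
#'
#' @param pairs Data frame with integer columns `q` and `s` (1-based
#'   residue serials), ordered by `q`.
#' @param q_len,s_len Residue counts of Q and S.
#' @return A `cp_alignment` tibble with attributes `q_len`, `s_len`.
#' @export
cp_alignment <- function(pairs, q_len, s_len) {
  pairs <- as_tibble(pairs)[, c("q", "s")]
  if (nrow(pairs) == 0) abort("not a CP alignment: no aligned pairs")
  if (any(diff(pairs$q) <= 0)) abort("not a CP alignment: q serials not strictly increasing")
  if (any(pairs$q < 1 | pairs$q > q_len | pairs$s < 1 | pairs$s > s_len)) {
    abort("not a CP alignment: serial out of bounds")
  }
  breaks <- sum(diff(pairs$s) <= 0)
  if (breaks > 1) abort("not a CP alignment: s serials form more than two increasing runs")
  structure(pairs, q_len = as.integer(q_len), s_len = as.integer(s_len),
            class = c("cp_alignment", class(tibble())))
}

#' Swap the roles of Q and S in a CP alignment
#' @param aln A `cp_alignment`.
#' @return The `cp_alignment` with Q and S exchanged.
#' @export
swap_alignment <- function(aln) {
  sw <- tibble(q = aln$s, s = aln$q) |> arrange(.data$q)
  cp_alignment(sw, attr(aln, "s_len"), attr(aln, "q_len"))
}

# walk forward on S serials with wrap-around L -> 1
walk_forward <- function(from, to, L) {
  if (from == to) return(integer(0))
  out <- integer(0)
  i <- from
  for (step in seq_len(L)) {
    i <- if (i == L) 1L else i + 1L
    if (i == to) break
    out <- c(out, i)
  }
  out
}

advance_wrap <- function(i, k, L) ((i - 1L + k) %% L) + 1L

#' Determine the termini linker for protein Q of a CP pair
#'
#' Given the CP-aware correspondence between Q and S, finds the fragment
#' of S that bridges Q's native termini. With `x_q`/`x_s` the first
#' aligned pair and `y_q`/`y_s` the last, the candidate linker is the
#' run of S residues strictly between `y_s` and `x_s` (walking forward in
#' S serial order, wrapping past the terminus); `l` is its length, `m`
#' and `n` the unaligned Q residues before `x_q` and after `y_q`. If
#' `m + n >= l` no linker is needed; otherwise the linker is the refined
#' span strictly between `y_s + n` and `x_s - m`.
#'
#' @param aln A [cp_alignment()] (Q vs S).
#' @param seq_s Amino-acid sequence of S.
#' @return A `linker_result` list: `needed`, `s_start`, `s_end`
#'   (exclusive serial bounds on S), `serials`, `sequence`, `l`, `m`, `n`.
#' @export
determine_linker <- function(aln, seq_s) {
  s_len <- attr(aln, "s_len")
  if (nchar(seq_s) != s_len) abort("seq_s length does not match s_len")
  x_q <- aln$q[1]; x_s <- aln$s[1]
  y_q <- aln$q[nrow(aln)]; y_s <- aln$s[nrow(aln)]
  cand <- walk_forward(y_s, x_s, s_len)
  l <- length(cand)
  m <- x_q - 1L
  n <- attr(aln, "q_len") - y_q
  if (m + n >= l) {
    return(structure(list(needed = FALSE, s_start = NA_integer_,
                          s_end = NA_integer_, serials = integer(0),
                          sequence = "", l = l, m = m, n = n),
                     class = "linker_result"))
  }
  s_start <- advance_wrap(y_s, n, s_len)
  s_end <- advance_wrap(x_s, -m, s_len)
  ser <- walk_forward(s_start, s_end, s_len)
  structure(list(needed = TRUE, s_start = s_start, s_end = s_end,
                 serials = ser,
                 sequence = paste(strsplit(seq_s, "")[[1]][ser], collapse = ""),
                 l = l, m = m, n = n),
            class = "linker_result")
}

#' @export
print.linker_result <- function(x, ...) {
  if (x$needed) {
    cat(sprintf("<linker_result> '%s' (l=%d, m=%d, n=%d; S span (%d,%d))\n",
                x$sequence, x$l, x$m, x$n, x$s_start, x$s_end))
  } else {
    cat(sprintf("<linker_result> no linker required (l=%d, m=%d, n=%d)\n",
                x$l, x$m, x$n))
  }
  invisible(x)
}

#' Determine the linkers for both proteins of a CP pair
#'
#' Runs [determine_linker()] for Q, then repeats with the roles of Q and
#' S swapped.
#'
#' @param aln A [cp_alignment()] (Q vs S).
#' @param seq_q,seq_s Sequences of Q and S.
#' @return List with elements `q` and `s`, each a `linker_result`.
#' @export
determine_linkers_pair <- function(aln, seq_q, seq_s) {
  list(q = determine_linker(aln, seq_s),
       s = determine_linker(swap_alignment(aln), seq_q))
}

#' Build a CP alignment from two sequences (doubled-sequence trick)
#'
#' Sequence-level convenience for when no structural correspondence is
#' available: Q is locally aligned against S concatenated with itself,
#' and subject positions are folded back modulo `nchar(seq_s)`. This is
#' an approximation to a CP-aware structural alignment.
#'
#' @param seq_q,seq_s Protein sequences.
#' @param scheme A [scoring_scheme()].
#' @return A [cp_alignment()].
#' @export
cp_align_sequences <- function(seq_q, seq_s, scheme = scoring_scheme("nw")) {
  check_protein(seq_q, "seq_q"); check_protein(seq_s, "seq_s")
  Ls <- nchar(seq_s)
  mat <- substitution_matrix(scheme$matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq_q, subject = paste0(seq_s, seq_s), type = "local",
    substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  pr <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sr <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  spos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qs <- integer(0); ss <- integer(0)
  for (k in seq_along(pr)) {
    if (pr[k] != "-") qpos <- qpos + 1L
    if (sr[k] != "-") spos <- spos + 1L
    if (pr[k] != "-" && sr[k] != "-") {
      qs <- c(qs, qpos); ss <- c(ss, ((spos - 1L) %% Ls) + 1L)
    }
  }
  keep <- !duplicated(ss)
  cp_alignment(tibble(q = qs[keep], s = ss[keep]), nchar(seq_q), Ls)
}

# ---- solvent accessibility ----------------------------------------------

# Tien et al. theoretical maximum ASA (A^2) per residue, all-atom.
.max_asa_tien <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

.vdw_radius <- function(elety) {
  el <- substr(gsub("^[0-9]", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  out <- unname(r[el])
  out[is.na(out)] <- 1.70
  out
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n = 92) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 92) {
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  rr <- radii + probe
  sasa <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    surf <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    if (length(neigh) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in neigh) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rr[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    sasa[i] <- 4 * pi * rr[i]^2 * frac
  }
  sasa
}

#' Per-residue relative solvent accessibility
#'
#' Shrake-Rupley solvent-accessible surface area (probe 1.4 Angstrom, 92
#' deterministic golden-spiral points per atom), normalized to percent by
#' the Tien et al. theoretical maximum ASA of each residue type. For
#' CA-only traces each residue is approximated by a single sphere
#' (`ca_radius`) and normalized by the isolated-sphere area, so an
#' isolated residue reads ~100%.
#'
#' @param s A `cpm_structure`.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom.
#' @param ca_radius Per-residue sphere radius used for CA-only traces.
#' @return Tibble with columns `serial`, `resname`, `sasa`, `rsa`.
#' @export
compute_rsa <- function(s, probe = 1.4, n_points = 92, ca_radius = 2.5) {
  validate_structure(s)
  if (n_residues(s) == 0) abort("empty structure")
  ca_only <- all(s$atom == "CA")
  if (ca_only) {
    xyz <- ca_coords(s)
    radii <- rep(ca_radius, nrow(xyz))
    sasa <- shrake_rupley(xyz, radii, probe, n_points)
    ref <- 4 * pi * (ca_radius + probe)^2
    ca <- filter(s, .data$atom == "CA")
    tibble(serial = ca$serial, resname = ca$resname,
           sasa = sasa, rsa = 100 * sasa / ref)
  } else {
    xyz <- as.matrix(s[, c("x", "y", "z")])
    sasa_atom <- shrake_rupley(xyz, .vdw_radius(s$atom), probe, n_points)
    res <- s |> mutate(.sasa = sasa_atom) |>
      group_by(.data$serial) |>
      summarise(resname = first(.data$resname), sasa = sum(.data$.sasa),
                .groups = "drop")
    one <- aa_three_to_one(res$resname)
    mutate(res, rsa = 100 * .data$sasa / unname(.max_asa_tien[one]))
  }
}

#' Maximal solvent-exposed fragments
#'
#' Maximal runs of consecutive residues whose relative solvent
#' accessibility exceeds the threshold (20% by default) — the candidate
#' CP regions used when synthesizing in-silico permutants.
#'
#' @param rsa Either the tibble from [compute_rsa()] or a numeric vector
#'   of per-residue RSA values in serial order.
#' @param threshold Exposure threshold, percent.
#' @return Tibble with columns `start`, `end` (inclusive serials) and
#'   `length`.
#' @export
exposed_fragments <- function(rsa, threshold = 20) {
  v <- if (is.data.frame(rsa)) rsa$rsa else as.numeric(rsa)
  if (length(v) == 0) return(tibble(start = integer(0), end = integer(0),
                                    length = integer(0)))
  r <- rle(v > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep],
         length = ends[keep] - starts[keep] + 1L)
}

#' Synthesize an in-silico circular permutant
#'
#' For a protein whose native termini are close enough to join directly
#' (termini distance at most `3 * d_consecutive`), sets the CP site at
#' the residue following an exposed fragment, rotates the residue records
#' ([make_pseudo_cp_template()]), and removes the fragment. The removed
#' sequence is the known "missing linker" of the synthetic permutant.
#'
#' @param s A renumbered `cpm_structure`.
#' @param frag_start,frag_end Inclusive serial bounds of the exposed
#'   fragment (e.g. a row of [exposed_fragments()]).
#' @param d_consecutive Average consecutive-residue CA distance used in
#'   the direct-connection rule, Angstrom.
#' @return List: `structure` (the permuted, fragment-free permutant),
#'   `linker` (removed sequence), `cp_site`, `linker_position` (0-based
#'   count of residues preceding the excision point in the permutant).
#' @export
make_in_silico_cpm <- function(s, frag_start, frag_end, d_consecutive = 3.36) {
  validate_structure(s)
  if (!is_renumbered(s)) s <- renumber(s)
  L <- n_residues(s)
  stopifnot(frag_start >= 1, frag_end >= frag_start, frag_end <= L)
  b <- termini_distance(s)
  if (b > 3 * d_consecutive) {
    abort(sprintf(
      "direct connection not allowed: termini distance %.2f A exceeds 3*d = %.2f A",
      b, 3 * d_consecutive))
  }
  site <- if (frag_end == L) 1L else frag_end + 1L
  perm <- make_pseudo_cp_template(s, site)
  # positions of the fragment residues in the permuted order
  frag <- seq(frag_start, frag_end)
  new_pos <- ((frag - site) %% L) + 1L
  seq_perm <- structure_sequence(perm)
  linker <- paste(strsplit(seq_perm, "")[[1]][sort(new_pos)], collapse = "")
  out <- filter(perm, !(.data$serial %in% new_pos))
  out <- renumber(new_structure(out, chain_id = attr(s, "chain_id") %||% "A"))
  list(structure = out, linker = linker, cp_site = site,
       linker_position = min(new_pos) - 1L)
}
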