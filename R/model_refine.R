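# Coarse comparative model construction (CA-trace surrogate backend), the
# surrogate energy, the CP-site-hinged rigid-body refinement, and the
# structural evaluation metrics.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("zero-length vector")
  v / n
}

rot_about_axis <- function(axis, deg) {
  a <- unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# deterministic unit vector perpendicular to `ab`
perp_of <- function(ab) {
  ab <- unit(ab)
  basis <- diag(3)
  k <- which.min(abs(ab))
  unit(basis[, k] - sum(basis[, k] * ab) * ab)
}

# place g residues between anchors A and B on a circular arc whose arc
# length is (g + 1) * spacing; falls back to even chord spacing when the
# anchors are too far apart for the arc to exist
arc_place <- function(A, B, g, spacing = 3.8) {
  if (g == 0) return(matrix(numeric(0), ncol = 3))
  chord <- sqrt(sum((B - A)^2))
  s <- (g + 1) * spacing
  if (chord < 1e-9) {
    # closed loop: full circle through A in a deterministic plane
    R <- s / (2 * pi)
    w <- c(0, 0, 1); u <- c(1, 0, 0)
    O <- A + R * w
    ang <- 2 * pi * seq_len(g) / (g + 1)
    return(t(vapply(ang, function(t_) O + R * (-cos(t_) * w + sin(t_) * u),
                    numeric(3))))
  }
  if (s <= chord + 1e-9) {
    # cannot bulge: straight interpolation
    t_ <- seq_len(g) / (g + 1)
    return(t(vapply(t_, function(f) A + f * (B - A), numeric(3))))
  }
  f <- function(th) sin(th / 2) / (th / 2) - chord / s
  th <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  R <- s / th
  w <- perp_of(B - A)
  M <- (A + B) / 2
  h <- sqrt(max(R^2 - chord^2 / 4, 0))
  O <- M + h * w
  a_v <- A - O; b_v <- B - O
  axis <- tryCatch(unit(pracma_cross(a_v, b_v)), error = function(e) perp_of(a_v))
  if (th > pi) axis <- -axis
  t(vapply(seq_len(g), function(k) {
    O + rot_about_axis(axis, (k * th / (g + 1)) * 180 / pi) %*% a_v
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Surrogate energy of a CA trace
#'
#' A dependency-free stand-in for a statistical potential, used to rank
#' models and snapshots: the squared deviation of consecutive CA-CA
#' distances from the ideal 3.8 Angstrom, plus 10 per clashing pair
#' (sequence separation >= 3 and distance < 4 Angstrom). Lower is better;
#' rigid motions leave it unchanged.
#'
#' @param s A `cpm_structure` or a CA coordinate matrix.
#' @param clash_cut,clash_penalty,ideal Knobs of the two terms.
#' @return A single numeric score.
#' @export
surrogate_energy <- function(s, clash_cut = 4.0, clash_penalty = 10,
                             ideal = 3.8) {
  m <- if (is.matrix(s)) s else ca_coords(s)
  n <- nrow(m)
  if (n < 2) return(0)
  dcon <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  bond <- sum((dcon - ideal)^2)
  D <- as.matrix(stats::dist(m))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  clash <- sum(D < clash_cut & sep >= 3 & upper.tri(D))
  bond + clash_penalty * clash
}

#' Build a coarse CA-trace model from a target-template alignment
#'
#' Target residues aligned to a template residue inherit its CA
#' coordinates; unaligned target residues (designed linkers, insertions)
#' are placed on a circular arc between the flanking anchor CAs at 3.8
#' Angstrom spacing (straight interpolation when the anchors are too far
#' apart; linear extension at dangling termini). This surrogate stands
#' behind the modeling-backend contract.
#'
#' @param aln A `seq_alignment` whose first row degaps to the target
#'   sequence (with any linker inserted) and second row to the template
#'   sequence.
#' @param template A renumbered `cpm_structure` whose sequence equals the
#'   degapped second row.
#' @return List: `structure` (CA-only model, target numbering 1..n),
#'   `energy` (its [surrogate_energy()]).
#' @export
build_coarse_model <- function(aln, template) {
  ta <- strsplit(aln$rows[1], "")[[1]]
  tb <- strsplit(aln$rows[2], "")[[1]]
  tmpl_seq <- paste(tb[tb != "-"], collapse = "")
  if (tmpl_seq != structure_sequence(template)) {
    abort("alignment/template mismatch: second row does not degap to the template sequence")
  }
  tmpl_xyz <- ca_coords(template)
  ti <- cumsum(ta != "-")
  si <- cumsum(tb != "-")
  n_t <- sum(ta != "-")
  xyz <- matrix(NA_real_, nrow = n_t, ncol = 3)
  for (k in seq_along(ta)) {
    if (ta[k] != "-" && tb[k] != "-") xyz[ti[k], ] <- tmpl_xyz[si[k], ]
  }
  # fill unanchored runs
  miss <- which(is.na(xyz[, 1]))
  if (length(miss) > 0) {
    r <- rle(is.na(xyz[, 1]))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]; g <- b - a + 1
      if (a > 1 && b < n_t) {
        xyz[a:b, ] <- arc_place(xyz[a - 1, ], xyz[b + 1, ], g)
      } else if (a == 1 && b < n_t) {
        dirv <- if (b + 2 <= n_t && !is.na(xyz[b + 2, 1])) {
          unit(xyz[b + 1, ] - xyz[b + 2, ])
        } else c(1, 0, 0)
        for (k in b:a) xyz[k, ] <- xyz[k + 1, ] + 3.8 * dirv
      } else if (a > 1 && b == n_t) {
        dirv <- if (a - 2 >= 1 && !is.na(xyz[a - 2, 1])) {
          unit(xyz[a - 1, ] - xyz[a - 2, ])
        } else c(1, 0, 0)
        for (k in a:b) xyz[k, ] <- xyz[k - 1, ] + 3.8 * dirv
      } else {
        abort("alignment has no anchored residues")
      }
    }
  }
  target_seq <- paste(ta[ta != "-"], collapse = "")
  model <- new_structure(tibble(
    serial = seq_len(n_t),
    resname = aa_one_to_three(strsplit(target_seq, "")[[1]]),
    atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    eleno = seq_len(n_t), occ = 1
  ))
  list(structure = model, energy = surrogate_energy(model))
}

#' The surrogate modeling backend
#'
#' Returns a backend function with the contract
#' `backend(aln, template) -> list(structure, energy)`, implemented by
#' [build_coarse_model()] + [surrogate_energy()]. Deterministic. External
#' modeling software can be plugged in by supplying any function with the
#' same contract.
#'
#' @return A backend function.
#' @export
surrogate_backend <- function() {
  function(aln, template) build_coarse_model(aln, template)
}

# ---- hinge refinement ----------------------------------------------------

#' Split a model at the CP-site hinge
#'
#' A model built from a pseudo-CP template consists of two native-protein
#' proportions joined (possibly through a linker) at the point where the
#' native termini meet. The hinge is the CA of the middle linker residue
#' (`ceiling(l/2)`), or the midpoint of the two joined CAs when there is
#' no linker. The proportion with fewer residues is "small"; on a tie the
#' C-terminal proportion is taken as small.
#'
#' @param model A `cpm_structure` (model numbering 1..n).
#' @param junction Serial of the last residue of the first (N-terminal)
#'   proportion; the linker, if any, occupies
#'   `junction + 1 .. junction + linker_len`.
#' @param linker_len Number of linker residues.
#' @return A `hinge_frame` list: `hinge`, `com_small`, `com_large`,
#'   `axis_r`, `normal`, `small_serials`, `large_serials`,
#'   `small_is_cterm`.
#' @export
split_by_hinge <- function(model, junction, linker_len = 0) {
  validate_structure(model)
  L <- n_residues(model)
  stopifnot(junction >= 1, junction + linker_len < L)
  xyz <- ca_coords(model)
  seg1 <- seq_len(junction)
  seg2 <- seq(junction + linker_len + 1, L)
  hinge <- if (linker_len >= 1) {
    xyz[junction + ceiling(linker_len / 2), ]
  } else {
    (xyz[junction, ] + xyz[junction + 1, ]) / 2
  }
  small_is_cterm <- length(seg2) <= length(seg1)
  small <- if (small_is_cterm) seg2 else seg1
  large <- if (small_is_cterm) seg1 else seg2
  hinge <- unname(hinge)
  com_small <- unname(colMeans(xyz[small, , drop = FALSE]))
  com_large <- unname(colMeans(xyz[large, , drop = FALSE]))
  axis_r <- unit(com_small - hinge)
  nrm <- pracma_cross(com_small - hinge, com_large - hinge)
  if (sqrt(sum(nrm^2)) < 1e-9) {
    # collinear centroids: pick the perpendicular of axis_r with the
    # largest z component, tie-broken toward +x
    cands <- vapply(list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)), function(e) {
      v <- e - sum(e * axis_r) * axis_r
      if (sqrt(sum(v^2)) < 1e-9) rep(NA_real_, 3) else unit(v)
    }, numeric(3))
    k <- which(!is.na(cands[1, ]))[1]
    normal <- cands[, k]
  } else {
    normal <- unit(nrm)
  }
  structure(list(hinge = hinge, com_small = com_small, com_large = com_large,
                 axis_r = axis_r, normal = normal,
                 small_serials = small, large_serials = large,
                 small_is_cterm = small_is_cterm),
            class = "hinge_frame")
}

#' The 162-pose snapshot grid
#'
#' In-plane angles theta in 0, 20, ..., 160 degrees (180/20 = 9 values)
#' crossed with axial angles phi in 0, 20, ..., 340 degrees (360/20 = 18
#' values): 162 poses, with (0, 0) the identity.
#'
#' @param step Angular step in degrees.
#' @return Tibble with columns `theta`, `phi`.
#' @export
snapshot_grid <- function(step = 20) {
  tidyr::expand_grid(theta = seq(0, 180 - step, by = step),
                     phi = seq(0, 360 - step, by = step))
}

apply_pose <- function(xyz_small, frame, theta, phi) {
  R1 <- rot_about_axis(frame$normal, theta)
  axis2 <- as.numeric(R1 %*% frame$axis_r)
  R2 <- rot_about_axis(axis2, phi)
  centered <- sweep(xyz_small, 2, frame$hinge)
  moved <- t(R2 %*% R1 %*% t(centered))
  sweep(moved, 2, frame$hinge, `+`)
}

#' Rigid-body hinge refinement over the snapshot grid
#'
#' Rotates the small proportion about the hinge: in the plane defined by
#' the hinge and the two proportion centroids (rotation about the plane
#' normal, theta), and about the hinge-to-small-centroid axis in its
#' current pose (phi). All 162 grid poses are evaluated with `energy_fn`
#' and the lowest-energy snapshot is returned; ties break toward the
#' smallest `(theta, phi)`. The large proportion and linker never move.
#'
#' @param model A `cpm_structure`.
#' @param frame A [split_by_hinge()] frame.
#' @param energy_fn Energy function over a `cpm_structure` (lower is
#'   better); default [surrogate_energy()].
#' @param step Grid step, degrees.
#' @return The refined `cpm_structure`, with attributes `trace` (tibble
#'   `theta`, `phi`, `energy`), `pose` (chosen angles), `n_snapshots`.
#' @export
hinge_refine <- function(model, frame, energy_fn = surrogate_energy,
                         step = 20) {
  grid <- snapshot_grid(step)
  ca <- filter(model, .data$atom == "CA")
  small_rows_all <- which(model$serial %in% frame$small_serials)
  xyz_all <- as.matrix(model[, c("x", "y", "z")])
  xyz_small <- xyz_all[small_rows_all, , drop = FALSE]
  energies <- numeric(nrow(grid))
  best <- NULL; best_e <- Inf
  for (g in seq_len(nrow(grid))) {
    posed <- apply_pose(xyz_small, frame, grid$theta[g], grid$phi[g])
    xyz_new <- xyz_all
    xyz_new[small_rows_all, ] <- posed
    cand <- model
    cand$x <- xyz_new[, 1]; cand$y <- xyz_new[, 2]; cand$z <- xyz_new[, 3]
    e <- energy_fn(cand)
    energies[g] <- e
    if (e < best_e - 1e-12) {
      best_e <- e; best <- cand
    }
  }
  trace <- mutate(grid, energy = energies)
  attr(best, "trace") <- trace
  attr(best, "pose") <- as.list(grid[which.min(energies), ])
  attr(best, "n_snapshots") <- nrow(grid)
  attr(best, "energy") <- best_e
  best
}

# ---- evaluation ----------------------------------------------------------

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Superposes matched coordinate sets with the optimal proper rotation
#' (SVD with determinant correction) and reports the RMSD of the
#' superposed pairs.
#'
#' @param A,B Numeric matrices (n x 3) of matched coordinates, n >= 3.
#' @return List: `rmsd`, `rotation` (3x3, applied to centered B),
#'   `translation`.
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3 || nrow(A) < 3) {
    abort("A and B must be matched n x 3 matrices with n >= 3")
  }
  ca_ <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca_); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rmsd = rmsd, rotation = R, translation = ca_ - as.numeric(R %*% cb))
}

#' Structural alignment ratio
#'
#' Number of aligned residues over the target's size, in percent.
#'
#' @param n_aligned Number of aligned residues.
#' @param target_size Residue count of the target protein.
#' @return Percentage.
#' @export
alignment_ratio <- function(n_aligned, target_size) {
  if (target_size <= 0) abort("target size must be positive")
  stopifnot(n_aligned >= 0, n_aligned <= target_size)
  100 * n_aligned / target_size
}

#' Evaluate a model against a reference structure
#'
#' Sequence-aligns the model and reference, superposes the aligned CA
#' pairs with [kabsch_rmsd()], and reports the Kabsch RMSD together with
#' the alignment ratio over the reference size.
#'
#' @param model,reference `cpm_structure`s.
#' @return One-row tibble: `n_aligned`, `alignment_ratio`, `rmsd`,
#'   `identity`.
#' @export
evaluate_model <- function(model, reference) {
  aln <- align_best(structure_sequence(model), structure_sequence(reference))
  cols <- tidy.seq_alignment(aln)
  mi <- cumsum(cols$a != "-"); ri <- cumsum(cols$b != "-")
  both <- cols$a != "-" & cols$b != "-"
  A <- ca_coords(reference)[ri[both], , drop = FALSE]
  B <- ca_coords(model)[mi[both], , drop = FALSE]
  fit <- kabsch_rmsd(A, B)
  tibble(n_aligned = sum(both),
         alignment_ratio = alignment_ratio(sum(both), n_residues(reference)),
         rmsd = fit$rmsd,
         identity = identity_percent(aln))
}
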