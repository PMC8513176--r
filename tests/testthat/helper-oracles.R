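# Independent oracles and tiny fixture builders used across the suite.

# One PDB ATOM/HETATM line in fixed-column format.
pdb_line <- function(eleno, atom, resname, resno, x, y, z, occ = 1,
                     chain = "A", rec = "ATOM", alt = " ", insert = " ") {
  name <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else atom
  sprintf("%-6s%5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          rec, eleno, name, alt, resname, chain, resno, insert, x, y, z, occ, 0)
}

# CA-only PDB text from residue names and coordinates.
pdb_text <- function(resnames, xyz, resno = seq_along(resnames), chain = "A") {
  lines <- vapply(seq_along(resnames), function(i) {
    pdb_line(i, "CA", resnames[i], resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
             chain = chain)
  }, character(1))
  paste(c(lines, "TER", "END"), collapse = "\n")
}

# Exhaustive-path global alignment score with affine gaps (a gap of
# length g costs open + g * ext; end gaps penalized). Independent of any
# dynamic-programming implementation: enumerates every alignment path.
brute_force_score <- function(a, b, matrix = "BLOSUM62", open = 10, ext = 0.5) {
  mat <- cirperm:::substitution_matrix(matrix)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > n && j > m) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= n) rec(i + 1, j, "X", sc - ext - if (last != "X") open else 0)
    if (j <= m) rec(i, j + 1, "Y", sc - ext - if (last != "Y") open else 0)
    if (i <= n && j <= m) rec(i + 1, j + 1, "M", sc + mat[ca[i], cb[j]])
  }
  rec(1, 1, "", 0)
  best
}

# Quaternion (Horn) closed-form best-rotation RMSD: an independent
# oracle for the SVD-based superposition.
quaternion_rmsd <- function(A, B) {
  A0 <- scale(A, scale = FALSE); B0 <- scale(B, scale = FALSE)
  M <- t(B0) %*% A0
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3], M[1, 2] + M[2, 1], M[1, 3] + M[3, 1],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1], -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[1, 3] + M[3, 1], M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A))
}

# Independent axis-angle rotation (Rodrigues formula written out on the
# vectors, not as a matrix product chain) for the hinge-grid oracle.
rodrigues <- function(v, axis, deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  v * cos(th) + c(
    k[2] * v[3] - k[3] * v[2],
    k[3] * v[1] - k[1] * v[3],
    k[1] * v[2] - k[2] * v[1]
  ) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Exhaustive oracle: minimum surrogate energy over the full snapshot
# grid, re-deriving every pose with rodrigues() instead of the package's
# rotation matrices.
oracle_grid_min <- function(model, frame, step = 20) {
  xyz <- ca_coords(model)
  small <- frame$small_serials
  best <- Inf
  for (theta in seq(0, 180 - step, by = step)) {
    axis2 <- rodrigues(frame$axis_r, frame$normal, theta)
    for (phi in seq(0, 360 - step, by = step)) {
      posed <- xyz
      for (i in small) {
        v <- xyz[i, ] - frame$hinge
        v <- rodrigues(v, frame$normal, theta)
        v <- rodrigues(v, axis2, phi)
        posed[i, ] <- frame$hinge + v
      }
      best <- min(best, surrogate_energy(posed))
    }
  }
  best
}

random_protein <- function(n, seed) {
  withr::with_seed(seed, paste(sample(aa_alphabet(), n, replace = TRUE),
                               collapse = ""))
}
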