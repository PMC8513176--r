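#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   slice bind_rows distinct left_join row_number n pull first last across
NULL

# 3-letter -> 1-letter map for the 20 standard amino acids, plus the
# common substituted residues that have an unambiguous parent.
.standard_aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.nonstandard_parent <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS", PTR = "TYR",
  SEP = "SER", TPO = "THR", HYP = "PRO", MLY = "LYS"
)

#' Amino-acid alphabet used throughout the package
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order.
#' Feature vectors, propensity tables and probability profiles are all
#' indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() unname(.standard_aa3[order(.standard_aa3)])

aa_three_to_one <- function(resname) {
  out <- unname(.standard_aa3[resname])
  if (anyNA(out)) {
    bad <- unique(resname[is.na(out)])
    abort(paste0("non-standard residue name(s): ", paste(bad, collapse = ", ")))
  }
  out
}

aa_one_to_three <- function(one) {
  map <- stats::setNames(names(.standard_aa3), unname(.standard_aa3))
  out <- unname(map[one])
  if (anyNA(out)) abort("unknown one-letter amino-acid code")
  out
}

new_structure <- function(df, chain_id = "A") {
  df <- as_tibble(df)
  structure(df, chain_id = chain_id,
            class = c("cpm_structure", class(tibble())))
}

#' @export
print.cpm_structure <- function(x, ...) {
  ca <- dplyr::filter(x, .data$atom == "CA")
  cat(sprintf("<cpm_structure> chain %s, %d residues, %d atoms\n",
              attr(x, "chain_id") %||% "A", nrow(ca), nrow(x)))
  NextMethod()
}

validate_structure <- function(s) {
  stopifnot(is.data.frame(s))
  need <- c("serial", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(s))) {
    abort(paste0("structure table needs columns: ", paste(need, collapse = ", ")))
  }
  ca <- s[s$atom == "CA", ]
  res <- unique(s$serial)
  if (!all(res %in% ca$serial)) {
    missing <- setdiff(res, ca$serial)
    abort(paste0("incomplete residue (no CA): serial ",
                 paste(missing, collapse = ", ")))
  }
  invisible(s)
}

#' Parse a single chain from PDB-format text
#'
#' Reads `ATOM` records of one chain into a tidy atom table (one row per
#' atom). Waters and other hetero records are dropped, except nonstandard
#' residues with an unambiguous parent amino acid (e.g. selenomethionine),
#' which are renamed to the parent. For alternate locations the
#' highest-occupancy conformer is kept. Residues lacking an alpha-carbon
#' are rejected.
#'
#' @param pdb Path to a PDB file, or a character string of PDB text
#'   (anything containing a newline is treated as text).
#' @param chain Chain identifier; defaults to the first chain present.
#' @return A `cpm_structure`: a tibble with columns `serial` (residue
#'   serial as numbered in the file), `resname`, `atom`, `x`, `y`, `z`,
#'   `eleno` (atom serial) and `occ`.
#' @export
parse_structure <- function(pdb, chain = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
  }
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- as_tibble(p$atom)
  if (is.null(chain)) chain <- at$chain[1]
  at <- filter(at, .data$chain == !!chain)
  # rescue mapped nonstandard residues recorded as HETATM, drop the rest
  at <- mutate(at, resid = dplyr::if_else(
    .data$resid %in% names(.nonstandard_parent),
    unname(.nonstandard_parent[.data$resid]), .data$resid))
  at <- filter(at, .data$type == "ATOM" | .data$resid %in% names(.standard_aa3))
  if (nrow(at) == 0) abort(paste0("empty chain: no ATOM records for chain ", chain))
  bad <- setdiff(unique(at$resid), names(.standard_aa3))
  if (length(bad) > 0) {
    abort(paste0("non-standard residue name(s): ", paste(bad, collapse = ", ")))
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # residue identity in file order (insertion codes distinguished here,
  # collapsed later by renumber())
  key <- paste(at$resno, at$insert, sep = "|")
  ridx <- match(key, unique(key))
  at$._res <- ridx
  # alternate locations: keep the highest-occupancy conformer per atom name
  at <- at |>
    group_by(.data$._res, .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$._res, .data$eleno)
  # insertion-code dialects collapse to a dense file-order numbering at
  # parse time so that residue serials stay unique
  serial <- if (any(at$insert != "")) at$._res else at$resno
  out <- tibble(
    serial = serial, resname = at$resid, atom = at$elety,
    x = at$x, y = at$y, z = at$z, eleno = at$eleno, occ = at$o
  )
  validate_structure(out)
  new_structure(out, chain_id = chain)
}

#' Write a structure to a PDB file
#'
#' Emits standard `ATOM` records (chain A, 8.3 coordinate fields) via
#' [bio3d::write.pdb()].
#'
#' @param s A `cpm_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  validate_structure(s)
  xyz <- as.numeric(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file, xyz = xyz, resno = s$serial, resid = s$resname,
    eleno = seq_len(nrow(s)), elety = s$atom, chain = "A",
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  invisible(file)
}

#' Renumber residues and atoms from 1
#'
#' Residue serials become `1..L` in current record order (insertion-code
#' dialects collapse here); atom serials become `1..M`. Coordinates are
#' untouched. Idempotent.
#'
#' @param s A `cpm_structure`.
#' @return The renumbered `cpm_structure`.
#' @export
renumber <- function(s) {
  validate_structure(s)
  key <- s$serial
  # file-order dense index over runs of equal serial
  r <- rle(key)
  new_serial <- rep(seq_along(r$values), r$lengths)
  out <- mutate(s, serial = new_serial, eleno = row_number())
  new_structure(out, chain_id = attr(s, "chain_id") %||% "A")
}

is_renumbered <- function(s) {
  ser <- unique(s$serial)
  identical(as.integer(ser), seq_along(ser))
}

#' Number of residues in a structure
#' @param s A `cpm_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) length(unique(s$serial))

#' One-letter amino-acid sequence of a structure
#' @param s A `cpm_structure`.
#' @return A single character string.
#' @export
structure_sequence <- function(s) {
  ca <- filter(s, .data$atom == "CA") |> arrange(match(.data$serial, unique(s$serial)))
  paste(aa_three_to_one(ca$resname), collapse = "")
}

#' Alpha-carbon coordinates of a structure
#'
#' @param s A `cpm_structure`.
#' @return A numeric matrix (residues x 3), rows in residue order.
#' @export
ca_coords <- function(s) {
  ca <- filter(s, .data$atom == "CA")
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$serial
  m
}

#' Build the pseudo-circularly-permuted template
#'
#' Moves the `n - 1` residues preceding the CP site from the top of the
#' record list to the bottom, then renumbers from 1: the output residue
#' order is `(n, ..., L, 1, ..., n - 1)` of the input. Coordinates are
#' unchanged; this is a pure record rotation. `n = 1` is the co-linear
#' (no-permutation) case.
#'
#' @param s A renumbered `cpm_structure`.
#' @param site CP site: 1-based residue serial that becomes the new
#'   N-terminus.
#' @return The permuted, renumbered `cpm_structure`.
#' @export
make_pseudo_cp_template <- function(s, site) {
  validate_structure(s)
  if (!is_renumbered(s)) abort("structure must be renumbered (serials 1..L)")
  L <- n_residues(s)
  if (!(is.numeric(site) && length(site) == 1 && site >= 1 && site <= L)) {
    abort(sprintf("invalid CP site: %s (structure has %d residues)",
                  paste(site, collapse = ","), L))
  }
  site <- as.integer(site)
  order_new <- c(seq(site, L), if (site > 1) seq(1, site - 1))
  out <- s[order(match(s$serial, order_new)), ]
  renumber(new_structure(out, chain_id = attr(s, "chain_id") %||% "A"))
}

#' Circularly permute an amino-acid sequence
#'
#' Returns `seq[n..L] + seq[1..n-1]` — the sequence-level equivalent of
#' the structural record rotation.
#'
#' @param seq Amino-acid string.
#' @param n CP site (1-based).
#' @return The rotated string.
#' @export
cp_sequence <- function(seq, n) {
  L <- nchar(seq)
  if (!(is.numeric(n) && length(n) == 1 && n >= 1 && n <= L)) {
    abort(sprintf("invalid CP site: %s (sequence length %d)",
                  paste(n, collapse = ","), L))
  }
  n <- as.integer(n)
  if (n == 1) return(seq)
  paste0(substr(seq, n, L), substr(seq, 1, n - 1))
}

#' Distance between the termini of a chain
#'
#' Euclidean distance (Angstrom) between the alpha-carbons of the first
#' and last residues.
#'
#' @param s A `cpm_structure` with at least 2 residues.
#' @return Distance in Angstrom.
#' @export
termini_distance <- function(s) {
  validate_structure(s)
  m <- ca_coords(s)
  if (nrow(m) < 2) abort("need at least 2 residues")
  sqrt(sum((m[1, ] - m[nrow(m), ])^2))
}
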