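# Global sequence alignment, the multi-aligner selection rule, and the
# identity / similarity metrics. Dynamic programming is delegated to
# Biostrings::pairwiseAlignment; the selection rule and metrics are ours.

#' Scoring schemes for global alignment
#'
#' Two schemes are shipped: `"nw"`, Needleman-Wunsch with affine gaps at
#' the EMBOSS needle defaults (BLOSUM62, open 10, extend 0.5), and
#' `"stretcher"`, a Stretcher-like scheme (BLOSUM62, open 12, extend 2).
#' Alignments from every configured scheme compete under
#' [select_alignment()].
#'
#' @param name `"nw"` or `"stretcher"`, or any name if `matrix`,
#'   `gap_open` and `gap_extend` are given explicitly.
#' @param matrix Substitution matrix name (a Biostrings data set).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(name = c("nw", "stretcher"), matrix = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  if (is.null(matrix)) {
    name <- match.arg(name)
    def <- switch(name,
      nw = list(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5),
      stretcher = list(matrix = "BLOSUM62", gap_open = 12, gap_extend = 2)
    )
    matrix <- def$matrix; gap_open <- def$gap_open; gap_extend <- def$gap_extend
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(name = name[1], matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Default set of competing scoring schemes
#' @return List of `scoring_scheme` objects.
#' @export
default_schemes <- function() list(scoring_scheme("nw"), scoring_scheme("stretcher"))

.matrix_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name) {
  if (!exists(name, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache)
}

check_protein <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1 || nchar(x) < 1) {
    abort(paste0(arg, " must be a nonempty string"))
  }
  ok <- strsplit(x, "")[[1]] %in% aa_alphabet()
  if (!all(ok)) {
    abort(sprintf("illegal character '%s' at position %d in %s",
                  substr(x, which(!ok)[1], which(!ok)[1]), which(!ok)[1], arg))
  }
  invisible(x)
}

new_alignment <- function(row_a, row_b, score, scheme) {
  stopifnot(nchar(row_a) == nchar(row_b))
  ca <- strsplit(row_a, "")[[1]]; cb <- strsplit(row_b, "")[[1]]
  structure(list(rows = c(row_a, row_b),
                 aligned_columns = sum(ca != "-" & cb != "-"),
                 score = score, scheme = scheme),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> score %.1f, %d aligned columns (%s)\n",
              x$score, x$aligned_columns, x$scheme$name %||% "?"))
  cat(x$rows[1], "\n", x$rows[2], "\n", sep = "")
  invisible(x)
}

#' Tidy an alignment into one row per column
#'
#' @param x A `seq_alignment`.
#' @param ... Unused.
#' @return Tibble with columns `column`, `a`, `b`, `match`.
#' @export
tidy.seq_alignment <- function(x, ...) {
  ca <- strsplit(x$rows[1], "")[[1]]; cb <- strsplit(x$rows[2], "")[[1]]
  tibble(column = seq_along(ca), a = ca, b = cb,
         match = ca == cb & ca != "-")
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (end gaps
#' penalized), computed by [Biostrings::pairwiseAlignment()]. A gap of
#' length `g` costs `gap_open + g * gap_extend`.
#'
#' @param a,b Protein sequences (strings over the 20-letter alphabet).
#' @param scheme A [scoring_scheme()].
#' @return A `seq_alignment` with fields `rows` (two gapped strings),
#'   `aligned_columns`, `score`, `scheme`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nw")) {
  check_protein(a, "a"); check_protein(b, "b")
  mat <- substitution_matrix(scheme$matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  new_alignment(as.character(Biostrings::alignedPattern(pa)),
                as.character(Biostrings::alignedSubject(pa)),
                Biostrings::score(pa), scheme)
}

#' Pick the best alignment among candidates
#'
#' The candidate with the largest number of aligned residue pairs wins;
#' ties break by higher score, then by first occurrence.
#'
#' @param cands Nonempty list of `seq_alignment` objects.
#' @return The selected `seq_alignment`.
#' @export
select_alignment <- function(cands) {
  if (length(cands) == 0) abort("no candidate alignments")
  cols <- vapply(cands, function(x) x$aligned_columns, numeric(1))
  sc <- vapply(cands, function(x) x$score, numeric(1))
  best <- order(-cols, -sc)[1]
  cands[[best]]
}

#' Align two sequences under every configured scheme and keep the best
#'
#' @param a,b Protein sequences.
#' @param schemes List of [scoring_scheme()]s.
#' @return The selected `seq_alignment`.
#' @export
align_best <- function(a, b, schemes = default_schemes()) {
  select_alignment(lapply(schemes, function(sch) global_align(a, b, sch)))
}

#' Percent sequence similarity of an alignment
#'
#' Fraction of alignment columns whose residue pair scores positively in
#' the substitution matrix (BLOSUM45 by default, matching how designed
#' linkers are compared with native ones); gap columns are never similar.
#' The denominator is the alignment length.
#'
#' @param aln A `seq_alignment`.
#' @param matrix Substitution matrix name.
#' @return Percentage in `[0, 100]`.
#' @export
similarity_percent <- function(aln, matrix = "BLOSUM45") {
  mat <- substitution_matrix(matrix)
  cols <- tidy.seq_alignment(aln)
  both <- cols$a != "-" & cols$b != "-"
  if (nrow(cols) == 0) return(0)
  sim <- both & mat[cbind(
    match(cols$a, rownames(mat)), match(cols$b, colnames(mat)))] > 0
  sim[is.na(sim)] <- FALSE
  100 * sum(sim) / nrow(cols)
}

#' Percent sequence identity of an alignment
#'
#' Identical columns over alignment length.
#'
#' @param aln A `seq_alignment`.
#' @return Percentage in `[0, 100]`.
#' @export
identity_percent <- function(aln) {
  cols <- tidy.seq_alignment(aln)
  if (nrow(cols) == 0) return(0)
  100 * sum(cols$match) / nrow(cols)
}

#' BLOSUM45 similarity between two sequences
#'
#' Convenience wrapper: globally aligns `a` and `b`, then scores
#' [similarity_percent()] with BLOSUM45.
#'
#' @param a,b Protein sequences.
#' @return Percentage in `[0, 100]`.
#' @export
sequence_similarity <- function(a, b) {
  similarity_percent(global_align(a, b), "BLOSUM45")
}

#' Sequence identity between two sequences
#' @param a,b Protein sequences.
#' @return Percentage in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) identity_percent(global_align(a, b))
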