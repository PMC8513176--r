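# Inverse-square-distance structural features, the three-class bootstrap
# vote ensemble (decision trees + small neural nets), and restoration of
# class probabilities to per-amino-acid probabilities.

.class_levels <- c("hydrophilic", "hydrophobic", "neutral")

#' Three-class amino-acid scheme
#'
#' Partition of the 20 amino acids into hydrophilic, hydrophobic and
#' neutral classes (Kyte-Doolittle-guided defaults), optionally carrying
#' per-class amino-acid compositions `p(A|C)` estimated from a set of
#' known linkers.
#'
#' @param hydrophobic,hydrophilic,neutral Character vectors of one-letter
#'   codes; together they must cover the alphabet exactly once.
#' @return A `class_scheme` list with fields `classes` (named vector
#'   amino acid -> class) and `composition` (NULL until estimated).
#' @export
class_scheme <- function(
    hydrophobic = c("A", "V", "L", "I", "M", "F", "C", "W"),
    hydrophilic = c("R", "K", "D", "E", "N", "Q", "H"),
    neutral = c("G", "P", "S", "T", "Y")) {
  all <- c(hydrophobic, hydrophilic, neutral)
  if (!setequal(all, aa_alphabet()) || anyDuplicated(all)) {
    abort("classes must partition the 20 standard amino acids")
  }
  classes <- c(stats::setNames(rep("hydrophobic", length(hydrophobic)), hydrophobic),
               stats::setNames(rep("hydrophilic", length(hydrophilic)), hydrophilic),
               stats::setNames(rep("neutral", length(neutral)), neutral))
  structure(list(classes = classes[aa_alphabet()], composition = NULL),
            class = "class_scheme")
}

#' Class label of each residue of a sequence
#' @param seq Amino-acid string.
#' @param scheme A [class_scheme()].
#' @return Character vector of class labels.
#' @export
aa_classes <- function(seq, scheme = class_scheme()) {
  unname(scheme$classes[strsplit(seq, "")[[1]]])
}

#' Estimate per-class amino-acid compositions from known linkers
#'
#' Counts amino acids in the supplied linker sequences within each class,
#' with Laplace smoothing (+1 per amino acid) so no composition is zero,
#' and stores the normalized `p(A|C)` in the scheme.
#'
#' @param scheme A [class_scheme()].
#' @param linkers Character vector of linker sequences.
#' @param laplace Smoothing pseudo-count.
#' @return The scheme with a `composition` matrix (3 classes x 20 amino
#'   acids; rows sum to 1 over the class's members).
#' @export
estimate_composition <- function(scheme, linkers, laplace = 1) {
  aa <- unlist(strsplit(paste(linkers, collapse = ""), ""))
  counts <- table(factor(aa, levels = aa_alphabet())) + laplace
  comp <- matrix(0, nrow = 3, ncol = 20,
                 dimnames = list(.class_levels, aa_alphabet()))
  for (cl in .class_levels) {
    members <- names(scheme$classes)[scheme$classes == cl]
    comp[cl, members] <- as.numeric(counts[members]) / sum(counts[members])
  }
  scheme$composition <- comp
  scheme
}

#' Structural feature vector of a residue
#'
#' For the residue of interest `i`, sums `1 / d^2` over the surrounding
#' residues of each amino-acid type whose alpha-carbon lies within
#' `d_r` Angstrom of `i`'s. The residue itself and its five sequence
#' neighbors on either side are excluded — a linker to be designed has
#' unknown local sequence, so the same window is discarded for known
#' linkers at training time.
#'
#' @param s A `cpm_structure` (CA coordinates are used).
#' @param i Residue serial of interest.
#' @param d_r Inclusion radius, Angstrom.
#' @return Named numeric vector of 20 non-negative feature values in
#'   [aa_alphabet()] order, with attribute `d_r`.
#' @export
compute_features <- function(s, i, d_r = 20) {
  validate_structure(s)
  ca <- filter(s, .data$atom == "CA")
  if (!i %in% ca$serial) abort(sprintf("residue %s has no CA", i))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  pos <- match(i, ca$serial)
  d <- sqrt(rowSums(sweep(xyz, 2, xyz[pos, ], `-`)^2))
  sep <- abs(ca$serial - i)
  keep <- sep > 5 & d <= d_r
  f <- stats::setNames(numeric(20), aa_alphabet())
  if (any(keep)) {
    contrib <- tapply(1 / d[keep]^2, aa_three_to_one(ca$resname[keep]), sum)
    f[names(contrib)] <- contrib
  }
  attr(f, "d_r") <- d_r
  f
}

#' Feature table for several residues
#'
#' @param s A `cpm_structure`.
#' @param serials Residue serials of interest.
#' @param d_r Inclusion radius, Angstrom.
#' @return Tibble: `serial` plus the 20 feature columns.
#' @export
compute_features_tbl <- function(s, serials, d_r = 20) {
  rows <- purrr::map(serials, function(i) {
    f <- compute_features(s, i, d_r)
    tibble::as_tibble_row(c(serial = i, as.list(f)))
  })
  bind_rows(rows)
}

feature_matrix <- function(features) {
  m <- as.matrix(as.data.frame(features)[, aa_alphabet(), drop = FALSE])
  colnames(m) <- aa_alphabet()
  m
}

#' Train the bootstrap vote ensemble
#'
#' Trains 250 decision-tree minors (depth-capped) and 50 single-hidden-
#' layer neural-net minors, each on an independent bootstrap resample of
#' the cases (same size as the input, with replacement). The ensemble
#' predicts by vote: class probabilities are the vote fractions.
#'
#' @param features Data frame with the 20 feature columns (names =
#'   [aa_alphabet()]), one row per case.
#' @param labels Class label per case (`hydrophilic`, `hydrophobic`,
#'   `neutral`).
#' @param scheme A [class_scheme()], ideally with compositions estimated
#'   (see [estimate_composition()]); stored in the predictor.
#' @param seed Integer seed; training is deterministic given it.
#' @param n_tree,n_net Minor counts.
#' @param tree_maxdepth,net_size,net_maxit Minor-model hyperparameters.
#' @return A `linker_ensemble` object.
#' @export
train_ensemble <- function(features, labels, scheme = class_scheme(),
                           seed = 1, n_tree = 250, n_net = 50,
                           tree_maxdepth = 8, net_size = 16, net_maxit = 120) {
  X <- feature_matrix(features)
  if (nrow(X) == 0) abort("empty training set")
  y <- factor(labels, levels = .class_levels)
  if (anyNA(y)) abort("labels must be hydrophilic/hydrophobic/neutral")
  constant <- length(unique(y)) < 2
  if (constant) warn("single-class training set: predictor is constant")
  df <- as.data.frame(X)
  df$.y <- y
  minors <- withr::with_seed(seed, {
    boots <- purrr::map(seq_len(n_tree + n_net),
                        ~ sample.int(nrow(df), replace = TRUE))
    trees <- purrr::map(boots[seq_len(n_tree)], function(idx) {
      d <- df[idx, ]
      d$.y <- droplevels(d$.y)
      if (nlevels(d$.y) < 2) return(as.character(d$.y[1]))
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = tree_maxdepth, cp = 0.001,
                     minsplit = 4, xval = 0))
    })
    nets <- purrr::map(boots[n_tree + seq_len(n_net)], function(idx) {
      d <- df[idx, ]
      d$.y <- droplevels(d$.y)
      if (nlevels(d$.y) < 2) return(as.character(d$.y[1]))
      nnet::nnet(.y ~ ., data = d, size = net_size, maxit = net_maxit,
                 decay = 0.01, trace = FALSE, MaxNWts = 5000)
    })
    list(trees = trees, nets = nets)
  })
  structure(list(trees = minors$trees, nets = minors$nets, scheme = scheme,
                 levels = .class_levels, seed = seed,
                 n_minor = n_tree + n_net,
                 feature_names = aa_alphabet()),
            class = "linker_ensemble")
}

minor_vote <- function(minor, X) {
  if (is.character(minor)) return(rep(minor, nrow(X)))
  df <- as.data.frame(X)
  if (inherits(minor, "rpart")) {
    as.character(predict(minor, df, type = "class"))
  } else {
    as.character(predict(minor, df, type = "class"))
  }
}

#' Predict class probabilities by ensemble vote
#'
#' Each minor model casts one vote per case; the returned probabilities
#' are the vote fractions (they sum to 1 by construction).
#'
#' @param object A `linker_ensemble`.
#' @param features Data frame (or named vector from [compute_features()])
#'   of feature values.
#' @return Tibble with columns `hydrophilic`, `hydrophobic`, `neutral`,
#'   one row per case.
#' @export
predict_class_probs <- function(object, features) {
  if (is.numeric(features) && !is.data.frame(features)) {
    features <- tibble::as_tibble_row(as.list(features))
  }
  X <- feature_matrix(features)
  votes <- matrix(0, nrow = nrow(X), ncol = 3,
                  dimnames = list(NULL, .class_levels))
  for (minor in c(object$trees, object$nets)) {
    v <- minor_vote(minor, X)
    for (cl in .class_levels) votes[, cl] <- votes[, cl] + (v == cl)
  }
  as_tibble(votes / object$n_minor)
}

#' @export
print.linker_ensemble <- function(x, ...) {
  cat(sprintf("<linker_ensemble> %d tree + %d net minors (seed %d)\n",
              length(x$trees), length(x$nets), x$seed))
  invisible(x)
}

#' Glance at a trained ensemble
#' @param x A `linker_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with minor counts and seed.
#' @export
glance.linker_ensemble <- function(x, ...) {
  tibble(n_tree = length(x$trees), n_net = length(x$nets),
         n_minor = x$n_minor, seed = x$seed,
         has_composition = !is.null(x$scheme$composition))
}

#' Tidy a trained ensemble
#' @param x A `linker_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per minor model.
#' @export
tidy.linker_ensemble <- function(x, ...) {
  tibble(minor = seq_len(x$n_minor),
         kind = rep(c("tree", "net"), c(length(x$trees), length(x$nets))),
         constant = vapply(c(x$trees, x$nets), is.character, logical(1)))
}

#' Restore class probabilities to amino-acid probabilities
#'
#' `pe(A) = pe(C) * p(A|C)`: the predicted probability of amino acid `A`
#' is the probability of its class times `A`'s proportion within that
#' class. If each class probability vector sums to 1 and each class
#' composition sums to 1, the result sums to 1.
#'
#' @param class_probs Numeric vector of 3 class probabilities (named, or
#'   in hydrophilic/hydrophobic/neutral order), or a data frame of such
#'   rows as from [predict_class_probs()].
#' @param scheme A [class_scheme()] with estimated `composition`.
#' @return Named numeric 20-vector (or matrix, one row per input row) of
#'   amino-acid probabilities in [aa_alphabet()] order.
#' @export
restore_aa_probs <- function(class_probs, scheme) {
  if (is.null(scheme$composition)) {
    abort("scheme has no composition; call estimate_composition() first")
  }
  comp <- scheme$composition
  one_row <- function(p) {
    p <- unlist(p)
    if (is.null(names(p))) names(p) <- .class_levels
    if (!setequal(names(p), .class_levels)) abort("class probabilities must be named by class")
    if (abs(sum(p) - 1) > 1e-6) abort("class probabilities must sum to 1")
    cls <- unname(scheme$classes[aa_alphabet()])
    pe <- unname(p[cls]) * comp[cbind(cls, aa_alphabet())]
    stats::setNames(pe, aa_alphabet())
  }
  if (is.data.frame(class_probs)) {
    out <- t(apply(class_probs, 1, one_row))
    colnames(out) <- aa_alphabet()
    out
  } else one_row(class_probs)
}

#' Per-position amino-acid probability profile of a linker
#'
#' Runs the ensemble on the feature vector of every linker position of a
#' coarse model, then restores the three class probabilities to 20
#' amino-acid probabilities.
#'
#' @param model A `cpm_structure` (coarse model carrying a temporary
#'   linker).
#' @param serials Residue serials of the linker positions in `model`.
#' @param predictor A `linker_ensemble` whose scheme has compositions.
#' @param d_r Feature radius, Angstrom.
#' @return An `aa_profile`: matrix (positions x 20) of probabilities,
#'   rows summing to 1.
#' @export
aa_probability_profile <- function(model, serials, predictor, d_r = 20) {
  feats <- compute_features_tbl(model, serials, d_r)
  probs <- predict_class_probs(predictor, feats)
  prof <- restore_aa_probs(probs, predictor$scheme)
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1,
                                         dimnames = list(NULL, aa_alphabet()))
  rownames(prof) <- as.character(seq_len(nrow(prof)))
  structure(prof, class = c("aa_profile", "matrix", "array"))
}

#' Tidy an amino-acid probability profile
#' @param x An `aa_profile`.
#' @param ... Unused.
#' @return Tibble with columns `position`, `aa`, `probability`.
#' @export
tidy.aa_profile <- function(x, ...) {
  m <- unclass(x)
  tibble(position = rep(seq_len(nrow(m)), times = ncol(m)),
         aa = rep(colnames(m), each = nrow(m)),
         probability = as.vector(m))
}
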