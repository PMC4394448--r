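#' Build a feature space from training records
#'
#' The feature space fixes the vector layout used for training and for every
#' later encoding: 20 amino-acid composition fractions (alphabetical order),
#' followed by one binary indicator per functional-domain identifier seen in
#' the training records (lexicographic registry), optionally followed by the
#' 400 dipeptide fractions. The registry is built from the whole training set
#' (both classes) and then frozen: domains first seen at scan time contribute
#' nothing.
#'
#' @param training_records a non-empty [proteome()].
#' @param include_dipeptides add the 400-element dipeptide block (off by
#'   default: it does not usually help and triples the dimension).
#' @return object of class `feature_space`.
#' @export
feature_space <- function(training_records, include_dipeptides = FALSE) {
  stopifnot(inherits(training_records, "proteome"))
  if (nrow(training_records) == 0) {
    stop("cannot build a feature space from an empty collection", call. = FALSE)
  }
  registry <- sort(unique(unlist(training_records$domains, use.names = FALSE)))
  if (is.null(registry)) registry <- character(0)
  structure(list(amino_acids = AA_ALPHABET, domains = registry,
                 include_dipeptides = isTRUE(include_dipeptides)),
            class = "feature_space")
}

#' Feature-space dimension
#' @param space a [feature_space()].
#' @return integer: `20 + |registry|` (+400 with dipeptides).
#' @export
space_dimension <- function(space) {
  stopifnot(inherits(space, "feature_space"))
  20L + length(space$domains) + if (space$include_dipeptides) 400L else 0L
}

#' Feature names in vector order
#' @param space a [feature_space()].
#' @return character vector of length [space_dimension()].
#' @export
space_feature_names <- function(space) {
  nm <- c(paste0("aa_", space$amino_acids),
          paste0("dom_", space$domains, recycle0 = TRUE))
  if (space$include_dipeptides) {
    dp <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
    nm <- c(nm, paste0("dp_", dp))
  }
  nm
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf(
    "feature space: 20 amino acids + %d domain indicators%s (dimension %d)\n",
    length(x$domains),
    if (x$include_dipeptides) " + 400 dipeptides" else "",
    space_dimension(x)))
  invisible(x)
}

#' Amino-acid composition of a sequence
#'
#' Occurrence of each of the 20 amino acids divided by the total number of
#' residues; entries sum to 1.
#'
#' @param sequence sanitized sequence, length >= 1.
#' @return named 20-vector.
#' @export
aa_composition <- function(sequence) {
  sequence <- as.character(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  f <- factor(ch, levels = AA_ALPHABET)
  if (anyNA(f)) {
    stop("non-standard residue(s): ",
         paste(unique(ch[is.na(f)]), collapse = ", "), call. = FALSE)
  }
  counts <- tabulate(f, nbins = 20L)
  stats::setNames(counts / length(ch), AA_ALPHABET)
}

#' Dipeptide composition of a sequence
#'
#' Overlapping residue-pair counts divided by (length - 1); the 400 entries
#' sum to 1. Kept available but excluded from the default feature space.
#'
#' @param sequence sanitized sequence, length >= 2.
#' @return named 400-vector (names `"AA"`, `"AC"`, ... row-major by first
#'   residue).
#' @export
dipeptide_composition <- function(sequence) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (n < 2) stop("dipeptide composition needs length >= 2", call. = FALSE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pairs <- paste0(ch[-n], ch[-1])
  lev <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  f <- factor(pairs, levels = lev)
  if (anyNA(f)) stop("non-standard residue(s) in sequence", call. = FALSE)
  stats::setNames(tabulate(f, nbins = 400L) / (n - 1L), lev)
}

#' Encode one protein in a frozen feature space
#'
#' Concatenates the amino-acid composition, the binary domain-presence block
#' in registry order, and (if enabled) the dipeptide block. Domains not in the
#' registry are ignored.
#'
#' @param record one-row [proteome()] (or a list with `sequence` and
#'   `domains`).
#' @param space a [feature_space()].
#' @return named numeric vector of length [space_dimension()].
#' @export
encode_protein <- function(record, space) {
  stopifnot(inherits(space, "feature_space"))
  if (inherits(record, "proteome")) {
    stopifnot(nrow(record) == 1)
    record <- list(sequence = record$sequence[[1]],
                   domains = record$domains[[1]])
  }
  v <- aa_composition(record$sequence)
  dom <- as.numeric(space$domains %in% record$domains)
  v <- c(v, dom)
  if (space$include_dipeptides) v <- c(v, dipeptide_composition(record$sequence))
  stats::setNames(v, space_feature_names(space))
}

#' Encode a proteome as a feature matrix
#'
#' @param records a [proteome()].
#' @param space a [feature_space()].
#' @return numeric matrix, one row per record (rownames = accessions).
#' @export
encode_proteome <- function(records, space) {
  stopifnot(inherits(records, "proteome"), inherits(space, "feature_space"))
  m <- t(vapply(seq_len(nrow(records)), function(i) {
    encode_protein(list(sequence = records$sequence[[i]],
                        domains = records$domains[[i]]), space)
  }, numeric(space_dimension(space))))
  rownames(m) <- records$accession
  colnames(m) <- space_feature_names(space)
  m
}

# F-score of each column of x for binary labels y (1 = positive class):
#   F(i) = [(m+ - m)^2 + (m- - m)^2] / (s+^2 + s-^2)
# with class sample variances. Degenerate cases: 0/0 -> 0, >0/0 -> Inf
# (a within-class-constant feature that separates the classes perfectly).
f_score_values <- function(x, y) {
  y <- as.integer(y)
  pos <- x[y == 1L, , drop = FALSE]
  neg <- x[y == 0L, , drop = FALSE]
  if (nrow(pos) < 2 || nrow(neg) < 2) {
    stop("F-score needs at least 2 samples in each class", call. = FALSE)
  }
  m <- colMeans(x)
  mp <- colMeans(pos)
  mn <- colMeans(neg)
  num <- (mp - m)^2 + (mn - m)^2
  den <- apply(pos, 2, var) + apply(neg, 2, var)
  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  unname(f)
}

#' Rank features by F-score
#'
#' For each feature the F-score contrasts the class means against the pooled
#' mean, normalized by the sum of the within-class variances. Features are
#' ranked by descending score; ties break by ascending feature index so the
#' ranking is deterministic.
#'
#' @param dataset a [labeled_dataset()] (needs >= 2 samples per class).
#' @return data frame with columns `feature_index`, `feature`, `f_score`,
#'   `rank`, sorted by rank.
#' @export
f_score_rank <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  f <- f_score_values(dataset$x, dataset$y)
  ord <- order(-f, seq_along(f))
  out <- data.frame(
    feature_index = ord,
    feature = colnames(dataset$x)[ord],
    f_score = f[ord],
    rank = seq_along(f),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a labeled dataset as a dense TSV
#'
#' Columns: accession, label, then one column per feature.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(accession = dataset$accession, label = dataset$y,
                   dataset$x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled dataset in the sparse `label index:value` dialect
#'
#' The plain-text training-file format used by common SVM tools: one sample
#' per line, label first, then `index:value` pairs (1-based) for the non-zero
#' features. A sidecar of accessions can be written with
#' [write_feature_tsv()] or kept from the dataset object.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  lines <- vapply(seq_along(dataset$y), function(i) {
    v <- dataset$x[i, ]
    nz <- which(v != 0)
    paste(c(dataset$y[i], sprintf("%d:%.10g", nz, v[nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse `label index:value` file
#'
#' @param path input path.
#' @param dimension number of features (columns) of the dense result.
#' @return list with `x` (dense matrix) and `y` (integer labels).
#' @export
read_svmlight <- function(path, dimension) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  y <- integer(length(lines))
  x <- matrix(0, nrow = length(lines), ncol = dimension)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    y[i] <- as.integer(tok[1])
    if (length(tok) > 1) {
      kv <- strsplit(tok[-1], ":", fixed = TRUE)
      idx <- vapply(kv, function(p) as.integer(p[1]), integer(1))
      val <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
      x[i, idx] <- val
    }
  }
  list(x = x, y = y)
}
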