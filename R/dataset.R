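#' Negative-sampling configuration
#'
#' @param n_negatives number of negatives to draw (default: match the number
#'   of positives at assembly time, the balanced design).
#' @param identity_threshold identity fraction above which a background
#'   protein is considered a positive homolog and excluded.
#' @param upsample_factor integer 1..5; how many times each positive is
#'   duplicated (1 = no upsampling).
#' @param n_repeats number of negative re-sampling repeats for robustness
#'   experiments.
#' @param seed master RNG seed.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(n_negatives = NULL, identity_threshold = 0.70,
                            upsample_factor = 1L, n_repeats = 1L, seed = 1L) {
  upsample_factor <- as.integer(upsample_factor)
  if (upsample_factor < 1L) stop("`upsample_factor` must be >= 1", call. = FALSE)
  if (!is.null(n_negatives) && n_negatives < 1) {
    stop("`n_negatives` must be >= 1", call. = FALSE)
  }
  structure(list(n_negatives = n_negatives,
                 identity_threshold = identity_threshold,
                 upsample_factor = upsample_factor,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Eligible negative pool
#'
#' Background proteins that satisfy both negative-set constraints: (i) not in
#' the positive set, and (ii) not more than `identity_threshold` identical to
#' any positive (global-alignment identity, [cross_filter()]).
#'
#' @param proteome background [proteome()].
#' @param positives positive [proteome()].
#' @param config a [sampling_config()].
#' @return [proteome()] of eligible negatives.
#' @export
eligible_negative_pool <- function(proteome, positives,
                                   config = sampling_config()) {
  stopifnot(inherits(proteome, "proteome"), inherits(positives, "proteome"))
  pool <- proteome[!(proteome$accession %in% positives$accession), ,
                   drop = FALSE]
  rownames(pool) <- NULL
  cross_filter(pool, positives,
               identity_config(threshold = config$identity_threshold))
}

#' Sample a negative training set
#'
#' Uniform random sample without replacement from the eligible pool
#' ([eligible_negative_pool()]), seeded and returned sorted by accession so a
#' given seed always yields the same set.
#'
#' @param proteome background [proteome()] (or a precomputed eligible pool —
#'   pass `pool` to skip the homology filter).
#' @param positives positive [proteome()].
#' @param config a [sampling_config()]; `n_negatives = NULL` draws as many
#'   negatives as there are positives.
#' @param pool optional precomputed eligible pool (skips re-filtering, useful
#'   for repeated sampling).
#' @return [proteome()] of sampled negatives.
#' @export
sample_negatives <- function(proteome, positives, config = sampling_config(),
                             pool = NULL) {
  if (is.null(pool)) pool <- eligible_negative_pool(proteome, positives, config)
  n <- config$n_negatives
  if (is.null(n)) n <- nrow(positives) * config$upsample_factor
  if (nrow(pool) < n) {
    stop(sprintf("only %d eligible negative(s) available, %d requested",
                 nrow(pool), n), call. = FALSE)
  }
  idx <- with_rng(config$seed, sample.int(nrow(pool), n))
  out <- pool[sort(idx), , drop = FALSE]
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upsample the positive set by an integer factor
#'
#' Each positive is duplicated `factor` times; replicates carry suffixed
#' accessions (`ACC#2`, `ACC#3`, ...) so their common source protein remains
#' recoverable (used to keep replicates in the same cross-validation fold).
#' `factor = 1` is the identity.
#'
#' @param positives a [proteome()].
#' @param factor integer >= 1.
#' @return [proteome()] with `nrow(positives) * factor` records.
#' @export
upsample_positives <- function(positives, factor) {
  stopifnot(inherits(positives, "proteome"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(positives)
  acc <- unlist(lapply(positives$accession, function(a) {
    c(a, paste0(a, "#", seq.int(2L, factor)))
  }))
  idx <- rep(seq_len(nrow(positives)), each = factor)
  proteome(accession = acc, sequence = positives$sequence[idx],
           domains = positives$domains[idx], sanitize = FALSE)
}

# Source accession of a possibly replicate-suffixed accession.
source_accession <- function(accession) sub("#[0-9]+$", "", accession)

#' Assemble a labeled training dataset
#'
#' Encodes positives and negatives in a common feature space; labels are 1 for
#' interacting, 0 for non-interacting. Ordering is stable: positives first,
#' then negatives, each sorted by accession. The two classes must be disjoint
#' by source accession.
#'
#' @param positives,negatives [proteome()] collections.
#' @param space a [feature_space()] (default: built from the union of both,
#'   the convention for the frozen training registry).
#' @param seed seed recorded as dataset provenance.
#' @return object of class `labeled_dataset`: list with feature matrix `x`,
#'   integer labels `y`, `accession`, replicate `group` (source accession),
#'   `space` and `seed`.
#' @export
assemble_dataset <- function(positives, negatives, space = NULL, seed = NA) {
  stopifnot(inherits(positives, "proteome"), inherits(negatives, "proteome"))
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  overlap <- intersect(source_accession(positives$accession),
                       source_accession(negatives$accession))
  if (length(overlap)) {
    stop("accession(s) present in both classes: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  pos <- positives[order(positives$accession), , drop = FALSE]
  neg <- negatives[order(negatives$accession), , drop = FALSE]
  all <- rbind(pos, neg)
  class(all) <- c("proteome", "data.frame")
  if (is.null(space)) space <- feature_space(all)
  x <- encode_proteome(all, space)
  labeled_dataset(x = x, y = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
                  accession = all$accession, space = space, seed = seed)
}

#' Labeled dataset constructor
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y integer labels, 1 = interacting, 0 = non-interacting.
#' @param accession sample identifiers (replicates may carry `#k` suffixes).
#' @param space the [feature_space()] used for encoding (optional).
#' @param seed provenance seed.
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, y, accession = NULL, space = NULL, seed = NA) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (is.null(accession)) accession <- sprintf("S%04d", seq_along(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  rownames(x) <- as.character(accession)
  structure(list(x = x, y = y, accession = as.character(accession),
                 group = source_accession(as.character(accession)),
                 space = space, seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d samples (%d positive / %d negative), %d features\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0), ncol(x$x)))
  invisible(x)
}

# Row subset of a labeled dataset (keeps space/provenance).
dataset_subset <- function(dataset, idx) {
  labeled_dataset(dataset$x[idx, , drop = FALSE], dataset$y[idx],
                  dataset$accession[idx], dataset$space, dataset$seed)
}
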