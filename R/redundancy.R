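#' Identity / alignment configuration
#'
#' Controls redundancy removal. `threshold` is the identity fraction above
#' which (strictly) two sequences are considered redundant; the default 0.70
#' is the conventional cutoff for removing close homologs from training sets.
#' Alignment scoring is a plain (linear-gap) global alignment.
#'
#' @param threshold identity fraction in (0, 1].
#' @param match,mismatch,gap integer alignment scores.
#' @return object of class `identity_config`.
#' @export
identity_config <- function(threshold = 0.70, match = 1L, mismatch = -1L,
                            gap = -1L) {
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  structure(list(threshold = threshold, match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap)),
            class = "identity_config")
}

#' Pairwise global-alignment sequence identity
#'
#' Identity of an optimal global (Needleman-Wunsch) alignment, defined as the
#' number of identical aligned residue pairs divided by the length of the
#' shorter sequence — the convention used by greedy clustering tools such as
#' CD-HIT. Among equal-score optimal alignments the one with the most
#' identities is used, making the value well defined and symmetric.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @param config an [identity_config()] supplying alignment scores.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACDE", "ACDE") # 1
#' pairwise_identity("AAAA", "AAAT") # 0.75
#' @export
pairwise_identity <- function(a, b, config = identity_config()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (identical(a, b)) return(1.0)
  res <- .nw_align(a, b, config$match, config$mismatch, config$gap)
  res[2] / min(nchar(a), nchar(b))
}

#' Remove redundant sequences within a collection
#'
#' Greedy incremental clustering in the style of CD-HIT: records are sorted by
#' decreasing length (ties by accession), each unclaimed record becomes a
#' cluster representative and claims every remaining record with identity
#' strictly above `config$threshold`. Representatives are returned in that
#' deterministic order. Idempotent.
#'
#' @param records a [proteome()].
#' @param config an [identity_config()].
#' @return the non-redundant [proteome()].
#' @export
dedupe_within <- function(records, config = identity_config()) {
  stopifnot(inherits(records, "proteome"))
  n <- nrow(records)
  if (n <= 1) return(records)
  ord <- order(-nchar(records$sequence), records$accession)
  x <- records[ord, , drop = FALSE]
  claimed <- rep(FALSE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (claimed[i]) next
    keep[i] <- TRUE
    if (i == n) break
    for (j in seq.int(i + 1L, n)) {
      if (claimed[j]) next
      if (pairwise_identity(x$sequence[i], x$sequence[j], config) >
          config$threshold) {
        claimed[j] <- TRUE
      }
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates against a reference set by identity
#'
#' Keeps the candidates whose identity to every reference sequence is at or
#' below `config$threshold` (removal requires *more than* the threshold),
#' mirroring two-set filtering tools such as CD-HIT-2D. Candidate order is
#' preserved.
#'
#' @param candidates,reference [proteome()] collections.
#' @param config an [identity_config()].
#' @return the filtered candidates [proteome()].
#' @export
cross_filter <- function(candidates, reference, config = identity_config()) {
  stopifnot(inherits(candidates, "proteome"))
  if (nrow(candidates) == 0 || is.null(reference) || nrow(reference) == 0) {
    return(candidates)
  }
  keep <- vapply(candidates$sequence, function(s) {
    for (r in reference$sequence) {
      if (pairwise_identity(s, r, config) > config$threshold) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
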