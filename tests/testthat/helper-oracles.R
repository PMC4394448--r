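# Independent oracles and small fixture builders shared across tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len, letters = AA20) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

make_proteome <- function(...) {
  seqs <- c(...)
  proteome(accession = names(seqs), sequence = unname(seqs))
}

# Exhaustive global-alignment oracle: walks every monotone alignment path,
# keeps the lexicographic best (score, identities). Exponential; for short
# sequences only.
oracle_alignment <- function(a, b, match = 1L, mismatch = -1L, gap = -1L) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  best_score <- -Inf
  best_id <- -Inf
  rec <- function(i, j, score, id) {
    if (i > na && j > nb) {
      if (score > best_score || (score == best_score && id > best_id)) {
        best_score <<- score
        best_id <<- id
      }
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) {
      eq <- A[i] == B[j]
      rec(i + 1L, j + 1L, score + if (eq) match else mismatch, id + eq)
    }
    if (i <= na) rec(i + 1L, j, score + gap, id)
    if (j <= nb) rec(i, j + 1L, score + gap, id)
  }
  rec(1L, 1L, 0L, 0L)
  c(score = best_score, identities = best_id)
}

oracle_identity <- function(a, b) {
  unname(oracle_alignment(a, b)["identities"]) / min(nchar(a), nchar(b))
}

# Two-pass brute-force F-score: explicit sums, no shared code with the
# package's vectorized implementation.
oracle_f_score <- function(x, y) {
  vapply(seq_len(ncol(x)), function(i) {
    v <- x[, i]
    vp <- v[y == 1]
    vn <- v[y == 0]
    m <- sum(v) / length(v)
    mp <- sum(vp) / length(vp)
    mn <- sum(vn) / length(vn)
    sp2 <- sum((vp - mp)^2) / (length(vp) - 1)
    sn2 <- sum((vn - mn)^2) / (length(vn) - 1)
    num <- (mp - m)^2 + (mn - m)^2
    den <- sp2 + sn2
    if (den > 0) num / den else if (num > 0) Inf else 0
  }, numeric(1))
}

# All-pairs (tie-corrected Mann-Whitney) AUC oracle.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Fixed-length sequences with an exact number of identical positions and no
# way for gaps to add matches (mismatch positions use residues private to
# each sequence). Distinct `base`/mismatch letters keep independent pairs
# mutually dissimilar.
seq_pair_with_identity <- function(n_match, n_total, base = "A",
                                   mis_a = "C", mis_b = "D") {
  a <- paste(c(rep(base, n_match), rep(mis_a, n_total - n_match)),
             collapse = "")
  b <- paste(c(rep(base, n_match), rep(mis_b, n_total - n_match)),
             collapse = "")
  c(a = a, b = b)
}

# Small linearly separable 2-feature dataset embedded in a 2-column matrix.
separable_dataset <- function(n_per_class = 10, gap = 2, seed = 42) {
  withr::with_seed(seed, {
    xp <- cbind(stats::rnorm(n_per_class, gap, 0.2),
                stats::rnorm(n_per_class, gap, 0.2))
    xn <- cbind(stats::rnorm(n_per_class, -gap, 0.2),
                stats::rnorm(n_per_class, -gap, 0.2))
  })
  x <- rbind(xp, xn)
  colnames(x) <- c("f1", "f2")
  labeled_dataset(x, rep(c(1L, 0L), each = n_per_class))
}

# Assembled training dataset from a synthetic preset, as the pipeline builds
# it: dedupe positives, homology-filtered balanced negatives.
preset_dataset <- function(name, seed, sample_seed = seed + 1) {
  sim <- generate_proteome(synthetic_preset(name, seed = seed))
  pos <- dedupe_within(proteome_subset(sim$proteome, sim$positives))
  neg <- sample_negatives(sim$proteome, pos,
                          sampling_config(seed = sample_seed))
  list(dataset = assemble_dataset(pos, neg), sim = sim,
       positives = pos, negatives = neg)
}
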