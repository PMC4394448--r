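# Background amino-acid frequencies resembling the Swiss-Prot average
# (fractions; alphabetical by one-letter code, renormalized on construction).
SWISSPROT_FREQS <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)

#' Synthetic proteome configuration
#'
#' Describes a simulated study: a background proteome of i.i.d. random
#' sequences plus a positive class with planted signal — a multiplicative
#' amino-acid composition tilt (renormalized, so frequencies stay on the
#' simplex at any strength) and a subset of domain identifiers enriched in the
#' positive class.
#'
#' @param n_positives,n_background class sizes.
#' @param length_range integer `c(min, max)` sequence length (uniform).
#' @param background_freqs amino-acid frequency 20-simplex (named by residue).
#' @param tilt named multipliers applied to `background_freqs` for the
#'   positive class, e.g. `c(C = 3)`; renormalized. Empty = no tilt.
#' @param domain_universe number of domain identifiers in play.
#' @param n_enriched how many domains (the first of the universe) are
#'   enriched in positives.
#' @param p_domain_background per-domain presence probability in background
#'   proteins (and for non-enriched domains in positives).
#' @param p_domain_positive presence probability of enriched domains in
#'   positive proteins.
#' @param seed RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positives = 60, n_background = 400,
                             length_range = c(100L, 300L),
                             background_freqs = SWISSPROT_FREQS,
                             tilt = c(C = 3),
                             domain_universe = 40L,
                             n_enriched = 5L,
                             p_domain_background = 0.05,
                             p_domain_positive = 0.8,
                             seed = 1L) {
  if (n_positives < 1 || n_background < 1) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[2] < length_range[1]) {
    stop("invalid `length_range`", call. = FALSE)
  }
  if (length(background_freqs) != 20 ||
      is.null(names(background_freqs)) ||
      !setequal(names(background_freqs), AA_ALPHABET) ||
      any(background_freqs < 0) || sum(background_freqs) <= 0) {
    stop("`background_freqs` must be a named non-negative 20-vector",
         call. = FALSE)
  }
  background_freqs <- background_freqs[AA_ALPHABET]
  background_freqs <- background_freqs / sum(background_freqs)
  n_enriched <- as.integer(n_enriched)
  domain_universe <- as.integer(domain_universe)
  if (n_enriched > domain_universe) {
    stop("`n_enriched` cannot exceed `domain_universe`", call. = FALSE)
  }
  probs <- c(p_domain_background, p_domain_positive)
  if (any(probs < 0 | probs > 1)) stop("domain probabilities must be in [0, 1]",
                                       call. = FALSE)
  pos_freqs <- background_freqs
  if (length(tilt)) {
    if (is.null(names(tilt)) || !all(names(tilt) %in% AA_ALPHABET)) {
      stop("`tilt` must be named by amino-acid letters", call. = FALSE)
    }
    pos_freqs[names(tilt)] <- pos_freqs[names(tilt)] * tilt
    pos_freqs <- pos_freqs / sum(pos_freqs)
  }
  structure(list(
    n_positives = as.integer(n_positives),
    n_background = as.integer(n_background),
    length_range = length_range,
    background_freqs = background_freqs,
    positive_freqs = pos_freqs,
    tilt = tilt,
    domain_universe = domain_universe,
    n_enriched = n_enriched,
    p_domain_background = p_domain_background,
    p_domain_positive = p_domain_positive,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Named synthetic presets
#'
#' Three fixed study conditions used throughout the tests and examples:
#' * `"null"` — no planted signal: 50 positives + 150 background, no
#'   composition tilt, every domain at the background presence rate in both
#'   classes. A classifier should perform at chance.
#' * `"weak"` — 60 + 200, cysteine frequency x1.5 in positives, 5 domains
#'   enriched at 0.3 vs 0.05.
#' * `"strong"` — 60 + 400, cysteine x3, 5 domains enriched at 0.8 vs 0.05.
#'   Recoverable signal; cross-validated accuracy should be high.
#'
#' @param name one of `"null"`, `"weak"`, `"strong"`.
#' @param seed RNG seed.
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("strong", "weak", "null"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    null = synthetic_config(n_positives = 50, n_background = 150,
                            tilt = numeric(0), n_enriched = 5L,
                            p_domain_positive = 0.05, seed = seed),
    weak = synthetic_config(n_positives = 60, n_background = 200,
                            tilt = c(C = 1.5), p_domain_positive = 0.3,
                            seed = seed),
    strong = synthetic_config(n_positives = 60, n_background = 400,
                              tilt = c(C = 3), p_domain_positive = 0.8,
                              seed = seed)
  )
}

#' Generate a synthetic proteome with planted interaction signal
#'
#' Background proteins are drawn i.i.d. from the background amino-acid
#' frequencies with domains present independently at the background rate;
#' positive-class proteins use the tilted frequencies and the enriched domain
#' rates. Deterministic for a fixed config (same seed gives byte-identical
#' FASTA/annotation files via [write_synthetic()]).
#'
#' @param config a [synthetic_config()].
#' @return list with `proteome` (positives + background, domains attached),
#'   `positives` (accession vector) and `truth` (the generation parameters,
#'   including the enriched domain identifiers).
#' @export
generate_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  domains <- sprintf("DOM%04d", seq_len(config$domain_universe))
  enriched <- head(domains, config$n_enriched)
  p_bg <- rep(config$p_domain_background, config$domain_universe)
  p_pos <- p_bg
  p_pos[seq_len(config$n_enriched)] <- config$p_domain_positive

  gen_class <- function(n, prefix, freqs, p_dom) {
    len <- sample(seq.int(config$length_range[1], config$length_range[2]),
                  n, replace = TRUE)
    seqs <- vapply(len, function(l) {
      paste(sample(AA_ALPHABET, l, replace = TRUE, prob = freqs),
            collapse = "")
    }, character(1))
    doms <- lapply(seq_len(n), function(i) {
      domains[rbinom(config$domain_universe, 1L, p_dom) == 1L]
    })
    proteome(accession = sprintf("%s%04d", prefix, seq_len(n)),
             sequence = seqs, domains = doms, sanitize = FALSE)
  }

  res <- with_rng(config$seed, {
    pos <- gen_class(config$n_positives, "POS", config$positive_freqs, p_pos)
    bg <- gen_class(config$n_background, "BG", config$background_freqs, p_bg)
    list(pos = pos, bg = bg)
  })
  all <- rbind(res$pos, res$bg)
  class(all) <- c("proteome", "data.frame")
  list(proteome = all,
       positives = res$pos$accession,
       truth = list(config = config, enriched_domains = enriched,
                    domain_universe = domains))
}

#' Write a synthetic study to standard flat files
#'
#' Emits the four inputs the pipeline consumes: `proteome.fasta`,
#' `domains.tsv` (accession, domain id), `positives.txt` (one accession per
#' line) and `truth.tsv` (generation parameters, for benchmarking only).
#'
#' @param simulated output of [generate_proteome()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(simulated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             domains = file.path(dir, "domains.tsv"),
             positives = file.path(dir, "positives.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(simulated$proteome, paths[["fasta"]])
  p <- simulated$proteome
  acc <- rep(p$accession, lengths(p$domains))
  writeLines(if (length(acc)) paste(acc, unlist(p$domains), sep = "\t")
             else character(0), paths[["domains"]])
  writeLines(simulated$positives, paths[["positives"]])
  cfg <- simulated$truth$config
  kv <- c(n_positives = cfg$n_positives, n_background = cfg$n_background,
          length_min = cfg$length_range[1], length_max = cfg$length_range[2],
          seed = cfg$seed,
          p_domain_background = cfg$p_domain_background,
          p_domain_positive = cfg$p_domain_positive,
          tilt = if (length(cfg$tilt)) {
            paste(sprintf("%s:%g", names(cfg$tilt), cfg$tilt), collapse = ",")
          } else "none",
          enriched_domains = paste(simulated$truth$enriched_domains,
                                   collapse = ","))
  writeLines(paste(names(kv), kv, sep = "\t"), paths[["truth"]])
  invisible(paths)
}
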