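#' Construct a proteome collection
#'
#' A proteome is a data frame with one row per protein: `accession`
#' (unique, non-empty), `sequence` (uppercase, 20-letter alphabet after
#' sanitization) and `domains` (list column of character vectors of
#' functional-domain identifiers, possibly empty).
#'
#' @param accession character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param domains optional list of character vectors, one per protein.
#' @param sanitize replace non-standard residues before validation (see
#'   [sanitize_sequence()]).
#' @return An object of class `proteome` (a data frame).
#' @export
proteome <- function(accession, sequence, domains = NULL, sanitize = TRUE) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence)) {
    stop("`accession` and `sequence` must have the same length", call. = FALSE)
  }
  if (sanitize) sequence <- sanitize_sequence(sequence)
  if (any(!nzchar(accession))) stop("empty accession", call. = FALSE)
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    bad <- accession[!nzchar(sequence)]
    stop("empty sequence for accession(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_chr <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad_chr)) {
    stop("non-standard residues remain in: ",
         paste(accession[bad_chr], collapse = ", "), call. = FALSE)
  }
  if (is.null(domains)) {
    domains <- rep(list(character(0)), length(accession))
  }
  stopifnot(length(domains) == length(accession))
  domains <- lapply(domains, function(d) sort(unique(as.character(d))))
  out <- data.frame(accession = accession, sequence = sequence,
                    stringsAsFactors = FALSE)
  out$domains <- domains
  rownames(out) <- NULL
  class(out) <- c("proteome", "data.frame")
  out
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome: %d protein(s), %d with domain annotations\n",
              nrow(x), sum(lengths(x$domains) > 0)))
  n <- min(nrow(x), 6L)
  if (n > 0) {
    prev <- data.frame(
      accession = x$accession[seq_len(n)],
      length = nchar(x$sequence[seq_len(n)]),
      n_domains = lengths(x$domains[seq_len(n)])
    )
    print(prev)
    if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  }
  invisible(x)
}

#' Sanitize amino-acid sequences to the 20-letter alphabet
#'
#' Ambiguity and rare codes are resolved to their conventional representative:
#' B->D, Z->E, J->L, U->C (selenocysteine), O->K (pyrrolysine). Stop marks
#' (`*`) and fully ambiguous `X` residues are dropped, so composition
#' denominators count only retained residues and the 20-element composition
#' stays well defined.
#'
#' @param sequence character vector (uppercased internally).
#' @return character vector over the 20 standard letters.
#' @export
sanitize_sequence <- function(sequence) {
  s <- toupper(as.character(sequence))
  s <- chartr("BZJUO", "DELCK", s)
  gsub("[X*]", "", s)
}

# Accession from a FASTA header: first whitespace-delimited token; UniProt
# pipe dialect ("sp|P04637|P53_HUMAN") resolves to the middle token.
header_accession <- function(header) {
  tok <- sub("\\s.*$", "", header)
  pipey <- grepl("^(sp|tr)\\|[^|]+\\|", tok)
  tok[pipey] <- vapply(strsplit(tok[pipey], "|", fixed = TRUE), `[`, "", 2L)
  tok
}

#' Read a FASTA file into a proteome
#'
#' Sequences are uppercased and sanitized ([sanitize_sequence()]); domain sets
#' start empty (see [attach_domains()]). Accessions are the first whitespace
#' token of each header, with UniProt `sp|ACC|NAME` headers resolved to the
#' accession token.
#'
#' @param path path to a FASTA file.
#' @return A [proteome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("not FASTA: expected '>' header at line %d of %s",
                 first, path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  proteome(accession = header_accession(names(set)),
           sequence = as.character(set))
}

#' Write a proteome to a FASTA file
#'
#' Inverse of [read_fasta()] (domain annotations are not serialized; they
#' travel in the companion table, see [read_domain_table()]).
#'
#' @param x a [proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$accession
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a two-column protein-to-domain annotation table
#'
#' Tab-separated, two columns per line: accession and domain identifier
#' (InterPro-style). Repeated pairs collapse to presence/absence.
#'
#' @param path path to the TSV file.
#' @return named list: accession -> sorted character vector of domain ids.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- keep[which(nfield != 2L)[1]]
    stop(sprintf("malformed annotation line %d in %s: expected 2 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  acc <- vapply(parts, `[`, "", 1L)
  dom <- vapply(parts, `[`, "", 2L)
  if (length(acc) == 0) return(structure(list(), names = character(0)))
  lapply(split(dom, acc), function(d) sort(unique(d)))
}

#' Read a plain-text accession list (one accession per line)
#'
#' @param path path to the file.
#' @return character vector of unique accessions, input order preserved.
#' @export
read_accessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  acc <- trimws(readLines(path, warn = FALSE))
  unique(acc[nzchar(acc)])
}

#' Attach domain annotations to a proteome
#'
#' Each record's domain set is replaced by its entry in `annotations`;
#' accessions absent from the map get the empty set. Annotations for unknown
#' accessions are ignored with a warning. Idempotent for a fixed map.
#'
#' @param x a [proteome()].
#' @param annotations named list as returned by [read_domain_table()].
#' @return the annotated [proteome()].
#' @export
attach_domains <- function(x, annotations) {
  stopifnot(inherits(x, "proteome"))
  extra <- setdiff(names(annotations), x$accession)
  if (length(extra)) {
    warning("annotations for ", length(extra),
            " accession(s) not in the proteome were ignored: ",
            paste(head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  hit <- annotations[match(x$accession, names(annotations))]
  x$domains <- lapply(hit, function(d) {
    if (is.null(d)) character(0) else sort(unique(as.character(d)))
  })
  x
}

#' Subset a proteome by accession
#'
#' @param x a [proteome()].
#' @param accessions accessions to keep; all must exist.
#' @return the subset [proteome()], in the order of `accessions`.
#' @export
proteome_subset <- function(x, accessions) {
  stopifnot(inherits(x, "proteome"))
  miss <- setdiff(accessions, x$accession)
  if (length(miss)) {
    stop("accession(s) not in proteome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- x[match(accessions, x$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
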