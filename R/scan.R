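#' Derive the probability call threshold from the training set
#'
#' Predicts the calibrated probability of the *assigned* class for every
#' training sample and returns the minimum over correctly classified samples,
#' floored at 0.5. The floor keeps a badly calibrated model from calling
#' majority-negative scores positive. The count of correct training samples
#' sitting below the returned threshold (i.e. exactly at the minimum before
#' flooring) is attached as attribute `n_below_floor`.
#'
#' @param model a calibrated [train_svm()] model.
#' @param training the [labeled_dataset()] the model was trained on.
#' @return numeric threshold in `[0.5, 1]` with attributes `n_correct` and
#'   `n_below_floor`.
#' @export
derive_threshold <- function(model, training) {
  stopifnot(inherits(model, "ppi_svm"), inherits(training, "labeled_dataset"))
  if (is.null(model$platt)) {
    stop("model is uncalibrated; train with calibrate = TRUE", call. = FALSE)
  }
  p <- predict(model, training$x, type = "probability")
  pred <- as.integer(p >= 0.5)
  correct <- pred == training$y
  if (!any(correct)) {
    stop("no correctly classified training samples; cannot derive a threshold",
         call. = FALSE)
  }
  p_assigned <- ifelse(pred == 1L, p, 1 - p)
  thr <- threshold_from_probabilities(p_assigned[correct])
  thr
}

# Minimum assigned-class probability among correct samples, floored at 0.5.
threshold_from_probabilities <- function(correct_probs) {
  m <- min(correct_probs)
  thr <- max(0.5, m)
  structure(thr, n_correct = length(correct_probs),
            n_below_floor = sum(correct_probs < thr))
}

#' Scan a proteome for candidate interaction partners
#'
#' Encodes every non-excluded protein in the model's frozen feature space
#' (proteins without any domain annotation are scored on composition alone,
#' with an all-zero domain block), scores it with the calibrated probability
#' of the interacting class, and calls it against the threshold. Output is
#' sorted by descending probability, ties by accession, so it is invariant to
#' the input ordering.
#'
#' @param model a calibrated [train_svm()] model.
#' @param proteome the [proteome()] to scan (with domains attached where
#'   known).
#' @param exclude accessions to drop before scanning (typically the training
#'   set).
#' @param threshold probability call threshold (see [derive_threshold()]).
#' @return data frame `accession`, `probability`, `call` (logical), class
#'   `scan_result`.
#' @export
scan_proteome <- function(model, proteome, exclude = character(0),
                          threshold = 0.5) {
  stopifnot(inherits(model, "ppi_svm"), inherits(proteome, "proteome"))
  keep <- !(proteome$accession %in% exclude)
  scanned <- proteome[keep, , drop = FALSE]
  if (nrow(scanned) == 0) {
    stop("proteome is empty after exclusion", call. = FALSE)
  }
  p <- predict(model, scanned, type = "probability")
  out <- data.frame(accession = scanned$accession, probability = as.numeric(p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$accession), , drop = FALSE]
  out$call <- out$probability >= threshold
  rownames(out) <- NULL
  attr(out, "threshold") <- as.numeric(threshold)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("proteome scan: %d proteins, %d called at p >= %.3g\n",
              nrow(x), sum(x$call), attr(x, "threshold")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Tabulate functional categories (GOslim-style) for a protein list
#'
#' Counts how many proteins of `accessions` map to each category in
#' `category_map` (accession -> set of category names, e.g. GOslim molecular
#' function terms). A protein mapped to several categories contributes to each
#' count, so counts may exceed the number of proteins; fractions are over
#' mapped proteins. Unmapped proteins are counted separately.
#'
#' @param accessions character vector of proteins to tabulate.
#' @param category_map named list: accession -> character vector of category
#'   names (same shape as [read_domain_table()] output).
#' @return data frame `category`, `count`, `fraction` (descending count),
#'   with attributes `n_mapped`, `n_unmapped` and `multi_mapping`.
#' @export
goslim_summary <- function(accessions, category_map) {
  accessions <- as.character(accessions)
  hits <- category_map[match(accessions, names(category_map))]
  mapped <- !vapply(hits, is.null, logical(1)) & lengths(hits) > 0
  cats <- unlist(hits[mapped], use.names = FALSE)
  if (length(cats)) {
    tab <- sort(table(cats), decreasing = TRUE)
    out <- data.frame(category = names(tab), count = as.integer(tab),
                      fraction = as.integer(tab) / sum(mapped),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(category = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_mapped") <- sum(mapped)
  attr(out, "n_unmapped") <- sum(!mapped)
  attr(out, "multi_mapping") <- any(lengths(hits[mapped]) > 1)
  out
}

#' Side-by-side category table for two protein lists
#'
#' Convenience wrapper around [goslim_summary()] for comparing, e.g., known
#' partners against newly predicted candidates.
#'
#' @param known,predicted accession vectors.
#' @param category_map as in [goslim_summary()].
#' @return data frame `category`, `known_count`, `known_fraction`,
#'   `predicted_count`, `predicted_fraction`, sorted by descending known
#'   fraction.
#' @export
goslim_compare <- function(known, predicted, category_map) {
  a <- goslim_summary(known, category_map)
  b <- goslim_summary(predicted, category_map)
  out <- merge(a, b, by = "category", all = TRUE,
               suffixes = c("_known", "_predicted"))
  names(out) <- c("category", "known_count", "known_fraction",
                  "predicted_count", "predicted_fraction")
  for (col in names(out)[-1]) out[[col]][is.na(out[[col]])] <- 0
  out <- out[order(-out$known_fraction, -out$predicted_fraction,
                   out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
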