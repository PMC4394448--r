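test_that("threshold rule: minimum correct assigned-class probability, floored", {
  tfp <- protint:::threshold_from_probabilities
  expect_equal(as.numeric(tfp(c(0.99, 0.97, 0.96))), 0.96)
  expect_equal(as.numeric(tfp(c(1, 1, 1))), 1.0)
  expect_equal(as.numeric(tfp(c(0.55, 0.9))), 0.55)
  floored <- tfp(c(0.4, 0.9))
  expect_equal(as.numeric(floored), 0.5)
  expect_equal(attr(floored, "n_below_floor"), 1L)
})

test_that("derived threshold bounds the assigned-class probability of correct calls", {
  d <- preset_dataset("strong", seed = 19)
  m <- train_svm(d$dataset, model_config(C = 2, gamma = 0.5), seed = 4)
  thr <- derive_threshold(m, d$dataset)
  expect_gte(as.numeric(thr), 0.5)
  expect_lte(as.numeric(thr), 1.0)
  p <- predict(m, d$dataset$x, type = "probability")
  pred <- as.integer(p >= 0.5)
  p_assigned <- ifelse(pred == 1L, p, 1 - p)
  correct <- pred == d$dataset$y
  expect_true(all(p_assigned[correct] >= as.numeric(thr) - 1e-12 |
                    p_assigned[correct] < 0.5))

  m_uncal <- train_svm(d$dataset, model_config(C = 2, gamma = 0.5),
                       calibrate = FALSE)
  expect_error(derive_threshold(m_uncal, d$dataset), "uncalibrated")

  # scanning ranks the held-back planted partners at the top
  held_out <- setdiff(d$sim$positives, d$positives$accession)
  scan_pool <- proteome_subset(
    d$sim$proteome,
    setdiff(d$sim$proteome$accession,
            c(d$positives$accession, d$negatives$accession)))
  if (length(held_out) == 0) {
    # dedupe kept all positives: hold some out explicitly instead
    keep <- d$positives$accession[1:50]
    held_out <- setdiff(d$positives$accession, keep)
    m <- train_svm(assemble_dataset(proteome_subset(d$sim$proteome, keep),
                                    d$negatives),
                   model_config(C = 2, gamma = 0.5), seed = 4)
    scan_pool <- proteome_subset(
      d$sim$proteome,
      setdiff(d$sim$proteome$accession, c(keep, d$negatives$accession)))
  }
  sc <- scan_proteome(m, scan_pool, threshold = 0.5)
  top <- utils::head(sc$accession, 2 * length(held_out))
  expect_gte(sum(held_out %in% top), ceiling(0.8 * length(held_out)))
})

test_that("scan output ordering is input-order invariant and threshold-monotone", {
  d <- preset_dataset("weak", seed = 27)
  m <- train_svm(d$dataset, model_config(C = 2, gamma = 0.5), seed = 2)
  pool <- proteome_subset(
    d$sim$proteome,
    setdiff(d$sim$proteome$accession,
            c(d$positives$accession, d$negatives$accession)))
  sc1 <- scan_proteome(m, pool, threshold = 0.6)
  shuffled <- pool[withr::with_seed(3, sample.int(nrow(pool))), , drop = FALSE]
  class(shuffled) <- c("proteome", "data.frame")
  sc2 <- scan_proteome(m, shuffled, threshold = 0.6)
  expect_equal(sc1$accession, sc2$accession)
  expect_equal(sc1$probability, sc2$probability)
  expect_true(all(diff(sc1$probability) <= 0))

  lo <- scan_proteome(m, pool, threshold = 0.3)
  expect_true(all(sc1$accession[sc1$call] %in% lo$accession[lo$call]))

  # calls and ranking are decoupled: an unreachable threshold still ranks
  none <- scan_proteome(m, pool, threshold = 1.01)
  expect_equal(nrow(none), nrow(pool))
  expect_equal(sum(none$call), 0)

  # excluded training accessions never appear
  sc3 <- scan_proteome(m, d$sim$proteome, exclude = d$positives$accession)
  expect_length(intersect(sc3$accession, d$positives$accession), 0)
  expect_error(scan_proteome(m, pool, exclude = pool$accession), "empty")
})

test_that("functional category tables count mapped, multi-mapped and unmapped", {
  map <- list(P1 = "kinase activity", P2 = "kinase activity",
              P3 = "kinase activity",
              P4 = c("kinase activity", "nucleic acid binding"))
  t1 <- goslim_summary(c("P1", "P2", "P3"), map)
  expect_equal(t1$count, 3L)
  expect_equal(t1$fraction, 1.0)
  expect_equal(attr(t1, "n_unmapped"), 0L)

  t2 <- goslim_summary(c("P4", "P9"), map)
  expect_equal(t2$count[t2$category == "kinase activity"], 1L)
  expect_equal(t2$count[t2$category == "nucleic acid binding"], 1L)
  expect_equal(attr(t2, "n_unmapped"), 1L)
  expect_true(attr(t2, "multi_mapping"))

  t3 <- goslim_summary(character(0), map)
  expect_equal(nrow(t3), 0L)

  cmp <- goslim_compare(c("P1", "P2"), c("P3", "P4"), map)
  expect_true(all(c("known_count", "predicted_count") %in% names(cmp)))
  expect_equal(cmp$known_count[cmp$category == "kinase activity"], 2)
  expect_equal(cmp$predicted_count[cmp$category == "nucleic acid binding"], 1)
})
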