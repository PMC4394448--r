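test_that("feature space: sorted registry union, frozen dimension", {
  p <- proteome(c("P1", "P2"), c("AAAA", "CCCC"),
                domains = list("D2", c("D1", "D2")))
  sp <- feature_space(p)
  expect_equal(sp$domains, c("D1", "D2"))
  expect_equal(space_dimension(sp), 22L)

  q <- make_proteome(P1 = "AAAA")
  expect_equal(space_dimension(feature_space(q)), 20L)

  # a 413-domain registry gives the canonical 433-dimension layout
  r <- proteome("P1", "ACDE", domains = list(sprintf("IPR%06d", 1:413)))
  expect_equal(space_dimension(feature_space(r)), 433L)

  expect_error(feature_space(q[0, ]), "empty")
  expect_equal(space_dimension(feature_space(q, include_dipeptides = TRUE)),
               420L)
})

test_that("amino-acid composition is the normalized residue count", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v["A"]), 1.0)
  expect_equal(sum(v), 1.0)

  v <- aa_composition("ACDE")
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))

  v <- aa_composition("AAC")
  expect_equal(unname(v["A"]), 2 / 3)
  expect_equal(unname(v["C"]), 1 / 3)

  expect_error(aa_composition(""), "empty")
  expect_error(aa_composition("ACX"), "non-standard")
})

test_that("composition blocks always sum to one", {
  withr::with_seed(31, {
    for (i in 1:25) {
      s <- random_sequence(sample(1:200, 1))
      expect_equal(sum(aa_composition(s)), 1.0, tolerance = 1e-12)
      if (nchar(s) >= 2) {
        expect_equal(sum(dipeptide_composition(s)), 1.0, tolerance = 1e-12)
      }
    }
  })
})

test_that("dipeptide composition counts overlapping pairs over length - 1", {
  v <- dipeptide_composition("AAA")
  expect_equal(unname(v["AA"]), 1.0)

  v <- dipeptide_composition("ACAC")
  expect_equal(unname(v["AC"]), 2 / 3)
  expect_equal(unname(v["CA"]), 1 / 3)

  expect_equal(unname(dipeptide_composition("AC")["AC"]), 1.0)
  expect_error(dipeptide_composition("A"), "length")
})

test_that("encoding concatenates composition and registry-ordered indicators", {
  sp <- feature_space(proteome(c("X1", "X2"), c("AAAA", "AAAA"),
                               domains = list("D1", "D2")))
  rec <- proteome("P", "AAAA", domains = list("D2"))
  v <- encode_protein(rec, sp)
  expect_equal(unname(v["aa_A"]), 1.0)
  expect_equal(unname(v["dom_D1"]), 0)
  expect_equal(unname(v["dom_D2"]), 1)

  # unseen domain encodes like no domain at all (frozen space)
  unseen <- encode_protein(proteome("P", "AAAA", domains = list("D9")), sp)
  none <- encode_protein(proteome("P", "AAAA"), sp)
  expect_equal(unseen, none)

  # all registry domains present -> all-ones block
  full <- encode_protein(proteome("P", "AAAA", domains = list(c("D1", "D2"))),
                         sp)
  expect_equal(unname(full[c("dom_D1", "dom_D2")]), c(1, 1))

  m <- encode_proteome(proteome(c("A", "B"), c("AAAA", "CCCC"),
                                domains = list("D1", character(0))), sp)
  expect_equal(dim(m), c(2L, 22L))
  expect_equal(rownames(m), c("A", "B"))
})

test_that("F-score matches hand-computed values and degenerate conventions", {
  x <- cbind(f = c(2, 4, 0, 2),
             const = c(1, 1, 1, 1),
             perfect = c(1, 1, 0, 0))
  ds <- labeled_dataset(x, c(1, 1, 0, 0))
  fr <- f_score_rank(ds)
  expect_equal(fr$f_score[fr$feature == "f"], 0.5)
  expect_equal(fr$f_score[fr$feature == "const"], 0)
  expect_equal(fr$f_score[fr$feature == "perfect"], Inf)
  expect_equal(fr$feature[fr$rank == 1], "perfect")
  expect_equal(fr$rank, 1:3)
})

test_that("F-score is label-swap invariant and matches the two-pass oracle", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(6:30, 1)
      x <- matrix(stats::rnorm(n * 7), n, 7,
                  dimnames = list(NULL, paste0("v", 1:7)))
      y <- c(1L, 1L, 0L, 0L, sample(0:1, n - 4, replace = TRUE))
      ds <- labeled_dataset(x, y)
      ds_sw <- labeled_dataset(x, 1L - y)
      f1 <- f_score_rank(ds)
      f2 <- f_score_rank(ds_sw)
      expect_equal(f1$f_score, f2$f_score, tolerance = 1e-12)
      expect_equal(f1$f_score[order(f1$feature_index)], oracle_f_score(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(f_score_rank(labeled_dataset(matrix(1:4, 4, 1),
                                            c(1L, 0L, 0L, 0L))),
               "at least 2")
})

test_that("sparse svmlight export round-trips through the reader", {
  sim <- generate_proteome(synthetic_config(n_positives = 6, n_background = 20,
                                            length_range = c(30, 60),
                                            domain_universe = 8, seed = 13))
  pos <- proteome_subset(sim$proteome, sim$positives)
  neg <- sample_negatives(sim$proteome, pos, sampling_config(seed = 14))
  ds <- assemble_dataset(pos, neg)
  f <- withr::local_tempfile(fileext = ".svmlight")
  write_svmlight(ds, f)
  back <- read_svmlight(f, dimension = ncol(ds$x))
  expect_equal(back$y, ds$y)
  expect_equal(back$x, unname(ds$x), tolerance = 1e-9)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(ds, tsv)
  hdr <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_equal(hdr[1:2], c("accession", "label"))
  expect_length(hdr, 2 + ncol(ds$x))
})
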