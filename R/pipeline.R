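#' End-to-end run configuration
#'
#' @param proteome_fasta FASTA of the background proteome (the scan universe).
#' @param domain_tsv two-column accession/domain annotation TSV.
#' @param positives plain-text list of positive (interacting) accessions.
#' @param goslim_tsv optional two-column accession/category TSV for the
#'   functional summary.
#' @param out_dir output directory for artifacts.
#' @param identity_threshold redundancy / homology identity cutoff.
#' @param upsample_factor integer 1..5 positive-duplication factor.
#' @param grid a [grid_spec()].
#' @param k cross-validation folds.
#' @param seed master seed; all stage seeds derive from it.
#' @param global_selection rank features on the full training set instead of
#'   nested inside CV training folds (optimistic published-style protocol).
#' @param leaky_upsampling let upsampled replicates straddle CV folds
#'   (optimistic published-style protocol).
#' @return object of class `run_config`.
#' @export
run_config <- function(proteome_fasta, domain_tsv, positives,
                       goslim_tsv = NULL, out_dir = tempfile("protint_run"),
                       identity_threshold = 0.70, upsample_factor = 1L,
                       grid = grid_spec(), k = 5, seed = 1L,
                       global_selection = FALSE, leaky_upsampling = FALSE) {
  structure(list(proteome_fasta = proteome_fasta, domain_tsv = domain_tsv,
                 positives = positives, goslim_tsv = goslim_tsv,
                 out_dir = out_dir,
                 identity_threshold = identity_threshold,
                 upsample_factor = as.integer(upsample_factor),
                 grid = grid, k = as.integer(k), seed = as.integer(seed),
                 global_selection = isTRUE(global_selection),
                 leaky_upsampling = isTRUE(leaky_upsampling)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; `grid` may be a
#' mapping with `C_values`, `gamma_values`, `feature_counts`. Relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  grid <- grid_spec()
  if (!is.null(y$grid)) {
    grid <- grid_spec(
      C_values = if (!is.null(y$grid$C_values)) as.numeric(y$grid$C_values)
                 else 2^(-4:4),
      gamma_values = if (!is.null(y$grid$gamma_values))
                       as.numeric(y$grid$gamma_values) else 2^(-10:10),
      feature_counts = if (!is.null(y$grid$feature_counts))
                         as.integer(y$grid$feature_counts)
    )
  }
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  run_config(
    proteome_fasta = resolve(y$proteome_fasta),
    domain_tsv = resolve(y$domain_tsv),
    positives = resolve(y$positives),
    goslim_tsv = resolve(y$goslim_tsv),
    out_dir = pick("out_dir", tempfile("protint_run")),
    identity_threshold = pick("identity_threshold", 0.70),
    upsample_factor = pick("upsample_factor", 1L),
    grid = grid,
    k = pick("k", 5L),
    seed = pick("seed", 1L),
    global_selection = pick("global_selection", FALSE),
    leaky_upsampling = pick("leaky_upsampling", FALSE)
  )
}

# Pre-flight validation + input loading shared by run_pipeline and the
# robustness experiments. Fails before any output is written.
load_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- c(proteome_fasta = config$proteome_fasta,
             domain_tsv = config$domain_tsv,
             positives = config$positives)
  if (!is.null(config$goslim_tsv)) paths["goslim_tsv"] <- config$goslim_tsv
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("pre-flight failure, missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  prot <- read_fasta(config$proteome_fasta)
  prot <- attach_domains(prot, read_domain_table(config$domain_tsv))
  pos_acc <- read_accessions(config$positives)
  miss_pos <- setdiff(pos_acc, prot$accession)
  if (length(miss_pos)) {
    stop("positive accession(s) absent from the proteome: ",
         paste(miss_pos, collapse = ", "), call. = FALSE)
  }
  positives <- dedupe_within(
    proteome_subset(prot, pos_acc),
    identity_config(threshold = config$identity_threshold))
  goslim <- if (!is.null(config$goslim_tsv)) {
    read_domain_table(config$goslim_tsv)
  }
  list(proteome = prot, positives = positives, goslim = goslim)
}

stage <- function(name, code) {
  t0 <- Sys.time()
  res <- force(code)
  message(sprintf("[protint] %-22s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full prediction pipeline
#'
#' Executes: redundancy removal of positives, homology-filtered negative
#' sampling, optional upsampling, dataset assembly, grid search over
#' `(C, gamma, n_features)`, final training with probability calibration at
#' the optimum, threshold derivation, whole-proteome scan, and (if a category
#' map is given) functional summary tables. All intermediate artifacts plus a
#' machine-readable `report.json` are written under `config$out_dir`. Fully
#' reproducible for fixed seeds.
#'
#' @param config a [run_config()].
#' @return the run report (named list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  inputs <- stage("load inputs", load_inputs(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  positives <- inputs$positives
  pos_train <- upsample_positives(positives, config$upsample_factor)

  scfg <- sampling_config(identity_threshold = config$identity_threshold,
                          upsample_factor = config$upsample_factor,
                          seed = derive_seed(config$seed, 2))
  negatives <- stage("sample negatives",
                     sample_negatives(inputs$proteome, positives, scfg))

  dataset <- stage("assemble dataset",
                   assemble_dataset(pos_train, negatives,
                                    seed = derive_seed(config$seed, 2)))

  gs <- stage("grid search",
              grid_search(dataset, config$grid, k = config$k,
                          seed = derive_seed(config$seed, 3),
                          global_selection = config$global_selection,
                          leaky_upsampling = config$leaky_upsampling))
  cv <- stage("cross validate optimum",
              cross_validate(dataset, gs$best, k = config$k,
                             seed = derive_seed(config$seed, 3),
                             global_selection = config$global_selection,
                             leaky_upsampling = config$leaky_upsampling))

  model <- stage("final training",
                 train_svm(dataset, gs$best,
                           seed = derive_seed(config$seed, 4)))
  threshold <- derive_threshold(model, dataset)

  exclude <- unique(c(inputs$positives$accession, negatives$accession,
                      source_accession(dataset$accession)))
  scan <- stage("proteome scan",
                scan_proteome(model, inputs$proteome, exclude = exclude,
                              threshold = as.numeric(threshold)))

  goslim_known <- goslim_predicted <- NULL
  if (!is.null(inputs$goslim)) {
    goslim_known <- goslim_summary(positives$accession, inputs$goslim)
    goslim_predicted <- goslim_summary(scan$accession[scan$call],
                                       inputs$goslim)
  }

  # artifacts
  out <- function(f) file.path(config$out_dir, f)
  write_fasta(positives, out("nonredundant_positives.fasta"))
  write_svmlight(dataset, out("dataset.svmlight"))
  write.table(data.frame(accession = dataset$accession, label = dataset$y),
              out("dataset_accessions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gs$surface, out("accuracy_surface.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cv$roc$points, out("roc_points.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(scan), out("predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(goslim_known)) {
    write.table(goslim_known, out("goslim_known.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(goslim_predicted, out("goslim_predicted.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  save_model(model, out("model.rds"))

  report <- list(
    inputs = list(proteome_fasta = config$proteome_fasta,
                  domain_tsv = config$domain_tsv,
                  positives = config$positives,
                  n_proteome = nrow(inputs$proteome),
                  n_positives_raw = length(read_accessions(config$positives)),
                  n_positives_nonredundant = nrow(positives),
                  n_negatives = nrow(negatives),
                  n_training_samples = length(dataset$y)),
    modes = list(upsample_factor = config$upsample_factor,
                 leaky_upsampling = config$leaky_upsampling,
                 global_selection = config$global_selection,
                 identity_threshold = config$identity_threshold,
                 k = config$k, seed = config$seed),
    best = list(C = gs$best$C, gamma = gs$best$gamma,
                n_features = gs$best$n_features,
                n_grid_cells = nrow(gs$surface)),
    cv = list(accuracy = cv$metrics$accuracy,
              sensitivity = cv$metrics$sensitivity,
              specificity = cv$metrics$specificity,
              auc = cv$roc$auc,
              confusion = list(tp = cv$metrics$confusion$tp,
                               fp = cv$metrics$confusion$fp,
                               tn = cv$metrics$confusion$tn,
                               fn = cv$metrics$confusion$fn)),
    scan = list(threshold = as.numeric(threshold),
                n_scanned = nrow(scan),
                n_candidates = sum(scan$call))
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Negative-set robustness experiment
#'
#' Re-samples the negative training set `n_repeats` times with seeds derived
#' from the master seed, re-runs cross validation at a fixed model
#' configuration, and summarizes the accuracy distribution.
#'
#' @param config a [run_config()].
#' @param n_repeats number of negative re-samplings.
#' @param model_config the fixed [model_config()] to evaluate.
#' @return list with `accuracies` (data frame `repeat_id`, `seed`,
#'   `accuracy`) and `summary` (`mean`, `min`, `max`, `sd`).
#' @export
repeat_negatives <- function(config, n_repeats, model_config) {
  inputs <- load_inputs(config)
  scfg0 <- sampling_config(identity_threshold = config$identity_threshold,
                           upsample_factor = config$upsample_factor)
  pool <- eligible_negative_pool(inputs$proteome, inputs$positives, scfg0)
  pos_train <- upsample_positives(inputs$positives, config$upsample_factor)
  acc <- vapply(seq_len(n_repeats), function(i) {
    scfg <- sampling_config(identity_threshold = config$identity_threshold,
                            upsample_factor = config$upsample_factor,
                            seed = derive_seed(config$seed, 100 + i))
    negatives <- sample_negatives(inputs$proteome, inputs$positives, scfg,
                                  pool = pool)
    ds <- assemble_dataset(pos_train, negatives)
    cross_validate(ds, model_config, k = config$k,
                   seed = derive_seed(config$seed, 200 + i),
                   global_selection = config$global_selection,
                   leaky_upsampling = config$leaky_upsampling)$accuracy
  }, numeric(1))
  df <- data.frame(repeat_id = seq_len(n_repeats),
                   seed = vapply(seq_len(n_repeats),
                                 function(i) derive_seed(config$seed, 100 + i),
                                 integer(1)),
                   accuracy = acc)
  list(accuracies = df,
       summary = list(mean = mean(acc), min = min(acc), max = max(acc),
                      sd = if (n_repeats > 1) stats::sd(acc) else 0))
}

#' Upsampling-factor sweep
#'
#' For each upsampling factor, duplicates the positive set, draws a balanced
#' negative set `n_repeats` times, and records cross-validated accuracy at a
#' fixed model configuration (mean and sd per factor). With
#' `config$leaky_upsampling = TRUE` replicates may straddle folds, which
#' inflates apparent accuracy at high factors; the leakage-safe default keeps
#' replicates of a source protein in one fold.
#'
#' @param config a [run_config()] (its `upsample_factor` is ignored; the sweep
#'   supplies it).
#' @param factors integer upsampling factors to sweep.
#' @param n_repeats negative re-samplings per factor.
#' @param model_config the fixed [model_config()] to evaluate.
#' @return data frame `factor`, `mean_accuracy`, `sd_accuracy`, `n_repeats`.
#' @export
upsample_sweep <- function(config, factors = 1:5, n_repeats = 10,
                           model_config) {
  inputs <- load_inputs(config)
  scfg0 <- sampling_config(identity_threshold = config$identity_threshold)
  pool <- eligible_negative_pool(inputs$proteome, inputs$positives, scfg0)
  rows <- lapply(factors, function(f) {
    pos_train <- upsample_positives(inputs$positives, f)
    acc <- vapply(seq_len(n_repeats), function(i) {
      scfg <- sampling_config(identity_threshold = config$identity_threshold,
                              upsample_factor = f,
                              seed = derive_seed(config$seed, 1000 * f + i))
      negatives <- sample_negatives(inputs$proteome, inputs$positives, scfg,
                                    pool = pool)
      ds <- assemble_dataset(pos_train, negatives)
      cross_validate(ds, model_config, k = config$k,
                     seed = derive_seed(config$seed, 2000 * f + i),
                     global_selection = config$global_selection,
                     leaky_upsampling = config$leaky_upsampling)$accuracy
    }, numeric(1))
    data.frame(factor = f, mean_accuracy = mean(acc),
               sd_accuracy = if (n_repeats > 1) stats::sd(acc) else 0,
               n_repeats = n_repeats)
  })
  do.call(rbind, rows)
}
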