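#' End-to-end run configuration
#'
#' Collects every stage parameter with defaults at the reference recipe's
#' values: normalization range \[4, 15\], 90/10 split, hidden widths
#' 500-100-500, 100 epochs, 10% dropout, L2 alpha 1e-6, k = 943 landmarks,
#' permutation alpha 0.01. A single global seed drives every stochastic
#' stage.
#'
#' @param low,high Normalization range.
#' @param dedup_threshold Correlation threshold for profile deduplication
#'   (`NULL` skips deduplication).
#' @param dedup_clusters k-means cluster count for deduplication.
#' @param train_fraction Train split fraction.
#' @param hidden_widths Autoencoder hidden widths.
#' @param epochs,dropout_rate,l2_alpha,batch_size Autoencoder training
#'   parameters.
#' @param reference Attribution reference: `"train_mean"` or `"zeros"`.
#' @param k Number of landmark genes to select.
#' @param attribution_subsample Optional cap on samples used for attribution.
#' @param regressor A [regressor_spec()] for benchmarking.
#' @param alpha Permutation-test significance level.
#' @param seed Global seed.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(low = 4, high = 15, dedup_threshold = 0.99,
                       dedup_clusters = NULL, train_fraction = 0.9,
                       hidden_widths = c(500L, 100L, 500L), epochs = 100L,
                       dropout_rate = 0.10, l2_alpha = 1e-6,
                       batch_size = 256L, reference = c("train_mean", "zeros"),
                       k = 943L, attribution_subsample = NULL,
                       regressor = regressor_spec(), alpha = 0.01,
                       seed = 1L) {
  reference <- match.arg(reference)
  structure(list(low = low, high = high, dedup_threshold = dedup_threshold,
                 dedup_clusters = dedup_clusters,
                 train_fraction = train_fraction,
                 hidden_widths = as.integer(hidden_widths),
                 epochs = as.integer(epochs), dropout_rate = dropout_rate,
                 l2_alpha = l2_alpha, batch_size = as.integer(batch_size),
                 reference = reference, k = as.integer(k),
                 attribution_subsample = attribution_subsample,
                 regressor = regressor, alpha = alpha,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are refused.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the landmark discovery workflow
#'
#' Executes preprocess (quantile normalization, optional deduplication,
#' seeded split), autoencoder training, Rescale attribution, and top-k
#' selection. When `out_dir` is given, every artifact is written together
#' with a manifest recording the config hash and seed.
#'
#' @param X An `ExpressionMatrix`, or a path readable by
#'   [read_expression()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Print stage banners.
#' @return A list with `split`, `model` (NetworkParams), `reference`,
#'   `ranking`, `landmarks`, and `manifest`.
#' @export
run_discovery <- function(X, config = run_config(), out_dir = NULL,
                          verbose = FALSE) {
  say <- function(fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 sprintf(fmt, ...)))
  }
  if (is.character(X)) X <- read_expression(X)
  stage <- "preprocess"
  result <- tryCatch({
    say("preprocess: quantile normalization to [%g, %g]", config$low, config$high)
    Xn <- quantile_normalize(X, low = config$low, high = config$high)
    if (!is.null(config$dedup_threshold)) {
      nc <- config$dedup_clusters %||% min(100L, ncol(Xn))
      Xn <- deduplicate_profiles(Xn, n_clusters = nc,
                                 corr_threshold = config$dedup_threshold,
                                 seed = config$seed)
      say("preprocess: %d profiles retained after deduplication", ncol(Xn))
    }
    split <- train_test_split(Xn, train_fraction = config$train_fraction,
                              seed = config$seed)
    stage <- "train"
    say("train: autoencoder %s, %d epochs",
        paste(config$hidden_widths, collapse = "-"), config$epochs)
    train_unit <- minmax_to_unit(split$train, config$low, config$high)
    tc <- train_config(epochs = config$epochs, l2_alpha = config$l2_alpha,
                       dropout_rate = config$dropout_rate,
                       batch_size = config$batch_size, seed = config$seed)
    model <- train_autoencoder(train_unit, hidden_widths = config$hidden_widths,
                               config = tc)
    stage <- "attribute"
    ref <- if (config$reference == "train_mean") {
      reference_from_training(train_unit)
    } else {
      reference_input(rep(0, nrow(train_unit)), source = "zeros")
    }
    say("attribute: Rescale contributions over %d samples", ncol(train_unit))
    C <- contribution_tensor(model, train_unit, ref = ref,
                             n_subsample = config$attribution_subsample,
                             seed = config$seed)
    ranking <- aggregate_importance(C)
    stage <- "select"
    k <- min(config$k, nrow(ranking))
    landmarks <- select_landmarks(ranking, k = k)
    say("select: top %d landmarks", k)
    manifest <- list(config = unclass(config),
                     config_hash = config_hash(config),
                     seed = config$seed,
                     n_genes = nrow(X), n_samples_in = ncol(X),
                     n_train = ncol(split$train), n_test = ncol(split$test),
                     k = k)
    list(split = split, model = model, reference = ref, ranking = ranking,
         landmarks = landmarks, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(result$split$train, file.path(out_dir, "train.tsv"))
    write_expression(result$split$test, file.path(out_dir, "test.tsv"))
    save_model(result$model, file.path(out_dir, "model.ae"),
               low = config$low, high = config$high)
    write_gene_list(result$landmarks, file.path(out_dir, "landmarks.txt"))
    write_scores(result$ranking, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}

#' Benchmark landmark sets by landmark-to-target inference
#'
#' For each landmark set: train the regressor on the train split, predict
#' target genes on the test split, and evaluate with MAE / PCC / the
#' permutation test. Pairwise comparisons are computed over each pair's
#' common target genes.
#'
#' @param train,test `ExpressionMatrix` splits on the expression scale.
#' @param landmark_sets Named list of `LandmarkSet` objects (or id vectors).
#' @param config A [run_config()] supplying the regressor spec, bounds, and
#'   alpha.
#' @return A list of class `BenchmarkResult` with per-set `reports` and a
#'   list of pairwise `comparisons`.
#' @export
run_benchmark <- function(train, test, landmark_sets, config = run_config()) {
  if (length(landmark_sets) < 1) stop("need at least one landmark set")
  if (is.null(names(landmark_sets))) {
    names(landmark_sets) <- paste0("set", seq_along(landmark_sets))
  }
  reports <- list()
  for (nm in names(landmark_sets)) {
    parts_train <- split_landmark_target(train, landmark_sets[[nm]])
    parts_test <- split_landmark_target(test, landmark_sets[[nm]])
    model <- train_regressor(parts_train$landmark, parts_train$target,
                             spec = config$regressor,
                             low = config$low, high = config$high)
    pred <- predict_targets(model, parts_test$landmark)
    reports[[nm]] <- evaluate_predictions(parts_test$target, pred,
                                          alpha = config$alpha)
  }
  comparisons <- list()
  nms <- names(reports)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq((i + 1), length(nms))) {
        key <- paste(nms[i], nms[j], sep = "_vs_")
        comparisons[[key]] <- compare_landmark_sets(reports[[nms[i]]],
                                                    reports[[nms[j]]])
      }
    }
  }
  structure(list(reports = reports, comparisons = comparisons),
            class = "BenchmarkResult")
}

#' Draw a seeded random landmark set of a given size
#'
#' Used as the negative control in benchmarking: a uniformly random gene
#' subset of the same size as a discovered landmark set.
#'
#' @param gene_universe Character vector of all gene ids.
#' @param k Set size.
#' @param seed Integer seed.
#' @return A `LandmarkSet`.
#' @export
random_landmark_set <- function(gene_universe, k, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- sample(gene_universe, k)
  structure(list(gene_ids = ids, scores = rep(NA_real_, k), k = as.integer(k)),
            class = "LandmarkSet")
}
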