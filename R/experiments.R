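#' Stratified train/test split
#'
#' Splits an encoded dataset into train and test indices, stratified by
#' configuration, object size and direction, so every stratum is represented
#' in proportion to `frac_train` (to within one pair). Errors if any
#' direction would receive an empty training or test cell.
#'
#' @param encoded An [encode_dataset()] result.
#' @param frac_train Fraction of each stratum assigned to training.
#' @param seed Integer seed for the within-stratum sampling.
#' @return A list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(encoded, frac_train, seed = 1L) {
  if (frac_train <= 0 || frac_train >= 1)
    stop("frac_train must lie strictly between 0 and 1")
  set.seed(seed)
  strata <- interaction(encoded$config, encoded$object_size, encoded$labels,
                        drop = TRUE)
  train <- integer(0)
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    k <- round(frac_train * length(idx))
    if (k < 1L || k >= length(idx))
      stop("split ", frac_train, " leaves an empty train or test cell in ",
           "stratum ", lev)
    train <- c(train, idx[sample.int(length(idx), k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(encoded$samples), train))
}

#' Subset an encoded dataset
#'
#' Keeps the selected samples (e.g. one side of a [stratified_split()])
#' together with their labels and metadata.
#'
#' @param encoded An [encode_dataset()] result.
#' @param idx Integer indices of the samples to keep.
#' @return An `avs_encoded` object.
#' @export
subset_encoded <- function(encoded, idx) {
  structure(
    list(samples = encoded$samples[idx], labels = encoded$labels[idx],
         config = encoded$config[idx], object_size = encoded$object_size[idx],
         eps_vertical = encoded$eps_vertical,
         eps_horizontal = encoded$eps_horizontal),
    class = "avs_encoded"
  )
}

.subset_encoded <- subset_encoded

# Generate and encode a single-configuration dataset from a template spec.
.encode_config <- function(template, config, seed, train) {
  sp <- dataset_spec(template$image_height, template$image_width,
                     configurations = config,
                     object_sizes = template$object_sizes,
                     pairs_per_direction = template$pairs_per_direction,
                     seed = seed)
  encode_dataset(generate_dataset(sp), train$eps_vertical,
                 train$eps_horizontal)
}

.report_row <- function(experiment, train_config, test_config, split,
                        train_accs, test_accs, seeds, param_count) {
  sdv <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(
    experiment = experiment, train_config = train_config,
    test_config = test_config, split = split,
    mean_train_acc = round(mean(train_accs), 4L),
    sd_train_acc = round(sdv(train_accs), 4L),
    mean_test_acc = round(mean(test_accs), 4L),
    sd_test_acc = round(sdv(test_accs), 4L),
    n_runs = length(seeds),
    seeds = paste(seeds, collapse = ";"),
    param_count = param_count,
    stringsAsFactors = FALSE
  )
}

#' Cross-configuration validation experiment
#'
#' Trains the network on one object--background configuration and evaluates
#' it on all eight: the training portion (75%, stratified) of the named
#' configuration supplies the gradient steps; "test" accuracy is measured on
#' the held-out 25% for the same configuration and on the full datasets of
#' the other seven. Repetitions vary the split/training seed; the datasets
#' themselves are fixed by `spec$seed`.
#'
#' @param train_on Configuration label to train on (e.g. `"DL"`).
#' @param spec Template [dataset_spec()] giving geometry, object sizes and
#'   pairs per direction. Its `configurations` field is ignored; one dataset
#'   per configuration is generated. Defaults to the reduced desk scale
#'   (sizes 8/16/32, 100 pairs per direction); set
#'   `paper_scale = TRUE` for the full benchmark scale.
#' @param train An [train_config()] object.
#' @param seeds Integer vector of repetition seeds.
#' @param test_on Configurations to evaluate (default all eight).
#' @param paper_scale Use the full benchmark scale (all eight object sizes,
#'   500 pairs per direction); a long run.
#' @param quiet Suppress progress messages.
#' @return An `avs_report` data.frame, one row per test configuration.
#' @export
run_cross_config_experiment <- function(train_on,
                                        spec = dataset_spec(
                                          object_sizes = c(8L, 16L, 32L),
                                          pairs_per_direction = 100L),
                                        train = train_config(),
                                        seeds = 1:3,
                                        test_on = NULL,
                                        paper_scale = FALSE,
                                        quiet = TRUE) {
  if (!train_on %in% .all_configs)
    stop("unknown configuration label: ", train_on)
  if (paper_scale)
    spec <- dataset_spec(spec$image_height, spec$image_width,
                         object_sizes = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
                         pairs_per_direction = 500L, seed = spec$seed)
  if (is.null(test_on)) test_on <- .all_configs
  bad <- setdiff(test_on, .all_configs)
  if (length(bad) > 0L) stop("unknown configuration label: ", bad[1L])

  enc_train_cfg <- .encode_config(spec, train_on,
                                  spec$seed + match(train_on, .all_configs),
                                  train)
  others <- setdiff(test_on, train_on)
  enc_others <- lapply(others, function(cf)
    .encode_config(spec, cf, spec$seed + match(cf, .all_configs), train))
  names(enc_others) <- others

  acc_train <- numeric(0)
  acc_test <- matrix(NA_real_, length(seeds), length(test_on),
                     dimnames = list(NULL, test_on))
  for (r in seq_along(seeds)) {
    sp <- stratified_split(enc_train_cfg, 0.75, seed = seeds[r])
    cfg <- train
    cfg$seed <- seeds[r]
    fit <- train_model(.subset_encoded(enc_train_cfg, sp$train), cfg,
                       quiet = quiet)
    acc_train[r] <- evaluate_accuracy(fit$params,
                                      .subset_encoded(enc_train_cfg, sp$train))
    if (train_on %in% test_on)
      acc_test[r, train_on] <-
        evaluate_accuracy(fit$params, .subset_encoded(enc_train_cfg, sp$test))
    for (cf in others)
      acc_test[r, cf] <- evaluate_accuracy(fit$params, enc_others[[cf]])
    if (!quiet)
      message("seed ", seeds[r], ": train acc ", round(acc_train[r], 4L))
  }
  pc <- count_learnable(avs_params())
  rows <- lapply(test_on, function(cf)
    .report_row("cross_config", train_on, cf, NA_character_,
                acc_train, acc_test[, cf], seeds, pc))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("avs_report", "data.frame"))
}

.parse_ratio <- function(ratio) {
  parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1L]])
  if (length(parts) != 2L || any(is.na(parts)) || any(parts <= 0))
    stop("malformed ratio: ", ratio)
  parts[1L] / sum(parts)
}

#' Train/test-ratio robustness experiment
#'
#' Generates one dataset from `spec` (by default a balanced pool over all
#' eight configurations), then for each requested train:test ratio performs a
#' stratified split, trains, and reports train and test accuracy averaged
#' over repetition seeds.
#'
#' @param spec A [dataset_spec()]; defaults to the reduced desk scale.
#' @param ratios Character vector like `c("75:25", "50:50", "10:90", "5:95")`.
#' @param train An [train_config()] object.
#' @param seeds Integer vector of repetition seeds.
#' @param paper_scale Use the full benchmark scale.
#' @param quiet Suppress progress messages.
#' @return An `avs_report` data.frame, one row per ratio.
#' @export
run_ratio_experiment <- function(spec = dataset_spec(
                                   object_sizes = c(8L, 16L, 32L),
                                   pairs_per_direction = 100L),
                                 ratios = c("75:25", "50:50", "10:90", "5:95"),
                                 train = train_config(),
                                 seeds = 1:3,
                                 paper_scale = FALSE,
                                 quiet = TRUE) {
  if (paper_scale)
    spec <- dataset_spec(spec$image_height, spec$image_width,
                         configurations = spec$configurations,
                         object_sizes = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
                         pairs_per_direction = 500L, seed = spec$seed)
  fracs <- vapply(ratios, .parse_ratio, numeric(1L))
  enc <- encode_dataset(generate_dataset(spec), train$eps_vertical,
                        train$eps_horizontal)
  pc <- count_learnable(avs_params())
  rows <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    acc_train <- numeric(0); acc_test <- numeric(0)
    for (r in seq_along(seeds)) {
      sp <- stratified_split(enc, fracs[k], seed = seeds[r])
      cfg <- train
      cfg$seed <- seeds[r]
      fit <- train_model(.subset_encoded(enc, sp$train), cfg, quiet = quiet)
      acc_train[r] <- evaluate_accuracy(fit$params,
                                        .subset_encoded(enc, sp$train))
      acc_test[r] <- evaluate_accuracy(fit$params,
                                       .subset_encoded(enc, sp$test))
      if (!quiet)
        message(ratios[k], " seed ", seeds[r], ": test acc ",
                round(acc_test[r], 4L))
    }
    rows[[k]] <- .report_row("ratio", NA_character_, NA_character_,
                             ratios[k], acc_train, acc_test, seeds, pc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("avs_report", "data.frame"))
}

#' Write / read an experiment report as CSV
#'
#' `summarize_report()` writes the report with a deterministic column order
#' and accuracies as fractions with four decimals; `read_report()` restores
#' it so that `read_report(summarize_report(x, p))` equals `x`.
#'
#' @param report An `avs_report`.
#' @param path Output CSV path.
#' @return `summarize_report()` the path, invisibly; `read_report()` an
#'   `avs_report`.
#' @export
summarize_report <- function(report, path) {
  if (!inherits(report, "avs_report") || nrow(report) == 0L)
    stop("report must be a non-empty avs_report")
  cols <- c("experiment", "train_config", "test_config", "split",
            "mean_train_acc", "sd_train_acc", "mean_test_acc", "sd_test_acc",
            "n_runs", "seeds", "param_count")
  utils::write.csv(report[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname summarize_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(seeds = "character"))
  for (col in c("experiment", "train_config", "test_config", "split"))
    df[[col]] <- as.character(df[[col]])
  structure(df, class = c("avs_report", "data.frame"))
}
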