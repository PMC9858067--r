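#' Build the common Kennard-Stone split for an experiment
#'
#' The split is computed once, per class, on the Z-scored fused
#' representation (the most neutral arm: standardised but otherwise
#' untreated spectra), and shared by every preprocessing and modality arm
#' so that arm comparisons ride on a common partition. The Z-score used
#' here is fitted on all samples and feeds only the split geometry; each
#' arm's modelling Z-score is refitted on the training rows alone.
#'
#' @param data `list(nirr =, nirt =)` paired datasets, as from
#'   [generate_dataset()].
#' @param train_fraction training fraction (default 2/3).
#' @return A `split_result` from [ks_split()].
#' @export
make_split <- function(data, train_fraction = 2 / 3) {
  fused <- fuse(data$nirr, data$nirt)
  st <- zscore_fit(fused)
  ks_split(zscore_apply(fused, st), train_fraction)
}

#' Assemble one experiment arm
#'
#' Cuts the shared split into train/test, fits the per-variable Z-score on
#' the training rows of each modality, applies the configured
#' preprocessing per modality, and fuses the blocks when the fused arm is
#' requested. Preprocessing precedes fusion because the two modalities
#' differ in absorbance level and morphology; treating them separately
#' closes the gap at the splicing site.
#'
#' @param data `list(nirr =, nirt =)` paired datasets.
#' @param split a [make_split()] result.
#' @param modality `"fused"`, `"nirr"` or `"nirt"`.
#' @param method preprocessing method (`"np"`, `"fd"`, `"snv"`) or a full
#'   [preprocess_config()].
#' @return `list(train =, test =)` of preprocessed [spectral_dataset()]s.
#' @export
prepare_arm <- function(data, split, modality = c("fused", "nirr", "nirt"),
                        method = "np") {
  modality <- match.arg(modality)
  cfg <- if (inherits(method, "preprocess_config")) method
         else preprocess_config(method)
  one_block <- function(ds) {
    tr <- subset_samples(ds, split$train_indices)
    te <- subset_samples(ds, split$test_indices)
    st <- zscore_fit(tr)
    list(train = preprocess(tr, cfg, st), test = preprocess(te, cfg, st))
  }
  if (modality != "fused") return(one_block(data[[modality]]))
  r <- one_block(data$nirr); t <- one_block(data$nirt)
  list(train = fuse(r$train, t$train), test = fuse(r$test, t$test))
}

#' Experiment configuration
#'
#' Declares the full grid: data source, preprocessing arms, modality arms,
#' model kinds with their configs, the repeat protocol, and an optional
#' output directory for artifacts.
#'
#' @param synthetic a [synthetic_config()] (default [default_config()]).
#'   Ignored when `nirr_csv`/`nirt_csv` point at measured data files.
#' @param nirr_csv,nirt_csv optional CSV paths ([read_dataset()] dialect).
#' @param modalities subset of `c("fused", "nirr", "nirt")`.
#' @param methods subset of `c("np", "fd", "snv")`.
#' @param models subset of `c("cnn", "ann", "svm", "knn")`.
#' @param model_configs named list of config objects overriding the
#'   defaults per model kind.
#' @param n_repeats repeats of the training protocol (default 8).
#' @param base_seed first training seed (default 1).
#' @param out_dir artifact directory or `NULL` for none.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synthetic = default_config(),
                              nirr_csv = NULL, nirt_csv = NULL,
                              modalities = "fused", methods = "fd",
                              models = "cnn", model_configs = list(),
                              n_repeats = 8L, base_seed = 1L,
                              out_dir = NULL) {
  stopifnot(all(modalities %in% c("fused", "nirr", "nirt")),
            all(methods %in% c("np", "fd", "snv")),
            all(models %in% c("cnn", "ann", "svm", "knn")))
  structure(list(synthetic = synthetic, nirr_csv = nirr_csv,
                 nirt_csv = nirt_csv, modalities = modalities,
                 methods = methods, models = models,
                 model_configs = model_configs,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys: `modalities`, `methods`, `models`, `n_repeats`,
#' `base_seed`, `out_dir`, `data: {nirr: path, nirt: path}`,
#' `synthetic: {seed: int, counts: [n0, n1, n2]}` and a `cnn:` block with
#' [cnn_config()] fields. Anything omitted falls back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- default_config()
  if (!is.null(y$synthetic$seed)) syn$seed <- as.integer(y$synthetic$seed)
  if (!is.null(y$synthetic$counts)) {
    cn <- as.integer(y$synthetic$counts)
    for (i in 1:3) syn$profiles[[i]]$n_samples <- cn[i]
  }
  mc <- list()
  if (!is.null(y$cnn)) mc$cnn <- do.call(cnn_config, y$cnn)
  experiment_config(
    synthetic = syn,
    nirr_csv = y$data$nirr, nirt_csv = y$data$nirt,
    modalities = y$modalities %||% "fused",
    methods = y$methods %||% "fd",
    models = y$models %||% "cnn",
    model_configs = mc,
    n_repeats = y$n_repeats %||% 8L,
    base_seed = y$base_seed %||% 1L,
    out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full experiment grid
#'
#' Generates (or reads) the paired datasets, computes the shared
#' Kennard-Stone split, and runs the repeat protocol for every
#' modality x preprocessing x model combination. All randomness flows from
#' `cfg$synthetic$seed` (data) and `cfg$base_seed` (training), so a rerun
#' with the same configuration reproduces the summary exactly under
#' single-threaded linear algebra. When `out_dir` is set, writes
#' `summary.json`, per-arm mean test confusion matrices
#' (`confusion_<arm>.csv`) and, for CNN arms, the first repeat's
#' accuracy/loss history (`history_<arm>.csv`).
#'
#' Failure policy: an arm that errors is recorded in the summary with
#' `NA` metrics and the grid continues.
#'
#' @param cfg an [experiment_config()] or a YAML path.
#' @return A list: `reports` (named `modality.method.model`), `summary`
#'   data frame, and the `split`.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  data <- if (!is.null(cfg$nirr_csv)) {
    list(nirr = read_dataset(cfg$nirr_csv, "nirr"),
         nirt = read_dataset(cfg$nirt_csv, "nirt"))
  } else generate_dataset(cfg$synthetic)
  split <- make_split(data)

  reports <- list()
  rows <- list()
  for (modality in cfg$modalities) {
    for (method in cfg$methods) {
      arm <- prepare_arm(data, split, modality, method)
      for (kind in cfg$models) {
        label <- paste(modality, method, kind, sep = ".")
        rep_ <- tryCatch(
          repeat_protocol(kind, arm$train, arm$test,
                          cfg = cfg$model_configs[[kind]],
                          n_repeats = cfg$n_repeats,
                          base_seed = cfg$base_seed),
          error = function(e) e)
        if (inherits(rep_, "error")) {
          warning("arm ", label, " failed: ", conditionMessage(rep_))
          rows[[label]] <- data.frame(
            modality = modality, method = method, model = kind,
            pa_train = NA_real_, sd_pa_train = NA_real_,
            pa_test = NA_real_, sd_pa_test = NA_real_,
            f1_train = NA_real_, sd_f1_train = NA_real_,
            f1_test = NA_real_, sd_f1_test = NA_real_,
            failed = TRUE)
          next
        }
        reports[[label]] <- rep_
        rows[[label]] <- data.frame(
          modality = modality, method = method, model = kind,
          pa_train = rep_$mean[["pa_train"]], sd_pa_train = rep_$sd[["pa_train"]],
          pa_test = rep_$mean[["pa_test"]], sd_pa_test = rep_$sd[["pa_test"]],
          f1_train = rep_$mean[["f1_train"]], sd_f1_train = rep_$sd[["f1_train"]],
          f1_test = rep_$mean[["f1_test"]], sd_f1_test = rep_$sd[["f1_test"]],
          failed = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(n_repeats = cfg$n_repeats, base_seed = cfg$base_seed,
           data_seed = cfg$synthetic$seed, summary = summary),
      file.path(cfg$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (label in names(reports)) {
      rp <- reports[[label]]
      utils::write.csv(round(rp$confusion_test_pct, 4),
                       file.path(cfg$out_dir,
                                 paste0("confusion_", gsub("\\.", "_", label), ".csv")))
      if (rp$kind == "cnn" && nrow(rp$runs[[1]]$confusion_test) > 0) {
        utils::write.csv(rp$model$history,
                         file.path(cfg$out_dir,
                                   paste0("history_", gsub("\\.", "_", label), ".csv")),
                         row.names = FALSE)
      }
    }
  }
  list(reports = reports, summary = summary, split = split)
}
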