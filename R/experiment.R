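# End-to-end one-class experiment: simulate (or load) beats, train on normals,
# fit the threshold on training-set anomaly scores, score and classify the
# test set, evaluate. Every run logs its fully resolved configuration.

#' Configuration of an end-to-end run
#'
#' A flat key-value union of the simulation, training and detection settings.
#' Unspecified fields take the documented defaults of [sim_config()],
#' [train_config()] and [anomaly_score()].
#'
#' @param n_train Normal training beats to simulate.
#' @param n_test_normal,n_test_abnormal Test-set composition.
#' @param noise_sd,baseline_amp,baseline_freq,class_mix See [sim_config()].
#' @param epochs,batch_size,lr_ae,lr_d,gamma,patience See [train_config()].
#' @param lambda Anomaly-score mixing weight (0 scores by reconstruction
#'   error alone).
#' @param threshold_mode Only `"mean+sd"` is implemented.
#' @param seed Master seed for simulation and training.
#' @param out_dir Optional directory for run artifacts (scores, report,
#'   history, reconstruction examples, resolved config, log).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_train = 2000L, n_test_normal = 500L,
                       n_test_abnormal = 500L, noise_sd = 0.03,
                       baseline_amp = 0.1, baseline_freq = 0.3,
                       class_mix = c(N = 0.8, A = 0.05, L = 0.05, R = 0.05,
                                     V = 0.05),
                       epochs = 8L, batch_size = 64L, lr_ae = 1e-3,
                       lr_d = 2e-4, gamma = 0.05, patience = 8L, lambda = 0,
                       threshold_mode = "mean+sd", seed = 1L,
                       out_dir = NULL) {
  if (!identical(threshold_mode, "mean+sd"))
    stopf("unsupported threshold_mode '%s' (only \"mean+sd\")",
          threshold_mode)
  check_scalar_num(lambda, "lambda", 0, 1)
  structure(list(n_train = as.integer(n_train),
                 n_test_normal = as.integer(n_test_normal),
                 n_test_abnormal = as.integer(n_test_abnormal),
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, class_mix = class_mix,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_ae = lr_ae, lr_d = lr_d, gamma = gamma,
                 patience = as.integer(patience), lambda = lambda,
                 threshold_mode = threshold_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a run configuration as flat key=value text
#'
#' Vector fields are comma-joined with their names (`class_mix=N:0.8,...`).
#' The round trip restores an identical configuration.
#'
#' @param config A [run_config()].
#' @param path Text file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt_field <- function(v) {
    if (is.null(v)) return("")
    if (!is.null(names(v)) && length(v) > 1)
      return(paste(sprintf("%s:%.17g", names(v), v), collapse = ","))
    if (is.numeric(v)) return(sprintf("%.17g", v))
    as.character(v)
  }
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, fmt_field, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(f)
    if (length(f) > 1) paste(f[-1], collapse = "=") else "", character(1))
  parse_field <- function(key, val) {
    if (val == "") return(NULL)
    if (grepl(":", val, fixed = TRUE)) {
      parts <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      return(stats::setNames(vapply(parts, function(p) as.numeric(p[2]),
                                    numeric(1)),
                             vapply(parts, `[[`, character(1), 1)))
    }
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) num else val
  }
  fields <- stats::setNames(lapply(seq_along(keys), function(i)
    parse_field(keys[i], vals[i])), keys)
  do.call(run_config, fields[!vapply(fields, is.null, logical(1))])
}

#' @noRd
stage <- function(name, log_fun, expr) {
  log_fun(sprintf("stage %s: start", name))
  out <- tryCatch(expr, error = function(e)
    stopf("stage %s failed: %s", name, conditionMessage(e)))
  log_fun(sprintf("stage %s: done", name))
  out
}

#' Run the full one-class detection experiment
#'
#' Simulate (or accept pre-built) train/test beat matrices, train the
#' adversarial autoencoder on the normal training beats, fit the threshold
#' as mean + 1 sd of the training-set anomaly scores, score and classify the
#' test set, and evaluate with abnormal as the positive class. With
#' `n_test_abnormal = 0` the AUC is reported as `NA` (single-class) and every
#' other stage proceeds.
#'
#' @param config A [run_config()].
#' @param data Optional list with `train` and `test` [beat_matrix()] objects;
#'   when omitted they are simulated from `config`.
#' @param verbose Log stage progress and per-epoch losses to the console.
#' @return A list of class `run_result`: `report` ([evaluate_detector()]
#'   output), `threshold`, `train_scores`, `test_scores` (both `score_set`),
#'   `history`, `fit`, and the resolved `config`.
#' @export
run_experiment <- function(config = run_config(), data = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_con <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
    on.exit(close(log_con))
  }
  log_fun <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    if (!is.null(log_con)) writeLines(line, log_con)
    if (verbose) message(line)
  }
  log_fun(sprintf("resolved config: %s",
                  paste(sprintf("%s=%s", names(config),
                                vapply(config, function(v)
                                  paste(format(v), collapse = ","),
                                  character(1))),
                        collapse = " ")))

  if (is.null(data)) {
    data <- stage("simulate", log_fun, {
      sc <- sim_config(noise_sd = config$noise_sd,
                       baseline_amp = config$baseline_amp,
                       baseline_freq = config$baseline_freq,
                       seed = config$seed, class_mix = config$class_mix)
      make_dataset(config$n_train, config$n_test_normal,
                   config$n_test_abnormal, sc)
    })
  }

  fit <- stage("train", log_fun, {
    tc <- train_config(epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr_ae = config$lr_ae, lr_d = config$lr_d,
                       gamma = config$gamma, patience = config$patience,
                       seed = config$seed)
    train_aae(data$train, model_spec(), tc, verbose = verbose)
  })

  train_scores <- stage("fit_threshold", log_fun, {
    ss <- score_beats(data$train, fit$params, config$lambda)
    ss$threshold <- fit_threshold(ss$scores$anomaly)
    ss
  })

  test_scores <- stage("score_test", log_fun, {
    ss <- score_beats(data$test, fit$params, config$lambda)
    ss$threshold <- train_scores$threshold
    ss
  })

  report <- stage("evaluate", log_fun, {
    truth <- ifelse(data$test$labels == "N", "normal", "abnormal")
    evaluate_detector(test_scores$scores$anomaly, truth,
                      train_scores$threshold)
  })

  if (!is.null(config$out_dir)) stage("artifacts", log_fun, {
    od <- config$out_dir
    write_run_config(config, file.path(od, "config.txt"))
    utils::write.csv(train_scores$scores,
                     file.path(od, "train_scores.csv"), row.names = FALSE)
    utils::write.csv(test_scores$scores, file.path(od, "test_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$history, file.path(od, "history.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(report$counts),
           acc = report$acc, pre = report$pre, rec = report$rec,
           f1 = report$f1, auc = report$auc, threshold = report$threshold),
      file.path(od, "report.json"), auto_unbox = TRUE, digits = NA)
    # reconstruction examples: first normal and first abnormal test beat
    ex_idx <- c(which(data$test$labels == "N")[1],
                which(data$test$labels != "N")[1])
    ex_idx <- ex_idx[!is.na(ex_idx)]
    if (length(ex_idx)) {
      xb <- data$test$beats[ex_idx, , drop = FALSE]
      rec <- reconstruct(xb, fit$params)
      utils::write.csv(
        data.frame(label = rep(data$test$labels[ex_idx], each = 250),
                   sample = rep(1:250, length(ex_idx)),
                   input = as.vector(t(xb)),
                   reconstruction = as.vector(t(rec))),
        file.path(od, "reconstruction_examples.csv"), row.names = FALSE)
    }
    invisible(NULL)
  })

  structure(list(report = report, threshold = train_scores$threshold,
                 train_scores = train_scores, test_scores = test_scores,
                 history = fit$history, fit = fit, config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("One-class ECG anomaly detection run\n")
  print(x$report)
  invisible(x)
}
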