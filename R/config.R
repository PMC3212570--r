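#' Run configuration
#'
#' The single configuration surface of the pipeline. Every parameter has a
#' fixed documented default — the pipeline is designed to run without
#' per-image tuning — and the whole configuration round-trips through a
#' flat key=value text file so runs are reproducible.
#'
#' @param patch_size patch side in pixels (default 20).
#' @param threshold_method automatic confidence threshold, `"otsu"` or
#'   `"svm-zero"`.
#' @param connectivity region connectivity on the patch grid, 4 or 8.
#' @param lambda graph-cut pairwise strength.
#' @param logistic_scale confidence-to-probability logistic scale.
#' @param seed_erosion_px hard-seed erosion margin in pixels (`NA` = one
#'   patch).
#' @param lbp_target_um_per_px common scale of the scatter descriptor.
#' @param svm_cost soft-margin cost of every linear SVM.
#' @param rng_seed integer seed for every stochastic step.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(patch_size = 20L,
                       threshold_method = "otsu",
                       connectivity = 4L,
                       lambda = 1.0,
                       logistic_scale = 1.0,
                       seed_erosion_px = NA,
                       lbp_target_um_per_px = 5,
                       svm_cost = 1,
                       rng_seed = 1L) {
  structure(list(patch_size = as.integer(patch_size),
                 threshold_method = threshold_method,
                 connectivity = as.integer(connectivity),
                 lambda = as.numeric(lambda),
                 logistic_scale = as.numeric(logistic_scale),
                 seed_erosion_px = if (is.na(seed_erosion_px)) NA_real_
                                   else as.numeric(seed_erosion_px),
                 lbp_target_um_per_px = as.numeric(lbp_target_um_per_px),
                 svm_cost = as.numeric(svm_cost),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Write / read a configuration file
#'
#' Flat `key=value` text, one entry per line; unknown keys are rejected so
#' typos fail loudly.
#'
#' @param config a [run_config].
#' @param path file path.
#' @return `read_run_config` returns a [run_config].
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s=%s", k, format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  args <- as.list(defaults)
  for (i in seq_along(keys)) {
    k <- keys[i]
    args[[k]] <- if (is.character(defaults[[k]])) vals[i]
                 else if (vals[i] == "NA") NA
                 else as.numeric(vals[i])
  }
  do.call(run_config, args)
}
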