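#' Model and protocol configuration
#'
#' A flat registry of every constant the model uses, with the study's
#' default values.  All weights and efficacies are peak conductance
#' increments in nS (negative sign selects the inhibitory receptor), rates
#' are in Hz, durations in ms unless suffixed `_s`.
#'
#' Key groups:
#' * network: `n_in`, `n_re`, `n_tc`, `group_size`, fixed weights
#'   `w_in_cx`, `w_cx_in`, `w_tc_re`, `w_re_tc`, `w_in_in`, `w_re_re`, the
#'   sleep override `w_in_cx_sleep`, plastic initial values `w0_*` and
#'   ceilings `wmax_*`;
#' * plasticity: `stdp_lam`, `stdp_tau`, `alpha_train`, `alpha_sleep`;
#' * drives: contextual (`rate_ctx`, `eff_ctx`), inhibitory training drive
#'   (`rate_in_drive`, `eff_in_drive`), thalamic feature drive
#'   (`rate_feat`, `eff_feat`), sleep cortical noise (`rate_noise`,
#'   `eff_noise`);
#' * neuron/integration: `b_wake`, `b_sleep`, `t_ref`, `dt`, `kernel`
#'   (`"exp"` or `"alpha"` synaptic kernel);
#' * protocol timing: `present_ms`, `gap_ms`, `retrieve_ms`,
#'   `retrieve_gap_ms`, `sleep_s`, `epoch_s`;
#' * experiment: `n_classes`, `n_instances`, `within`, `cross`,
#'   `n_holdout`, `thalamic_feedback`, `awake_control`, `seed`, `record`
#'   (populations whose spikes are kept).
#'
#' @param ... overrides of the defaults by name; unknown names error.
#' @return An object of class `somnet_config`.
#' @export
#' @examples
#' cf <- somnet_config(sleep_s = 60)
#' cf$sleep_s
somnet_config <- function(...) {
  defaults <- list(
    # populations / connectivity
    n_in = 200, n_re = 200, n_tc = 324, group_size = 20,
    w_in_cx = -4, w_cx_in = 60, w_tc_re = 10, w_re_tc = -10,
    w_in_in = -1, w_re_re = -1, w_in_cx_sleep = -2,
    w0_cx_cx = 1, w0_cx_tc = 1, w0_tc_cx = 1,
    wmax_cx_cx = 150, wmax_cx_tc = 130, wmax_tc_cx = 5.5,
    # plasticity
    stdp_lam = 0.005, stdp_lam_sleep = 0.002, stdp_tau = 20, alpha_train = 1, alpha_sleep = 3,
    # external drives
    rate_ctx = 2000, eff_ctx = 12.5,
    rate_in_drive = 10000, eff_in_drive = 1.85,
    rate_feat = 30000, eff_feat = 21,
    rate_noise = 700, eff_noise = 17,
    # neuron / integration
    b_wake = 5, b_sleep = 60, b_in = 80.5, b_tc = 80.5, b_re = 80.5,
    t_ref = 0.5, dt = 0.1, delay_ms = 0, kernel = "alpha",
    # protocol timing
    present_ms = 6000, gap_ms = 500,
    retrieve_ms = 500, retrieve_gap_ms = 250,
    sleep_s = 200, epoch_s = 100,
    # experiment
    n_classes = 3, n_instances = 3, within = 0.75, cross = 0.35,
    n_holdout = 4, holdout_within = 0.65, thalamic_feedback = TRUE, awake_control = FALSE,
    seed = 1, record = c("cx", "tc"))
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  num <- vapply(defaults, is.numeric, logical(1))
  if (!all(vapply(defaults[num], function(x) all(is.finite(x)), logical(1))))
    stop("all numeric configuration values must be finite")
  structure(defaults, class = "somnet_config")
}

#' @export
print.somnet_config <- function(x, ...) {
  cat("<somnet_config>\n")
  for (k in names(x))
    cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

#' Read a configuration from a flat key-value text file
#'
#' Lines have the form `key = value`; blank lines and lines starting with
#' `#` are ignored.  Values are coerced to the type of the corresponding
#' default; the `record` key takes a comma-separated population list.
#' Unknown keys are rejected by name.
#'
#' @param path file path.
#' @return A [somnet_config()] with the file's overrides merged in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- somnet_config()
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", key)
    ref <- defaults[[key]]
    over[[key]] <-
      if (is.logical(ref)) as.logical(val)
      else if (is.numeric(ref)) as.numeric(val)
      else if (key == "record") strsplit(val, ",")[[1]]
      else val
  }
  do.call(somnet_config, over)
}

#' Write a configuration to a flat key-value text file
#'
#' @param config a [somnet_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(config[[k]], collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read spike rasters
#'
#' Rasters are stored as a three-column tab-separated table
#' (`time_ms`, `neuron`, `pop`) sorted by time; reading enforces the sort
#' order and round-trips exactly.
#'
#' @param raster a raster tibble (`time_ms`, `neuron`, `pop`).
#' @param path file path.
#' @return `write_raster()` returns `path` invisibly; `read_raster()`
#'   returns the raster tibble.
#' @export
write_raster <- function(raster, path) {
  stopifnot(all(c("time_ms", "neuron", "pop") %in% names(raster)))
  raster <- dplyr::arrange(raster, .data$time_ms, .data$neuron)
  write.table(raster[, c("time_ms", "neuron", "pop")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_ms", "neuron", "pop")))
    stop("not a raster file (expected columns time_ms, neuron, pop)")
  if (is.unsorted(df$time_ms))
    stop("raster file is not sorted by time")
  tibble::as_tibble(df)
}

#' Persist weight snapshots as plain-text matrices
#'
#' Each projection matrix is written as a TSV file `<name>.tsv` inside
#' `dir`, with a `meta.tsv` recording phase, time and seed.
#'
#' @param snapshots named list of weight matrices.
#' @param dir output directory (created if missing).
#' @param meta named list of scalar metadata.
#' @return `dir`, invisibly.
#' @export
write_weights <- function(snapshots, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(snapshots)) {
    write.table(snapshots[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (length(meta)) {
    mdf <- data.frame(key = names(meta),
                      value = vapply(meta, function(x)
                        paste(x, collapse = ","), character(1)))
    write.table(mdf, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_weights
#' @param name projection name to read back.
#' @export
read_weights <- function(dir, name) {
  f <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(f)) stop("no stored matrix named ", name, " in ", dir)
  as.matrix(read.delim(f, header = FALSE))
}
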