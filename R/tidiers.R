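#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the metrics of a protocol report
#'
#' Computes the report's summary measurements -- held-out accuracy before
#' and after the offline phase, post/pre weight ratio per block category,
#' mean slow-oscillation frequency and median Up-state duration, the
#' firing-rate rotation trend, and the mean absolute recurrent weight
#' change -- and returns them in long form.
#'
#' @param x a [run_full_protocol()] report.
#' @param ... unused.
#' @return A tibble with columns `metric`, `value`.
#' @export
tidy.somnet_report <- function(x, ...) {
  out <- list()
  add <- function(metric, value)
    out[[length(out) + 1]] <<- tibble::tibble(metric = metric,
                                              value = as.numeric(value))
  if (!is.null(x$net$log$classify_pre)) {
    add("accuracy_pre", report_accuracy(x, "pre"))
    add("accuracy_post", report_accuracy(x, "post"))
  }
  bs <- report_block_stats(x)
  for (k in seq_len(nrow(bs)))
    add(paste0("ratio_", bs$category[k]), bs$ratio[k])
  so <- report_so(x)
  add("so_hz_mean", mean(so$so_hz))
  add("up_ms_median", stats::median(so$median_up_ms, na.rm = TRUE))
  add("weight_change_mean_abs", report_weight_change(x))
  rc <- try(report_rate_change(x), silent = TRUE)
  if (!inherits(rc, "try-error")) add("rate_trend", rc$trend)
  dplyr::bind_rows(out)
}

#' One-row summary of a protocol report
#'
#' @param x a [run_full_protocol()] report.
#' @param ... unused.
#' @return A one-row tibble: seed, condition flags, problem size, sleep
#'   duration, slow-oscillation frequency and pre/post accuracy.
#' @export
glance.somnet_report <- function(x, ...) {
  so <- report_so(x)
  tibble::tibble(
    seed = x$seed,
    n_images = x$net$n_images,
    n_classes = length(unique(x$net$groups$class)),
    thalamic_feedback = x$config$thalamic_feedback,
    awake_control = x$config$awake_control,
    sleep_s = x$config$sleep_s,
    so_hz = mean(so$so_hz),
    accuracy_pre = if (is.null(x$net$log$classify_pre)) NA_real_
      else report_accuracy(x, "pre"),
    accuracy_post = if (is.null(x$net$log$classify_post)) NA_real_
      else report_accuracy(x, "post"))
}
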