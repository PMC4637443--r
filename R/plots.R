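#' Detection-rate curves across lead systems
#'
#' Plots the detection rate as a function of the decision threshold, one
#' curve per acquisition scenario, for one ST-deviation feature.
#'
#' @param object An `ischemia_study`.
#' @param feature `"stsd"`, `"kpd"` or `"k_elevation"`.
#' @param thresholds Threshold vector (uV); defaults to a fine sweep over
#'   the feature's standard grid range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ischemia_study <- function(object, feature = "kpd",
                                    thresholds = NULL, ...) {
  if (is.null(thresholds)) {
    rng <- range(threshold_grid(if (feature == "stsd") "stsd_grid" else "kpd_grid"))
    thresholds <- seq(rng[1], rng[2], length.out = 100)
  }
  scen <- unique(object$table$scenario)
  df <- purrr::map_dfr(scen, function(sc) {
    tibble::tibble(scenario = sc, threshold = thresholds,
                   rate = detection_rate(object, sc, feature, thresholds))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$rate,
                                   colour = .data$scenario)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "threshold (µV)", y = "detection rate",
                  colour = "lead system",
                  title = paste("Detection rate vs threshold,", feature)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.detection_report <- function(object, ...) {
  by <- attr(object, "by")
  df <- tibble::as_tibble(unclass(object))
  if (by == "lead") {
    return(ggplot2::ggplot(df, ggplot2::aes(factor(.data$segment), .data$lead,
                                            fill = .data$rate)) +
             ggplot2::geom_tile() +
             ggplot2::labs(x = "AHA segment", y = "lead",
                           fill = "avg. rate") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$level), .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = by, y = "grid-averaged detection rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot ECG traces
#'
#' @param object An `ecg_record`.
#' @param leads Leads to show (default: up to the first 12).
#' @param ... Unused.
#' @return A ggplot object, one facet per lead.
#' @export
autoplot.ecg_record <- function(object, leads = NULL, ...) {
  if (is.null(leads)) leads <- head(object$lead_names, 12)
  df <- purrr::map_dfr(leads, function(l) {
    tibble::tibble(lead = l, time_ms = object$times,
                   uv = object$signals[l, ])
  })
  df$lead <- factor(df$lead, levels = leads)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "signal (µV)") +
    ggplot2::theme_minimal()
}

#' Rate-vs-threshold comparison of the two ST features
#'
#' @param study An `ischemia_study`.
#' @param scenario Scenario to compare in.
#' @return A ggplot object with one curve per feature.
#' @export
plot_feature_comparison <- function(study, scenario = "12-lead") {
  thresholds <- seq(9, 240, length.out = 120)
  df <- purrr::map_dfr(c("stsd", "kpd", "k_elevation"), function(f) {
    tibble::tibble(feature = f, threshold = thresholds,
                   rate = detection_rate(study, scenario, f, thresholds))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$rate,
                                   colour = .data$feature)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "threshold (µV)", y = "detection rate",
                  title = paste("Feature comparison,", scenario)) +
    ggplot2::theme_minimal()
}
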