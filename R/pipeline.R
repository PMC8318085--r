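#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis pipeline with its
#' module default, so a whole analysis is reproducible from one object.
#' Configurations round-trip through YAML via [write_config()] /
#' [read_config()].
#'
#' @param bin_size Rate-map pixel side, cm.
#' @param smoothing_sigma Rate-map smoothing sigma, bins.
#' @param hd_bin_width Head-direction bin width, degrees.
#' @param min_coverage Session-inclusion coverage threshold (fraction of
#'   arena pixels visited; default 0.90).
#' @param max_intra_isi,min_burst_spikes,min_ibi Burst-detector
#'   parameters, ms / count / ms.
#' @param n_downsample_reps Downsampling repetitions.
#' @param posterior_resolution Posterior grid points per axis.
#' @param thresholds A [classification_thresholds()] list.
#' @param seed Integer seed recorded with the configuration.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_size = 3, smoothing_sigma = 1,
                            hd_bin_width = 5, min_coverage = 0.9,
                            max_intra_isi = 6, min_burst_spikes = 2,
                            min_ibi = 50, n_downsample_reps = 200,
                            posterior_resolution = 1001,
                            thresholds = classification_thresholds(),
                            seed = 1L) {
  structure(list(bin_size = bin_size, smoothing_sigma = smoothing_sigma,
                 hd_bin_width = hd_bin_width, min_coverage = min_coverage,
                 max_intra_isi = max_intra_isi,
                 min_burst_spikes = min_burst_spikes, min_ibi = min_ibi,
                 n_downsample_reps = n_downsample_reps,
                 posterior_resolution = posterior_resolution,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to write.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (nm == "thresholds") next
    if (!is.null(raw[[nm]])) defaults[[nm]] <- raw[[nm]]
  }
  th <- classification_thresholds()
  for (nm in names(th))
    if (!is.null(raw$thresholds[[nm]])) th[[nm]] <- raw$thresholds[[nm]]
  defaults$thresholds <- th
  defaults$seed <- as.integer(defaults$seed)
  defaults
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Analyse one unit end to end
#'
#' Applies the session-inclusion gate (arena coverage of at least
#' `config$min_coverage`), computes the full [cell_report()], and
#' optionally renders the standard four-panel unit figure (rate heatmap,
#' path with spike locations, head-direction tuning, mean waveform) to a
#' PNG file.
#'
#' @param track A [position_track()].
#' @param spikes A [spike_train()].
#' @param config A [pipeline_config()].
#' @param unit_id Identifier for the unit.
#' @param figure_path Optional PNG output path for the unit panel.
#' @return A [cell_report()] with extra fields `excluded` (logical) and
#'   `exclusion_reason`; when excluded, metric fields are absent and only
#'   the coverage is reported.
#' @export
run_unit_analysis <- function(track, spikes, config = pipeline_config(),
                              unit_id = "unit", figure_path = NULL) {
  cov <- coverage(track, config$bin_size)
  if (cov < config$min_coverage) {
    message(sprintf("unit '%s' excluded: coverage %.2f below %.2f",
                    unit_id, cov, config$min_coverage))
    return(structure(list(unit_id = unit_id, excluded = TRUE,
                          exclusion_reason = sprintf(
                            "coverage %.3f < %.3f", as.numeric(cov),
                            config$min_coverage),
                          coverage = as.numeric(cov)),
                     class = "cell_report"))
  }
  rep <- cell_report(track, spikes, unit_id = unit_id,
                     bin_size = config$bin_size,
                     smoothing_sigma = config$smoothing_sigma,
                     hd_bin_width = config$hd_bin_width,
                     thresholds = config$thresholds)
  rep$excluded <- FALSE
  rep$coverage <- as.numeric(cov)
  if (!is.null(figure_path)) {
    grDevices::png(figure_path, width = 1600, height = 400, res = 120)
    on.exit(grDevices::dev.off())
    plot(rep)
  }
  rep
}

#' Four-panel unit figure
#'
#' Rate-map heatmap, path with spike overlay, head-direction tuning curve
#' in polar form, and the mean waveform (when present), in the layout
#' conventionally used to present open-field single units.
#'
#' @param x A [cell_report()].
#' @param ... Ignored.
#' @export
plot.cell_report <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    graphics::plot.new()
    graphics::title(sprintf("%s (excluded: %s)", x$unit_id,
                            x$exclusion_reason))
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 4), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  r <- field_rate(x$map)
  graphics::image(seq_len(x$map$nx) * x$map$bin_size,
                  seq_len(x$map$ny) * x$map$bin_size,
                  r, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  asp = 1, xlab = "", ylab = "",
                  main = sprintf("%s: %s (%.1f Hz peak)", x$unit_id,
                                 x$spatial_label, max(r, na.rm = TRUE)))
  graphics::plot(x$track$x, x$track$y, type = "l", col = "black",
                 asp = 1, xlab = "", ylab = "", main = "path + spikes")
  sx <- stats::approx(x$track$t, x$track$x, x$spikes$times, rule = 2)$y
  sy <- stats::approx(x$track$t, x$track$y, x$spikes$times, rule = 2)$y
  graphics::points(sx, sy, col = "blue", pch = 16, cex = 0.3)
  th <- x$hd$bin_centers * pi / 180
  rr <- x$hd$bin_rate
  rr[is.na(rr)] <- 0
  rmax <- max(rr, 1e-6)
  graphics::plot(rr / rmax * cos(th), rr / rmax * sin(th), type = "l",
                 asp = 1, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "", ylab = "",
                 main = sprintf("HD (R = %.2f)", x$hd$resultant_length))
  if (!is.null(x$spikes$waveform)) {
    wf <- x$spikes$waveform
    graphics::plot((seq_along(wf$samples) - 1) * wf$sample_interval,
                   wf$samples, type = "l", xlab = "us", ylab = "uV",
                   main = "waveform")
  } else {
    graphics::plot.new()
    graphics::title("no waveform")
  }
  invisible(x)
}

#' Condition-level presence analysis
#'
#' Accumulates per-recording presence flags into the spatial-cell and
#' nonspatial-cell contingency tables and computes the condition-level
#' statistics on the spatial table: the posterior over `(PC, PL)`, the
#' posterior probabilities `P(PC > PL)` and `P(PC > 5 PL)`, the Wald
#' statistic and Barnard's unconditional exact test.
#'
#' @param recordings A list; each element is a list with fields
#'   `condition` (`"control"` or `"lesion"`) and `reports` (list of
#'   [cell_report()]s for that recording).
#' @param config A [pipeline_config()].
#' @return An object of class `presence_analysis`: `spatial_table`,
#'   `nonspatial_table` (both [contingency_table()]s), `posterior`,
#'   `p_greater` (named vector for k = 1 and k = 5), `wald`, `barnard`.
#' @export
run_presence_analysis <- function(recordings,
                                  config = pipeline_config()) {
  conds <- vapply(recordings, function(r) r$condition, character(1))
  if (!any(conds == "control"))
    stop("no recordings in condition 'control'")
  if (!any(conds == "lesion"))
    stop("no recordings in condition 'lesion'")
  flags <- lapply(recordings, function(r) recording_presence(r$reports))
  spat <- vapply(flags, function(f) f$has_spatial, logical(1))
  nonspat <- vapply(flags, function(f) f$has_nonspatial, logical(1))
  ctrl <- conds == "control"
  spatial_table <- contingency_table(sum(spat[ctrl]), sum(ctrl),
                                     sum(spat[!ctrl]), sum(!ctrl))
  nonspatial_table <- contingency_table(sum(nonspat[ctrl]), sum(ctrl),
                                        sum(nonspat[!ctrl]), sum(!ctrl))
  post <- presence_posterior(spatial_table, config$posterior_resolution)
  structure(list(spatial_table = spatial_table,
                 nonspatial_table = nonspatial_table,
                 posterior = post,
                 p_greater = c(k1 = prob_greater(post, 1),
                               k5 = prob_greater(post, 5)),
                 wald = wald_statistic(spatial_table),
                 barnard = barnard_test(spatial_table)),
            class = "presence_analysis")
}

#' @export
print.presence_analysis <- function(x, ...) {
  cat("<presence_analysis>\n  spatial:    ")
  print(x$spatial_table)
  cat("  nonspatial: ")
  print(x$nonspatial_table)
  cat(sprintf("  P(PC > PL) = %.4f, P(PC > 5 PL) = %.4f\n",
              x$p_greater["k1"], x$p_greater["k5"]))
  cat(sprintf("  Wald %.3f, Barnard two-sided p %.4g\n",
              x$wald, x$barnard$p_two_sided))
  invisible(x)
}
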