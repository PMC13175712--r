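# Plotting and tabular reporting. Every figure has a data-frame
# counterpart (the plots are decorative, the CSVs canonical).

#' Plot an abundance-by-year series with intervals
#'
#' @param ab Data frame as returned by [abundance()].
#' @param main Plot title.
#' @param ... Further arguments to [graphics::plot()].
#' @return `ab`, invisibly.
#' @export
plot_abundance_series <- function(ab, main = "Abundance by primary period",
                                  ...) {
  graphics::plot(ab$primary, ab$n_hat, ylim = range(ab$ci_low, ab$ci_high),
                 xlab = "Primary period", ylab = "Estimated abundance",
                 pch = 19, xaxt = "n", main = main, ...)
  graphics::axis(1, at = ab$primary)
  graphics::segments(ab$primary, ab$ci_low, ab$primary, ab$ci_high)
  invisible(ab)
}

#' Plot power against percent decline
#'
#' One panel per initial population size, one line per secondary-occasion
#' count — the standard monitoring-design summary of a [run_power_grid()]
#' result.
#'
#' @param x A `"power_grid"` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.power_grid <- function(x, ...) {
  ns <- sort(unique(x$n_initial))
  ks <- sort(unique(x$n_secondary))
  op <- graphics::par(mfrow = c(1, length(ns)))
  on.exit(graphics::par(op))
  for (n0 in ns) {
    sub <- x[x$n_initial == n0, ]
    graphics::plot(NULL, xlim = range(sub$decline_pct), ylim = c(0, 1),
                   xlab = "Population decline (%)", ylab = "Power",
                   main = paste0("n = ", n0))
    graphics::abline(h = 0.8, lty = 3)
    for (i in seq_along(ks)) {
      s <- sub[sub$n_secondary == ks[i], ]
      graphics::lines(s$decline_pct, s$power, lty = i)
    }
    graphics::legend("bottomright", legend = paste(ks, "secondary"),
                     lty = seq_along(ks), bty = "n")
  }
  invisible(x)
}

#' Plot paired Lincoln-Petersen / robust-design interval comparison
#'
#' @param cmp Data frame from [compare_lp_rd()].
#' @param ... Further arguments to [graphics::plot()].
#' @return `cmp`, invisibly.
#' @export
plot_lp_rd <- function(cmp, ...) {
  xx <- rep(cmp$primary, 2) + rep(c(-0.1, 0.1), each = nrow(cmp))
  yy <- c(cmp$lp_n_hat, cmp$rd_n_hat)
  lo <- c(cmp$lp_low, cmp$rd_low)
  hi <- c(cmp$lp_high, cmp$rd_high)
  graphics::plot(xx, yy, ylim = range(lo, hi), pch = rep(c(1, 19),
                 each = nrow(cmp)),
                 xlab = "Primary period", ylab = "Estimated abundance",
                 xaxt = "n", ...)
  graphics::axis(1, at = cmp$primary)
  graphics::segments(xx, lo, xx, hi)
  graphics::legend("topright", legend = c("Lincoln-Petersen",
                                          "Robust design"),
                   pch = c(1, 19), bty = "n")
  invisible(cmp)
}

# JSON run manifest used by the command-line wrapper so outputs are
# reproducible from their recorded configuration.
run_manifest <- function(config, path) {
  manifest <- list(
    package = "cmrpower",
    version = as.character(utils::packageVersion("cmrpower")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)), path)
  }
  invisible(path)
}
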