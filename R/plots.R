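# Basic base-graphics renderings of a run: the heart-rate trace with ON
# phases marked, and the neurons-by-intervals activity raster.

#' Plot the heart-rate trace of a scenario
#'
#' Scaled heart rate against time, with stimulation-ON intervals shaded.
#'
#' @param x a `vns_scenario`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vns_scenario <- function(x, ...) {
  dt <- x$config_snapshot$parameters$interval_duration
  graphics::plot(x$hr_trace$time_seconds, x$hr_trace$H_scaled, type = "l",
                 xlab = "time (s)", ylab = "scaled heart rate H",
                 ylim = c(0, 1), main = x$scenario_name, ...)
  on <- which(x$on_mask)
  if (length(on))
    graphics::rect((on - 1) * dt, 0, on * dt, 0.03, col = "red",
                   border = NA)
  invisible(x)
}

#' Raster image of a network activity map
#'
#' Neurons (ordered branch / level / index) against intervals, activity as
#' grey level; for difference maps use a symmetric `zlim` such as
#' `c(-1, 1)`.
#'
#' @param map a neurons-by-intervals matrix (an `activity_map` or the output
#'   of [activity_difference_map()]).
#' @param zlim value range mapped to the palette; default `c(0, 1)`.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_activity_map <- function(map, zlim = c(0, 1), main = "activity map") {
  graphics::image(x = seq_len(ncol(map)), y = seq_len(nrow(map)),
                  z = t(map), zlim = zlim,
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "interval k", ylab = "neuron", main = main,
                  useRaster = TRUE)
  invisible(NULL)
}
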