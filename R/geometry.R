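#' Experiment interface geometry
#'
#' Pixel geometry of the two-choice interface: the category buttons are
#' `button_separation_x` pixels apart horizontally, and the Next button —
#' where the cursor starts every trial — sits centered between them,
#' `next_to_buttons_y` pixels below. Defaults are the layout used in the
#' validation interface (570 px between buttons, 472 px vertical offset).
#'
#' The expected horizontal displacement on a trial is therefore half the
#' button separation (cursor travels from the midline to one button);
#' `scaling_tolerance` is the relative band around that expectation outside
#' which a trial is deemed to show non-standard pixel scaling (browser zoom,
#' unusual device scaling).
#'
#' @param button_separation_x Horizontal distance between category buttons
#'   (px, default 570).
#' @param next_to_buttons_y Vertical distance from the Next button to the
#'   category buttons (px, default 472).
#' @param scaling_tolerance Relative tolerance around the expected half
#'   separation for the `weird_scaling` flag (default 0.25).
#' @param min_window_width,min_window_height Smallest browser window (px)
#'   that can display the full interface; smaller windows set the `wts`
#'   (window-too-small) flag. Defaults 800 x 600.
#' @return An object of class `mt_geometry`.
#' @export
geometry <- function(button_separation_x = 570,
                     next_to_buttons_y = 472,
                     scaling_tolerance = 0.25,
                     min_window_width = 800,
                     min_window_height = 600) {
  stopifnot(button_separation_x > 0, next_to_buttons_y > 0,
            scaling_tolerance > 0, scaling_tolerance < 1,
            min_window_width > 0, min_window_height > 0)
  structure(
    list(button_separation_x = button_separation_x,
         next_to_buttons_y = next_to_buttons_y,
         scaling_tolerance = scaling_tolerance,
         min_window_width = min_window_width,
         min_window_height = min_window_height),
    class = "mt_geometry"
  )
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat("<mt_geometry> buttons ", x$button_separation_x, " px apart, ",
      x$next_to_buttons_y, " px above Next; scaling tolerance ",
      x$scaling_tolerance, "; min window ", x$min_window_width, "x",
      x$min_window_height, " px\n", sep = "")
  invisible(x)
}
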