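#' Visual-field test grid matching the 24-2 perimetry pattern
#'
#' Builds the 54-location stimulus grid used by chromatic pupilloperimetry,
#' matching the Humphrey 24-2 test pattern: rows at y = +/-3, +/-9, +/-15
#' and +/-21 degrees, |x| up to 21 degrees, plus two nasal-extension points
#' at 27 degrees on the y = +/-3 rows. For the right eye the temporal visual
#' field is x > 0 and the nasal extension sits at x = -27; the left-eye grid
#' is the horizontal mirror (x -> -x) with identical target indices, so that
#' index k refers to mirror-symmetric field locations in the two eyes.
#'
#' Targets are indexed row by row from superior (y = +21) to inferior
#' (y = -21), left to right within a row (right-eye coordinates).
#'
#' @param eye `"right"` or `"left"`
#' @return `data.frame` with columns `index` (1..54), `x`, `y` (degrees,
#'   positive x = right of fixation), `temporal` (logical, temporal visual
#'   field for that eye), and attribute `eye`.
#' @examples
#' g <- makeGrid("right")
#' nrow(g)           # 54
#' sum(g$y == 3)     # 9 locations on the y = +3 row
#' @export
makeGrid <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  rows <- list(
    `21` = seq(-9, 9, by = 6),
    `15` = seq(-15, 15, by = 6),
    `9` = seq(-21, 21, by = 6),
    `3` = c(-27, seq(-21, 21, by = 6))
  )
  xs <- c()
  ys <- c()
  for (ay in c(21, 15, 9, 3, -3, -9, -15, -21)) {
    x <- rows[[as.character(abs(ay))]]
    xs <- c(xs, x)
    ys <- c(ys, rep(ay, length(x)))
  }
  if (eye == "left") xs <- -xs
  g <- data.frame(index = seq_along(xs), x = xs, y = ys)
  g$temporal <- if (eye == "right") g$x > 0 else g$x < 0
  attr(g, "eye") <- eye
  g
}
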