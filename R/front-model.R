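#' Medio-lateral arrest-front models
#'
#' A front model maps normalised midrib-to-margin distance `x` in \[0, 1\]
#' to the probability that a cell in the transition zone still expresses
#' the mitotic reporter. Three named presets encode the qualitative front
#' shapes reported for wild-type-like, round-cupped-mutant-like, and
#' margin-overgrowth-like leaves:
#'
#' * `"col0"` — linear decline from 0.25 at the midrib to 0.10 at the
#'   margin (mildly convex front: more division in the medial region).
#' * `"tni"` — 0.27 at the midrib, rising to a smooth interior peak of
#'   0.40 part-way to the margin, falling to 0.15 at the extreme margin
#'   (strongly convex front with a dip at the midrib). The two flanks are
#'   quadratic arcs with zero slope at the peak, so the front is smooth
#'   rather than kinked; the peak sits at `x = 0.35`.
#' * `"jawD"` — linear rise from 0.10 at the midrib to 0.30 at the margin
#'   (concave front: more division at the margin).
#'
#' @param preset one of `"col0"`, `"tni"`, `"jawD"`, or `"custom"`.
#' @param p for `preset = "custom"`, a vectorised function of `x` in
#'   \[0, 1\] returning probabilities in \[0, 1\].
#' @param name label used in printing.
#' @return An object of class `front_model`: a list with elements `p`
#'   (the probability function) and `name`.
#' @examples
#' fm <- front_model("col0")
#' fm$p(c(0, 0.5, 1))
#' @export
front_model <- function(preset = c("col0", "tni", "jawD", "custom"),
                        p = NULL, name = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (!is.function(p)) stop("custom front model needs a probability function `p`")
    fn <- p
    name <- name %||% "custom"
  } else {
    fn <- switch(preset,
      col0 = function(x) 0.25 - 0.15 * x,
      tni = function(x) {
        xp <- 0.35
        cl <- (0.40 - 0.27) / xp^2        # left flank coefficient
        cr <- (0.40 - 0.15) / (1 - xp)^2  # right flank coefficient
        ifelse(x < xp, 0.40 - cl * (xp - x)^2, 0.40 - cr * (x - xp)^2)
      },
      jawD = function(x) 0.10 + 0.20 * x
    )
    name <- preset
  }
  # probe the probability function across the domain
  pr <- fn(seq(0, 1, length.out = 201))
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
    stop("front model probabilities must lie in [0, 1] on [0, 1]")
  structure(list(p = fn, name = name), class = "front_model")
}

#' @export
print.front_model <- function(x, ...) {
  cat(sprintf("<front_model '%s'>  p(0) = %.3f, p(0.5) = %.3f, p(1) = %.3f\n",
              x$name, x$p(0), x$p(0.5), x$p(1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
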