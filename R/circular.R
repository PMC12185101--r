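#' Wrap angles into (-180, 180]
#'
#' Circular wrapping with the half-open convention used throughout: exactly
#' 180 degrees stays +180, never -180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
#' @examples
#' wrap_signed(c(340, -190, 180, 185))
wrap_signed <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Wrap angles into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Signed circular distance from a current direction to a previous direction
#'
#' Computed as previous minus current, wrapped into (-180, 180]. A positive
#' value means the previous direction was more clockwise than the current one
#' (axis convention of the behavioral bias curve); a distance of exactly 180
#' keeps the positive sign.
#'
#' @param prev_dir,cur_dir directions in degrees, in \[0, 360).
#' @return signed distance in degrees, in (-180, 180].
#' @export
#' @examples
#' signed_distance(20, 10)   # +10
#' signed_distance(355, 15)  # -20
#' signed_distance(185, 5)   # 180, not -180
signed_distance <- function(prev_dir, cur_dir) {
  wrap_signed(prev_dir - cur_dir)
}

#' Circular mean of angles in degrees
#'
#' @param x angles in degrees.
#' @return circular mean in [0, 360).
#' @export
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular-circular correlation coefficient
#'
#' Jammalamadaka-SenGupta correlation between two samples of angles:
#' \deqn{r = \frac{\sum \sin(a_i - \bar a)\sin(b_i - \bar b)}
#'   {\sqrt{\sum \sin^2(a_i - \bar a) \sum \sin^2(b_i - \bar b)}}}
#' where \eqn{\bar a}, \eqn{\bar b} are the circular means.
#'
#' @param a,b angle vectors in degrees, equal length.
#' @return correlation in \[-1, 1\].
#' @export
circ_corr <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok] * pi / 180
  b <- b[ok] * pi / 180
  if (length(a) < 3L) stop("circ_corr: fewer than 3 complete pairs")
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - am)
  sb <- sin(b - bm)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  sum(sa * sb) / den
}

# Evaluate an expression with a temporary RNG state; restores the caller's
# stream so simulation helpers do not perturb each other.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and stage indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 1009 + 12345) %% 2147483647
  }
  as.integer(h)
}
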