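#' @importFrom stats lm coef cor pnorm qnorm rnorm runif sd var median quantile
#' @importFrom stats shapiro.test t.test wilcox.test aov kruskal.test
#' @importFrom stats chisq.test fisher.test cor.test glm binomial anova add1
#' @importFrom stats complete.cases pchisq pf qf logLik as.formula setNames
#' @importFrom stats predict confint rbinom
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices of identical dimension.
#' @return Dice coefficient in \[0, 1\]; 1 for identical non-empty masks.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Hash a list of settings into a short hex string for run manifests.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  # simple polynomial rolling hash, stable across sessions
  h <- 0
  for (byte in utf8ToInt(as.character(s))) {
    h <- (h * 31 + byte) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Rasterize a closed polyline onto a binary pixel grid
#'
#' Pixels are marked along each segment by dense sub-pixel sampling, giving an
#' 8-connected curve. Coordinates are (row, col), 1-based.
#'
#' @param poly two-column matrix of (row, col) vertex coordinates; the curve is
#'   closed implicitly (last vertex connects back to the first).
#' @param size integer image side length (square output).
#' @return logical `size x size` matrix with the curve pixels set.
#' @export
rasterize_polyline <- function(poly, size) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  pts <- rbind(poly, poly[1, , drop = FALSE])
  out <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    n <- max(2L, ceiling(max(abs(p1 - p0)) * 4))
    t <- seq(0, 1, length.out = n)
    r <- round(p0[1] + t * (p1[1] - p0[1]))
    c <- round(p0[2] + t * (p1[2] - p0[2]))
    keep <- r >= 1 & r <= size & c >= 1 & c <= size
    out[cbind(r[keep], c[keep])] <- TRUE
  }
  out
}
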