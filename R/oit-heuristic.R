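## Heuristic orientation-invariant transformation.
##
## A tri-axial sequence v[n] is mapped to nine channels that depend only on
## rotation-invariant geometry:
##   w1 = |v|          w2 = |dv|           w3 = |ddv|
##   w4 = angle(v[n], v[n+1])
##   w5 = angle(dv[n], dv[n+1])
##   w6 = angle(ddv[n], ddv[n+1])
##   w7 = angle(p[n], p[n+1]),  p[n] = v[n]  x v[n+1]
##   w8 = angle(q[n], q[n+1]),  q[n] = dv[n] x dv[n+1]
##   w9 = angle(r[n], r[n+1]),  r[n] = ddv[n] x ddv[n+1]
## where dv/ddv are first/second-order time differences and p, q, r are the
## (unnormalized) rotation axes between consecutive samples.  Rotating the
## whole block by a constant proper rotation leaves all nine channels
## unchanged: rotations preserve norms, angles, and map cross products to the
## rotated cross product.

col_norms <- function(m) sqrt(colSums(m * m))

cross_cols <- function(a, b) {
  rbind(a[2L, ] * b[3L, ] - a[3L, ] * b[2L, ],
        a[3L, ] * b[1L, ] - a[1L, ] * b[3L, ],
        a[1L, ] * b[2L, ] - a[2L, ] * b[1L, ])
}

#' First-order time difference of a tri-axial block
#'
#' Column `n` of the result equals column `n + 1` minus column `n` of the
#' input. Differencing commutes with any constant rotation of the block.
#'
#' @param m Real 3 x L matrix with `L >= 2`.
#' @return A 3 x (L - 1) matrix.
#' @export
first_difference <- function(m) {
  m <- as.matrix(m)
  L <- ncol(m)
  if (L < 2L) stop("need at least 2 columns to difference, got ", L)
  m[, 2:L, drop = FALSE] - m[, 1:(L - 1L), drop = FALSE]
}

#' Angle between two 3-vectors
#'
#' `acos` of the normalized inner product, with the argument clipped to
#' `[-1, 1]` to guard against floating-point round-off. If either vector is
#' the zero vector the angle is undefined and is set to 0 by convention.
#'
#' @param u,w Numeric 3-vectors.
#' @return Angle in radians, in `[0, pi]`.
#' @export
angle_between <- function(u, w) {
  nu <- sqrt(sum(u * u)); nw <- sqrt(sum(w * w))
  if (nu == 0 || nw == 0) return(0)
  acos(min(1, max(-1, sum(u * w) / (nu * nw))))
}

## Columnwise angle between paired columns of two 3 x n matrices, with the
## same zero-vector and clipping conventions as angle_between().
col_angles <- function(a, b) {
  na <- col_norms(a); nb <- col_norms(b)
  dot <- colSums(a * b)
  denom <- na * nb
  arg <- ifelse(denom == 0, 1, pmin(1, pmax(-1, dot / ifelse(denom == 0, 1, denom))))
  acos(arg) * (denom != 0)
}

#' Nine-channel heuristic orientation-invariant transform
#'
#' Transforms a 3 x L block into a 9 x (L - 4) matrix of orientation-invariant
#' channels (see the file header for the channel list). The deepest stencil
#' (`w9`) needs five consecutive samples, so all channels are aligned to the
#' common valid range of length `L - 4` to form a rectangular output.
#'
#' @param block Real 3 x L matrix with `L >= 5`.
#' @return A 9 x (L - 4) matrix with rownames `w1` ... `w9`. Rows 1-3 are
#'   non-negative norms; rows 4-9 are angles in `[0, pi]`.
#' @export
heuristic_transform <- function(block) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == 3L)
  L <- ncol(block)
  if (L < 5L)
    stop("segment too short for the heuristic transform: need L >= 5, got ", L)
  Lp <- L - 4L
  i0 <- 1:Lp          # common valid range
  i1 <- 2:(Lp + 1L)
  d1 <- first_difference(block)   # 3 x (L-1)
  d2 <- first_difference(d1)      # 3 x (L-2)
  p <- cross_cols(block[, 1:(L - 1L), drop = FALSE], block[, 2:L, drop = FALSE])
  q <- cross_cols(d1[, 1:(L - 2L), drop = FALSE], d1[, 2:(L - 1L), drop = FALSE])
  r <- cross_cols(d2[, 1:(L - 3L), drop = FALSE], d2[, 2:(L - 2L), drop = FALSE])
  out <- rbind(
    w1 = col_norms(block)[i0],
    w2 = col_norms(d1)[i0],
    w3 = col_norms(d2)[i0],
    w4 = col_angles(block[, i0, drop = FALSE], block[, i1, drop = FALSE]),
    w5 = col_angles(d1[, i0, drop = FALSE], d1[, i1, drop = FALSE]),
    w6 = col_angles(d2[, i0, drop = FALSE], d2[, i1, drop = FALSE]),
    w7 = col_angles(p[, i0, drop = FALSE], p[, i1, drop = FALSE]),
    w8 = col_angles(q[, i0, drop = FALSE], q[, i1, drop = FALSE]),
    w9 = col_angles(r[, i0, drop = FALSE], r[, i1, drop = FALSE]))
  out
}

#' Per-sample Euclidean norm of a tri-axial block
#'
#' The simplest proper orientation-invariant transform; equals channel `w1`
#' of [heuristic_transform()] on the shared index range (computed by the same
#' norm routine). No truncation is applied.
#'
#' @param block Real 3 x L matrix.
#' @return A 1 x L matrix.
#' @export
euclidean_norm_transform <- function(block) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == 3L)
  matrix(col_norms(block), nrow = 1L, dimnames = list("w1", NULL))
}

#' Keep the first 3, 6 or 9 heuristic channels
#'
#' The three- and six-element variants trade discriminative detail for
#' runtime on constrained platforms; channel order is preserved.
#'
#' @param ch Output of [heuristic_transform()].
#' @param n One of 3, 6, 9.
#' @return The first `n` rows of `ch`.
#' @export
truncate_channels <- function(ch, n) {
  if (!n %in% c(3L, 6L, 9L)) stop("n must be one of 3, 6, 9; got ", n)
  ch[seq_len(n), , drop = FALSE]
}
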