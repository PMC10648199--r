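#' Wrap angles to the half-open interval (-180, 180]
#'
#' Angular differences between backbone dihedrals are only meaningful modulo
#' 360 degrees; all angular arithmetic in the package goes through this wrap
#' before squaring or averaging.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every element in (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 180, 359))
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

# circular mean of angles in degrees
circular_mean <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# dihedral angle (degrees, IUPAC sign convention) defined by four points
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# coerce a backbone representation (n x 3 matrix or a tibble with
# x/y/z columns) to a plain coordinate matrix
as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("coordinate matrix must have 3 columns")
    return(unname(x))
  }
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      abort("coordinate data frame must have columns x, y, z")
    }
    return(unname(as.matrix(x[, c("x", "y", "z")])))
  }
  abort("cannot interpret `x` as coordinates (need n x 3 matrix or x/y/z data frame)")
}

# population standard deviation (divides by n, not n - 1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
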