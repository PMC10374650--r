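# Internal 3D geometry helpers.  Coordinates are n x 3 matrices in
# Angstrom; angles are returned in degrees.  The dihedral follows the
# IUPAC convention (trans = 180 degrees).

vnorm <- function(v) sqrt(sum(v * v))
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dist3 <- function(x, i, j) vnorm(x[j, ] - x[i, ])

angle3 <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  cosv <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

dihedral4 <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# out-of-plane angle of the bond center->l against the plane through
# (center, j, k); 0 for a planar arrangement
improper4 <- function(x, center, j, k, l) {
  n <- vcross(x[j, ] - x[center, ], x[k, ] - x[center, ])
  u <- x[l, ] - x[center, ]
  s <- sum(n * u) / (vnorm(n) * vnorm(u))
  asin(pmin(1, pmax(-1, s))) * 180 / pi
}

# Z-matrix style placement: D bonded to C at distance r, angle D-C-B =
# theta (deg), dihedral D-C-B-A = phi (deg)
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- (C - B) / vnorm(C - B)
  n <- vcross(B - A, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  C + r * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

# build a chain of positions from (r, theta, phi) triples; entry k (1-based
# along the chain) uses the three previously placed atoms as references
chain_coords <- function(r, theta = NULL, phi = NULL) {
  n <- length(r) + 1L
  x <- matrix(0, n, 3)
  if (n >= 2L) x[2, ] <- c(r[1L], 0, 0)
  if (n >= 3L) {
    th <- theta[1L] * pi / 180
    x[3, ] <- x[2, ] + r[2L] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4L) {
    for (k in 4:n) {
      x[k, ] <- place_atom(x[k - 3L, ], x[k - 2L, ], x[k - 1L, ],
                           r[k - 1L], theta[k - 2L], phi[k - 3L])
    }
  }
  x
}

#' Read and write XYZ coordinate files
#'
#' Plain XYZ: an atom count line, a comment line, then one
#' `symbol x y z` line per site.
#'
#' @param path file path.
#' @return `read_xyz()` returns a list with `elements` (character) and
#'   `coords` (n x 3 matrix, Angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(stringr::str_trim(lines[1L])))
  if (is.na(n) || length(lines) < n + 2L) {
    rlang::abort(sprintf("malformed XYZ file: %s", path), class = "ffdat_format_error")
  }
  fields <- stringr::str_split(stringr::str_trim(lines[3:(n + 2L)]), "\\s+")
  bad <- lengths(fields) < 4L
  if (any(bad)) {
    rlang::abort(sprintf("malformed XYZ record on line %d", which(bad)[1L] + 2L),
                 class = "ffdat_format_error")
  }
  m <- do.call(rbind, fields)
  coords <- matrix(as.numeric(m[, 2:4]), ncol = 3)
  if (anyNA(coords)) {
    rlang::abort("non-numeric coordinate in XYZ file", class = "ffdat_format_error")
  }
  list(elements = m[, 1L], coords = coords)
}

#' @rdname read_xyz
#' @param elements character vector of site symbols.
#' @param coords n x 3 coordinate matrix.
#' @param comment comment line.
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  stopifnot(length(elements) == nrow(coords))
  writeLines(c(length(elements), comment,
               sprintf("%-3s %17.10f %17.10f %17.10f",
                       elements, coords[, 1], coords[, 2], coords[, 3])),
             path)
  invisible(path)
}
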