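# Chaos game representation of RNA/DNA sequences on the unit square.
# Vertex convention: A = (0,0), T/U = (1,0), C = (0,1), G = (1,1);
# the walk starts at the centre (0.5, 0.5) and each step moves halfway
# toward the current nucleotide's vertex. Every prefix lands on a unique
# point, so the final point encodes the whole sequence.

.cgr_vertices <- matrix(c(0, 0,   # A
                          1, 0,   # T (and U)
                          0, 1,   # C
                          1, 1),  # G
                        ncol = 2, byrow = TRUE,
                        dimnames = list(c("A", "T", "C", "G"), c("x", "y")))

.cgr_clean <- function(sequence) {
  s <- chartr("u", "U", toupper(sequence))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars[chars %in% rownames(.cgr_vertices)]
}

#' Chaos game representation trajectory of a sequence
#'
#' @param sequence RNA or DNA sequence string; characters outside
#'   A/C/G/T/U are dropped, U is treated as T.
#' @return an L x 2 matrix of points in the open unit square, one row
#'   per nucleotide of the filtered sequence.
#' @export
cgr_trajectory <- function(sequence) {
  chars <- .cgr_clean(sequence)
  if (length(chars) == 0L) {
    stop("empty sequence after filtering to A/C/G/T/U")
  }
  pts <- matrix(0, length(chars), 2L, dimnames = list(NULL, c("x", "y")))
  p <- c(0.5, 0.5)
  for (l in seq_along(chars)) {
    p <- 0.5 * (p + .cgr_vertices[chars[l], ])
    pts[l, ] <- p
  }
  pts
}

#' Decode a CGR point back to its generating sequence
#'
#' Inverts the chaos game: the final point of a length-L trajectory lies
#' in the quadrant of its last nucleotide's vertex, and doubling the
#' point minus that vertex recovers the previous point. DNA alphabet is
#' returned (U appears as T).
#'
#' @param point length-2 numeric, the final trajectory point.
#' @param length number of nucleotides to recover.
#' @return the decoded sequence string.
#' @export
cgr_decode <- function(point, length) {
  p <- as.numeric(point)
  out <- character(length)
  for (l in seq(length, 1L)) {
    nt <- if (p[2] < 0.5) {
      if (p[1] < 0.5) "A" else "T"
    } else {
      if (p[1] < 0.5) "C" else "G"
    }
    out[l] <- nt
    p <- 2 * p - .cgr_vertices[nt, ]
  }
  paste(out, collapse = "")
}

#' Grid feature vector of a CGR trajectory
#'
#' Partitions the unit square into an N x N grid of half-open cells
#' (upper boundary clamped into the last cell) and computes, per cell i:
#' `X_i` = sum of abscissae and `Y_i` = sum of ordinates of the points in
#' the cell, and `Z_i` = z-score of the cell's point count against all
#' N^2 counts (population SD; all zero when the counts have zero
#' variance). Cells are enumerated y-major (row by row bottom-up) and the
#' feature vector interleaves (X_i, Y_i, Z_i) triples, length 3 N^2.
#'
#' @param trajectory L x 2 point matrix from [cgr_trajectory()].
#' @param grid_size N, cells per axis (default 8).
#' @return a `cgr_feature`: list with `grid_size`, `vector`,
#'   `trajectory_length`.
#' @export
cgr_feature_vector <- function(trajectory, grid_size = 8L) {
  stopifnot(is.matrix(trajectory), ncol(trajectory) == 2L,
            nrow(trajectory) >= 1L, grid_size >= 1L)
  N <- as.integer(grid_size)
  ix <- pmin(floor(trajectory[, 1L] * N), N - 1L)
  iy <- pmin(floor(trajectory[, 2L] * N), N - 1L)
  cell <- iy * N + ix + 1L                      # y-major enumeration
  ncell <- N * N
  X <- Y <- Num <- numeric(ncell)
  sums_x <- tapply(trajectory[, 1L], cell, sum)
  sums_y <- tapply(trajectory[, 2L], cell, sum)
  cnt <- table(cell)
  occ <- as.integer(names(cnt))
  X[occ] <- sums_x
  Y[occ] <- sums_y
  Num[occ] <- as.numeric(cnt)
  sd_pop <- sqrt(mean((Num - mean(Num))^2))
  Z <- if (sd_pop > 0) (Num - mean(Num)) / sd_pop else numeric(ncell)
  structure(list(grid_size = N,
                 vector = as.numeric(rbind(X, Y, Z)),
                 trajectory_length = nrow(trajectory)),
            class = "cgr_feature")
}
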