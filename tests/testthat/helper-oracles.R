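# Independent oracles, coded differently from the package internals.

# Cubic B-spline weights via the monomial coefficient matrix (rows B0..B3,
# columns 1, u, u^2, u^3) rather than the four piecewise polynomials.
oracle_basis_matrix <- matrix(c(
  1, -3,  3, -1,
  4,  0, -6,  3,
  1,  3,  3, -3,
  0,  0,  0,  1), nrow = 4, byrow = TRUE) / 6

oracle_basis <- function(l, u) {
  drop(outer(u, 0:3, "^") %*% oracle_basis_matrix[l + 1, ])
}

# Cardinal (centered) cubic B-spline: the weight a control point at
# lattice position p contributes at lattice coordinate t is bs3(t - p).
oracle_bs3 <- function(d) {
  ad <- abs(d)
  ifelse(ad < 1, (4 - 6 * ad^2 + 3 * ad^3) / 6,
         ifelse(ad < 2, (2 - ad)^3 / 6, 0))
}

# Brute-force single-level displacement: sum over ALL control points of the
# lattice, no support shortcut, weights from oracle_bs3.
oracle_level_displacement <- function(lattice, point) {
  nd <- length(lattice$domain_shape)
  t <- point / lattice$spacing
  n_int <- lattice$grid_shape - 3L
  disp <- numeric(nd)
  idx_grid <- as.matrix(do.call(expand.grid,
                                lapply(seq_len(nd), function(a) (-1):(n_int[a] + 1L))))
  for (r in seq_len(nrow(idx_grid))) {
    p <- idx_grid[r, ]
    w <- prod(oracle_bs3(t - p))
    if (w != 0)
      disp <- disp + w * control_point(lattice, p)
  }
  disp
}

# Random lattice with displacements drawn N(0, sd)
random_lattice <- function(domain_shape, spacing, sd = 2, level = 1L) {
  lat <- create_lattice(domain_shape, spacing, level)
  lat$displacements <- array(stats::rnorm(length(lat$displacements), sd = sd),
                             dim = dim(lat$displacements))
  lat
}

# Integer-shift oracle: content of `img` translated by integer `shift`
# per axis (positive = toward higher indices), fill 0 outside.
oracle_integer_shift <- function(img, shift) {
  d <- dim(img)
  out <- array(0, d)
  src <- lapply(seq_along(d), function(a) {
    v <- seq_len(d[a]) - shift[a]
    v
  })
  ok <- lapply(seq_along(d), function(a) src[[a]] >= 1 & src[[a]] <= d[a])
  if (length(d) == 2L) {
    out[ok[[1]], ok[[2]]] <- img[src[[1]][ok[[1]]], src[[2]][ok[[2]]]]
  } else {
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      img[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  }
  out
}

# 4-connected component count of a logical matrix (breadth-first fill).
count_components <- function(mask) {
  d <- dim(mask)
  seen <- matrix(FALSE, d[1], d[2])
  ncomp <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- (cur - 1L) %% d[1] + 1L
      j <- (cur - 1L) %/% d[1] + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > d[1] || nb[2] < 1L || nb[2] > d[2]) next
        k <- nb[1] + (nb[2] - 1L) * d[1]
        if (mask[k] && !seen[k]) {
          seen[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  ncomp
}
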