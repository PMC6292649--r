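# Knot screening via the Alexander polynomial evaluated at t = -1.
#
# The open chain is closed deterministically (termini pushed radially onto a
# large sphere and joined by an arc), optionally simplified by KMT triangle
# elimination, projected onto a generic plane, and the Alexander determinant
# of the crossing diagram is evaluated at t = -1. |Delta(-1)| = 1 for the
# unknot, 3 for the trefoil, 5 for the figure-eight knot.

# deterministic rotation list used to search for a generic projection plane
projection_rotations <- function(n = 24L) {
  golden <- (1 + sqrt(5)) / 2
  lapply(seq_len(n), function(k) {
    # quasi-random axis + angle from a low-discrepancy sequence
    u <- (k / golden) %% 1
    v <- (k / golden^2) %% 1
    w <- (k / golden^3) %% 1
    th <- acos(2 * u - 1)
    ph <- 2 * pi * v
    ax <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    ang <- 2 * pi * w + 0.4
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  })
}

# close an open chain: project both termini radially (from the centroid)
# onto a sphere of radius 3 x max extent, then join them by a great-circle
# arc on that sphere
close_chain <- function(x) {
  cen <- colMeans(x)
  xc <- sweep(x, 2, cen)
  R <- 3 * max(sqrt(rowSums(xc^2)))
  ends <- function(p) {
    r <- sqrt(sum(p^2))
    if (r < 1e-12) p <- c(R, 0, 0) else p <- p * R / r
    p
  }
  a <- ends(xc[1, ])
  b <- ends(xc[nrow(xc), ])
  # arc from b to a on the sphere
  ca <- sum(a * b) / R^2
  ang <- acos(max(-1, min(1, ca)))
  n_arc <- max(2L, ceiling(ang / (pi / 8)))
  if (ang < 1e-9) {
    arc <- NULL
  } else {
    axis <- c(b[2] * a[3] - b[3] * a[2],
              b[3] * a[1] - b[1] * a[3],
              b[1] * a[2] - b[2] * a[1])
    an <- sqrt(sum(axis^2))
    if (an < 1e-12) { # antipodal: pick any perpendicular axis
      axis <- c(-b[2], b[1], 0)
      an <- sqrt(sum(axis^2))
      if (an < 1e-12) {
        axis <- c(0, -b[3], b[2])
        an <- sqrt(sum(axis^2))
      }
    }
    axis <- axis / an
    ts <- seq(0, 1, length.out = n_arc + 1)[-c(1, n_arc + 1)]
    arc <- t(vapply(ts, function(tt) {
      th <- tt * ang
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3)
      Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      as.numeric(Rm %*% b)
    }, numeric(3)))
  }
  # closed polygon: x1..xn, out to B, along the sphere arc B -> A, then A;
  # the implicit closing edge A -> x1 is radial and cannot entangle
  rbind(xc, matrix(b, 1), arc, matrix(a, 1))
}

# does segment (p, q) intersect triangle (a, b, c)? vectorised over segments
segment_hits_triangle <- function(p, q, a, b, c, eps = 1e-12) {
  e1 <- b - a
  e2 <- c - a
  d <- q - p # n_seg x 3
  h1 <- d[, 2] * e2[3] - d[, 3] * e2[2]
  h2 <- d[, 3] * e2[1] - d[, 1] * e2[3]
  h3 <- d[, 1] * e2[2] - d[, 2] * e2[1]
  det <- e1[1] * h1 + e1[2] * h2 + e1[3] * h3
  ok <- abs(det) > eps
  s1 <- p[, 1] - a[1]; s2 <- p[, 2] - a[2]; s3 <- p[, 3] - a[3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / det
  q1 <- s2 * e1[3] - s3 * e1[2]
  q2 <- s3 * e1[1] - s1 * e1[3]
  q3 <- s1 * e1[2] - s2 * e1[1]
  v <- (d[, 1] * q1 + d[, 2] * q2 + d[, 3] * q3) / det
  tt <- (e2[1] * q1 + e2[2] * q2 + e2[3] * q3) / det
  hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
    tt >= -eps & tt <= 1 + eps
  hit[!is.finite(hit)] <- FALSE
  any(hit)
}

# KMT vertex reduction of a closed polygon: remove vertex i when triangle
# (i-1, i, i+1) is not pierced by any other segment. Does not change the knot
# type.
kmt_reduce <- function(x) {
  repeat {
    n <- nrow(x)
    if (n <= 4) return(x)
    removed <- FALSE
    i <- 1
    while (i <= nrow(x) && nrow(x) > 4) {
      n <- nrow(x)
      ip <- if (i == 1) n else i - 1
      inx <- if (i == n) 1 else i + 1
      a <- x[ip, ]; b <- x[i, ]; c <- x[inx, ]
      # all segments not touching vertices ip, i, in
      segs <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
      drop <- segs[, 1] %in% c(ip, i, inx) | segs[, 2] %in% c(ip, i, inx)
      segs <- segs[!drop, , drop = FALSE]
      hit <- if (nrow(segs) == 0) FALSE else
        segment_hits_triangle(x[segs[, 1], , drop = FALSE],
                              x[segs[, 2], , drop = FALSE], a, b, c)
      if (!hit) {
        x <- x[-i, , drop = FALSE]
        removed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!removed) return(x)
  }
}

# crossings of the xy-projection of a closed polygon; returns a data.frame
# with, per crossing, the chain positions (segment + parameter) of the two
# strands and which is the over-strand
diagram_crossings <- function(x, tol = 1e-9) {
  n <- nrow(x)
  i2 <- c(seq_len(n)[-1], 1)
  p <- x[, 1:2, drop = FALSE]
  crossings <- list()
  for (i in seq_len(n - 2)) {
    a1 <- p[i, ]; a2 <- p[i2[i], ]
    jmax <- if (i == 1) n - 1 else n
    js <- seq.int(i + 2, jmax)
    for (j in js) {
      b1 <- p[j, ]; b2 <- p[i2[j], ]
      d1 <- a2 - a1
      d2 <- b2 - b1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-14) next
      r <- b1 - a1
      s <- (r[1] * d2[2] - r[2] * d2[1]) / den
      t <- (r[1] * d1[2] - r[2] * d1[1]) / den
      if (s <= tol || s >= 1 - tol || t <= tol || t >= 1 - tol) next
      if (min(s, 1 - s, t, 1 - t) < 100 * tol) # too close to a vertex: retry
        return(NULL)
      z1 <- x[i, 3] + s * (x[i2[i], 3] - x[i, 3])
      z2 <- x[j, 3] + t * (x[i2[j], 3] - x[j, 3])
      if (abs(z1 - z2) < tol) return(NULL)
      crossings[[length(crossings) + 1]] <-
        data.frame(pos_a = i + s, pos_b = j + t, a_over = z1 > z2)
    }
  }
  if (length(crossings) == 0)
    return(data.frame(pos_a = numeric(0), pos_b = numeric(0),
                      a_over = logical(0)))
  cr <- do.call(rbind, crossings)
  # degenerate projection: coincident crossing points
  pts_u <- sort(c(cr$pos_a, cr$pos_b))
  if (any(diff(pts_u) < tol)) return(NULL)
  cr
}

# |Alexander polynomial at t = -1| from the crossing diagram
alexander_det <- function(cr) {
  n_cr <- nrow(cr)
  if (n_cr < 2) return(1L)
  # underpass positions along the chain, in order
  under_pos <- ifelse(cr$a_over, cr$pos_b, cr$pos_a)
  over_pos <- ifelse(cr$a_over, cr$pos_a, cr$pos_b)
  ord <- order(under_pos)
  under_pos <- under_pos[ord]
  over_pos <- over_pos[ord]
  n <- n_cr
  # arc k runs from underpass k-1 to underpass k (cyclic; arc 1 wraps)
  arc_of <- function(pos) {
    k <- findInterval(pos, under_pos)
    (k %% n) + 1L
  }
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    jin <- k
    jout <- (k %% n) + 1L
    i <- arc_of(over_pos[k])
    if (i == jin) {
      M[k, jin] <- M[k, jin] + 1
      M[k, jout] <- M[k, jout] - 1
    } else if (i == jout) {
      M[k, jin] <- M[k, jin] - 1
      M[k, jout] <- M[k, jout] + 1
    } else {
      # at t = -1: overpass 1 - t = 2, incoming t = -1, outgoing -1
      M[k, i] <- M[k, i] + 2
      M[k, jin] <- M[k, jin] - 1
      M[k, jout] <- M[k, jout] - 1
    }
  }
  minor <- M[-n, -n, drop = FALSE]
  as.integer(round(abs(det(minor))))
}

#' Knot invariant |Delta(-1)| of a chain conformation
#'
#' Closes the open chain deterministically, simplifies it by KMT triangle
#' elimination, projects it onto a generic plane (trying a fixed list of
#' rotations until the diagram is regular), and evaluates the Alexander
#' polynomial of the diagram at t = -1. Returns 1 for unknotted chains, 3
#' for the trefoil, 5 for the figure-eight knot. Invariant under rigid
#' transforms and chain reversal.
#'
#' @param conf N x 3 coordinate matrix (N >= 3), an open chain.
#' @param closed treat `conf` as already closed (skip the closure arc).
#' @param reduce apply KMT reduction before projecting (recommended; does
#'   not change the invariant).
#' @return Nonnegative integer |Delta(-1)|.
#' @export
alexander_polynomial <- function(conf, closed = FALSE, reduce = TRUE) {
  if (!is.matrix(conf) || ncol(conf) != 3 || nrow(conf) < 3)
    stop("conf must be an N x 3 matrix with N >= 3")
  x <- if (closed) sweep(conf, 2, colMeans(conf)) else close_chain(conf)
  if (reduce) x <- kmt_reduce(x)
  rots <- projection_rotations()
  scale <- max(abs(x))
  for (k in seq_along(rots)) {
    xk <- x
    if (k > length(rots) / 2) {
      # deterministic sub-angstrom jitter to break exact degeneracies
      # (e.g. coincident vertices); far below any bead separation, so the
      # topology is untouched
      u <- sin(seq_len(length(xk)) * 9301.77 * k)
      xk <- xk + matrix(u, nrow(xk), 3) * (1e-6 * scale)
    }
    cr <- diagram_crossings(xk %*% t(rots[[k]]))
    if (!is.null(cr)) return(alexander_det(cr))
  }
  stop("alexander_polynomial: no generic projection found (degenerate chain)")
}
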