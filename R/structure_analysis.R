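#' Distance-based root-mean-square deviation (DRMS)
#'
#' `DRMS(A,B) = sqrt( 2/(N(N-1)) * sum_{i>j} (r^A_ij - r^B_ij)^2 )`, a
#' rigid-motion-invariant metric on conformations built from internal
#' pairwise distances.
#'
#' @param confA,confB N x 3 coordinate matrices with equal N >= 2.
#' @return Nonnegative scalar (a).
#' @export
drms <- function(confA, confB) {
  if (!is.matrix(confA) || !is.matrix(confB) || ncol(confA) != 3 ||
      ncol(confB) != 3)
    stop("conformations must be N x 3 matrices")
  if (nrow(confA) != nrow(confB)) stop("conformations differ in bead count")
  if (nrow(confA) < 2) stop("need at least 2 beads")
  dA <- dist(confA)
  dB <- dist(confB)
  sqrt(mean((dA - dB)^2))
}

#' All-pairs DRMS matrix of an ensemble
#'
#' @param ensemble list of N x 3 coordinate matrices.
#' @return Symmetric matrix with zero diagonal.
#' @export
drms_matrix <- function(ensemble) {
  M <- length(ensemble)
  dl <- lapply(ensemble, dist)
  out <- matrix(0, M, M)
  if (M >= 2) {
    for (i in seq_len(M - 1)) {
      for (j in seq.int(i + 1, M)) {
        out[i, j] <- out[j, i] <- sqrt(mean((dl[[i]] - dl[[j]])^2))
      }
    }
  }
  out
}

# flat clusters from an hclust tree: merge subtrees whose merge distance is
# strictly below D_c (union-find over the merge history)
cut_below <- function(hc, D_c) {
  n <- length(hc$order)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cluster_of_merge <- integer(nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    if (hc$height[m] >= D_c) {
      cluster_of_merge[m] <- NA_integer_
      next
    }
    a <- hc$merge[m, 1]
    b <- hc$merge[m, 2]
    ia <- if (a < 0) -a else cluster_of_merge[a]
    ib <- if (b < 0) -b else cluster_of_merge[b]
    if (is.na(ia) || is.na(ib)) {
      cluster_of_merge[m] <- NA_integer_
      next
    }
    ra <- find(ia)
    rb <- find(ib)
    parent[rb] <- ra
    cluster_of_merge[m] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' Complete-linkage hierarchical clustering of conformations
#'
#' Agglomerative clustering under the complete-linkage rule (inter-cluster
#' distance = maximum pairwise distance between members), as used to group
#' sampled chromosome structures by DRMS. Flat clusters at the cut are the
#' subtrees whose merge distances are strictly below `D_c`.
#'
#' @param dmat symmetric distance matrix (e.g. from [drms_matrix()]).
#' @param D_c cut distance.
#' @return List of class `cluster_tree` with the `hclust` object (`tree`),
#'   `clusters` (integer assignment, 1-based cluster ids) and `D_c`.
#' @export
cluster_hierarchical <- function(dmat, D_c) {
  dmat <- as.matrix(dmat)
  if (nrow(dmat) != ncol(dmat) || max(abs(dmat - t(dmat))) > 1e-8)
    stop("dmat must be a symmetric distance matrix")
  if (nrow(dmat) == 1) {
    return(structure(list(tree = NULL, clusters = 1L, D_c = D_c,
                          method = "complete"), class = "cluster_tree"))
  }
  hc <- hclust(as.dist(dmat), method = "complete")
  structure(list(tree = hc, clusters = cut_below(hc, D_c), D_c = D_c,
                 method = "complete"),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  k <- length(unique(x$clusters))
  cat("<cluster_tree> ", length(x$clusters), " conformations, ",
      k, " clusters at D_c = ", x$D_c, " (", x$method, " linkage)\n", sep = "")
  invisible(x)
}

#' Dendrogram as a newick-style string
#'
#' Nested-parenthesis serialisation of the merge history with merge
#' distances as branch lengths.
#'
#' @param ct a `cluster_tree` (or `hclust`).
#' @export
as_newick <- function(ct) {
  hc <- if (inherits(ct, "cluster_tree")) ct$tree else ct
  if (is.null(hc)) return("(1);")
  node <- function(i, parent_h) {
    if (i < 0) return(paste0(-i, ":", format(parent_h / 2)))
    h <- hc$height[i]
    kids <- vapply(hc$merge[i, ], node, character(1), parent_h = h)
    paste0("(", kids[1], ",", kids[2], "):", format((parent_h - h) / 2))
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  kids <- vapply(hc$merge[top, ], node, character(1), parent_h = h)
  paste0("(", kids[1], ",", kids[2], ");")
}

#' Quality-threshold clustering
#'
#' Around every point, grows the largest candidate cluster whose diameter
#' (maximum intra-cluster distance) stays below `d_c`; the largest candidate
#' is removed from the pool, and the process repeats until every point is
#' assigned.
#'
#' @param dmat symmetric distance matrix.
#' @param d_c cluster diameter threshold.
#' @return List of integer index vectors (1-based), in removal order;
#'   clusters are disjoint and cover all indices.
#' @export
cluster_qt <- function(dmat, d_c) {
  dmat <- as.matrix(dmat)
  if (nrow(dmat) != ncol(dmat) || max(abs(dmat - t(dmat))) > 1e-8)
    stop("dmat must be a symmetric distance matrix")
  remaining <- seq_len(nrow(dmat))
  clusters <- list()
  while (length(remaining) > 0) {
    best <- integer(0)
    for (seed_pt in remaining) {
      members <- seed_pt
      cand <- setdiff(remaining, seed_pt)
      repeat {
        if (length(cand) == 0) break
        # for each candidate, diameter if added
        diam <- vapply(cand, function(p) max(dmat[p, members]), numeric(1))
        ok <- which(diam < d_c)
        if (length(ok) == 0) break
        add <- cand[ok[which.min(diam[ok])]]
        members <- c(members, add)
        cand <- setdiff(cand, add)
      }
      if (length(members) > length(best)) best <- sort(members)
    }
    clusters[[length(clusters) + 1]] <- best
    remaining <- setdiff(remaining, best)
  }
  clusters
}

#' Centroid structure of each cluster
#'
#' The centroid of a cluster is the member minimising the sum of its
#' distances to all other members; ties break to the smallest index.
#'
#' @param dmat symmetric distance matrix.
#' @param clusters integer assignment vector (as in `cluster_tree$clusters`)
#'   or list of index vectors (as from [cluster_qt()]).
#' @return Integer vector, one member index per cluster.
#' @export
cluster_centroids <- function(dmat, clusters) {
  dmat <- as.matrix(dmat)
  if (!is.list(clusters))
    clusters <- split(seq_along(clusters), clusters)
  vapply(clusters, function(members) {
    members <- as.integer(sort(members))
    s <- vapply(members, function(k) sum(dmat[k, members]), numeric(1))
    members[which.min(s)]
  }, integer(1), USE.NAMES = FALSE)
}

#' Ensemble contact map
#'
#' `c_ij = <f(r_ij)>`, the ensemble mean of the contact indicator.
#'
#' @param ensemble list of N x 3 coordinate matrices.
#' @param mu,r_c contact-function parameters (see [contact_indicator()]).
#' @return List of class `contact_map` with `matrix` (N x N, entries in
#'   (0, 1), diagonal f(0)) and `n_samples`.
#' @export
contact_map_from_ensemble <- function(ensemble, mu = 3, r_c = 1.5) {
  if (!is.list(ensemble) || length(ensemble) == 0)
    stop("ensemble must be a nonempty list of conformations")
  m <- cpp_contact_map(ensemble, mu, r_c)
  structure(list(matrix = m, n_samples = length(ensemble),
                 mu = mu, r_c = r_c),
            class = "contact_map")
}

#' Contact probability versus genomic distance
#'
#' `P(s) = sum_i c_{i,i+s} / (N - s)`: the mean of the s-th super-diagonal
#' of the contact map.
#'
#' @param map a `contact_map` (or plain contact matrix).
#' @return data.frame with columns `s` and `p`.
#' @export
contact_probability_curve <- function(map) {
  m <- if (inherits(map, "contact_map")) map$matrix else map
  N <- nrow(m)
  s <- seq_len(N - 1)
  p <- vapply(s, function(k) {
    i <- seq_len(N - k)
    mean(m[cbind(i, i + k)])
  }, numeric(1))
  data.frame(s = s, p = p)
}

#' Contact probability curve computed directly from an ensemble
#'
#' Equivalent to [contact_probability_curve()] on
#' [contact_map_from_ensemble()] but only accumulates the requested
#' diagonals, which is much cheaper for large ensembles.
#'
#' @param ensemble list of conformations.
#' @param s genomic separations to evaluate.
#' @param mu,r_c contact-function parameters.
#' @export
contact_probability_direct <- function(ensemble, s, mu = 3, r_c = 1.5) {
  N <- nrow(ensemble[[1]])
  s <- as.integer(s)
  if (any(s < 1 | s >= N)) stop("s out of range")
  data.frame(s = s, p = cpp_pscurve(ensemble, s, mu, r_c))
}

#' Mean spatial distance versus genomic separation
#'
#' `R(s) = sqrt(mean |r_{i+s} - r_i|^2)` over loci and the ensemble.
#'
#' @param ensemble list of N x 3 matrices (or a single matrix).
#' @param s_values separations to evaluate (default all 1..N-1).
#' @return data.frame with columns `s`, `r`, `n_pairs`.
#' @export
ree_curve <- function(ensemble, s_values = NULL) {
  if (is.matrix(ensemble)) ensemble <- list(ensemble)
  N <- nrow(ensemble[[1]])
  if (is.null(s_values)) s_values <- seq_len(N - 1)
  s_values <- as.integer(s_values)
  r2 <- vapply(s_values, function(s) {
    acc <- 0
    n <- 0
    for (cf in ensemble) {
      d <- cf[seq.int(1 + s, N), , drop = FALSE] -
        cf[seq_len(N - s), , drop = FALSE]
      acc <- acc + sum(d^2)
      n <- n + (N - s)
    }
    acc / n
  }, numeric(1))
  data.frame(s = s_values, r = sqrt(r2),
             n_pairs = (N - s_values) * length(ensemble))
}

#' Unweighted log-log power-law fit
#'
#' Least squares of `log(y) ~ log(x)` restricted to `window`; fitting
#' windows are always explicit.
#'
#' @param x,y positive data.
#' @param window length-2 numeric, inclusive range of `x` to fit.
#' @return List with `exponent`, `prefactor` and `n_points`.
#' @export
fit_power_law <- function(x, y, window = range(x)) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0 &
    x >= window[1] & x <= window[2]
  if (sum(keep) < 3) stop("fewer than 3 points in the fitting window")
  fit <- lm(log(y[keep]) ~ log(x[keep]))
  list(exponent = unname(coef(fit)[2]),
       prefactor = unname(exp(coef(fit)[1])),
       n_points = sum(keep))
}

#' Normalised radial density profile
#'
#' Shell histogram of distances from the chain centroid for the loci in
#' `subset`, normalised by that subset's mean density over the probed ball,
#' so a uniformly distributed subset gives a flat profile at 1.
#'
#' @param ensemble list of N x 3 matrices (or one matrix).
#' @param annotation optional [chrom_annotation] (needed when `subset` is a
#'   set of labels).
#' @param subset `NULL` for all loci, a character vector of labels, or an
#'   integer vector of 1-based locus indices.
#' @param n_bins number of radial shells.
#' @param r_max outer radius (default: maximum observed radius).
#' @return data.frame with `r_mid`, `density` (rho/rho0) and `n`.
#' @export
radial_density <- function(ensemble, annotation = NULL, subset = NULL,
                           n_bins = 25L, r_max = NULL) {
  if (is.matrix(ensemble)) ensemble <- list(ensemble)
  N <- nrow(ensemble[[1]])
  idx <- if (is.null(subset)) {
    seq_len(N)
  } else if (is.character(subset)) {
    if (is.null(annotation)) stop("label subset needs an annotation")
    which(annotation$labels %in% subset)
  } else {
    as.integer(subset)
  }
  if (length(idx) == 0) stop("empty subset")
  rads <- unlist(lapply(ensemble, function(cf) {
    cen <- colMeans(cf)
    sqrt(rowSums(sweep(cf[idx, , drop = FALSE], 2, cen)^2))
  }))
  if (is.null(r_max)) r_max <- max(rads) * (1 + 1e-9)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  counts <- tabulate(findInterval(rads, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  vshell <- 4 / 3 * pi * diff(edges^3)
  rho <- counts / vshell / length(ensemble)
  rho0 <- sum(counts) / (4 / 3 * pi * r_max^3) / length(ensemble)
  data.frame(r_mid = (edges[-1] + edges[-length(edges)]) / 2,
             density = rho / rho0, n = counts)
}

#' Write a contact map as dense TSV or sparse triplet text
#'
#' @param map a `contact_map`.
#' @param path output path.
#' @param format `"dense"` (N x N tab-separated matrix) or `"triplet"`
#'   (i, j, value rows for the upper triangle above `threshold`).
#' @param threshold minimum value kept in triplet output.
#' @export
write_contact_map <- function(map, path, format = c("dense", "triplet"),
                              threshold = 1e-4) {
  format <- match.arg(format)
  m <- if (inherits(map, "contact_map")) map$matrix else map
  if (format == "dense") {
    write.table(round(m, 6), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m, diag = TRUE) & m > threshold, arr.ind = TRUE)
    write.table(data.frame(i = idx[, 1], j = idx[, 2],
                           value = round(m[idx], 6)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
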