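# shared toy builders and independent oracles

# parameters with every heteropolymer coupling switched off
free_params <- function(bond_k = 1, bond_r0 = 1, ev_k = 0, wall_k = 0,
                        R_s = 10) {
  chrom_params(bond_k = bond_k, bond_r0 = bond_r0, ev_k = ev_k,
               hardcore_sigma = 1, type_matrix = matrix(0, 6, 6),
               ideal_gamma = numeric(2), loop_eps = 0,
               R_s = R_s, wall_k = wall_k)
}

# ideal (zero-rest-length Gaussian springs) phantom chain
rouse_params <- function() free_params(bond_k = 3, bond_r0 = 0)

uniform_annotation <- function(n, label = "NA") chrom_annotation(rep(label, n))

random_conformation <- function(n, sd = 2) matrix(rnorm(n * 3, sd = sd), ncol = 3)

# straight-line (fully extended) chain along x
extended_chain <- function(n) cbind(seq_len(n) - 1, 0, 0)

# independent R implementation of the decomposed energy (slow double loop)
energy_oracle <- function(conf, ann, par, confine = TRUE) {
  N <- nrow(conf)
  f <- function(r) 0.5 * (1 + tanh(par$mu * (par$r_c - r)))
  eb <- ee <- et <- el <- ei <- ec <- 0
  for (i in seq_len(N - 1)) {
    r <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    eb <- eb + 0.5 * par$bond_k * (r - par$bond_r0)^2
  }
  lset <- if (nrow(ann$loops)) paste(ann$loops[, 1], ann$loops[, 2]) else character(0)
  for (i in seq_len(N - 1)) for (j in seq.int(i + 1, N)) {
    r <- sqrt(sum((conf[j, ] - conf[i, ])^2))
    fr <- f(r)
    et <- et + par$type_matrix[ann$labels[i], ann$labels[j]] * fr
    if (paste(i - 1, j - 1) %in% lset) el <- el + par$loop_eps * fr
    d <- j - i
    if (d >= 2 && d <= par$d_max) ei <- ei + par$ideal_gamma[d] * fr
    if (d >= 2 && r < par$hardcore_sigma)
      ee <- ee + 0.5 * par$ev_k * (par$hardcore_sigma - r)^2
  }
  if (confine) for (i in seq_len(N)) {
    rr <- sqrt(sum(conf[i, ]^2))
    if (rr > par$R_s) ec <- ec + par$wall_k * (rr - par$R_s)^2
  }
  c(bonded = eb, excluded = ee, type = et, loop = el, ideal = ei,
    confinement = ec)
}

# naive agglomerative complete-linkage oracle: returns flat clusters (list of
# sorted index vectors) after merging while the minimum complete-linkage
# distance is below D_c
complete_linkage_oracle <- function(dmat, D_c) {
  clusters <- as.list(seq_len(nrow(dmat)))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestd) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    if (bestd >= D_c) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  clusters[order(vapply(clusters, min, numeric(1)))]
}

# canonical form of a flat clustering for comparison
canonical_clusters <- function(x) {
  if (!is.list(x)) x <- split(seq_along(x), x)
  x <- lapply(x, sort)
  unname(x[order(vapply(x, min, numeric(1)))])
}

# standard polygonal knots
unknot_polygon <- function(n = 12) {
  cbind(cos(2 * pi * seq_len(n) / n), sin(2 * pi * seq_len(n) / n), 0)
}
trefoil_polygon <- function(n = 120) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
}
figure8_polygon <- function(n = 160) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
}

# build a trajectory object directly from a T x N x 3 array
manual_trajectory <- function(frames, frame_interval = 1) {
  chromodyn:::new_trajectory(frames, frame_interval = frame_interval,
                             dt = NA_real_, seed = NA,
                             activity_profile = rep(1, dim(frames)[2]))
}
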