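#' Chromatin annotation object
#'
#' One record per 50 kb locus with a subcompartment label, plus an optional
#' list of loop-anchor pairs (0-based locus indices, i < j).
#'
#' @param labels character vector of subcompartment codes (see [chrom_types]).
#' @param loops integer matrix with two columns (i, j), 0-based, i < j.
#' @return An object of class `chrom_annotation` with fields `n_loci`,
#'   `labels` and `loops`.
#' @export
chrom_annotation <- function(labels, loops = NULL) {
  label_codes(labels) # validates
  n <- length(labels)
  if (n < 1L) stop("annotation needs at least one locus")
  if (is.null(loops)) loops <- matrix(integer(), ncol = 2L)
  loops <- matrix(as.integer(loops), ncol = 2L)
  if (nrow(loops) > 0L) {
    if (any(loops < 0L) || any(loops >= n))
      stop("loop indices must lie in [0, n_loci)")
    if (any(loops[, 1L] >= loops[, 2L]))
      stop("loop pairs must satisfy i < j")
    if (anyDuplicated(paste(loops[, 1L], loops[, 2L])))
      stop("duplicated loop pair")
  }
  structure(list(n_loci = n, labels = labels, loops = loops),
            class = "chrom_annotation")
}

#' @export
print.chrom_annotation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = chrom_types))
  cat("<chrom_annotation> ", x$n_loci, " loci (50 kb each), ",
      nrow(x$loops), " loops\n", sep = "")
  cat("  type counts: ", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n", sep = "")
  afrac <- mean(x$labels %in% active_types)
  cat(sprintf("  active (A1+A2) fraction: %.3f\n", afrac))
  invisible(x)
}

#' Fraction of loci carrying an active (A1/A2) label
#' @param annotation a [chrom_annotation]
#' @export
active_fraction <- function(annotation) {
  mean(annotation$labels %in% active_types)
}

#' Generate a blocky synthetic subcompartment barcode
#'
#' Labels are drawn as consecutive blocks of a single subcompartment type.
#' Block lengths are geometric (memoryless) with the configured mean, the
#' simplest one-parameter family producing megabase-scale blocky barcodes;
#' block types are i.i.d. with probabilities proportional to `type_weights`,
#' so the expected fraction of loci of each type equals its normalised weight.
#'
#' @param n_loci number of 50 kb loci (N).
#' @param mean_block_len mean block length in loci (default 20, i.e. ~1 Mb).
#' @param type_weights six non-negative weights in [chrom_types] order
#'   (B3, B2, B1, NA, A1, A2). The default puts 40% of mass on A1+A2,
#'   matching the active-locus fraction of the Chr10 barcode.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param target_active optional target fraction of A1+A2 loci. For short
#'   chains the block granularity makes the realised active fraction highly
#'   variable; when set, barcodes are redrawn (deterministic sub-seed
#'   sequence) until the realised fraction is within `active_tol` of the
#'   target.
#' @param active_tol acceptance half-width for `target_active`.
#' @return A [chrom_annotation] with empty loop list.
#' @export
generate_annotation <- function(n_loci,
                                mean_block_len = 20,
                                type_weights = c(B3 = 0.25, B2 = 0.15,
                                                 B1 = 0.12, "NA" = 0.08,
                                                 A1 = 0.22, A2 = 0.18),
                                seed = 1L,
                                target_active = NULL, active_tol = 0.03) {
  stopifnot_scalar(n_loci, "n_loci", positive = TRUE)
  if (n_loci < 2) stop("n_loci must be >= 2")
  stopifnot_scalar(mean_block_len, "mean_block_len", positive = TRUE)
  if (length(type_weights) != 6L || any(type_weights < 0))
    stop("type_weights must be 6 nonnegative reals")
  if (sum(type_weights) <= 0) stop("type_weights must not all be zero")
  p <- type_weights / sum(type_weights)
  draw <- function(s) {
    with_seed(s, {
      labels <- character(0L)
      # geometric block lengths with mean m: 1 + Geom(prob = 1/m)
      pr <- min(1, 1 / mean_block_len)
      while (length(labels) < n_loci) {
        len <- 1L + rgeom(1L, prob = pr)
        type <- sample(chrom_types, 1L, prob = p)
        labels <- c(labels, rep(type, len))
      }
      chrom_annotation(labels[seq_len(n_loci)])
    })
  }
  if (is.null(target_active)) return(draw(seed))
  for (k in 0:499) {
    ann <- draw(seed + k * 7919)
    if (abs(active_fraction(ann) - target_active) <= active_tol) return(ann)
  }
  stop("could not realise target_active = ", target_active,
       " within tolerance; widen active_tol or shorten blocks")
}

#' Draw CTCF-like loop anchor pairs
#'
#' Samples `n_loops` distinct anchor pairs (i, j) uniformly over all pairs
#' with `min_sep <= j - i <= max_sep`. With `bias_active = TRUE`, pairs whose
#' anchors both carry active labels get double weight.
#'
#' @param annotation a [chrom_annotation].
#' @param n_loops number of pairs to draw.
#' @param min_sep,max_sep admissible genomic separation range (loci).
#' @param seed integer seed.
#' @param bias_active logical; bias anchors towards A-type blocks.
#' @return The annotation with its `loops` field replaced.
#' @export
generate_loops <- function(annotation, n_loops, min_sep = 10L, max_sep = 100L,
                           seed = 1L, bias_active = FALSE) {
  stopifnot(inherits(annotation, "chrom_annotation"))
  n <- annotation$n_loci
  stopifnot_scalar(n_loops, "n_loops")
  if (n_loops < 0) stop("n_loops must be >= 0")
  if (min_sep < 1 || min_sep > max_sep || max_sep >= n)
    stop("need 1 <= min_sep <= max_sep < n_loci")
  seps <- seq.int(min_sep, max_sep)
  ii <- unlist(lapply(seps, function(s) seq.int(0L, n - 1L - s)))
  jj <- unlist(lapply(seps, function(s) seq.int(s, n - 1L)))
  if (n_loops > length(ii))
    stop("n_loops exceeds the ", length(ii), " admissible pairs")
  if (n_loops == 0L) {
    annotation$loops <- matrix(integer(), ncol = 2L)
    return(annotation)
  }
  w <- rep(1, length(ii))
  if (bias_active) {
    act <- annotation$labels %in% active_types
    w <- w + (act[ii + 1L] & act[jj + 1L])
  }
  with_seed(seed, {
    pick <- sample.int(length(ii), n_loops, replace = FALSE, prob = w)
    annotation$loops <- cbind(ii[pick], jj[pick])
    annotation
  })
}

#' Equilibrium Gaussian-chain (Rouse) reference ensemble
#'
#' Successive bond vectors are i.i.d. isotropic Gaussian with mean-square
#' length `bond_len^2`, so `<Ree^2(s)> = s * bond_len^2` exactly.
#'
#' @param n_loci chain length N (>= 2).
#' @param bond_len root-mean-square bond length b (units of a).
#' @param n_samples number of independent chains.
#' @param seed integer seed.
#' @return List of N x 3 coordinate matrices.
#' @export
make_rouse_ensemble <- function(n_loci, bond_len = 1, n_samples = 100L,
                                seed = 1L) {
  stopifnot_scalar(n_loci, "n_loci", positive = TRUE)
  if (n_loci < 2) stop("n_loci must be >= 2")
  stopifnot_scalar(bond_len, "bond_len", positive = TRUE)
  stopifnot_scalar(n_samples, "n_samples", positive = TRUE)
  sdc <- bond_len / sqrt(3)
  with_seed(seed, {
    lapply(seq_len(n_samples), function(k) {
      steps <- matrix(rnorm(3L * (n_loci - 1L), sd = sdc), ncol = 3L)
      rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    })
  })
}

#' Collapsed self-avoiding chain fixture
#'
#' Builds a compact, confined, non-overlapping chain in two stages: a random
#' walk is radially compressed into the target sphere in one global rescale
#' (imprinting compact large-scale statistics), then relaxed by short
#' low-temperature Brownian annealing rounds under a repulsion-only
#' potential (bonds, excluded volume, confinement) until the hard-core,
#' bond-length and confinement constraints hold. The quench inflates local
#' scales to the packing limit, which emulates space-filling
#' (crumpled-globule) statistics, R(s) ~ s^(1/3) at intermediate s. This is
#' a fast test fixture and starting structure; physically sampled ensembles
#' come from [langevin_sample()].
#'
#' @param n_loci chain length N (>= 8).
#' @param target_phi bead volume fraction in the confining sphere; sets the
#'   sphere radius R = (a/2) (N / phi)^(1/3).
#' @param seed integer seed.
#' @param hardcore minimum allowed centre-centre distance between non-bonded
#'   beads (units of a).
#' @param bond_tol allowed deviation of consecutive-bead distances from 1 a.
#' @param max_rounds bounded annealing budget; exceeded -> generation error.
#' @return An N x 3 coordinate matrix inside the sphere.
#' @export
make_collapsed_fixture <- function(n_loci, target_phi = 0.1, seed = 1L,
                                   hardcore = 0.8, bond_tol = 0.2,
                                   max_rounds = 40L) {
  stopifnot_scalar(n_loci, "n_loci", positive = TRUE)
  if (n_loci < 8) stop("n_loci must be >= 8")
  if (target_phi <= 0 || target_phi >= 1) stop("target_phi must be in (0,1)")
  R <- confinement_radius(n_loci, target_phi)
  x <- with_seed(seed, {
    rbind(c(0, 0, 0),
          apply(matrix(rnorm(3 * (n_loci - 1), sd = 1 / sqrt(3)),
                       ncol = 3), 2, cumsum))
  })
  x <- sweep(x, 2, colMeans(x))
  rad <- sqrt(rowSums(x^2))
  lambda <- min(1, (R - 0.6) / max(rad))
  x <- x * lambda
  # repulsion-only annealing model; wall slightly inside R so the final
  # structure sits strictly within the target sphere
  ann <- chrom_annotation(rep("NA", n_loci))
  par <- chrom_params(type_matrix = matrix(0, 6, 6),
                      ideal_gamma = numeric(2), loop_eps = 0,
                      R_s = max(R - 0.3, 1), wall_k = 100)
  T_anneal <- 0.03 # effective temperature of the quench (k_BT)
  ok <- FALSE
  for (round in seq_len(max_rounds)) {
    tr <- brownian_run(x, ann, par,
                       activity_profile = rep(T_anneal, n_loci),
                       t_total = 5, dt = 1.25e-3, frame_interval = 5,
                       seed = seed * 1000 + round)
    x <- frame_at(tr, n_frames(tr))
    x <- sweep(x, 2, colMeans(x))
    d <- dist(x)
    dm <- as.matrix(d)
    nonb <- abs(row(dm) - col(dm)) >= 2
    bl <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n_loci, , drop = FALSE])^2))
    if (max(sqrt(rowSums(x^2))) < R &&
        min(dm[nonb]) >= hardcore &&
        all(abs(bl - 1) <= bond_tol)) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    stop("make_collapsed_fixture: constraints not satisfied after ",
         max_rounds, " annealing rounds")
  dimnames(x) <- NULL
  x
}
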