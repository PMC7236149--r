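#' Specification of a synthetic activity class
#'
#' Defines a generator for clustered binary fingerprints with potencies
#' of controllable structure-activity character, emulating target-based
#' activity classes (compounds with pKi potencies spanning several log
#' units, structural analog series appearing as fingerprint clusters).
#' Topology controls how potency relates to structure: `smooth` puts
#' each cluster on a gradual potency ramp across a latent 2D chemical
#' space (SAR continuity); `rugged` plants activity cliffs by splitting
#' every cluster into two potency modes separated by `cliff_dp` (SAR
#' discontinuity); `heterogeneous` applies the smooth rule to half of
#' the clusters and the cliff rule to the rest, mirroring the mixed
#' character of real classes.
#'
#' @param n_compounds Number of compounds (default 150).
#' @param n_clusters Number of structural clusters (default 6).
#' @param fp_length Fingerprint length in bits (default 1024).
#' @param density Prototype bit density (default 0.1).
#' @param flip_rate Per-bit flip probability for cluster members
#'   (default 0.01; must be below 0.5).
#' @param topology `"smooth"`, `"rugged"` or `"heterogeneous"`.
#' @param potency_range pKi range `c(min, max)` (default `c(5, 10)`).
#' @param cliff_dp Minimum potency gap between cliff partners (pKi,
#'   default 2.5). Cliff clusters split into a low mode in the bottom
#'   fifth and a high mode in the top fifth of the potency range, so
#'   the realized gap is typically larger (cliffs pair weakly and
#'   highly potent compounds); `cliff_dp` is enforced as a floor.
#' @param mode_shift_bits In cliff clusters, number of prototype bits
#'   flipped for the high-potency mode (default 12). This keeps the two
#'   modes highly similar (they remain activity-cliff partners) while
#'   giving them a small structural offset, so that an embedding can
#'   separate them and the interpolated surface develops the
#'   characteristic cliffs instead of averaging the two modes away.
#' @param noise_sd Potency noise standard deviation (pKi, default 0.2).
#' @param name Class name stem.
#' @param seed Integer seed; the generated class is a deterministic
#'   function of the spec.
#' @return A `synthetic_class_spec` list.
#' @seealso [generate_activity_class()]
#' @export
synthetic_class_spec <- function(n_compounds = 150L, n_clusters = 6L,
                                 fp_length = 1024L, density = 0.1,
                                 flip_rate = 0.01,
                                 topology = c("heterogeneous", "smooth",
                                              "rugged"),
                                 potency_range = c(5, 10),
                                 cliff_dp = 2.5, mode_shift_bits = 12L,
                                 noise_sd = 0.2,
                                 name = "synthetic", seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(flip_rate > 0, flip_rate < 0.5,
            potency_range[1] < potency_range[2],
            noise_sd >= 0, n_clusters >= 1, n_compounds >= n_clusters)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_clusters = as.integer(n_clusters),
                 fp_length = as.integer(fp_length), density = density,
                 flip_rate = flip_rate, topology = topology,
                 potency_range = as.numeric(potency_range),
                 cliff_dp = cliff_dp,
                 mode_shift_bits = as.integer(mode_shift_bits),
                 noise_sd = noise_sd,
                 name = name, seed = as.integer(seed)),
            class = "synthetic_class_spec")
}

#' Generate a synthetic activity class
#'
#' Samples cluster prototype fingerprints at the specified bit density,
#' derives members by independent per-bit flips, assigns each cluster a
#' latent 2D coordinate, and sets potencies according to the planted
#' topology (see [synthetic_class_spec()]): smooth clusters follow a
#' linear potency ramp across the latent coordinates scaled to the
#' potency range, plus Gaussian noise; cliff clusters alternate members
#' between two modes `cliff_dp` apart. Deterministic per seed.
#'
#' @param spec A [synthetic_class_spec()].
#' @return An [activity_class()] with `variant = "heterogeneous"` (the
#'   planted topology is available as attribute `"topology"` and the
#'   cluster assignment as attribute `"cluster"`).
#' @export
generate_activity_class <- function(spec) {
  stopifnot(inherits(spec, "synthetic_class_spec"))
  set.seed(spec$seed)
  k <- spec$n_clusters
  n <- spec$n_compounds
  protos <- matrix(stats::rbinom(k * spec$fp_length, 1L, spec$density),
                   nrow = k)
  empty <- rowSums(protos) == 0L
  protos[empty, 1L] <- 1L
  latent <- matrix(stats::runif(k * 2L), nrow = k)

  # cluster ramp position, normalized across clusters to [0, 1]
  t_raw <- rowMeans(latent)
  t_pos <- if (k > 1L) (t_raw - min(t_raw)) / (max(t_raw) - min(t_raw)) else 0.5
  pr <- spec$potency_range
  rng <- pr[2] - pr[1]

  member_cluster <- rep_len(seq_len(k), n)
  cliff_cluster <- switch(spec$topology,
    smooth = rep(FALSE, k),
    rugged = rep(TRUE, k),
    heterogeneous = seq_len(k) > k / 2
  )

  fps <- protos[member_cluster, , drop = FALSE]
  potency <- numeric(n)
  for (c_i in seq_len(k)) {
    idx <- which(member_cluster == c_i)
    if (cliff_cluster[c_i]) {
      # cliff partners pair a weakly and a highly potent compound: the
      # low mode sits in the bottom fifth and the high mode in the top
      # fifth of the class range. Placing the modes at the distribution
      # extremes is what gives the reference selections their meaning -
      # the interquartile (smooth) selection drops at least one side of
      # every cliff pair, while the alternating-septile (rugged)
      # selection retains both.
      lo <- pr[1] + 0.2 * rng * t_pos[c_i]
      hi <- pr[2] - 0.2 * rng * (1 - t_pos[c_i])
      if (hi - lo < spec$cliff_dp) {
        mid <- (hi + lo) / 2
        lo <- mid - spec$cliff_dp / 2
        hi <- mid + spec$cliff_dp / 2
      }
      sgn <- rep_len(c(-1, 1), length(idx))
      potency[idx] <- ifelse(sgn < 0, lo, hi)
      # structural offset of the high-potency mode (cliff partners stay
      # highly similar but separable by an embedding)
      shift <- sample.int(spec$fp_length,
                          min(spec$mode_shift_bits, spec$fp_length))
      hi <- idx[sgn > 0]
      fps[hi, shift] <- 1L - fps[hi, shift]
    } else if (spec$topology == "heterogeneous") {
      # mixed classes: continuous clusters form the potency core while
      # cliff partners supply the extremes, as in real classes whose
      # interquartile range is narrow relative to the full range
      potency[idx] <- pr[1] + 0.25 * rng + 0.5 * rng * t_pos[c_i]
    } else {
      potency[idx] <- pr[1] + rng * t_pos[c_i]
    }
  }
  flips <- matrix(stats::rbinom(n * spec$fp_length, 1L, spec$flip_rate),
                  nrow = n)
  fps <- (fps + flips) %% 2L
  zero <- rowSums(fps) == 0L
  fps[zero, 1L] <- 1L
  potency <- potency + stats::rnorm(n, 0, spec$noise_sd)
  potency <- pmin(pmax(potency, pr[1] - 3 * spec$noise_sd),
                  pr[2] + 3 * spec$noise_sd)

  cls <- activity_class(spec$name, sprintf("%s_%04d", spec$name, seq_len(n)),
                        fps, potency, variant = "heterogeneous")
  attr(cls, "topology") <- spec$topology
  attr(cls, "cluster") <- member_cluster
  cls
}

#' Generate a list of synthetic activity classes
#'
#' @param n_classes Number of classes.
#' @param seed Master seed; class `i` uses a seed derived from it.
#' @param topology Planted topology for every class.
#' @param ... Further arguments to [synthetic_class_spec()].
#' @return List of [activity_class()] objects named `class01`,
#'   `class02`, ...
#' @export
generate_class_set <- function(n_classes, seed = 1L,
                               topology = "heterogeneous", ...) {
  lapply(seq_len(n_classes), function(i) {
    nm <- sprintf("class%02d", i)
    generate_activity_class(synthetic_class_spec(
      name = nm, topology = topology,
      seed = derive_seed(seed, paste0("class", i)), ...
    ))
  })
}

#' Specification of an analytic surface fixture
#'
#' A deterministic potency surface made of a base level plus Gaussian
#' bumps, used to exercise the rendering and edge-detection stages with
#' known topology (0 peaks = flat/smooth, many peaks = rugged).
#'
#' @param grid_size Nodes per axis (default 64).
#' @param n_peaks Number of Gaussian peaks (>= 0).
#' @param amplitudes Peak amplitudes in pKi (recycled).
#' @param widths Peak widths (Gaussian sd, in grid units; recycled).
#' @param base Base potency level (pKi).
#' @param placement `"spread"` places peaks on a jittered sub-grid
#'   (well separated); `"random"` samples uniformly.
#' @param seed Integer seed.
#' @return A `surface_fixture_spec` list.
#' @export
surface_fixture_spec <- function(grid_size = 64L, n_peaks = 4L,
                                 amplitudes = 2.5, widths = 0.06,
                                 base = 6, placement = c("spread", "random"),
                                 seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(n_peaks >= 0, all(is.finite(amplitudes)), grid_size >= 8)
  structure(list(grid_size = as.integer(grid_size),
                 n_peaks = as.integer(n_peaks),
                 amplitudes = amplitudes, widths = widths, base = base,
                 placement = placement, seed = as.integer(seed)),
            class = "surface_fixture_spec")
}

#' Generate an analytic surface fixture
#'
#' @param spec A [surface_fixture_spec()].
#' @param cmap Potency color map.
#' @return A `surface_grid` on the unit square.
#' @export
generate_surface_fixture <- function(spec, cmap = potency_colormap()) {
  stopifnot(inherits(spec, "surface_fixture_spec"))
  set.seed(spec$seed)
  g <- spec$grid_size
  xs <- seq(0, 1, length.out = g)
  ys <- seq(0, 1, length.out = g)
  z <- matrix(spec$base, g, g)
  k <- spec$n_peaks
  if (k > 0L) {
    amps <- rep_len(spec$amplitudes, k)
    wids <- rep_len(spec$widths, k)
    if (spec$placement == "spread") {
      m <- ceiling(sqrt(k))
      centers_1d <- (seq_len(m) - 0.5) / m
      grid_pts <- expand.grid(cx = centers_1d, cy = centers_1d)
      cx <- grid_pts$cx[seq_len(k)] + stats::runif(k, -0.2, 0.2) / m
      cy <- grid_pts$cy[seq_len(k)] + stats::runif(k, -0.2, 0.2) / m
    } else {
      cx <- stats::runif(k)
      cy <- stats::runif(k)
    }
    for (i in seq_len(k)) {
      z <- z + amps[i] *
        exp(-(outer(xs, ys, function(x, y) (x - cx[i])^2 + (y - cy[i])^2)) /
              (2 * wids[i]^2))
    }
  }
  surface_grid(xs, ys, z, cmap = cmap)
}

#' Count planted activity cliffs in a class
#'
#' Number of unordered compound pairs with Tanimoto similarity at least
#' `tc_min` and absolute potency difference at least `dp_min` — the
#' standard similarity/potency-difference criterion for activity
#' cliffs.
#'
#' @param cls An [activity_class()].
#' @param tc_min Minimum pair similarity (default 0.6).
#' @param dp_min Minimum potency difference in pKi (default 2).
#' @return Integer pair count.
#' @export
planted_cliff_count <- function(cls, tc_min = 0.6, dp_min = 2) {
  stopifnot(is_activity_class(cls))
  n <- length(cls)
  if (n < 2L) return(0L)
  tc <- tanimoto_matrix(cls$fps)
  dp <- abs(outer(cls$potency, cls$potency, "-"))
  ut <- upper.tri(tc)
  sum(tc[ut] >= tc_min & dp[ut] >= dp_min)
}
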