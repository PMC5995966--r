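# Coarse head geometry used for the neuron lattice: an ellipsoid (mm) that
# encloses the bundled scalp-projected 10-20 electrode coordinates.
.head_semi_axes <- c(78, 105, 80)
.head_center <- c(0, -15, 15)

#' Bundled 19-channel 10-20 electrode montage
#'
#' Approximate scalp-projected electrode coordinates (mm) in the same
#' template frame as the neuron lattice. Users may supply their own
#' `(label, x, y, z)` table anywhere a montage is accepted.
#'
#' @return Data frame with columns `label`, `x`, `y`, `z`.
#' @export
montage_1020 <- function() {
  read_delim_file(system.file("extdata", "montage_1020.tsv", package = "snnerp"),
                  c("label", "x", "y", "z"))
}

#' Channel labels of the bundled montage
#' @return Character vector of 19 channel labels.
#' @export
montage_channels <- function() montage_1020()$label

#' Bundled coarse brain-region parcellation
#'
#' Region centroids (possibly several rows per region) used for
#' nearest-centroid labelling of lattice neurons with eight coarse areas:
#' Temporal, Parietal, Frontal, Sub-lobar, Cerebellar, Limbic, Pituitary
#' and Occipital. This is a deliberately coarse synthetic parcellation in
#' the template frame, not an anatomical atlas; a user file with the same
#' columns can replace it.
#'
#' @return Data frame with columns `region`, `x`, `y`, `z`.
#' @export
region_centroids <- function() {
  read_delim_file(system.file("extdata", "region_centroids.tsv", package = "snnerp"),
                  c("region", "x", "y", "z"))
}

#' Build the 3D neuron atlas
#'
#' Fills an ellipsoidal head volume with neurons on a regular cubic lattice
#' of spacing `resolution` (mm), labels each neuron with the nearest region
#' centroid, and maps every electrode of `montage` to its nearest neuron,
#' which becomes an input neuron. The default 12 mm spacing yields roughly
#' 1,500 neurons.
#'
#' @param resolution lattice spacing in mm.
#' @param montage electrode table (`label`, `x`, `y`, `z`).
#' @param regions region-centroid table (`region`, `x`, `y`, `z`).
#' @return A `neuron_atlas` data frame: `id`, `x`, `y`, `z` (mm),
#'   `gx`, `gy`, `gz` (grid units), `region`, `is_input`, `channel`.
#' @export
build_atlas <- function(resolution = 12, montage = montage_1020(),
                        regions = region_centroids()) {
  if (resolution <= 0) stop_input("`resolution` must be positive")
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(montage))) stop_input("montage needs columns label,x,y,z")
  if (anyDuplicated(montage$label)) stop_input("duplicated electrode labels")
  a <- .head_semi_axes; ctr <- .head_center
  rng <- function(ax) {
    k <- floor(a[ax] / resolution)
    (-k):k
  }
  g <- expand.grid(gx = rng(1), gy = rng(2), gz = rng(3))
  x <- ctr[1] + g$gx * resolution
  y <- ctr[2] + g$gy * resolution
  z <- ctr[3] + g$gz * resolution
  inside <- ((x - ctr[1]) / a[1])^2 + ((y - ctr[2]) / a[2])^2 +
    ((z - ctr[3]) / a[3])^2 <= 1
  atlas <- data.frame(id = seq_len(sum(inside)),
                      x = x[inside], y = y[inside], z = z[inside],
                      gx = g$gx[inside], gy = g$gy[inside], gz = g$gz[inside])
  # nearest-centroid region labels
  d2 <- outer(atlas$x, regions$x, "-")^2 + outer(atlas$y, regions$y, "-")^2 +
    outer(atlas$z, regions$z, "-")^2
  atlas$region <- regions$region[max.col(-d2)]
  # electrode -> nearest neuron
  atlas$is_input <- FALSE
  atlas$channel <- NA_character_
  for (i in seq_len(nrow(montage))) {
    d <- (atlas$x - montage$x[i])^2 + (atlas$y - montage$y[i])^2 +
      (atlas$z - montage$z[i])^2
    j <- which.min(d)
    if (atlas$is_input[j]) {
      stop_input("electrodes %s and %s map to the same neuron; use a finer resolution",
                 atlas$channel[j], montage$label[i])
    }
    atlas$is_input[j] <- TRUE
    atlas$channel[j] <- montage$label[i]
  }
  attr(atlas, "resolution") <- resolution
  class(atlas) <- c("neuron_atlas", "data.frame")
  atlas
}

#' Small-world initialisation parameters
#'
#' Candidate post-synaptic partners of a neuron are all neurons within a
#' Chebyshev (axis-aligned box) radius of `radius` lattice steps in each of
#' x, y and z; within that box an ordered pair is connected with
#' probability `p0 * exp(-d / decay)` where `d` is the Euclidean distance
#' in lattice units, so connection probability decreases with distance.
#' Initial weight magnitudes are Uniform(0, `w_init_max`), positive with
#' probability `pos_fraction`. The defaults (`p0 = 0.9`, `decay = 2.2`)
#' give a mean in-degree of about 30 on the default lattice.
#'
#' @param radius maximum connection distance in lattice steps per axis.
#' @param p0 base connection probability at distance zero, in (0, 1].
#' @param decay distance-decay constant (lattice units).
#' @param pos_fraction fraction of excitatory (positive) weights.
#' @param w_init_max maximum initial weight magnitude.
#' @param seed RNG seed for the wiring draws.
#' @return A `small_world_config` object.
#' @export
small_world_config <- function(radius = 2L, p0 = 0.9, decay = 2.2,
                               pos_fraction = 0.8, w_init_max = 0.1,
                               seed = NULL) {
  radius <- check_count(radius, "radius", min = 1L)
  if (p0 <= 0 || p0 > 1) stop_input("`p0` must be in (0, 1]")
  if (decay <= 0) stop_input("`decay` must be positive")
  if (pos_fraction < 0 || pos_fraction > 1) stop_input("`pos_fraction` must be in [0, 1]")
  if (w_init_max <= 0) stop_input("`w_init_max` must be positive")
  structure(list(radius = radius, p0 = p0, decay = decay,
                 pos_fraction = pos_fraction, w_init_max = w_init_max,
                 seed = seed),
            class = "small_world_config")
}

#' Initialise small-world connectivity
#'
#' Draws the directed initial synapse set over a [build_atlas()] lattice
#' following the distance-decaying connection rule of
#' [small_world_config()]. No self-edges and at most one edge per ordered
#' pair are created; the draw is reproducible given `cfg$seed`.
#'
#' @param atlas a `neuron_atlas`.
#' @param cfg a [small_world_config()].
#' @return A `synapse_set` data frame (`pre`, `post`, `weight`) with an
#'   `n_neurons` attribute.
#' @export
init_small_world <- function(atlas, cfg = small_world_config()) {
  stopifnot(inherits(atlas, "neuron_atlas"))
  r <- cfg$radius
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx != 0 | off$dy != 0 | off$dz != 0, , drop = FALSE]
  key <- function(gx, gy, gz) (gx + 512) + 1025 * ((gy + 512) + 1025 * (gz + 512))
  keys <- key(atlas$gx, atlas$gy, atlas$gz)
  pre <- integer(0); post <- integer(0); wt <- numeric(0)
  with_seed(cfg$seed, {
    acc <- vector("list", nrow(off))
    for (o in seq_len(nrow(off))) {
      tgt <- match(key(atlas$gx + off$dx[o], atlas$gy + off$dy[o],
                       atlas$gz + off$dz[o]), keys)
      src <- which(!is.na(tgt))
      if (length(src) == 0) { acc[[o]] <- NULL; next }
      tgt <- tgt[src]
      d <- sqrt(off$dx[o]^2 + off$dy[o]^2 + off$dz[o]^2)
      keep <- runif(length(src)) < cfg$p0 * exp(-d / cfg$decay)
      if (!any(keep)) { acc[[o]] <- NULL; next }
      src <- src[keep]; tgt <- tgt[keep]
      mag <- runif(length(src), 0, cfg$w_init_max)
      sgn <- ifelse(runif(length(src)) < cfg$pos_fraction, 1, -1)
      acc[[o]] <- data.frame(pre = atlas$id[src], post = atlas$id[tgt],
                             weight = mag * sgn)
    }
    out <- do.call(rbind, acc)
    if (is.null(out)) out <- data.frame(pre = integer(0), post = integer(0),
                                        weight = numeric(0))
    out <- out[order(out$pre, out$post), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_neurons") <- nrow(atlas)
    class(out) <- c("synapse_set", "data.frame")
    out
  })
}
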