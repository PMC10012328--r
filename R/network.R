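# Two-region architecture: neocortex (visual + auditory subgroups of 10) and
# hippocampus (visual + auditory subgroups of 5).

NC_VIS <- 1:10
NC_AUD <- 11:20
HIP_VIS <- 21:25
HIP_AUD <- 26:30
N_NEURONS <- 30L

#' Build the cortico-hippocampal network
#'
#' Draws the synapse matrix for the two-region architecture from a seeded
#' RNG.  NC neurons connect within subgroup with probability `nc_intra_p`
#' (fixed weights, full efficacy); there are no NC inter-subgroup synapses.
#' Every NC neuron is fully connected to the hippocampal subgroup of its own
#' modality and vice versa (fixed weights).  Hippocampal directed pairs exist
#' independently with probability `hip_p` and are the only plastic synapses;
#' existing intra-subgroup pairs start at full efficacy (`rho = 1`) and
#' existing inter-subgroup pairs at zero efficacy.  No self-connections are
#' drawn.  Construction is a pure function of `(spec, seed)`.
#'
#' @param spec a [connectivity_spec()] object
#' @param seed integer seed; required, so that every network draw is
#'   reproducible
#' @return a list of class `lif_network` with fields `n`, `region`,
#'   `subgroup`, and `n x n` matrices `exists`, `w_max`, `rho`, `plastic`
#'   (row = presynaptic neuron, column = postsynaptic neuron)
#' @export
build_network <- function(spec = connectivity_spec(), seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: network construction must be reproducible")
  n <- N_NEURONS
  region <- c(rep("NC", 20), rep("HIP", 10))
  subgroup <- c(rep("vis", 10), rep("aud", 10), rep("vis", 5), rep("aud", 5))
  exists <- matrix(FALSE, n, n)
  w_max <- matrix(0, n, n)
  rho <- matrix(0, n, n)
  plastic <- matrix(FALSE, n, n)

  with_seed(seed, {
    # NC intra-subgroup, independent per directed pair
    for (grp in list(NC_VIS, NC_AUD)) {
      draw <- matrix(stats::runif(length(grp)^2) < spec$nc_intra_p,
                     length(grp), length(grp))
      diag(draw) <- FALSE
      exists[grp, grp] <- draw
      w_max[grp, grp][draw] <- spec$nc_intra_wmax
      rho[grp, grp][draw] <- 1
    }
    # NC <-> hippocampus, full bipartite within modality
    for (pair in list(list(NC_VIS, HIP_VIS), list(NC_AUD, HIP_AUD))) {
      nc <- pair[[1]]; hip <- pair[[2]]
      exists[nc, hip] <- TRUE
      w_max[nc, hip] <- spec$nc_to_hip_wmax
      rho[nc, hip] <- 1
      exists[hip, nc] <- TRUE
      w_max[hip, nc] <- spec$hip_to_nc_wmax
      rho[hip, nc] <- 1
    }
    # hippocampus: directed pairs with probability hip_p, plastic
    hip <- c(HIP_VIS, HIP_AUD)
    draw <- matrix(stats::runif(length(hip)^2) < spec$hip_p,
                   length(hip), length(hip))
    diag(draw) <- FALSE
    exists[hip, hip] <- draw
    w_max[hip, hip][draw] <- spec$hip_wmax
    plastic[hip, hip] <- draw
    same <- outer(subgroup[hip], subgroup[hip], "==")
    rho[hip, hip][draw & same] <- 1
    rho[hip, hip][draw & !same] <- 0
  })

  structure(list(n = n, region = region, subgroup = subgroup,
                 exists = exists, w_max = w_max, rho = rho,
                 plastic = plastic, seed = as.integer(seed)),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat("<lif_network> ", x$n, " neurons (20 NC + 10 hippocampal)\n", sep = "")
  cat("  synapses: ", sum(x$exists), " existing, ", sum(x$plastic),
      " plastic (hippocampal)\n", sep = "")
  invisible(x)
}

#' Neuron index helpers
#'
#' Integer indices of the four subgroups in the fixed 30-neuron layout.
#'
#' @return named list of integer vectors `nc_vis`, `nc_aud`, `hip_vis`,
#'   `hip_aud`
#' @export
neuron_groups <- function() {
  list(nc_vis = NC_VIS, nc_aud = NC_AUD, hip_vis = HIP_VIS, hip_aud = HIP_AUD)
}

#' Dump a network as a plain adjacency listing
#'
#' @param network a [build_network()] result
#' @return data frame with one row per existing directed synapse: `pre`,
#'   `post`, `w_max`, `rho0`, `plastic`
#' @export
network_adjacency <- function(network) {
  idx <- which(network$exists, arr.ind = TRUE)
  data.frame(pre = idx[, 1], post = idx[, 2],
             w_max = network$w_max[idx],
             rho0 = network$rho[idx],
             plastic = network$plastic[idx])
}

#' Reset the hippocampal theta phase at stimulus onset
#'
#' Returns the phase offset `phi0` such that the hippocampal theta phase at
#' `t >= onset` is `phi0 + 2 pi f (t - onset) / 1000`.  The reset aligns the
#' LTP-permissive trough (`theta = 0`) with the peaks of the visual stimulus
#' modulation: under the package's stimulus convention the visual envelope
#' starts at its trough at onset, so the reset sets `theta = 1` at onset
#' (`phi0` equal to the visual phase jitter, zero in the noise-free case).
#' The STDP-only variant does not reset theta; callers skip the reset there.
#'
#' @param visual_phase_rad phase of the visual modulation at onset (radians);
#'   0 in the noise-free case
#' @return phase offset `phi0` (radians)
#' @export
reset_theta_phase <- function(visual_phase_rad = 0) visual_phase_rad
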