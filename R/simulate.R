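# Synthetic particle generator. Emulates the OUTPUT of symmetry expansion +
# focused two-class 3D classification: each particle appears as six expanded
# copies, copy_index k interrogating binding site flat_index k, each labeled
# alpha "present" or "missing".

#' Binding model for true site occupancy
#'
#' Describes how alpha-subunits decorate the six binding sites of a particle
#' at equilibrium. Two modes:
#' \describe{
#'   \item{independent_site}{each site occupied independently with
#'     probability `p` — the stationary per-site occupancy implied by
#'     constant free alpha-subunit concentration and identical,
#'     non-interacting sites.}
#'   \item{explicit_distribution}{the formula n is drawn from `weights`
#'     (over n = 0..6), then a configuration is drawn uniformly among the
#'     `choose(6, n)` configurations with that n.}
#' }
#'
#' @param p Per-site occupancy probability in `[0, 1]` (independent_site
#'   mode). Exactly one of `p`, `weights` must be given.
#' @param weights Seven nonnegative weights over formulae n = 0..6; they are
#'   normalised to sum to 1.
#' @return An object of class `pcc_binding_model`.
#' @export
#' @examples
#' binding_model(p = 0.8)
#' binding_model(weights = c(0, 0, 0, 0, 1, 2, 4))
binding_model <- function(p = NULL, weights = NULL) {
  if (is.null(p) == is.null(weights)) {
    stop("give exactly one of `p` (independent_site) or `weights` (explicit_distribution)")
  }
  if (!is.null(p)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("`p` must be a single probability in [0, 1]")
    }
    return(structure(list(mode = "independent_site", p = as.numeric(p)),
                     class = "pcc_binding_model"))
  }
  if (!is.numeric(weights) || length(weights) != 7L || anyNA(weights) || any(weights < 0)) {
    stop("`weights` must be 7 nonnegative numbers (formulae n = 0..6)")
  }
  s <- sum(weights)
  if (s <= 0) stop("`weights` must have positive sum")
  structure(list(mode = "explicit_distribution", weights = weights / s),
            class = "pcc_binding_model")
}

#' Classification error model
#'
#' Per-site, per-copy independent label noise on top of the focused
#' classification: an occupied site's expanded copy lands in the
#' alpha-missing class with probability `eps_fn`; an unoccupied site's copy
#' lands in the alpha-present class with probability `eps_fp`. The defaults
#' (both 0) reproduce the idealised error-free sorting procedure.
#'
#' @param eps_fn False-negative probability in `[0, 1]`.
#' @param eps_fp False-positive probability in `[0, 1]`.
#' @return An object of class `pcc_error_model`.
#' @export
error_model <- function(eps_fn = 0, eps_fp = 0) {
  for (e in list(eps_fn, eps_fp)) {
    if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 0 || e > 1) {
      stop("error probabilities must be single values in [0, 1]")
    }
  }
  structure(list(eps_fn = as.numeric(eps_fn), eps_fp = as.numeric(eps_fp)),
            class = "pcc_error_model")
}

#' Sample ground-truth occupancy configurations
#'
#' Draws `n_particles` true occupancy configurations from a [binding_model()].
#' Occupancy sampling at a stationary per-site probability stands in for the
#' continuous assembly/disassembly of alpha-subunits at equilibrium.
#'
#' @param model A `pcc_binding_model`.
#' @param n_particles Number of particles (>= 1).
#' @param seed Integer seed; output is deterministic given `(model, n, seed)`.
#' @return A data.frame of class `pcc_truth` with columns `particle_id`
#'   (0-based, contiguous) and `bits` (6-character 0/1 string ordered by
#'   flat_index; "1" = alpha bound), plus attribute `bits_matrix`
#'   (n x 6 integer matrix) for convenience.
#' @export
#' @examples
#' tr <- sample_true_occupancy(binding_model(p = 0.8), 5, seed = 1)
#' tr$bits
sample_true_occupancy <- function(model, n_particles, seed) {
  stopifnot(inherits(model, "pcc_binding_model"))
  if (!is.numeric(n_particles) || length(n_particles) != 1L || n_particles < 1 ||
      n_particles != round(n_particles)) {
    stop("`n_particles` must be a positive integer")
  }
  n_particles <- as.integer(n_particles)
  set.seed(as.integer(seed))
  if (model$mode == "independent_site") {
    bits <- matrix(stats::rbinom(n_particles * N_SITES, 1L, model$p),
                   nrow = n_particles, ncol = N_SITES)
  } else {
    n_alpha <- sample.int(7L, n_particles, replace = TRUE, prob = model$weights) - 1L
    bits <- matrix(0L, nrow = n_particles, ncol = N_SITES)
    for (k in 1:5) {  # n = 0 and 6 need no site draw
      rows <- which(n_alpha == k)
      for (i in rows) bits[i, sample.int(N_SITES, k)] <- 1L
    }
    bits[n_alpha == 6L, ] <- 1L
  }
  storage.mode(bits) <- "integer"
  out <- data.frame(
    particle_id = 0:(n_particles - 1L),
    bits = apply(bits, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
  attr(out, "bits_matrix") <- bits
  class(out) <- c("pcc_truth", "data.frame")
  out
}

# 0/1 matrix (n x 6) from a truth data.frame
truth_bits_matrix <- function(truth) {
  m <- attr(truth, "bits_matrix")
  if (!is.null(m)) return(m)
  t(vapply(strsplit(truth$bits, ""), function(x) as.integer(x), integer(N_SITES)))
}

#' Expand particles and apply classification labels
#'
#' Emulates symmetry expansion followed by focused two-class classification:
#' each particle is duplicated into six expanded copies, copy `k`
#' interrogating binding site `flat_index = k`; the copy is labeled
#' `"present"` or `"missing"` according to the true occupancy, with
#' independent per-copy label flips from the [error_model()].
#'
#' @param truth A `pcc_truth` data.frame from [sample_true_occupancy()].
#' @param err A `pcc_error_model`; defaults to no error.
#' @param seed Integer seed for the flip draws.
#' @return A data.frame of class `pcc_records` with columns `particle_id`,
#'   `copy_index` (0..5) and `class_label` (`"present"`/`"missing"`),
#'   particle-major order.
#' @export
apply_classification_error <- function(truth, err = error_model(), seed = 0L) {
  stopifnot(inherits(err, "pcc_error_model"))
  bits <- truth_bits_matrix(truth)
  n <- nrow(bits)
  set.seed(as.integer(seed))
  # row-major flatten: records ordered particle-major, copy 0..5
  occ <- as.integer(t(bits))
  u <- stats::runif(length(occ))
  flip <- ifelse(occ == 1L, u < err$eps_fn, u < err$eps_fp)
  observed_present <- xor(occ == 1L, flip)
  out <- data.frame(
    particle_id = rep(truth$particle_id, each = N_SITES),
    copy_index = rep(0:(N_SITES - 1L), times = n),
    class_label = ifelse(observed_present, "present", "missing"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pcc_records", "data.frame")
  out
}
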