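# The sorting method: count alpha-missing labels among each particle's six
# symmetry-expanded copies; the count equals the number of unoccupied
# alpha-beta binding sites, so formula_n = 6 - k_missing.

#' Count alpha-missing labels per particle
#'
#' For each particle, counts how many of its six symmetry-expanded copies
#' were assigned to the alpha-missing class (`k_missing`, 0..6) and assigns
#' the oligomeric formula `alpha_n beta_6` with `n = 6 - k_missing`.
#'
#' Malformed particles (not exactly 6 records, duplicated copy indices,
#' unknown class labels) signal a truncated or corrupted particle table and
#' raise an error by default; with `skip_malformed = TRUE` they are dropped
#' with a warning reporting how many were skipped.
#'
#' @param records A `pcc_records` data.frame (columns `particle_id`,
#'   `copy_index`, `class_label`).
#' @param skip_malformed Drop malformed particles instead of erroring.
#' @return A data.frame with columns `particle_id`, `k_missing`,
#'   `formula_n`, one row per particle, ordered by `particle_id`.
#' @export
count_missing_per_particle <- function(records, skip_malformed = FALSE) {
  req <- c("particle_id", "copy_index", "class_label")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "))
  }
  bad_label <- !records$class_label %in% c("present", "missing")
  bad_ids <- unique(records$particle_id[bad_label])

  cnt <- table(records$particle_id)
  wrong_card <- as.integer(names(cnt)[cnt != N_SITES])
  dup <- duplicated(records[, c("particle_id", "copy_index")]) |
    !records$copy_index %in% 0:(N_SITES - 1L)
  dup_ids <- unique(records$particle_id[dup])
  malformed <- unique(c(bad_ids, wrong_card, dup_ids))
  if (length(malformed) > 0L) {
    if (!skip_malformed) {
      stop("malformed record sets for ", length(malformed),
           " particle(s), e.g. particle_id ", malformed[1L],
           " (expect exactly 6 records, copy_index 0..5 distinct, labels present/missing)")
    }
    warning("skipping ", length(malformed), " malformed particle(s)")
    records <- records[!records$particle_id %in% malformed, , drop = FALSE]
    if (nrow(records) == 0L) {
      return(data.frame(particle_id = integer(0), k_missing = integer(0),
                        formula_n = integer(0)))
    }
  }
  miss <- rowsum(as.integer(records$class_label == "missing"),
                 group = records$particle_id, reorder = TRUE)
  ids <- as.integer(rownames(miss))
  ord <- order(ids)
  data.frame(
    particle_id = ids[ord],
    k_missing = as.integer(miss[ord, 1L]),
    formula_n = N_SITES - as.integer(miss[ord, 1L])
  )
}

#' Build an oligomeric formula distribution
#'
#' Histogram of particle counts `N_n` over oligomeric formulae
#' `alpha_n beta_6`, n = 0..6 — the frequency distribution the sorting
#' method produces.
#'
#' @param assignments Data.frame from [count_missing_per_particle()], or any
#'   data.frame with a `formula_n` column in 0..6.
#' @return Object of class `pcc_formula_dist`: list with `counts` (named
#'   numeric vector, names "0".."6") and `total`.
#' @export
formula_distribution <- function(assignments) {
  if (NROW(assignments) == 0L) stop("no particle assignments to tally")
  fn <- assignments$formula_n
  if (is.null(fn)) stop("assignments must have a `formula_n` column")
  if (any(!fn %in% 0:6)) stop("formula_n values must be in 0..6")
  counts <- as.numeric(table(factor(fn, levels = 0:6)))
  names(counts) <- as.character(0:6)
  new_formula_dist(counts)
}

#' Construct a formula distribution from raw counts
#'
#' @param counts Seven nonnegative counts for n = 0..6 (may be real-valued,
#'   e.g. after misclassification correction).
#' @return A `pcc_formula_dist`.
#' @export
new_formula_dist <- function(counts) {
  if (length(counts) != 7L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be 7 nonnegative numbers (n = 0..6)")
  }
  counts <- as.numeric(counts)
  names(counts) <- as.character(0:6)
  structure(list(counts = counts, total = sum(counts)), class = "pcc_formula_dist")
}

#' @export
print.pcc_formula_dist <- function(x, ...) {
  cat("Oligomeric formula distribution (", format(x$total), " particles):\n", sep = "")
  df <- data.frame(formula = paste0("alpha_", 0:6, "beta_6"),
                   count = x$counts,
                   fraction = if (x$total > 0) x$counts / x$total else NA_real_)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Misclassification mixing matrix
#'
#' `M[k + 1, n + 1]` is the probability that a particle with `n` truly
#' occupied sites receives `k` alpha-missing labels: the convolution of
#' `Binomial(n, eps_fn)` (occupied sites falsely missing) and
#' `Binomial(6 - n, 1 - eps_fp)` (unoccupied sites correctly missing).
#'
#' @param err A [error_model()].
#' @return A 7 x 7 column-stochastic matrix.
#' @export
mixing_matrix <- function(err) {
  stopifnot(inherits(err, "pcc_error_model"))
  M <- matrix(0, 7L, 7L)
  for (n in 0:6) {
    # j occupied sites flipped to missing, m unoccupied sites labeled missing
    pj <- stats::dbinom(0:n, n, err$eps_fn)
    pm <- stats::dbinom(0:(6 - n), 6 - n, 1 - err$eps_fp)
    for (j in 0:n) {
      for (m in 0:(6 - n)) {
        M[j + m + 1L, n + 1L] <- M[j + m + 1L, n + 1L] + pj[j + 1L] * pm[m + 1L]
      }
    }
  }
  M
}

# condition-number guard for the deconvolution
MIXING_KAPPA_MAX <- 1e8

#' Deconvolve classification error from a formula distribution
#'
#' Inverts the [mixing_matrix()] by least squares to estimate the true
#' formula distribution from the observed one. Requires
#' `eps_fn + eps_fp < 1` (invertible mixing); errors if the matrix condition
#' number exceeds `1e8`. Negative least-squares components are clipped to 0
#' and the result rescaled to preserve the total, so corrected counts are
#' real-valued expected counts, not integers.
#'
#' @param dist Observed `pcc_formula_dist`, indexed by formula
#'   `n_obs = 6 - k_obs`.
#' @param err The [error_model()] assumed to have generated the labels.
#' @return A corrected `pcc_formula_dist` with real-valued counts.
#' @export
correct_misclassification <- function(dist, err) {
  stopifnot(inherits(dist, "pcc_formula_dist"), inherits(err, "pcc_error_model"))
  if (err$eps_fn + err$eps_fp >= 1) {
    stop("eps_fn + eps_fp must be < 1 for an invertible mixing matrix")
  }
  M <- mixing_matrix(err)
  if (kappa(M, exact = TRUE) > MIXING_KAPPA_MAX) {
    stop("mixing matrix is numerically singular (condition number > 1e8)")
  }
  # observed counts indexed by k_obs = 6 - n_obs
  obs_k <- rev(dist$counts)
  x <- stats::lsfit(M, obs_k, intercept = FALSE)$coefficients
  x[x < 0] <- 0
  s <- sum(x)
  if (s > 0) x <- x * dist$total / s
  new_formula_dist(x)  # x is indexed by n_true = 0..6 already
}
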