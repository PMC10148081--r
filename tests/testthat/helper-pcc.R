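# Shared fixtures built in code.

# Expanded records for given occupancy bit strings, error-free labels.
records_from_bits <- function(bits_strings) {
  n <- length(bits_strings)
  bits <- do.call(rbind, lapply(strsplit(bits_strings, ""), as.integer))
  out <- data.frame(
    particle_id = rep(seq_len(n) - 1L, each = 6L),
    copy_index = rep(0:5, times = n),
    class_label = ifelse(as.integer(t(bits)) == 1L, "present", "missing"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pcc_records", "data.frame")
  out
}

# Formula distribution exactly proportional to Binomial(6, p).
binom_dist <- function(p, total = 64000) {
  new_formula_dist(stats::dbinom(0:6, 6, p) * total)
}

# Ground-truth formula histogram from a pcc_truth object.
truth_histogram <- function(truth) {
  n_alpha <- vapply(strsplit(truth$bits, ""),
                    function(x) sum(as.integer(x)), integer(1))
  as.numeric(table(factor(n_alpha, levels = 0:6)))
}
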