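#' @keywords internal
"_PACKAGE"

# Site convention: six alpha-beta binding sites laid out as two stacked
# trimeric rings. flat_index = 3*layer + position with layer in {0,1}
# (top/bottom) and position in {0,1,2} within a ring. Internally sites are
# 1-based (flat_index + 1); every exported surface documents 0-based
# flat_index to match the symmetry-expansion copy index.

N_SITES <- 6L

#' Site labels of the alpha6-beta6 scaffold
#'
#' Returns the fixed layout of the six alpha-beta binding sites: two layers
#' (trimeric rings) of three positions each, with
#' `flat_index = 3 * layer + position`.
#'
#' @return A data.frame with columns `flat_index` (0..5), `layer` (0..1) and
#'   `position` (0..2).
#' @export
#' @examples
#' site_layout()
site_layout <- function() {
  data.frame(
    flat_index = 0:5,
    layer = rep(0:1, each = 3L),
    position = rep(0:2, times = 2L)
  )
}

# Compose two permutations given as image vectors: site i -> q[p[i]].
compose_perm <- function(q, p) q[p]

perm_key <- function(p) paste(p, collapse = ",")

#' Build a point-group action on the six binding sites
#'
#' Constructs the permutation representation of a small point group acting on
#' the six alpha-beta binding sites. `"D3"` is the symmetry of the
#' alpha6-beta6 dodecamer: a 3-fold rotation `r` advancing the position
#' within each ring, `(layer, position) -> (layer, (position + 1) mod 3)`,
#' and a 2-fold flip `f` exchanging the rings,
#' `(layer, position) -> (1 - layer, -position mod 3)`. `"C3"` and `"C2"`
#' are the rotation and flip subgroups; `"trivial"` is the identity-only
#' group. The group is stored extensionally (explicit permutations), so
#' closure is directly checkable.
#'
#' @param name One of `"D3"`, `"C3"`, `"C2"`, `"trivial"`.
#' @return An object of class `pcc_action`: a list with `name` and `perms`,
#'   a matrix whose rows are permutations given as 1-based image vectors
#'   (row `g`, column `i`: site `i-1` maps to site `perms[g, i] - 1`).
#' @export
#' @examples
#' d3 <- point_group("D3")
#' nrow(d3$perms)  # 6 elements
point_group <- function(name = c("D3", "C3", "C2", "trivial")) {
  name <- match.arg(name)
  lay <- site_layout()
  # generator images, 1-based
  rot <- 3L * lay$layer + (lay$position + 1L) %% 3L + 1L
  flip <- 3L * (1L - lay$layer) + (-lay$position) %% 3L + 1L
  id <- 1:6
  gens <- switch(name,
    D3 = list(rot, flip),
    C3 = list(rot),
    C2 = list(flip),
    trivial = list()
  )
  elems <- list(id)
  names(elems) <- perm_key(id)
  repeat {
    new <- list()
    for (e in elems) {
      for (g in gens) {
        cand <- compose_perm(g, e)
        k <- perm_key(cand)
        if (is.null(elems[[k]]) && is.null(new[[k]])) new[[k]] <- cand
      }
    }
    if (length(new) == 0L) break
    elems <- c(elems, new)
  }
  perms <- do.call(rbind, unname(elems))
  # deterministic element order
  perms <- perms[order(apply(perms, 1L, perm_key)), , drop = FALSE]
  structure(list(name = name, perms = perms), class = "pcc_action")
}

#' @rdname point_group
#' @export
build_d3_action <- function() point_group("D3")

#' Validate a point-group action
#'
#' Checks that `action$perms` is a set of distinct bijections on the six
#' sites containing the identity and closed under composition (closure of a
#' finite set of bijections implies inverses).
#'
#' @param action A `pcc_action` (or a bare permutation matrix).
#' @return The validated `pcc_action`, invisibly.
#' @export
validate_action <- function(action) {
  if (is.matrix(action)) action <- structure(list(name = "custom", perms = action), class = "pcc_action")
  perms <- action$perms
  if (!is.matrix(perms) || ncol(perms) != N_SITES) {
    stop("action permutations must be a matrix with ", N_SITES, " columns")
  }
  keys <- apply(perms, 1L, perm_key)
  if (anyDuplicated(keys)) stop("action contains duplicate permutations")
  for (i in seq_len(nrow(perms))) {
    if (!setequal(perms[i, ], 1:6)) stop("row ", i, " is not a permutation of the 6 sites")
  }
  if (!perm_key(1:6) %in% keys) stop("action does not contain the identity")
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(perms))) {
      if (!perm_key(compose_perm(perms[i, ], perms[j, ])) %in% keys) {
        stop("action is not closed under composition")
      }
    }
  }
  invisible(action)
}

#' Enumerate all occupancy configurations
#'
#' All `2^6 = 64` binary occupancy states of the six alpha-beta binding
#' sites, in lexicographic order of the bit vector (flat_index 0 most
#' significant). Each configuration corresponds to one way of decorating the
#' beta-homohexamer with alpha-subunits.
#'
#' @return A 64 x 6 integer matrix of 0/1 bits; column `j` is site
#'   flat_index `j - 1`. Row order is deterministic and lexicographic.
#' @export
#' @examples
#' cfg <- enumerate_configs()
#' table(rowSums(cfg))  # binomial coefficients C(6, n)
enumerate_configs <- function() {
  g <- as.matrix(expand.grid(rep(list(0:1), N_SITES))[, N_SITES:1])
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g[order(apply(g, 1L, paste, collapse = "")), , drop = FALSE]
}

config_to_string <- function(bits) paste(bits, collapse = "")

# Apply a permutation (image vector) to a config: the subunit at site i
# moves to site perm[i].
apply_perm_to_config <- function(perm, bits) {
  out <- integer(N_SITES)
  out[perm] <- bits
  out
}

#' Enumerate oligomeric isomers (orbits) under a point-group action
#'
#' Partitions the 64 occupancy configurations into orbits under `action` by
#' brute-force closure. Each orbit is one oligomeric isomer; orbits sharing
#' the same number of bound alpha-subunits share an oligomeric formula
#' `alpha_n beta_6`. Under D3 this yields 16 isomers in 7 formulae.
#'
#' @param action A `pcc_action`, e.g. from [point_group()].
#' @return An object of class `pcc_census`: list with
#'   \describe{
#'     \item{orbits}{data.frame with `representative` (lexicographically
#'       minimal member, as a 6-char 0/1 string), `size` (orbit size) and
#'       `formula_n` (alpha count), ordered by representative.}
#'     \item{per_formula}{named integer vector, isomer count per formula
#'       n = 0..6.}
#'     \item{group}{the group name.}
#'   }
#' @export
#' @examples
#' cen <- enumerate_orbits(point_group("D3"))
#' nrow(cen$orbits)   # 16
#' cen$per_formula    # 1 1 4 4 4 1 1
enumerate_orbits <- function(action) {
  validate_action(action)
  cfgs <- enumerate_configs()
  keys <- apply(cfgs, 1L, config_to_string)
  idx_of <- seq_len(nrow(cfgs))
  names(idx_of) <- keys
  seen <- logical(nrow(cfgs))
  reps <- character(0)
  sizes <- integer(0)
  formula_n <- integer(0)
  for (i in seq_len(nrow(cfgs))) {
    if (seen[i]) next
    bits <- cfgs[i, ]
    members <- unique(apply(action$perms, 1L, function(p) {
      config_to_string(apply_perm_to_config(p, bits))
    }))
    seen[idx_of[members]] <- TRUE
    reps <- c(reps, min(members))
    sizes <- c(sizes, length(members))
    formula_n <- c(formula_n, sum(bits))
  }
  ord <- order(reps)
  orbits <- data.frame(
    representative = reps[ord],
    size = sizes[ord],
    formula_n = formula_n[ord],
    stringsAsFactors = FALSE
  )
  per_formula <- integer(7L)
  names(per_formula) <- as.character(0:6)
  tab <- table(factor(orbits$formula_n, levels = 0:6))
  per_formula[] <- as.integer(tab)
  structure(
    list(orbits = orbits, per_formula = per_formula, group = action$name),
    class = "pcc_census"
  )
}

#' @export
print.pcc_census <- function(x, ...) {
  cat("Isomer census under", x$group, "symmetry:",
      nrow(x$orbits), "oligomeric isomers,",
      sum(x$per_formula > 0L), "oligomeric formulae\n")
  cat("isomers per formula alpha_n beta_6:\n")
  print(x$per_formula)
  invisible(x)
}

# number of cycles of a permutation (image-vector form)
count_cycles <- function(perm) {
  visited <- logical(length(perm))
  n <- 0L
  for (i in seq_along(perm)) {
    if (visited[i]) next
    n <- n + 1L
    j <- i
    while (!visited[j]) {
      visited[j] <- TRUE
      j <- perm[j]
    }
  }
  n
}

#' Count orbits with Burnside's lemma
#'
#' Independent oracle for [enumerate_orbits()]: the number of orbits equals
#' the group-averaged number of configurations fixed by each element. A
#' permutation with `c` cycles on the sites fixes `2^c` binary
#' configurations, so the count is `mean(2^cycles(g))` over the group.
#'
#' @inheritParams enumerate_orbits
#' @return Integer orbit count (16 for D3).
#' @export
burnside_count <- function(action) {
  validate_action(action)
  fixed <- apply(action$perms, 1L, function(p) 2^count_cycles(p))
  total <- sum(fixed) / nrow(action$perms)
  if (abs(total - round(total)) > 1e-9) stop("Burnside average is not an integer; invalid group")
  as.integer(round(total))
}
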