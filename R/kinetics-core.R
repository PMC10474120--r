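# Nonterminal (chain-end-independent) copolymerization model.
#
# In a living ring-opening copolymerization where the addition probability
# depends only on the incoming monomer, each monomer i is consumed first
# order in itself: d[M_i]/dt = -k_i [M_i] [P*]. All observable composition
# quantities then depend only on the rate *ratios* k_i/k_j. Writing
# a_i = [M_i]/[M_i]0 for the surviving fraction ("survival") of monomer i,
# the drift law couples the species: a_j = a_i^(k_j/k_i).

#' Monomer specification
#'
#' @param name Short species label (e.g. `"EtPPn"`), unique within a system.
#' @param molar_mass Molar mass of the repeat unit in g/mol.
#' @param shift_monomer,shift_polymer Optional 31P chemical shifts (ppm) of
#'   the monomer and incorporated-unit resonances; metadata only.
#' @return An object of class `monomer_spec`.
#' @export
monomer_spec <- function(name, molar_mass,
                         shift_monomer = NA_real_, shift_polymer = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0) {
    stop("molar_mass must be a single positive number")
  }
  structure(
    list(name = name, molar_mass = molar_mass,
         shift_monomer = shift_monomer, shift_polymer = shift_polymer),
    class = "monomer_spec"
  )
}

#' Relative propagation rate set
#'
#' Holds one relative propagation rate `k_i` per species. Only ratios are
#' identifiable from composition data, so by convention the last entry is
#' rescaled to 1. Every pairwise reactivity ratio is `r_xy = k_x / k_y`,
#' which automatically satisfies the ideal relations `r_xy * r_yx = 1` and
#' `r_xz = r_xy * r_yz`.
#'
#' @param k Positive numeric vector of relative propagation rates.
#' @param species Character labels, same length as `k` (default A, B, C...).
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(k, species = NULL) {
  k <- as.numeric(k)
  if (length(k) < 1L || any(!is.finite(k)) || any(k <= 0)) {
    stop("all relative rates k must be finite and > 0")
  }
  if (is.null(species)) species <- LETTERS[seq_along(k)]
  species <- as.character(species)
  stopifnot(length(species) == length(k))
  if (anyDuplicated(species)) stop("species names must be unique")
  structure(
    list(species = species, k = k / k[length(k)]),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> ", paste0(x$species, ": k=", signif(x$k, 6),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise reactivity ratio from a rate set
#'
#' @param rates A [rate_set()].
#' @param x,y Species names or indices; returns `k_x / k_y`.
#' @export
reactivity_ratio <- function(rates, x, y) {
  kx <- rates$k[.species_index(rates, x)]
  ky <- rates$k[.species_index(rates, y)]
  kx / ky
}

.species_index <- function(rates, s) {
  if (is.character(s)) {
    i <- match(s, rates$species)
    if (anyNA(i)) stop("unknown species: ", paste(s[is.na(i)], collapse = ", "))
    i
  } else {
    as.integer(s)
  }
}

#' Monomer drift under the nonterminal model
#'
#' Integrating d[A]/d[B] = r [A]/[B] (r = k_A/k_B) gives the power-law drift
#' `b = a^(1/r)` between the surviving fractions a = [A]/[A]0 and
#' b = [B]/[B]0.
#'
#' @param r Rate ratio k_A/k_B, > 0.
#' @param a Surviving fraction of A, in (0, 1].
#' @return Surviving fraction of B, in (0, 1].
#' @examples
#' drift(2, 0.25) # 0.5
#' @export
drift <- function(r, a) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop("rate ratio r must be positive and finite")
  }
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0) || any(a > 1)) {
    stop("survival a must lie in (0, 1]")
  }
  a^(1 / r)
}

#' Ideal reactivity-ratio pair from a gradient strength
#'
#' Under the ideal assumption r1 * r2 = 1 the gradient strength
#' `delta_r = r1 - r2` determines the pair uniquely:
#' `r1 = (delta_r + sqrt(delta_r^2 + 4)) / 2`, `r2 = 1/r1`.
#'
#' @param delta_r Non-negative gradient strength (order the pair so r1 >= r2).
#' @return Named numeric vector `c(r1, r2)` with `r1 - r2 == delta_r`.
#' @examples
#' ratios_from_delta(5)  # r1 = (5 + sqrt(29))/2
#' @export
ratios_from_delta <- function(delta_r) {
  stopifnot(is.numeric(delta_r), length(delta_r) == 1L, is.finite(delta_r))
  if (delta_r < 0) {
    stop("delta_r must be >= 0; order the pair so that r1 >= r2 first")
  }
  r1 <- (delta_r + sqrt(delta_r^2 + 4)) / 2
  c(r1 = r1, r2 = 1 / r1)
}

.check_f0 <- function(f0, n) {
  f0 <- as.numeric(f0)
  stopifnot(length(f0) == n, all(f0 >= 0))
  if (abs(sum(f0) - 1) > 1e-12) {
    stop("feed fractions f0 must sum to 1 (within 1e-12); got sum ",
         fmt_num(sum(f0)))
  }
  f0
}

#' Full feed state at a given survival of a reference species
#'
#' Given relative rates, the initial feed and the surviving fraction `a_ref`
#' of a reference species, the drift law fixes every other survival
#' `a_i = a_ref^(k_i/k_ref)` and hence the total conversion
#' `X = 1 - sum(f0_i * a_i)`, the instantaneous unreacted-feed fractions
#' `f_i = f0_i a_i / sum(f0_j a_j)` and the cumulative incorporated
#' fractions `F_i = f0_i (1 - a_i) / X` (defined as the continuous limit
#' `F_i = f0_i` at X = 0).
#'
#' @param rates A [rate_set()].
#' @param f0 Initial mole fractions, summing to 1.
#' @param a_ref Survival of the reference species, in (0, 1].
#' @param ref Index or name of the reference species (default first).
#' @return List with `X`, `survival`, `f` (instantaneous), `F` (cumulative).
#' @export
conversion_state <- function(rates, f0, a_ref, ref = 1L) {
  stopifnot(inherits(rates, "rate_set"))
  f0 <- .check_f0(f0, length(rates$k))
  if (!is.numeric(a_ref) || length(a_ref) != 1L || a_ref <= 0 || a_ref > 1) {
    stop("a_ref must lie in (0, 1]")
  }
  i_ref <- .species_index(rates, ref)
  a <- a_ref^(rates$k / rates$k[i_ref])
  X <- 1 - sum(f0 * a)
  X <- max(X, 0) # guard tiny negative round-off at a_ref = 1
  f <- f0 * a / sum(f0 * a)
  Fc <- if (X > 0) f0 * (1 - a) / X else f0
  names(a) <- names(f) <- names(Fc) <- rates$species
  list(X = X, survival = a, f = f, F = Fc)
}

# Vectorized bisection: survival of the *slowest* species at each requested
# total conversion. Parametrizing by the slowest species keeps all powers
# k_i/k_min >= 1, so no survival underflows even for rate ratios ~1e2.
survival_at_conversion <- function(rates, f0, X, tol = 1e-12) {
  stopifnot(inherits(rates, "rate_set"))
  f0 <- .check_f0(f0, length(rates$k))
  if (any(X < 0 | X >= 1)) stop("total conversion X must lie in [0, 1)")
  slow <- which.min(rates$k)
  p <- rates$k / rates$k[slow]
  X_of <- function(a) 1 - as.numeric(crossprod(f0, outer(p, a, function(pp, aa) aa^pp)))
  lo <- rep(0, length(X))
  hi <- rep(1, length(X))
  # X(a) is strictly decreasing in a; bisect until the bracket is < tol.
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    too_small <- X_of(mid) > X # a too small -> conversion overshoots
    lo <- ifelse(too_small, mid, lo)
    hi <- ifelse(too_small, hi, mid)
    if (max(hi - lo) < tol) break
  }
  a_slow <- (lo + hi) / 2
  a_slow[X == 0] <- 1
  list(a_slow = a_slow, slow = slow, p = p)
}

#' Composition-versus-conversion curve
#'
#' Evaluates the instantaneous and cumulative copolymer composition on a
#' monotone grid of total conversion, the coordinate system of the
#' composition plots and the ideal-integrated fit.
#'
#' @param rates A [rate_set()].
#' @param f0 Initial mole fractions.
#' @param n_grid Number of grid points (>= 2).
#' @param final_conversion Upper end of the grid, in (0, 1); capped at 0.999
#'   to avoid power-law underflow at complete conversion.
#' @return An object of class `composition_curve`: list with `X` (grid),
#'   `f` and `F` (n_grid x n_species matrices), `survival`, `species`.
#' @export
composition_curve <- function(rates, f0, n_grid = 201L,
                              final_conversion = 0.999) {
  stopifnot(inherits(rates, "rate_set"), n_grid >= 2)
  f0 <- .check_f0(f0, length(rates$k))
  final_conversion <- min(final_conversion, 0.999)
  stopifnot(final_conversion > 0)
  X <- seq(0, final_conversion, length.out = n_grid)
  sv <- survival_at_conversion(rates, f0, X)
  a <- outer(sv$a_slow, sv$p, `^`) # n_grid x n_species
  denom <- as.numeric(a %*% f0)
  f <- sweep(a, 2, f0, `*`) / denom
  Xsafe <- ifelse(X > 0, X, 1)
  Fc <- sweep(1 - a, 2, f0, `*`) / Xsafe
  Fc[X == 0, ] <- matrix(f0, nrow = sum(X == 0), ncol = length(f0),
                         byrow = TRUE)
  colnames(f) <- colnames(Fc) <- colnames(a) <- rates$species
  structure(
    list(X = X, f = f, F = Fc, survival = a,
         species = rates$species, rates = rates, f0 = f0),
    class = "composition_curve"
  )
}

#' @export
print.composition_curve <- function(x, ...) {
  cat("<composition_curve> ", length(x$X), " points, X in [0, ",
      fmt_num(max(x$X)), "], species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project a (possibly inconsistent) ratio table onto a rate set
#'
#' Six fitted pairwise ratios of a ternary system are noisy views of only
#' two free parameters (relative rates with one fixed to 1). This projects
#' a matrix of fitted `r_xy` onto the closest consistent [rate_set()] by
#' least squares on log k (equivalent to a geometric mean of the k-estimates
#' each ratio implies).
#'
#' @param ratio_matrix Square matrix with `[x, y] = r_xy`; diagonal ignored;
#'   `NA` entries (e.g. excluded fits) are skipped.
#' @param species Optional species names (default from dimnames).
#' @return A [rate_set()].
#' @export
project_rate_set <- function(ratio_matrix, species = NULL) {
  stopifnot(is.matrix(ratio_matrix), nrow(ratio_matrix) == ncol(ratio_matrix))
  n <- nrow(ratio_matrix)
  if (is.null(species)) species <- rownames(ratio_matrix)
  if (is.null(species)) species <- LETTERS[seq_len(n)]
  # Equations log k_x - log k_y = log r_xy, reference: k_n = 1.
  rows <- list(); rhs <- numeric(0)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y || is.na(ratio_matrix[x, y])) next
    v <- numeric(n); v[x] <- 1; v[y] <- -1
    rows[[length(rows) + 1L]] <- v
    rhs <- c(rhs, log(ratio_matrix[x, y]))
  }
  if (!length(rows)) stop("no usable ratios in matrix")
  A <- do.call(rbind, rows)[, -n, drop = FALSE]
  logk <- c(stats::coef(stats::lm.fit(A, rhs)), 0)
  logk[is.na(logk)] <- 0
  rate_set(exp(logk), species = species)
}
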