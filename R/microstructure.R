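# Monte Carlo chain microstructure under the nonterminal model.
#
# A shared monomer pool is split by the feed fractions; chains grow
# round-robin (each round every chain adds exactly one unit), which makes
# every chain the same length - dispersity exactly 1 - while all chains
# compete for the same depleting pool. At each addition the incoming
# monomer i is drawn with probability k_i N_i / sum_j k_j N_j, the
# nonterminal addition probability with N_i the remaining pool count.

#' Simulate a chain ensemble
#'
#' @param rates A [rate_set()].
#' @param f0 Feed mole fractions.
#' @param n_chains Number of chains (default 10, mirroring the standard
#'   microstructure plots).
#' @param L Chain length (default 100).
#' @param final_conversion Fraction of the pool consumed when all chains
#'   are complete; the pool holds `round(n_chains * L / final_conversion)`
#'   units (largest-remainder split by `f0`), so chain ends represent the
#'   composition actually reached at that conversion.
#' @param seed Integer RNG seed; identical seed gives an identical
#'   ensemble.
#' @return Object of class `chain_ensemble`: `chains` (n_chains x L
#'   integer matrix of species indices), `draw_order` (species index per
#'   global draw), `pool_initial`, `pool_final`, `N_total`, `species`,
#'   `rates`, `f0`, `seed`.
#' @export
simulate_chains <- function(rates, f0, n_chains = 10L, L = 100L,
                            final_conversion = 1, seed = 1L) {
  stopifnot(inherits(rates, "rate_set"), n_chains >= 1, L >= 1,
            final_conversion > 0, final_conversion <= 1)
  f0 <- .check_f0(f0, length(rates$k))
  n_draw <- n_chains * L
  N_total <- round(n_draw / final_conversion)
  pool0 <- largest_remainder(f0, N_total)
  if (sum(pool0) < n_draw) {
    stop("pool of ", sum(pool0), " units cannot supply ", n_draw,
         " chain units; check final_conversion/rounding")
  }
  ns <- length(f0)
  k <- rates$k
  draw_order <- integer(n_draw)
  pool <- as.numeric(pool0)
  with_seed(seed, {
    for (d in seq_len(n_draw)) {
      wts <- k * pool
      tot <- sum(wts)
      if (tot <= 0) {
        stop("monomer pool exhausted after ", d - 1L, " of ", n_draw,
             " draws")
      }
      u <- stats::runif(1) * tot
      i <- 1L
      acc <- wts[1L]
      while (acc < u && i < ns) {
        i <- i + 1L
        acc <- acc + wts[i]
      }
      draw_order[d] <- i
      pool[i] <- pool[i] - 1
    }
  })
  # Round-robin assignment: draw d extends chain ((d-1) mod n) at position
  # ((d-1) div n) + 1.
  chains <- matrix(draw_order, nrow = n_chains)
  structure(
    list(chains = chains, draw_order = draw_order,
         pool_initial = pool0, pool_final = as.integer(round(pool)),
         N_total = N_total, species = rates$species,
         rates = rates, f0 = f0, seed = as.integer(seed)),
    class = "chain_ensemble"
  )
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat("<chain_ensemble> ", nrow(x$chains), " chains x ", ncol(x$chains),
      " units from a pool of ", x$N_total, " (species: ",
      paste(x$species, collapse = ", "), ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Microstructure summary of a chain ensemble
#'
#' @param ensemble A [simulate_chains()] result.
#' @return Object of class `microstructure_summary`:
#'   `position_composition` (L x n_species matrix: fraction of chains
#'   carrying each species at each position), `cumulative` (data frame:
#'   conversion `X = draws/N_total` and running incorporated fractions
#'   after each draw), `junctions` (per-chain count of adjacent unlike
#'   units), `chain_composition` (n_chains x n_species fractions).
#' @export
summarize_chains <- function(ensemble) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  ch <- ensemble$chains
  ns <- length(ensemble$species)
  L <- ncol(ch)
  pos <- vapply(seq_len(ns), function(s) colMeans(ch == s),
                numeric(L))
  pos <- matrix(pos, nrow = L, dimnames = list(NULL, ensemble$species))
  d <- ensemble$draw_order
  cum <- vapply(seq_len(ns), function(s) cumsum(d == s),
                numeric(length(d)))
  cum <- matrix(cum / seq_along(d), ncol = ns,
                dimnames = list(NULL, ensemble$species))
  cumulative <- data.frame(draw = seq_along(d),
                           X = seq_along(d) / ensemble$N_total, cum,
                           check.names = FALSE)
  junctions <- apply(ch, 1, function(row) sum(diff(row) != 0))
  chain_comp <- matrix(t(apply(ch, 1, function(row)
    tabulate(row, nbins = ns) / L)), ncol = ns,
    dimnames = list(NULL, ensemble$species))
  structure(
    list(position_composition = pos, cumulative = cumulative,
         junctions = junctions, chain_composition = chain_comp,
         species = ensemble$species),
    class = "microstructure_summary"
  )
}

#' Cumulative incorporated fraction at chosen conversions
#'
#' Reads the running composition of the ensemble at the draws closest to
#' the requested total conversions, for comparison with the analytic
#' [composition_curve()].
#'
#' @param ensemble A [simulate_chains()] result.
#' @param X Conversions in (0, drawn fraction].
#' @return Data frame with `X` (actual draw-based conversion), `n_drawn`
#'   and one incorporated-fraction column per species.
#' @export
cumulative_at <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  d <- ensemble$draw_order
  ns <- length(ensemble$species)
  idx <- pmin(pmax(round(X * ensemble$N_total), 1), length(d))
  cum <- matrix(vapply(seq_len(ns), function(s) cumsum(d == s),
                       numeric(length(d))), ncol = ns)
  out <- cum[idx, , drop = FALSE] / idx
  colnames(out) <- ensemble$species
  data.frame(X = idx / ensemble$N_total, n_drawn = idx, out,
             check.names = FALSE)
}

.chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Serialize chains as text
#'
#' One line per chain (e.g. `"AABABBB..."`), preceded by `#` header lines
#' giving the label map and seed.
#'
#' @param ensemble A [simulate_chains()] result.
#' @return Character vector of lines.
#' @export
chains_to_text <- function(ensemble) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  ns <- length(ensemble$species)
  if (ns > length(.chain_alphabet)) {
    stop("more than ", length(.chain_alphabet),
         " species: label alphabet exhausted")
  }
  lab <- .chain_alphabet[seq_len(ns)]
  header <- c(
    paste0("# labels: ", paste(lab, "=", ensemble$species,
                               sep = "", collapse = ", ")),
    paste0("# seed: ", ensemble$seed)
  )
  body <- apply(ensemble$chains, 1, function(row)
    paste(lab[row], collapse = ""))
  c(header, body)
}

#' Parse chain text records
#'
#' Inverse of [chains_to_text()] up to the ensemble fields that text
#' retains (chains and label map).
#'
#' @param lines Character vector as produced by [chains_to_text()].
#' @return List with `chains` (integer matrix) and `species`.
#' @export
parse_chain_text <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  lab_line <- grep("^# labels:", hdr, value = TRUE)
  if (!length(lab_line)) stop("missing '# labels:' header")
  pairs <- strsplit(trimws(strsplit(sub("^# labels:\\s*", "", lab_line),
                                    ",")[[1]]), "=")
  lab <- vapply(pairs, `[`, character(1), 1)
  species <- vapply(pairs, `[`, character(1), 2)
  L <- nchar(body[1])
  if (any(nchar(body) != L)) stop("chains have unequal lengths")
  rows <- lapply(strsplit(body, ""), function(chs) {
    i <- match(chs, lab)
    if (anyNA(i)) stop("unknown chain label: ",
                       paste(unique(chs[is.na(i)]), collapse = ", "))
    i
  })
  chains <- do.call(rbind, rows)
  list(chains = chains, species = species)
}
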