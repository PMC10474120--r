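# Internal helpers shared across the pipeline.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never leak into (or depend on) global
#' RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# IUPAC 2021 standard atomic weights (conventional values) for the elements
# occurring in phosphoester monomers and initiators.
.atomic_weights <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999,
  P = 30.973761998, S = 32.06
)

#' Molar mass from a molecular formula
#'
#' Parses a Hill-style formula such as `"C4H9O3PS"` and sums IUPAC standard
#' atomic weights.
#'
#' @param formula Character molecular formula (elements C, H, N, O, P, S).
#' @return Molar mass in g/mol.
#' @examples
#' formula_mass("C3H8O2") # 2-methoxyethanol, 76.094
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse molecular formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.atomic_weights)) {
      stop("unknown element '", el, "' in formula ", formula)
    }
    total <- total + .atomic_weights[[el]] * n
  }
  total
}

#' Largest-remainder integer allocation
#'
#' Distributes `total` integer units proportionally to `x`, assigning the
#' leftover units to the largest fractional remainders. Used for rounded
#' composition percentages and for splitting a monomer pool by feed
#' fractions.
#'
#' @param x Non-negative weights.
#' @param total Integer total to allocate.
#' @return Integer vector summing exactly to `total`.
#' @export
largest_remainder <- function(x, total = 100L) {
  stopifnot(all(x >= 0), sum(x) > 0, total >= 0)
  q <- x / sum(x) * total
  fl <- floor(q)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0L) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# Fixed-format numeric rendering so serialized outputs are byte-stable.
fmt_num <- function(x) sprintf("%.12g", x)
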