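# Ingestion of integral time-series tables and conversion extraction.
#
# CSV dialect: optional leading '#' comment lines carrying metadata
# (`# species=A,B`, `# feed=0.5,0.5`, `# initiator=...`, `# seed=...`),
# then a header `time_min,<sp>_monomer,<sp>_polymer,...`, UTF-8, '.'
# decimal separator.

#' Kinetics dataset
#'
#' Time-stamped monomer and polymer 31P integrals per species, the raw
#' input of the pipeline.
#'
#' @param time Acquisition times in minutes, strictly increasing, >= 4.
#' @param monomer,polymer Numeric matrices (time x species) of integrals in
#'   arbitrary common units; negative values are clipped to 0 with a
#'   warning.
#' @param species Character species labels (column order).
#' @param meta Named list of metadata (feed fractions, provenance, ...).
#' @return An object of class `kinetics_dataset`.
#' @export
kinetics_dataset <- function(time, monomer, polymer, species, meta = list()) {
  time <- as.numeric(time)
  monomer <- as.matrix(monomer)
  polymer <- as.matrix(polymer)
  species <- as.character(species)
  if (length(time) < 4L) {
    stop("at least 4 time points are required for any fit; got ",
         length(time))
  }
  if (any(diff(time) <= 0)) stop("time not strictly increasing")
  if (nrow(monomer) != length(time) || nrow(polymer) != length(time) ||
      ncol(monomer) != length(species) || ncol(polymer) != length(species)) {
    stop("monomer/polymer must be time x species matrices matching ",
         "length(time) and length(species)")
  }
  if (anyDuplicated(species)) stop("species names must be unique")
  for (nm in c("monomer", "polymer")) {
    m <- get(nm)
    if (any(!is.finite(m))) stop("non-finite values in ", nm, " integrals")
    if (any(m < 0)) {
      warning(sum(m < 0), " negative ", nm, " integral(s) clipped to 0")
      m[m < 0] <- 0
      assign(nm, m)
    }
  }
  colnames(monomer) <- colnames(polymer) <- species
  structure(
    list(time = time, monomer = monomer, polymer = polymer,
         species = species, meta = meta),
    class = "kinetics_dataset"
  )
}

#' @export
print.kinetics_dataset <- function(x, ...) {
  cat("<kinetics_dataset> ", length(x$time), " spectra over ",
      fmt_num(max(x$time)), " min, species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a kinetics dataset as CSV
#'
#' Serializes in the package's CSV dialect with fixed numeric formatting,
#' so identical datasets produce byte-identical files.
#'
#' @param ds A [kinetics_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(ds, path) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  hdr <- c(paste0("# species=", paste(ds$species, collapse = ",")))
  if (!is.null(ds$meta$feed)) {
    # full precision so feed fractions round-trip exactly
    hdr <- c(hdr, paste0("# feed=", paste(sprintf("%.17g", ds$meta$feed),
                                          collapse = ",")))
  }
  if (!is.null(ds$meta$initiator)) {
    hdr <- c(hdr, paste0("# initiator=", ds$meta$initiator))
  }
  if (!is.null(ds$meta$seed)) {
    hdr <- c(hdr, paste0("# seed=", ds$meta$seed))
  }
  cols <- c("time_min",
            as.vector(rbind(paste0(ds$species, "_monomer"),
                            paste0(ds$species, "_polymer"))))
  body <- cbind(ds$time,
                do.call(cbind, lapply(seq_along(ds$species), function(i) {
                  cbind(ds$monomer[, i], ds$polymer[, i])
                })))
  lines <- c(hdr, paste(cols, collapse = ","),
             apply(body, 1, function(r) paste(fmt_num(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinetics dataset from CSV
#'
#' @param path CSV file in the dialect written by [write_kinetics_csv()]:
#'   header `time_min,<sp>_monomer,<sp>_polymer,...` with optional leading
#'   `#` metadata lines.
#' @return A [kinetics_dataset()].
#' @export
read_kinetics_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    kv <- sub("^\\s*#\\s*", "", cl)
    if (!grepl("=", kv)) next
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- if (key %in% c("feed", "seed")) {
      as.numeric(strsplit(val, ",")[[1]])
    } else if (key == "species") {
      strsplit(val, ",")[[1]]
    } else {
      val
    }
  }
  df <- utils::read.csv(text = paste(lines[!is_comment], collapse = "\n"),
                        check.names = FALSE)
  if (!"time_min" %in% names(df)) {
    stop("missing required column 'time_min'; found: ",
         paste(names(df), collapse = ", "))
  }
  mon_cols <- grep("_monomer$", names(df), value = TRUE)
  pol_cols <- grep("_polymer$", names(df), value = TRUE)
  species <- sub("_monomer$", "", mon_cols)
  if (!length(species)) stop("no '<species>_monomer' columns found")
  missing_pol <- setdiff(paste0(species, "_polymer"), pol_cols)
  if (length(missing_pol)) {
    stop("missing polymer column(s): ", paste(missing_pol, collapse = ", "))
  }
  if (nrow(df) < 4L) {
    stop("at least 4 rows are required; got ", nrow(df))
  }
  tm <- df[["time_min"]]
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1] + 1L
    stop("time not strictly increasing (first violation at row ", bad, ")")
  }
  kinetics_dataset(
    time = tm,
    monomer = as.matrix(df[mon_cols]),
    polymer = as.matrix(df[paste0(species, "_polymer")]),
    species = species, meta = meta
  )
}

#' Per-monomer and total conversion from integrals
#'
#' The default "paired" normalization uses each species' own monomer and
#' polymer resonances, `x_i = P_i / (M_i + P_i)`, which is invariant to
#' per-spectrum gain. The `monomer_only` mode, for cases where polymer
#' resonances overlap, uses `x_i = 1 - M_i(t) / M_i(0)`. The total
#' conversion is the feed-weighted mean `X = sum(f0_i x_i)`.
#'
#' @param ds A [kinetics_dataset()].
#' @param mode `"paired"` (default) or `"monomer_only"`.
#' @param f0 Feed fractions; defaults to `ds$meta$feed`, else to the first
#'   spectrum's normalized monomer integrals.
#' @return An object of class `conversion_series`: list with `time`, `x`
#'   (time x species conversions), `X` (total), `f0`, `species`.
#' @export
conversions <- function(ds, mode = c("paired", "monomer_only"), f0 = NULL) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  mode <- match.arg(mode)
  if (mode == "paired") {
    tot <- ds$monomer + ds$polymer
    if (any(tot == 0)) {
      bad <- which(tot == 0, arr.ind = TRUE)[1, ]
      stop("monomer + polymer integral is zero for species '",
           ds$species[bad[2]], "' at row ", bad[1])
    }
    x <- ds$polymer / tot
  } else {
    m0 <- ds$monomer[1, ]
    if (any(m0 == 0)) {
      stop("initial monomer integral is zero for species '",
           ds$species[which(m0 == 0)[1]], "'")
    }
    x <- 1 - sweep(ds$monomer, 2, m0, `/`)
  }
  if (is.null(f0)) f0 <- ds$meta$feed
  if (is.null(f0)) {
    m0 <- ds$monomer[1, ]
    f0 <- m0 / sum(m0)
  }
  stopifnot(length(f0) == length(ds$species), all(f0 >= 0))
  if (abs(sum(f0) - 1) > 1e-6) {
    stop("feed fractions must sum to 1; got ", fmt_num(sum(f0)))
  }
  f0 <- f0 / sum(f0) # absorb serialization round-off
  X <- as.numeric(x %*% f0)
  structure(
    list(time = ds$time, x = x, X = X, f0 = f0, species = ds$species),
    class = "conversion_series"
  )
}

#' @export
print.conversion_series <- function(x, ...) {
  cat("<conversion_series> ", length(x$time), " points, X(end) = ",
      fmt_num(x$X[length(x$X)]), ", species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Truncate a conversion series at a maximum total conversion
#'
#' Reactivity-ratio fits use data up to 60% total conversion by default;
#' beyond that, the depleted feed and accumulating error make the
#' nonterminal fits unstable.
#'
#' @param series A [conversions()] result.
#' @param x_max Keep points with total conversion `X <= x_max`.
#' @return The truncated `conversion_series`.
#' @export
truncate_conversions <- function(series, x_max = 0.60) {
  stopifnot(inherits(series, "conversion_series"),
            x_max > 0, x_max <= 1)
  keep <- series$X <= x_max
  if (sum(keep) < 4L) {
    stop("fewer than 4 points with X <= ", x_max,
         " survive truncation; use a larger x_max")
  }
  out <- series
  out$time <- series$time[keep]
  out$x <- series$x[keep, , drop = FALSE]
  out$X <- series$X[keep]
  out
}

#' Quality control of a kinetics dataset
#'
#' Exploits total 31P conservation: per species, the summed monomer +
#' polymer integral should be constant over time. Reports the relative
#' systematic drift of each species' sum (magnitude of the fitted linear
#' trend over the run, divided by the mean — insensitive to zero-mean
#' integration noise), warning above 5%, plus the noise level (coefficient
#' of variation) and non-monotone per-species conversion counts.
#'
#' @param ds A [kinetics_dataset()].
#' @param warn_drift Relative drift threshold for a warning (default 0.05).
#' @return List of class `kinetics_qc`: `drift` per species,
#'   `nonmonotone_steps` per species, `flags` character vector.
#' @export
qc_kinetics <- function(ds, warn_drift = 0.05) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  tot <- ds$monomer + ds$polymer
  drift <- apply(tot, 2, function(s) {
    if (mean(s) == 0) return(NA_real_)
    slope <- stats::cov(ds$time, s) / stats::var(ds$time)
    abs(slope) * diff(range(ds$time)) / mean(s)
  })
  cv <- apply(tot, 2, function(s) {
    if (mean(s) == 0) NA_real_ else stats::sd(s) / mean(s)
  })
  cs <- conversions(ds)
  nonmono <- apply(cs$x, 2, function(v) sum(diff(v) < 0))
  flags <- character(0)
  bad <- names(drift)[!is.na(drift) & drift > warn_drift]
  if (length(bad)) {
    flags <- c(flags, paste0("total-signal drift > ", 100 * warn_drift,
                             "% for species: ", paste(bad, collapse = ", ")))
    warning(flags[length(flags)])
  }
  structure(
    list(drift = drift, cv = cv, nonmonotone_steps = nonmono,
         flags = flags),
    class = "kinetics_qc"
  )
}

#' Serialize a QC report as JSON
#' @param qc A [qc_kinetics()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  stopifnot(inherits(qc, "kinetics_qc"))
  jsonlite::write_json(
    list(drift = as.list(qc$drift), cv = as.list(qc$cv),
         nonmonotone_steps = as.list(qc$nonmonotone_steps),
         flags = qc$flags),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
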