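# Reactivity-ratio estimation by three nonterminal models.
#
# All three estimators are reparametrizations of the same drift law
# (1 - x_B) = (1 - x_A)^(1/r1) and therefore agree exactly on noiseless
# data; they weight noise differently:
#   jaacks - through-origin regression of ln(1/(1-x_A)) on ln(1/(1-x_B));
#   bsl    - least squares directly in conversion-conversion coordinates;
#   ideal  - least squares of the instantaneous unreacted-feed fraction
#            against the integrated composition curve in total-conversion
#            coordinates.

.LOGR_BOUNDS <- log(c(1e-3, 1e3))

.pair_conversions <- function(series, pair) {
  stopifnot(inherits(series, "conversion_series"), length(pair) == 2L)
  idx <- match(pair, series$species)
  if (anyNA(idx)) {
    stop("unknown species in pair: ",
         paste(pair[is.na(idx)], collapse = ", "))
  }
  xA <- series$x[, idx[1]]
  xB <- series$x[, idx[2]]
  drop <- xA >= 1 | xB >= 1
  if (any(drop)) {
    warning(sum(drop), " point(s) with conversion >= 1 dropped for pair ",
            pair[1], "/", pair[2])
    xA <- xA[!drop]; xB <- xB[!drop]
  }
  if (all(xA == 0) && all(xB == 0)) stop("no consumption: all conversions 0")
  if (sum(xA > 0 & xA < 1 & xB > 0 & xB < 1) < 4L) {
    stop("need >= 4 points with conversions in (0, 1) for both species")
  }
  list(xA = xA, xB = xB, idx = idx)
}

.estimate <- function(model, pair, r1, r2, se1, se2, R2, n) {
  structure(
    list(model = model, pair = pair, r1 = r1, r2 = r2,
         se1 = se1, se2 = se2, R2 = R2, n_points = n),
    class = "reactivity_estimate"
  )
}

#' @export
print.reactivity_estimate <- function(x, ...) {
  cat(sprintf("<reactivity_estimate> %s  %s/%s: r1 = %.4g +/- %.2g, r2 = %.4g +/- %.2g (R2 = %.4f, n = %d)\n",
              x$model, x$pair[1], x$pair[2], x$r1, x$se1, x$r2, x$se2,
              x$R2, x$n_points))
  invisible(x)
}

# Through-origin least squares of u on v; returns slope, se, R2.
.origin_slope <- function(u, v) {
  sl <- sum(u * v) / sum(v * v)
  res <- u - sl * v
  n <- length(u)
  se <- if (n > 1) sqrt(sum(res^2) / (n - 1) / sum(v^2)) else NA_real_
  R2 <- 1 - sum(res^2) / sum(u^2)
  list(slope = sl, se = se, R2 = R2)
}

#' Jaacks fit
#'
#' Under the nonterminal model the log-drifts are proportional:
#' `ln(1/(1-x_A)) = r1 * ln(1/(1-x_B))`. `r1` is the through-origin
#' least-squares slope (the drift law has no intercept); `r2` comes from
#' the swapped regression.
#'
#' @param series A [conversions()] series (typically truncated with
#'   [truncate_conversions()]).
#' @param pair Character vector of two species names `(A, B)`.
#' @return A `reactivity_estimate`.
#' @export
fit_jaacks <- function(series, pair) {
  pc <- .pair_conversions(series, pair)
  u <- log(1 / (1 - pc$xA))
  v <- log(1 / (1 - pc$xB))
  d1 <- .origin_slope(u, v)
  d2 <- .origin_slope(v, u)
  .estimate("jaacks", pair, d1$slope, d2$slope, d1$se, d2$se,
            min(d1$R2, d2$R2), length(u))
}

# Bounded 1-D least squares on log r; errors if the optimum sticks to a
# bound. Returns r, se (curvature-based), R2.
.fit_logr <- function(obj, y, n) {
  opt <- stats::optimize(function(lr) obj(exp(lr)),
                         interval = .LOGR_BOUNDS, tol = 1e-10)
  if (min(abs(opt$minimum - .LOGR_BOUNDS)) < 1e-6) {
    stop("optimizer at bound (r outside [1e-3, 1e3]); inspect the data")
  }
  r <- exp(opt$minimum)
  S <- opt$objective
  h <- 1e-4 * r
  d2 <- (obj(r + h) - 2 * S + obj(r - h)) / h^2
  sigma2 <- S / max(n - 1, 1)
  se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  sst <- sum((y - mean(y))^2)
  R2 <- if (sst > 0) 1 - S / sst else 1
  list(r = r, se = se, R2 = R2)
}

#' BSL fit
#'
#' Nonterminal integrated fit directly in conversion-conversion
#' coordinates: `r1` minimizes `sum((x_B - (1 - (1-x_A)^(1/r)))^2)` by
#' bounded 1-D minimization on log r; `r2` from the swapped objective.
#' Standard errors come from the curvature of the objective at the
#' optimum.
#'
#' @inheritParams fit_jaacks
#' @return A `reactivity_estimate`.
#' @export
fit_bsl <- function(series, pair) {
  pc <- .pair_conversions(series, pair)
  obj1 <- function(r) sum((pc$xB - (1 - (1 - pc$xA)^(1 / r)))^2)
  obj2 <- function(r) sum((pc$xA - (1 - (1 - pc$xB)^(1 / r)))^2)
  d1 <- .fit_logr(obj1, pc$xB, length(pc$xA))
  d2 <- .fit_logr(obj2, pc$xA, length(pc$xA))
  .estimate("bsl", pair, d1$r, d2$r, d1$se, d2$se,
            min(d1$R2, d2$R2), length(pc$xA))
}

# Model instantaneous unreacted-feed fraction of the first species at
# total conversions Xv, for a binary subsystem with rates (r, 1) and feed w.
.ideal_model_f <- function(r, w, Xv) {
  rs <- rate_set(c(r, 1))
  sv <- survival_at_conversion(rs, w, Xv)
  a <- outer(sv$a_slow, sv$p, `^`)
  w[1] * a[, 1] / (w[1] * a[, 1] + w[2] * a[, 2])
}

#' Ideal integrated fit
#'
#' Fits the instantaneous unreacted-feed fraction of species A,
#' `f_A = f0_A (1-x_A) / (f0_A (1-x_A) + f0_B (1-x_B))`, against the
#' integrated composition curve `f_A(X; r)` evaluated at the observed
#' total conversions (the pair is treated as a renormalized binary
#' subsystem, which the nonterminal model makes exact even inside a
#' ternary mixture). The curve is inverted from X to survival by bisection
#' (tol 1e-10). Points whose observed X falls outside the model's range
#' are dropped with a warning; if more than half are dropped the fit
#' errors.
#'
#' @inheritParams fit_jaacks
#' @return A `reactivity_estimate`.
#' @export
fit_ideal_integrated <- function(series, pair) {
  pc <- .pair_conversions(series, pair)
  idx <- pc$idx
  w <- series$f0[idx] / sum(series$f0[idx])
  Xobs <- w[1] * pc$xA + w[2] * pc$xB
  uA <- w[1] * (1 - pc$xA)
  uB <- w[2] * (1 - pc$xB)
  fA <- uA / (uA + uB)
  ok <- Xobs >= 0 & Xobs < 1 - 1e-9
  if (!all(ok)) {
    warning(sum(!ok), " point(s) with pair conversion outside the model ",
            "range dropped")
    if (sum(!ok) > length(ok) / 2) {
      stop("more than half of the points fall outside the composition ",
           "model's conversion range")
    }
  }
  Xv <- Xobs[ok]
  n <- sum(ok)
  obj1 <- function(r) sum((fA[ok] - .ideal_model_f(r, w, Xv))^2)
  obj2 <- function(r) sum(((1 - fA[ok]) - .ideal_model_f(r, rev(w), Xv))^2)
  d1 <- .fit_logr(obj1, fA[ok], n)
  d2 <- .fit_logr(obj2, 1 - fA[ok], n)
  .estimate("ideal", pair, d1$r, d2$r, d1$se, d2$se,
            min(d1$R2, d2$R2), n)
}

#' Fit one nonterminal model by name
#'
#' @inheritParams fit_jaacks
#' @param model One of `"jaacks"`, `"bsl"`, `"ideal"`.
#' @return A `reactivity_estimate`.
#' @export
fit_reactivity <- function(series, pair, model = c("jaacks", "bsl", "ideal")) {
  model <- match.arg(model)
  switch(model,
         jaacks = fit_jaacks(series, pair),
         bsl = fit_bsl(series, pair),
         ideal = fit_ideal_integrated(series, pair))
}

#' Average reactivity estimates across models
#'
#' Unweighted mean and sample standard deviation of `r1` and `r2` across
#' the included models; the across-model scatter is the reported
#' uncertainty (per-fit standard errors stay on the individual
#' estimates).
#'
#' @param estimates List of `reactivity_estimate` objects for one pair.
#' @param exclude Character vector of model names to exclude (recorded
#'   with the result), or a named character vector whose names are models
#'   and values are reasons.
#' @return An object of class `reactivity_average`.
#' @export
average_models <- function(estimates, exclude = character(0)) {
  if (inherits(estimates, "reactivity_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, logical(1),
                       "reactivity_estimate")))
  pair <- estimates[[1]]$pair
  models <- vapply(estimates, `[[`, character(1), "model")
  excl_models <- if (is.null(names(exclude))) exclude else names(exclude)
  keep <- !models %in% excl_models
  if (!any(keep)) stop("no models left after exclusion")
  if (sum(keep) == 1L) {
    warning("average over a single model; sd reported as 0")
  }
  r1s <- vapply(estimates[keep], `[[`, numeric(1), "r1")
  r2s <- vapply(estimates[keep], `[[`, numeric(1), "r2")
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  excluded <- if (length(exclude)) {
    data.frame(model = excl_models,
               reason = if (is.null(names(exclude))) "excluded by config"
                        else unname(exclude))
  } else {
    data.frame(model = character(0), reason = character(0))
  }
  structure(
    list(pair = pair, models = models[keep],
         r1_mean = mean(r1s), r1_sd = sd0(r1s),
         r2_mean = mean(r2s), r2_sd = sd0(r2s),
         estimates = estimates, excluded = excluded),
    class = "reactivity_average"
  )
}

#' @export
print.reactivity_average <- function(x, ...) {
  cat(sprintf("<reactivity_average> %s/%s over {%s}: r1 = %.3g +/- %.2g, r2 = %.3g +/- %.2g\n",
              x$pair[1], x$pair[2], paste(x$models, collapse = ", "),
              x$r1_mean, x$r1_sd, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Gradient-strength classification
#'
#' Gradient strength is `delta_r = r1 - r2` with the pair ordered so
#' `r1 >= r2`. Classes use half-open boundaries: soft (0, 1.5], medium
#' (1.5, 7.5], hard (7.5, 25], block(-like) (25, Inf).
#'
#' @param r1 Either a `reactivity_average` or the first ratio.
#' @param r2 Second ratio (ignored when `r1` is an average object).
#' @return Object of class `gradient_assessment`: `delta_r` and `class`.
#' @examples
#' assess_gradient(4.9, 0.21) # delta_r = 4.69, medium
#' @export
assess_gradient <- function(r1, r2 = NULL) {
  if (inherits(r1, "reactivity_average")) {
    r2 <- r1$r2_mean
    r1 <- r1$r1_mean
  }
  stopifnot(is.numeric(r1), is.numeric(r2), r1 > 0, r2 > 0)
  d <- max(r1, r2) - min(r1, r2)
  cls <- if (d <= 1.5) "soft" else if (d <= 7.5) "medium"
         else if (d <= 25) "hard" else "block"
  structure(list(delta_r = d, class = cls), class = "gradient_assessment")
}

#' @export
print.gradient_assessment <- function(x, ...) {
  cat(sprintf("<gradient_assessment> delta_r = %.3g -> %s gradient\n",
              x$delta_r, x$class))
  invisible(x)
}

#' Fit all models for one pair and summarize
#'
#' Convenience wrapper: fits the requested models, averages them and
#' classifies the gradient strength.
#'
#' @inheritParams fit_jaacks
#' @param models Models to fit.
#' @param exclude Passed to [average_models()].
#' @return List with `estimates`, `average`, `gradient`.
#' @export
fit_pair <- function(series, pair, models = c("ideal", "jaacks", "bsl"),
                     exclude = character(0)) {
  est <- lapply(models, function(m) fit_reactivity(series, pair, m))
  avg <- average_models(est, exclude = exclude)
  list(estimates = est, average = avg, gradient = assess_gradient(avg))
}

#' Pairwise reactivity ratios of a ternary system
#'
#' Applies the binary estimators to each of the three unordered species
#' pairs (each fit yields both directed ratios), which is exact under the
#' nonterminal model because the drift between any two species is
#' independent of the third. Ratios can be excluded from the averages via
#' lambda flags.
#'
#' @param series A 3-species [conversions()] series.
#' @param triple Character vector of the three species (default: the
#'   series' species order).
#' @param models Models to fit per pair.
#' @param lambda_flags Optional list of exclusions, each a list with
#'   elements `pair` (ordered character pair whose directed ratio `r_xy`
#'   is flagged), `model`, and `reason`.
#' @return Object of class `ternary_ratio_table`: `species`, `table`
#'   (data frame of the six directed ratios with mean, sd and models
#'   used), `estimates`, `lambda_flags`.
#' @export
fit_ternary <- function(series, triple = NULL,
                        models = c("ideal", "jaacks", "bsl"),
                        lambda_flags = list()) {
  stopifnot(inherits(series, "conversion_series"))
  if (is.null(triple)) triple <- series$species
  stopifnot(length(triple) == 3L, all(triple %in% series$species))
  pairs <- list(triple[c(1, 2)], triple[c(1, 3)], triple[c(2, 3)])
  estimates <- list()
  for (pr in pairs) {
    for (m in models) {
      est <- tryCatch(fit_reactivity(series, pr, m), error = function(e) {
        stop("fit failed for pair ", pr[1], "/", pr[2], " [", m, "]: ",
             conditionMessage(e))
      })
      estimates[[paste(pr[1], pr[2], m, sep = ":")]] <- est
    }
  }
  flagged <- function(x, y, m) {
    for (fl in lambda_flags) {
      if (identical(as.character(fl$pair), c(x, y)) &&
          (is.null(fl$model) || identical(fl$model, m))) {
        return(TRUE)
      }
    }
    FALSE
  }
  rows <- list()
  for (pr in pairs) {
    for (dir in 1:2) {
      x <- pr[dir]; y <- pr[3 - dir]
      vals <- c(); used <- c()
      for (m in models) {
        est <- estimates[[paste(pr[1], pr[2], m, sep = ":")]]
        v <- if (dir == 1) est$r1 else est$r2
        if (!flagged(x, y, m)) {
          vals <- c(vals, v); used <- c(used, m)
        }
      }
      if (!length(vals)) {
        stop("all models flagged for directed ratio r_", x, ",", y)
      }
      rows[[paste(x, y, sep = ":")]] <- data.frame(
        from = x, to = y, r_mean = mean(vals),
        r_sd = if (length(vals) > 1) stats::sd(vals) else 0,
        n_models = length(vals),
        models = paste(used, collapse = ","))
    }
  }
  structure(
    list(species = triple, table = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)),
         estimates = estimates, lambda_flags = lambda_flags),
    class = "ternary_ratio_table"
  )
}

#' @export
print.ternary_ratio_table <- function(x, ...) {
  cat("<ternary_ratio_table> species:", paste(x$species, collapse = ", "),
      "\n")
  print(x$table, row.names = FALSE)
  if (length(x$lambda_flags)) {
    cat("lambda-flagged:",
        paste(vapply(x$lambda_flags, function(fl)
          paste0("r_", fl$pair[1], ",", fl$pair[2],
                 if (!is.null(fl$model)) paste0(" [", fl$model, "]") else ""),
          character(1)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Directed ratio matrix from a ternary table
#'
#' @param tt A [fit_ternary()] result.
#' @return 3x3 matrix with `[x, y] = r_xy` means, `NA` on the diagonal.
#' @export
ratio_matrix <- function(tt) {
  stopifnot(inherits(tt, "ternary_ratio_table"))
  sp <- tt$species
  m <- matrix(NA_real_, 3, 3, dimnames = list(sp, sp))
  for (i in seq_len(nrow(tt$table))) {
    m[tt$table$from[i], tt$table$to[i]] <- tt$table$r_mean[i]
  }
  m
}
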