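#' Fraction affected from viability signals
#'
#' Converts treated/control readouts (e.g. MTT absorbance) to the
#' fraction affected fa = 1 - treated/control, clipped into
#' [epsilon, 1 - epsilon] so the log-linearization of the median-effect
#' model is defined. Clipped points are flagged and excluded from fits
#' by default.
#'
#' @param treated_signal,control_signal numeric vectors (recycled);
#'   control must be positive.
#' @param epsilon clipping bound (default 1e-4).
#' @return list with numeric `fa` and logical `clipped`.
#' @export
viability_to_fa <- function(treated_signal, control_signal,
                            epsilon = 1e-4) {
  if (any(control_signal <= 0)) {
    stop("control signal must be positive", call. = FALSE)
  }
  fa <- 1 - treated_signal / control_signal
  clipped <- fa < epsilon | fa > 1 - epsilon
  fa <- pmin(pmax(fa, epsilon), 1 - epsilon)
  list(fa = fa, clipped = clipped)
}

#' Fit the median-effect model to a dose-response curve
#'
#' The median-effect equation fa/fu = (D/Dm)^m (fu = 1 - fa) is
#' linearized as log10(fa/fu) = m log10(D) - m log10(Dm) and fitted by
#' least squares. `m` is the sigmoidicity slope, `Dm` the dose giving
#' half effect, and `r` the correlation coefficient of the linearized
#' fit. A non-positive fitted slope marks the fit as flagged
#' (non-monotone data); identical doses are rejected.
#'
#' @param dose positive doses (>= 2 distinct values).
#' @param fa fractions affected in the open interval (0, 1).
#' @param clipped optional logical; clipped points are dropped before
#'   fitting.
#' @return object of class `median_effect_fit` with `m`, `Dm`, `r`,
#'   `n`, `flagged`.
#' @export
median_effect_fit <- function(dose, fa, clipped = NULL) {
  if (!is.null(clipped)) {
    dose <- dose[!clipped]; fa <- fa[!clipped]
  }
  if (length(dose) != length(fa)) {
    stop("`dose` and `fa` lengths differ", call. = FALSE)
  }
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(unique(dose)) < 2) {
    stop("need at least 2 distinct doses", call. = FALSE)
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(
    list(m = m, Dm = 10^(-b / m), r = r, n = length(dose),
         flagged = !is.finite(m) || m <= 0),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> m = %.4g, Dm = %.4g, r = %.4f (n = %d)%s\n",
              x$m, x$Dm, x$r, x$n,
              if (x$flagged) " [flagged: non-monotone]" else ""))
  invisible(x)
}

#' Fraction affected predicted at a dose
#' @param fit a `median_effect_fit` (or list with `m`, `Dm`).
#' @param dose positive dose(s).
#' @return fa values from the median-effect equation.
#' @export
effect_at_dose <- function(fit, dose) {
  ratio <- (dose / fit$Dm)^fit$m
  ratio / (1 + ratio)
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: Dx = Dm * (fa/fu)^(1/m). At
#' fa = 0.5, Dx equals Dm for any slope.
#' @param fit a `median_effect_fit`.
#' @param fa effect level(s), strictly between 0 and 1.
#' @return required dose(s).
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(fit$m) || fit$m <= 0 || fit$Dm <= 0) {
    stop("invalid median-effect fit", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index for one combination point
#'
#' Computes the mutually-exclusive (two-term) combination index
#' CI = d1/Dx1(fa) + d2/Dx2(fa), where Dx_i is the dose of agent i
#' alone required for the observed combined effect. CI below 1
#' indicates synergy, 1 additivity, above 1 antagonism; the
#' classification uses a tolerance band of +/- `tolerance` around 1 and
#' is reported alongside the raw value.
#'
#' @param fit_a,fit_b single-agent `median_effect_fit`s.
#' @param d1,d2 nonnegative doses of the two agents (not both zero).
#' @param fa_combo observed fraction affected of the combination,
#'   strictly between 0 and 1.
#' @param tolerance half-width of the additivity band (default 0.1).
#' @return list with `d1`, `d2`, `fa`, `Dx1`, `Dx2`, `CI`,
#'   `classification`.
#' @export
combination_index <- function(fit_a, fit_b, d1, d2, fa_combo,
                              tolerance = 0.1) {
  if (d1 < 0 || d2 < 0 || (d1 == 0 && d2 == 0)) {
    stop("doses must be nonnegative and not both zero", call. = FALSE)
  }
  if (fa_combo <= 0 || fa_combo >= 1) {
    stop("fa_combo must lie strictly between 0 and 1", call. = FALSE)
  }
  dx1 <- dose_for_effect(fit_a, fa_combo)
  dx2 <- dose_for_effect(fit_b, fa_combo)
  ci <- d1 / dx1 + d2 / dx2
  cls <- if (ci < 1 - tolerance) "synergy"
         else if (ci > 1 + tolerance) "antagonism"
         else "additive"
  list(d1 = d1, d2 = d2, fa = fa_combo, Dx1 = dx1, Dx2 = dx2,
       CI = ci, classification = cls)
}

#' Combination indices for a table of combination points
#'
#' @param fit_a,fit_b single-agent `median_effect_fit`s.
#' @param combos data.frame with columns `d1`, `d2`, `fa`.
#' @param tolerance additivity band half-width.
#' @return data.frame `d1`, `d2`, `fa`, `Dx1`, `Dx2`, `CI`,
#'   `classification`.
#' @export
combination_index_table <- function(fit_a, fit_b, combos,
                                    tolerance = 0.1) {
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    as.data.frame(combination_index(fit_a, fit_b, combos$d1[i],
                                    combos$d2[i], combos$fa[i],
                                    tolerance = tolerance),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Isobologram coordinates
#'
#' For each effect level, returns the additivity-line endpoints
#' (Dx1, 0) and (0, Dx2); combination points can be overlaid in
#' normalized coordinates (d1/Dx1, d2/Dx2), where points summing below
#' 1 fall under the additivity line (synergy).
#'
#' @param fit_a,fit_b single-agent `median_effect_fit`s.
#' @param fa_levels effect levels in (0, 1).
#' @param combos optional data.frame `d1`, `d2`, `fa` of observed
#'   combination points.
#' @return list with `lines` (data.frame `fa`, `Dx1`, `Dx2`) and
#'   `points` (data.frame `d1`, `d2`, `fa`, `norm1`, `norm2`, or
#'   `NULL`).
#' @export
isobologram <- function(fit_a, fit_b, fa_levels = c(0.5, 0.75, 0.9),
                        combos = NULL) {
  lines <- data.frame(
    fa = fa_levels,
    Dx1 = dose_for_effect(fit_a, fa_levels),
    Dx2 = dose_for_effect(fit_b, fa_levels)
  )
  points <- NULL
  if (!is.null(combos)) {
    points <- data.frame(
      d1 = combos$d1, d2 = combos$d2, fa = combos$fa,
      norm1 = combos$d1 / dose_for_effect(fit_a, combos$fa),
      norm2 = combos$d2 / dose_for_effect(fit_b, combos$fa)
    )
  }
  list(lines = lines, points = points)
}

#' Read / write dose-response tables
#'
#' Single-agent TSV: columns `agent`, `dose`, `fa`. Combination TSV:
#' columns `d1`, `d2`, `fa`.
#' @param path file path.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE)
}

#' @rdname read_dose_response
#' @param tab data.frame to write.
#' @export
write_dose_response <- function(tab, path) {
  con <- file(path, open = "wb")
  writeLines(c(paste(names(tab), collapse = "\t"),
               do.call(paste, c(lapply(tab, as.character), sep = "\t"))),
             con, sep = "\n")
  close(con)
  invisible(path)
}
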