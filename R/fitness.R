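# Relative fitness from serially propagated competition experiments:
# qPCR standard and calibration curves, detection-limit censoring, and
# the ratio-of-log-growth fitness estimator.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 copy number from a dilution
#' series; reports the amplification efficiency 10^(-1/slope) - 1 and
#' exposes the inverse map from Ct back to copies.
#'
#' @param log10_copies,ct Numeric vectors (>= 3 points spanning >= 2
#'   log10 units).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, and function `ct_to_copies(ct)`.
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  if (length(log10_copies) < 3L) stop("need at least 3 dilution points")
  if (diff(range(log10_copies)) < 2) {
    stop("dilution series must span at least 2 log10 units")
  }
  if (length(unique(log10_copies)) < 2L) {
    stop("rank-deficient standard curve: all dilutions identical")
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) warning("positive standard-curve slope: invalid assay")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 ct_to_copies = function(ct) 10^((ct - intercept) / slope)),
            class = "standard_curve")
}

#' Censor measurements below the qPCR detection limit
#'
#' Values below the limit are flagged below-detection (the boundary itself
#' is retained); downstream fitness for a censored cycle is marked
#' missing, never zero.
#'
#' @param copies_per_g Numeric vector of copy numbers per gram.
#' @param limit Detection limit (> 0; default 1e2 copies/g).
#' @return data.frame: `value` (NA where censored), `below_detection`.
#' @export
apply_detection_limit <- function(copies_per_g, limit = 1e2) {
  if (limit <= 0) stop("limit must be > 0")
  below <- !is.na(copies_per_g) & copies_per_g < limit
  data.frame(value = ifelse(below, NA_real_, copies_per_g),
             below_detection = below)
}

#' Calibration from gene copies to cell counts
#'
#' Linear map in log10 space (log10 CFU = slope * log10 copies +
#' intercept), fitted from paired single-strain sourdough measurements or
#' given directly.
#'
#' @param slope,intercept Coefficients of the log10-log10 map.
#' @param fit_range Optional range of log10 copies over which the curve
#'   was fitted; inputs outside it are flagged.
#' @return List of class `calibration`.
#' @export
calibration <- function(slope, intercept, fit_range = NULL) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    stop("calibration coefficients must be finite")
  }
  structure(list(slope = slope, intercept = intercept,
                 fit_range = fit_range), class = "calibration")
}

#' @rdname calibration
#' @param log10_copies,log10_cfu Paired calibration measurements.
#' @export
fit_calibration <- function(log10_copies, log10_cfu) {
  fit <- stats::lm(log10_cfu ~ log10_copies)
  calibration(unname(stats::coef(fit)[2L]), unname(stats::coef(fit)[1L]),
              fit_range = range(log10_copies))
}

#' Convert gene copies to CFU via a calibration curve
#'
#' @param copies_per_g Copy numbers (must already be above the detection
#'   limit; censored values are an error directing to
#'   [apply_detection_limit()]).
#' @param cal A [calibration()].
#' @return CFU per gram; attribute `out_of_range` flags extrapolation.
#' @export
copies_to_cfu <- function(copies_per_g, cal) {
  if (any(is.na(copies_per_g))) {
    stop("censored input: run apply_detection_limit() first and drop ",
         "below-detection cycles")
  }
  lg <- log10(copies_per_g)
  out <- 10^(cal$slope * lg + cal$intercept)
  if (!is.null(cal$fit_range)) {
    oor <- lg < cal$fit_range[1L] | lg > cal$fit_range[2L]
    attr(out, "out_of_range") <- oor
  }
  out
}

#' Relative fitness of strain x versus strain y over one cycle
#'
#' w = ln(x_F / x_0) / ln(y_F / y_0), the ratio of realized Malthusian
#' growth over the fermentation cycle; w = 1 means equal realized growth.
#'
#' @param x_0,x_F,y_0,y_F Start/end abundances (> 0), any common unit.
#' @return Fitness w.
#' @export
relative_fitness <- function(x_0, x_F, y_0, y_F) {
  vals <- c(x_0, x_F, y_0, y_F)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four abundances must be positive")
  }
  if (isTRUE(all.equal(y_F, y_0))) {
    stop("undefined fitness: reference strain did not change (y_F = y_0)")
  }
  log(x_F / x_0) / log(y_F / y_0)
}

#' Pool per-cycle fitness values into an estimate
#'
#' Computes per-cycle w from a tidy competition series and pools the
#' finite values across cycles and replicates into mean, sample standard
#' deviation and the replicate count. Cycles with any censored
#' measurement are excluded.
#'
#' @param series data.frame with columns replicate, cycle, strain
#'   (`"x"`/`"y"`), stage (`"start"`/`"end"`), measured (NA where
#'   censored) -- the layout written by [simulate_competition()].
#' @param inoculum_fraction When a cycle has no start measurement for a
#'   strain, its start defaults to `inoculum_fraction` times the previous
#'   cycle's end measurement (the back-slopping dilution); direct start
#'   measurements always take precedence. `NULL` (default) disables the
#'   imputation.
#' @return List of class `fitness_estimate`: `w` (per-cycle values with
#'   replicate/cycle ids), `mean`, `sd`, `n_replicates`.
#' @export
aggregate_fitness <- function(series, inoculum_fraction = NULL) {
  need <- c("replicate", "cycle", "strain", "stage", "measured")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(series$replicate, series$cycle, drop = TRUE)
  w <- do.call(rbind, lapply(split(series, key), function(s) {
    get1 <- function(df, strain, stage) {
      v <- df$measured[df$strain == strain & df$stage == stage]
      if (length(v) != 1L) NA_real_ else v
    }
    start_of <- function(strain) {
      v <- get1(s, strain, "start")
      if (!is.na(v) || is.null(inoculum_fraction)) return(v)
      prev <- series[series$replicate == s$replicate[1L] &
                       series$cycle == s$cycle[1L] - 1L, , drop = FALSE]
      if (!nrow(prev)) return(NA_real_)
      inoculum_fraction * get1(prev, strain, "end")
    }
    x0 <- start_of("x"); xF <- get1(s, "x", "end")
    y0 <- start_of("y"); yF <- get1(s, "y", "end")
    wv <- if (any(is.na(c(x0, xF, y0, yF)))) NA_real_
    else relative_fitness(x0, xF, y0, yF)
    data.frame(replicate = s$replicate[1L], cycle = s$cycle[1L], w = wv)
  }))
  finite <- w$w[is.finite(w$w)]
  if (!length(finite)) stop("no finite per-cycle fitness values")
  structure(list(w = w[order(w$replicate, w$cycle), ],
                 mean = mean(finite),
                 sd = if (length(finite) > 1L) stats::sd(finite) else 0,
                 n_replicates = length(finite)),
            class = "fitness_estimate")
}

#' Per-cycle strain proportions
#'
#' Proportion of each strain's abundance in the per-cycle total,
#' optionally log10 transformed.
#'
#' @param series Competition series (see [aggregate_fitness()]); the
#'   `"end"` stage measurements are used.
#' @param log10 Return log10 proportions?
#' @return data.frame: replicate, cycle, strain, proportion.
#' @export
proportion_series <- function(series, log10 = FALSE) {
  s <- series[series$stage == "end", , drop = FALSE]
  key <- interaction(s$replicate, s$cycle, drop = TRUE)
  out <- do.call(rbind, lapply(split(s, key), function(g) {
    tot <- sum(g$measured)
    if (!isTRUE(tot > 0)) stop("zero or missing total abundance in cycle ",
                               g$cycle[1L])
    data.frame(replicate = g$replicate, cycle = g$cycle,
               strain = g$strain,
               proportion = if (log10) log10(g$measured / tot)
               else g$measured / tot)
  }))
  rownames(out) <- NULL
  out[order(out$replicate, out$cycle, out$strain), ]
}
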