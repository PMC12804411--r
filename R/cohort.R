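#' Reference clinical cohort summary cells
#'
#' Published per-cell summary statistics (median and IQR) of femoropopliteal
#' morphometry in a nine-patient popliteal-aneurysm cohort imaged with the
#' knee straight and bent, before (PRE) and after (FU1) endovascular
#' stenting. These cells are the emulation targets of the cohort sampler and
#' the fixture input for the percentage-variation statistics; the underlying
#' per-patient scans are not redistributable, so raw values cannot be
#' recomputed from them.
#'
#' @return data.frame with columns `metric` (`length` mm, `diameter` mm,
#'   `tortuosity`, `t_front`, `t_lat`), `timepoint`, `segment`,
#'   `configuration`, `median`, `iqr`.
#' @export
reference_cohort_summary <- function() {
  read.csv(system.file("extdata", "reference_cohort_cells.csv",
                       package = "fpmorph"),
           stringsAsFactors = FALSE)
}

#' Cohort specification for the synthetic patient sampler
#'
#' Defines the population each synthetic cohort is drawn from: one
#' (median, IQR) pair per (metric, timepoint, segment, configuration) cell,
#' a patient count, a seed, and the within-patient correlation linking the
#' paired straight/bent (and PRE/FU1) draws.
#'
#' @param cells data.frame as returned by [reference_cohort_summary()]
#'   (the default).
#' @param n_patients number of synthetic patients (>= 3).
#' @param seed integer master seed; the same spec and seed always produce
#'   the identical cohort table.
#' @param pairing_rho equicorrelation of the Gaussian copula linking the
#'   four (timepoint x configuration) draws of one metric within a patient;
#'   default 0.8, giving the strong within-patient pairing that paired
#'   testing relies on.
#' @param calibrate `"sample"` (default) rescales each cell's draws in log
#'   space (rank-preserving) so the sample median and IQR equal the targets
#'   exactly, the median/IQR analogue of empirical covariance calibration;
#'   `"population"` leaves the i.i.d. draws untouched so sample summaries
#'   fluctuate around the targets.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = reference_cohort_summary(),
                        n_patients = 9L, seed = 1L, pairing_rho = 0.8,
                        calibrate = c("sample", "population")) {
  calibrate <- match.arg(calibrate)
  n_patients <- as.integer(n_patients)
  if (n_patients < 3L) stop("n_patients must be >= 3")
  req <- c("metric", "timepoint", "segment", "configuration", "median", "iqr")
  if (!all(req %in% names(cells))) stop("cells must have columns ", paste(req, collapse = ", "))
  if (any(cells$median <= 0)) stop("infeasible spec: all cell medians must be positive")
  if (any(cells$iqr < 0)) stop("infeasible spec: negative IQR")
  if (pairing_rho < 0 || pairing_rho >= 1) stop("pairing_rho must be in [0, 1)")
  cells <- cells[order(cells$metric, cells$segment, cells$timepoint,
                       cells$configuration), ]
  structure(list(cells = cells, n_patients = n_patients,
                 seed = as.integer(seed), pairing_rho = pairing_rho,
                 calibrate = calibrate),
            class = "cohort_spec")
}

# Log-normal sdlog hitting a target IQR at a given median:
# median * (exp(z s) - exp(-z s)) = IQR with z = qnorm(0.75), so
# s = asinh(IQR / (2 median)) / z. Zero IQR gives the degenerate
# point mass at the median.
lognormal_sdlog <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

# Rank-preserving calibration of one cell's latent normals so that the
# resulting log-normal sample hits the target (median, IQR) exactly:
# centre z on its sample median, then find the scale whose induced sample
# IQR matches the target (monotone in the scale, solved by uniroot).
calibrate_cell_z <- function(z, m, iqr, sdl) {
  zc <- z - median(z)
  if (sdl == 0 || iqr == 0) return(zc * 0)
  q <- quantile(zc, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[2] - q[1] < 1e-12) return(zc)
  g <- function(cc) m * (exp(cc * sdl * q[2]) - exp(cc * sdl * q[1])) - iqr
  cc <- stats::uniroot(g, lower = 1e-6, upper = 50, tol = 1e-12)$root
  cc * zc
}

#' Sample a synthetic patient cohort
#'
#' Draws one value per cell of the spec for each patient. Each metric cell
#' uses a log-normal marginal parameterized by the cell's (median, IQR);
#' the draws of the four (timepoint, configuration) variants of one metric
#' within a patient share an equicorrelated Gaussian copula, so
#' straight/bent and PRE/FU1 values are paired within patients. With the
#' default `calibrate = "sample"` each cell's draws are rescaled
#' (rank-preservingly, in log space) so the sample median and IQR equal the
#' targets exactly at any cohort size; with `"population"` the i.i.d. draws
#' are left untouched and sample summaries converge to the targets as the
#' cohort grows. Patients are exchangeable and the table is a deterministic
#' function of the spec and seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per (patient, timepoint, configuration,
#'   segment): columns `patient_id`, `timepoint`, `configuration`,
#'   `segment`, `length`, `tortuosity`, `mean_diameter`, `t_front`, `t_lat`
#'   (decomposition columns are `NA` for cells absent from the spec, e.g.
#'   SFA).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- spec$cells
  n <- spec$n_patients
  groups <- unique(cells[, c("metric", "segment")])
  groups <- groups[order(groups$metric, groups$segment), ]
  rho <- spec$pairing_rho
  set.seed(spec$seed)
  # value matrix per cell: patients x cells, drawn group-wise through the
  # within-patient copula
  cell_vals <- vector("list", nrow(cells))
  cell_key <- paste(cells$metric, cells$timepoint, cells$segment,
                    cells$configuration, sep = ".")
  names(cell_vals) <- cell_key
  for (g in seq_len(nrow(groups))) {
    sel <- which(cells$metric == groups$metric[g] &
                 cells$segment == groups$segment[g])
    k <- length(sel)
    common <- rnorm(n)
    z <- sqrt(rho) * matrix(common, n, k) +
         sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    for (j in seq_len(k)) {
      m <- cells$median[sel[j]]; iqr <- cells$iqr[sel[j]]
      sdl <- lognormal_sdlog(m, iqr)
      zj <- z[, j]
      if (spec$calibrate == "sample" && n >= 3)
        zj <- calibrate_cell_z(zj, m, iqr, sdl)
      cell_vals[[cell_key[sel[j]]]] <- m * exp(sdl * zj)
    }
  }
  combos <- unique(cells[, c("timepoint", "segment", "configuration")])
  combos <- combos[order(combos$timepoint, combos$configuration, combos$segment), ]
  metric_col <- c(length = "length", tortuosity = "tortuosity",
                  diameter = "mean_diameter", t_front = "t_front",
                  t_lat = "t_lat")
  rows <- lapply(seq_len(nrow(combos)), function(ci) {
    df <- data.frame(patient_id = seq_len(n),
                     timepoint = combos$timepoint[ci],
                     configuration = combos$configuration[ci],
                     segment = combos$segment[ci],
                     length = NA_real_, tortuosity = NA_real_,
                     mean_diameter = NA_real_, t_front = NA_real_,
                     t_lat = NA_real_, stringsAsFactors = FALSE)
    for (mt in names(metric_col)) {
      key <- paste(mt, combos$timepoint[ci], combos$segment[ci],
                   combos$configuration[ci], sep = ".")
      if (!is.null(cell_vals[[key]])) df[[metric_col[mt]]] <- cell_vals[[key]]
    }
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$timepoint, out$configuration, out$segment), ]
  rownames(out) <- NULL
  out
}
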