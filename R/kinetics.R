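#' Average replication rate across serial transfers
#'
#' The discrete growth-dilution model links marker-gene copies per bottle at
#' the end of transfer `t` to the copies initially inoculated into transfer
#' 1 of the same lineage through a constant average replication rate `R`
#' (h^-1) and the treatment's average dilution rate `D`:
#' `N_t = N_0 * (1 + R - D)^(t * interval)`. Solving for `R` gives
#' `R = (N_t / N_0)^(1 / (t * interval)) + D - 1`, which this function
#' returns. `R` may be negative or below `D`; the latter indicates washout.
#' With `n_final = 0` the rate is undefined (the model cannot reach exactly
#' zero); `NA` is returned with a warning and such lineages should be
#' classified as washing out.
#'
#' @param n_initial Gene copies per bottle inoculated at the start of
#'   transfer 1 (see [copies_inoculated()]).
#' @param n_final Gene copies per bottle at the end of transfer `transfer`.
#' @param transfer Transfer number of the sampled bottle (e.g. 4 or 8).
#' @param dilution_rate Average dilution rate `D` (h^-1).
#' @param interval Growth interval per transfer (h), default 72.
#' @return Replication rate `R` (h^-1).
#' @examples
#' replication_rate(1e8, 1e8, 8, 0.14)  # steady state: R = D = 0.14
#' @export
replication_rate <- function(n_initial, n_final, transfer, dilution_rate,
                             interval = sr_constants$interval_h) {
  if (any(n_initial <= 0, na.rm = TRUE))
    sr_stop("replication_rate: initial copies must be positive")
  if (any(n_final < 0, na.rm = TRUE))
    sr_stop("replication_rate: final copies must be >= 0")
  if (any(transfer < 1, na.rm = TRUE) || any(interval <= 0))
    sr_stop("replication_rate: transfer must be >= 1 and interval positive")
  if (any(dilution_rate <= 0, na.rm = TRUE) || any(dilution_rate >= 1, na.rm = TRUE))
    sr_stop("replication_rate: dilution rate must be in (0, 1) h^-1")
  zero <- !is.na(n_final) & n_final == 0
  if (any(zero)) {
    warning("replication_rate: n_final = 0, rate undefined (washout limit), returning NA")
    n_final[zero] <- NA_real_
  }
  (n_final / n_initial)^(1 / (transfer * interval)) + dilution_rate - 1
}

#' Gene copies inoculated per bottle at transfer 1
#'
#' Initial copies per bottle are reconstructed from the marker-gene copies
#' per gram of inoculum solids, the solids content of the rumen inoculum and
#' the inoculum volume delivered. The solids content is an explicit input;
#' the default of 0.05 g solids per mL strained rumen inoculum is an assumed
#' typical value, not a measured one.
#'
#' @param copies_per_g_solids Gene copies per gram of inoculum solids.
#' @param inoculum_volume Inoculum volume delivered (mL).
#' @param solids_content Solids content of the inoculum (g/mL), default 0.05.
#' @return Gene copies per bottle.
#' @examples
#' copies_inoculated(10^10.6, 1)
#' @export
copies_inoculated <- function(copies_per_g_solids, inoculum_volume,
                              solids_content = 0.05) {
  if (any(c(copies_per_g_solids, inoculum_volume, solids_content) < 0, na.rm = TRUE))
    sr_stop("copies_inoculated: inputs must be >= 0")
  copies_per_g_solids * solids_content * inoculum_volume
}

#' Doubling time from a replication rate
#'
#' The study defines doubling time as the reciprocal of the replication
#' rate, `1 / R`; that definition is the default. The conventional
#' exponential-growth form `ln(2) / R` is available behind an explicit
#' `method` flag but is never the default. Non-positive rates have no
#' doubling time and return `NA` with a warning.
#'
#' @param R Replication rate (h^-1).
#' @param method `"reciprocal"` (default, `1/R`) or `"log2"` (`ln(2)/R`).
#' @return Doubling time (h).
#' @examples
#' doubling_time(0.14)  # 7.14 h
#' @export
doubling_time <- function(R, method = c("reciprocal", "log2")) {
  method <- match.arg(method)
  bad <- !is.na(R) & R <= 0
  if (any(bad)) {
    warning("doubling_time: R <= 0, population not net-replicating, returning NA")
    R[bad] <- NA_real_
  }
  if (method == "reciprocal") 1 / R else log(2) / R
}

#' Classify a lineage as growing, steady or washing out
#'
#' A population grows when its replication rate exceeds the dilution rate,
#' is steady when the two balance (within tolerance) and washes out when
#' replication cannot keep up with dilution.
#'
#' @param R Replication rate (h^-1); `NA` (e.g. from a washed-out lineage
#'   with zero final copies) classifies as `washing_out`.
#' @param D Dilution rate (h^-1).
#' @param tol Absolute tolerance for the steady state (h^-1), default 1e-6.
#' @return Character vector: `"growing"`, `"steady"` or `"washing_out"`.
#' @examples
#' classify_trend(c(0.15, 0.14, 0.10), 0.14)
#' @export
classify_trend <- function(R, D, tol = 1e-6) {
  out <- ifelse(is.na(R), "washing_out",
         ifelse(abs(R - D) <= tol, "steady",
         ifelse(R > D, "growing", "washing_out")))
  out
}

#' Replication kinetics for a table of lineages
#'
#' Convenience wrapper applying [replication_rate()], [doubling_time()] and
#' [classify_trend()] row-wise to a kinetics table.
#'
#' @param data Data frame with columns `n_initial`, `n_final`, `transfer`,
#'   `dilution_rate` (and optionally `interval`).
#' @param ... Passed to [doubling_time()] and [classify_trend()].
#' @return `data` with added columns `R_per_h`, `doubling_h`, `trend`.
#' @export
replication_kinetics <- function(data, ...) {
  interval <- if ("interval" %in% names(data)) data$interval else sr_constants$interval_h
  R <- replication_rate(data$n_initial, data$n_final, data$transfer,
                        data$dilution_rate, interval)
  data$R_per_h <- R
  data$doubling_h <- suppressWarnings(doubling_time(R))
  data$trend <- classify_trend(R, data$dilution_rate)
  data
}
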