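#' Specify one incubation bottle
#'
#' Physical description of a single serum-bottle batch incubation in a serial
#' culture: the inoculum and fresh-medium volumes that set the average
#' dilution rate, the substrate dry mass, and the headspace geometry.
#'
#' @param inoculum_volume Volume of inoculum transferred from the donor
#'   bottle (mL); the study used 1, 2 or 4 mL.
#' @param medium_volume Volume of fresh incubation medium (mL); the study
#'   used 39, 38 or 36 mL so that the total is always 40 mL.
#' @param substrate_mass Substrate dry mass (mg DM), default 401.
#' @param headspace_volume Gas headspace (mL), default 60.
#' @param temperature Incubation temperature (degrees C), default 39.
#' @param interval Duration of one batch incubation (h), default 72.
#'
#' @return An object of class `bottle_spec`: a list with the above fields
#'   plus `total_volume = inoculum_volume + medium_volume`.
#' @examples
#' bottle_spec(1, 39)
#' @export
bottle_spec <- function(inoculum_volume, medium_volume,
                        substrate_mass = 401,
                        headspace_volume = sr_constants$headspace_ml,
                        temperature = sr_constants$temperature_c,
                        interval = sr_constants$interval_h) {
  for (v in c(inoculum_volume, substrate_mass, headspace_volume, interval))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      sr_stop("bottle_spec: volumes, masses and interval must be single positive numbers")
  if (!is.numeric(medium_volume) || medium_volume < 0)
    sr_stop("bottle_spec: medium_volume must be >= 0")
  if (temperature <= -273.15)
    sr_stop("bottle_spec: temperature below absolute zero")
  out <- list(inoculum_volume = inoculum_volume,
              medium_volume = medium_volume,
              total_volume = inoculum_volume + medium_volume,
              substrate_mass = substrate_mass,
              headspace_volume = headspace_volume,
              temperature = temperature,
              interval = interval)
  class(out) <- "bottle_spec"
  out
}

#' @export
print.bottle_spec <- function(x, ...) {
  cat(sprintf("Incubation bottle: %g mL inoculum + %g mL medium (%g mL total)\n",
              x$inoculum_volume, x$medium_volume, x$total_volume))
  cat(sprintf("  substrate %g mg DM, headspace %g mL, %g degC, %g h interval\n",
              x$substrate_mass, x$headspace_volume, x$temperature, x$interval))
  cat(sprintf("  average dilution rate: %.4f h^-1 (%.2f presented)\n",
              average_dilution_rate(x), round(average_dilution_rate(x), 2)))
  invisible(x)
}

#' Average dilution rate of a serial batch culture
#'
#' The average dilution rate of a serially transferred batch culture is the
#' total incubation volume divided by the inoculum volume and the transfer
#' interval, `D = (inoculum + medium) / (inoculum * interval)`. This is an
#' average transfer rate across sequential batch incubations, not a chemostat
#' constant. For the study's bottles (1, 2 or 4 mL of inoculum into a 40-mL
#' total over 72 h) it gives 0.56, 0.28 and 0.14 h^-1 after two-decimal
#' rounding. Internal arithmetic is full precision; rounding is left to the
#' presentation layer (base `round()`, which is half-to-even).
#'
#' @param spec A [bottle_spec()], or the inoculum volume in mL.
#' @param medium_volume Fresh medium volume (mL); ignored when `spec` is a
#'   `bottle_spec`.
#' @param interval Batch interval (h), default 72.
#'
#' @return Dilution rate in h^-1.
#' @examples
#' average_dilution_rate(bottle_spec(1, 39))    # 0.5556
#' average_dilution_rate(4, 36)                 # 0.1389
#' @export
average_dilution_rate <- function(spec, medium_volume = NULL,
                                  interval = sr_constants$interval_h) {
  if (inherits(spec, "bottle_spec")) {
    inoc <- spec$inoculum_volume
    medium_volume <- spec$medium_volume
    interval <- spec$interval
  } else {
    inoc <- spec
    if (is.null(medium_volume))
      sr_stop("average_dilution_rate: medium_volume required when spec is numeric")
  }
  if (any(!is.finite(inoc)) || any(inoc <= 0))
    sr_stop("average_dilution_rate: inoculum volume must be positive")
  if (any(!is.finite(interval)) || any(interval <= 0))
    sr_stop("average_dilution_rate: interval must be positive")
  if (any(medium_volume < 0))
    sr_stop("average_dilution_rate: medium volume must be >= 0")
  (inoc + medium_volume) / (inoc * interval)
}

#' The study's three dilution-level definitions
#'
#' @return A data frame with one row per dilution level (`low`, `mid`,
#'   `high`), its inoculum and medium volumes (mL) and the recomputed average
#'   dilution rate in h^-1 and d^-1. The numeric rate is always recomputed
#'   from the volumes, never read from input files.
#' @examples
#' dilution_levels()
#' @export
dilution_levels <- function() {
  lv <- data.frame(
    dilution_level = c("low", "mid", "high"),
    inoculum_volume_ml = c(4, 2, 1),
    medium_volume_ml = c(36, 38, 39),
    stringsAsFactors = FALSE
  )
  lv$dilution_rate_h <- average_dilution_rate(lv$inoculum_volume_ml,
                                              lv$medium_volume_ml)
  lv$dilution_rate_d <- lv$dilution_rate_h * 24
  lv
}

#' Full factorial design grid of the serial-culture experiment
#'
#' Expands the experiment's factorial: substrate (high_forage,
#' high_concentrate) x dilution level (low, mid, high) x replicate sequence
#' nested in incubation x incubation x transfer. The default dimensions
#' (2 x 3 x 3 x 2 x 8) give the study's 288 bottle-transfer rows.
#'
#' @param n_sequences Replicate serial-transfer lineages per treatment cell
#'   per incubation (default 3).
#' @param n_incubations Independent repetitions of the experiment (default 2).
#' @param n_transfers Serial transfers per lineage (default 8).
#' @return A data frame in the `design.csv` schema: `incubation`, `sequence`,
#'   `substrate`, `dilution_level`, `inoculum_volume_ml`, `medium_volume_ml`,
#'   `substrate_mass_mg`, `transfer`.
#' @examples
#' nrow(design_grid())  # 288
#' @export
design_grid <- function(n_sequences = 3, n_incubations = 2, n_transfers = 8) {
  lv <- dilution_levels()
  g <- expand.grid(
    transfer = seq_len(n_transfers),
    sequence = seq_len(n_sequences),
    dilution_level = lv$dilution_level,
    substrate = c("high_forage", "high_concentrate"),
    incubation = seq_len(n_incubations),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- merge(g, lv[, c("dilution_level", "inoculum_volume_ml", "medium_volume_ml")],
             by = "dilution_level", sort = FALSE)
  g$substrate_mass_mg <- 401
  g <- g[order(g$incubation, g$substrate, g$dilution_level, g$sequence, g$transfer), ]
  rownames(g) <- NULL
  g[, c("incubation", "sequence", "substrate", "dilution_level",
        "inoculum_volume_ml", "medium_volume_ml", "substrate_mass_mg",
        "transfer")]
}

#' Validate a design table against the expected factorial
#'
#' Checks that a long-format design covers the full substrate x dilution x
#' sequence x incubation factorial with contiguous transfers starting at 1,
#' and that no (incubation, substrate, dilution_level, sequence, transfer)
#' key is duplicated. Transfers are 1-based: transfer 1 is the first batch
#' inoculated from the rumen inoculum.
#'
#' @param rows A design data frame with at least columns `incubation`,
#'   `sequence`, `substrate`, `dilution_level`, `transfer`.
#' @param n_transfers Expected number of transfers per lineage (default 8).
#' @return An object of class `design_report`: list with `complete` (logical),
#'   `n_rows`, and `missing` (data frame of absent cells, zero rows when
#'   complete).
#' @examples
#' validate_design(design_grid())$complete
#' @export
validate_design <- function(rows, n_transfers = 8) {
  need <- c("incubation", "sequence", "substrate", "dilution_level", "transfer")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    sr_stop(paste("validate_design: missing columns:", paste(miss, collapse = ", ")))
  key <- do.call(paste, c(rows[need], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- rows[duplicated(key), need, drop = FALSE]
    sr_stop(paste0("validate_design: duplicated design keys, e.g. incubation ",
                   d$incubation[1], " sequence ", d$sequence[1], " ",
                   d$substrate[1], "/", d$dilution_level[1], " transfer ",
                   d$transfer[1]),
            class = "sr_integrity_error")
  }
  expected <- expand.grid(
    incubation = sort(unique(rows$incubation)),
    sequence = sort(unique(rows$sequence)),
    substrate = sort(unique(rows$substrate)),
    dilution_level = sort(unique(rows$dilution_level)),
    transfer = seq_len(n_transfers),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  ekey <- do.call(paste, c(expected, sep = "\r"))
  missing_cells <- expected[!(ekey %in% key), , drop = FALSE]
  rownames(missing_cells) <- NULL
  out <- list(complete = nrow(missing_cells) == 0L,
              n_rows = nrow(rows),
              missing = missing_cells)
  class(out) <- "design_report"
  out
}

#' @export
print.design_report <- function(x, ...) {
  if (x$complete) {
    cat(sprintf("Design complete: %d rows, no missing cells\n", x$n_rows))
  } else {
    cat(sprintf("Design INCOMPLETE: %d rows, %d missing cells:\n",
                x$n_rows, nrow(x$missing)))
    print(utils::head(x$missing, 10))
  }
  invisible(x)
}

#' Mean sequencing reads per sample
#'
#' Total raw amplicon reads divided by the number of sequenced samples. The
#' study sequenced 56 samples (2 substrates x 3 dilution rates x 3 replicates
#' x 3 incubation-transfer combinations + 2 initial inocula).
#'
#' @param total_reads Total raw reads across all samples.
#' @param n_samples Number of sequenced samples (default 56).
#' @return Mean reads per sample (unrounded).
#' @examples
#' round(reads_per_sample(16317083))  # bacterial libraries
#' @export
reads_per_sample <- function(total_reads, n_samples = 56) {
  if (any(n_samples <= 0)) sr_stop("reads_per_sample: n_samples must be positive")
  total_reads / n_samples
}
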