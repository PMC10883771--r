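#' Net metabolite production of one bottle over one transfer
#'
#' Net production corrects the final amount in the bottle for the amount
#' carried over with the inoculum from the donor bottle (or the rumen
#' inoculum in transfer 1):
#' `net = final_conc * total_volume - donor_conc * inoculum_volume`, in
#' µmol since mM x mL = µmol. Fresh medium is assumed metabolite-free by
#' default; supply `medium_conc` to subtract `medium_conc * medium_volume`
#' when the medium itself carries the analyte. Negative values mean net
#' consumption and are meaningful.
#'
#' @param final_conc Final concentration in the bottle (mM).
#' @param total_volume Total incubation volume (mL), default 40.
#' @param donor_conc Concentration in the donor bottle fluid actually
#'   transferred (mM).
#' @param inoculum_volume Inoculum volume received (mL).
#' @param medium_conc Analyte concentration of the fresh medium (mM),
#'   default 0.
#' @param medium_volume Fresh medium volume (mL); defaults to
#'   `total_volume - inoculum_volume`.
#' @return Net production (µmol per bottle per transfer).
#' @examples
#' net_production(100, 40, 50, 4)  # 3800
#' @export
net_production <- function(final_conc, total_volume, donor_conc,
                           inoculum_volume, medium_conc = 0,
                           medium_volume = total_volume - inoculum_volume) {
  if (any(total_volume <= 0) || any(inoculum_volume <= 0))
    sr_stop("net_production: volumes must be positive")
  if (any(final_conc < 0, na.rm = TRUE) || any(donor_conc < 0, na.rm = TRUE))
    sr_stop("net_production: concentrations must be >= 0")
  final_conc * total_volume - donor_conc * inoculum_volume -
    medium_conc * medium_volume
}

#' Carryover-corrected production along a serial-transfer lineage
#'
#' Applies [net_production()] along one lineage of serially transferred
#' bottles: the donor concentration for transfer `t` is the measured final
#' concentration of the same lineage at transfer `t - 1`, and transfer 1
#' uses the measured concentration of the rumen inoculum.
#'
#' @param final_conc Final concentrations (mM) ordered by transfer.
#' @param transfer Transfer indices; must be contiguous starting at 1.
#' @param inoculum_conc Analyte concentration of the initial rumen inoculum
#'   (mM).
#' @param inoculum_volume Volume transferred between bottles (mL).
#' @param total_volume Total incubation volume (mL), default 40.
#' @param medium_conc Fresh-medium concentration (mM), default 0.
#' @return Data frame with `transfer`, `donor_conc`, `final_conc`,
#'   `umol_net`.
#' @examples
#' chain_production(rep(100, 3), 1:3, inoculum_conc = 100, inoculum_volume = 4)
#' @export
chain_production <- function(final_conc, transfer, inoculum_conc,
                             inoculum_volume,
                             total_volume = sr_constants$total_volume_ml,
                             medium_conc = 0) {
  o <- order(transfer)
  transfer <- transfer[o]
  final_conc <- final_conc[o]
  if (!identical(as.integer(transfer), seq_along(transfer)))
    sr_stop(paste0("chain_production: transfers must be contiguous 1..n; got ",
                   paste(transfer, collapse = ",")),
            class = "sr_linkage_error")
  donor <- c(inoculum_conc, final_conc[-length(final_conc)])
  data.frame(
    transfer = transfer,
    donor_conc = donor,
    final_conc = final_conc,
    umol_net = net_production(final_conc, total_volume, donor,
                              inoculum_volume, medium_conc)
  )
}

#' Apparent dry matter disappearance
#'
#' `100 * (substrate - residue) / substrate`, in percent. Negative values
#' are allowed and biologically meaningful: the lyophilised residue includes
#' microbial biomass accreted during the incubation, which can exceed the
#' substrate mass that disappeared.
#'
#' @param substrate_dm Substrate dry mass incubated (mg).
#' @param residue_dm Lyophilised residue dry mass (mg).
#' @return Apparent DM disappearance (%).
#' @examples
#' dm_disappearance(401, 300)  # 25.19
#' dm_disappearance(400, 440)  # -10
#' @export
dm_disappearance <- function(substrate_dm, residue_dm) {
  if (any(substrate_dm <= 0)) sr_stop("dm_disappearance: substrate mass must be positive")
  if (any(residue_dm < 0, na.rm = TRUE)) sr_stop("dm_disappearance: residue mass must be >= 0")
  100 * (substrate_dm - residue_dm) / substrate_dm
}

#' Re-reference a redox potential to the standard hydrogen electrode
#'
#' Redox potentials recorded against an Ag/AgCl (saturated KCl) electrode are
#' re-referenced to the standard hydrogen electrode by adding the fixed
#' electrode offset of 197 mV. The result carries a `reference` attribute
#' ("SHE") so a value cannot be corrected twice: passing an already
#' SHE-referenced value is an error.
#'
#' @param eh_measured Redox potential (mV) against Ag/AgCl, or a value
#'   previously tagged by this function.
#' @return Redox potential (mV) vs SHE, with `attr(, "reference") == "SHE"`.
#' @examples
#' eh_to_she(-400)  # -203 mV vs SHE
#' @export
eh_to_she <- function(eh_measured) {
  if (identical(attr(eh_measured, "reference"), "SHE"))
    sr_stop("eh_to_she: value is already SHE-referenced; refusing to add the offset twice")
  out <- unclass(eh_measured) + sr_constants$she_offset_mv
  attr(out, "reference") <- "SHE"
  out
}

#' Acetate to propionate molar ratio
#'
#' Ratio of acetate to propionate net production (or concentration, if both
#' are on the same scale). Non-positive propionate makes the ratio undefined:
#' the value is returned as `NA` with a warning rather than an error, so
#' affected records can be excluded downstream.
#'
#' @param acetate Acetate amount (µmol) or concentration.
#' @param propionate Propionate amount or concentration, same units.
#' @return Dimensionless molar ratio, `NA` where propionate <= 0.
#' @examples
#' acetate_propionate_ratio(3000, 1000)  # 3
#' @export
acetate_propionate_ratio <- function(acetate, propionate) {
  bad <- !is.na(propionate) & propionate <= 0
  if (any(bad)) {
    warning("acetate_propionate_ratio: propionate <= 0, ratio undefined, returning NA")
    propionate[bad] <- NA_real_
  }
  acetate / propionate
}
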