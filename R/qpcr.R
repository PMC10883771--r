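#' Copies of a dsDNA standard fragment per microliter
#'
#' Standard dsDNA copy-number computation for an absolute qPCR standard
#' (e.g. a synthetic gene fragment of known length and concentration):
#' `copies/uL = conc (ng/uL) * 1e-9 (g/ng) / (length (bp) * 660 (g/mol/bp))
#' * 6.02214e23`. The 660 g/mol average base-pair mass ignores end-group
#' mass, the usual convention.
#'
#' @param dna_conc DNA concentration (ng/µL).
#' @param fragment_length Fragment length (bp).
#' @return Copies per microliter.
#' @examples
#' copies_per_microliter(1, 500)  # about 1.825e9
#' @export
copies_per_microliter <- function(dna_conc, fragment_length) {
  if (any(dna_conc < 0, na.rm = TRUE))
    sr_stop("copies_per_microliter: concentration must be >= 0")
  if (any(fragment_length <= 0, na.rm = TRUE))
    sr_stop("copies_per_microliter: fragment length must be positive")
  dna_conc * 1e-9 / (fragment_length * sr_constants$bp_mass) * sr_constants$avogadro
}

#' Gene copies per gram of lyophilised culture
#'
#' Scales the copies recovered from an extraction aliquot to a one-gram
#' basis: `copies_per_g = copies_in_eluate * 1000 / aliquot_mass_mg`. The
#' study extracted nominally 100-mg aliquots of lyophilised residue.
#'
#' @param copies_in_eluate Total gene copies recovered from the aliquot.
#' @param aliquot_mass Mass of lyophilised residue extracted (mg).
#' @return Gene copies per gram of lyophilised culture.
#' @examples
#' copies_per_gram(1e9, 100)  # 1e10
#' @export
copies_per_gram <- function(copies_in_eluate, aliquot_mass) {
  if (any(aliquot_mass <= 0, na.rm = TRUE))
    sr_stop("copies_per_gram: aliquot mass must be positive")
  copies_in_eluate * 1000 / aliquot_mass
}

#' Gene copies per bottle
#'
#' Copies per gram of lyophilised residue times the residue dry mass of the
#' whole bottle.
#'
#' @param copies_per_g Gene copies per gram of lyophilised culture.
#' @param residue_mass Lyophilised residue mass of the bottle (g).
#' @return Gene copies per bottle.
#' @examples
#' copies_per_bottle(1e10, 0.35)  # 3.5e9
#' @export
copies_per_bottle <- function(copies_per_g, residue_mass) {
  if (any(residue_mass < 0, na.rm = TRUE))
    sr_stop("copies_per_bottle: residue mass must be >= 0")
  copies_per_g * residue_mass
}
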