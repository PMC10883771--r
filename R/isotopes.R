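#' Ion assignments for VFA isotopolog spectra
#'
#' GC-MS molecular-ion assignments for the three measured volatile fatty
#' acids: base m/z of the M+0 isotopolog and the number of carbon atoms.
#' M+0, M+1 and M+2 correspond to m/z 117-119 (acetate), 131-133
#' (propionate) and 145-147 (butyrate). M+3 and higher isotopologs were not
#' detected and are not part of the spectra.
#'
#' @return Data frame with columns `analyte`, `n_carbons`, `base_mz`.
#' @export
vfa_ions <- function() {
  data.frame(analyte = c("acetate", "propionate", "butyrate"),
             n_carbons = c(2L, 3L, 4L),
             base_mz = c(117L, 131L, 145L),
             stringsAsFactors = FALSE)
}

#' 13C/12C isotope ratio from isotopolog peak intensities
#'
#' The isotope ratio of a VFA is computed from the absolute intensities of
#' its M+0, M+1 and M+2 isotopolog peaks, each weighted by its number of 13C
#' carbons in the numerator and 12C carbons in the denominator:
#' `IR = sum(k * AI_k) / sum((n - k) * AI_k)` for `k = 0, 1, 2` and `n`
#' carbons. For acetate (n = 2) this is `(AI1 + 2 AI2) / (2 AI0 + AI1)`.
#' The ratio is invariant to uniform scaling of the intensities. For
#' intensities following a binomial isotopolog distribution with per-carbon
#' 13C probability `p`, the full (untruncated) ratio equals `p / (1 - p)`
#' exactly; truncation at M+2 biases the ratio low by an amount that grows
#' with `p` and `n` (negligible at natural abundance).
#'
#' @param intensities Numeric vector of absolute intensities for M+0, M+1,
#'   M+2 (length 3; longer vectors, up to M+n, are accepted and weighted
#'   accordingly). Values below `noise_floor` are clamped to 0.
#' @param n_carbons Number of carbon atoms of the analyte (2, 3 or 4 for
#'   acetate, propionate, butyrate).
#' @param noise_floor Intensities below this are treated as 0 (default 0).
#' @return The dimensionless 13C/12C isotope ratio.
#' @examples
#' isotope_ratio(c(100, 0, 50), 4)  # 0.25
#' @export
isotope_ratio <- function(intensities, n_carbons, noise_floor = 0) {
  if (length(intensities) < 2L || length(intensities) > n_carbons + 1L)
    sr_stop("isotope_ratio: intensities must cover M+0..M+k with 1 <= k <= n_carbons")
  if (any(intensities < 0, na.rm = TRUE))
    sr_stop("isotope_ratio: intensities must be >= 0")
  intensities[intensities < noise_floor] <- 0
  k <- seq_along(intensities) - 1
  num <- sum(k * intensities)
  den <- sum((n_carbons - k) * intensities)
  if (!is.finite(den) || den <= 0)
    sr_stop("isotope_ratio: zero or undefined 12C denominator (all-zero spectrum?)",
            class = "sr_undefined_ratio")
  num / den
}

#' Delta-notation 13C enrichment relative to an unlabeled standard
#'
#' `delta = (IR_labeled / IR_standard - 1) * 1000`, in per mil. Zero when
#' sample and standard spectra are proportional; negative for depletion.
#'
#' @param ir_labeled Isotope ratio of the labeled sample.
#' @param ir_standard Isotope ratio of the treatment-matched natural
#'   abundance standard; must be positive.
#' @return Enrichment in per mil.
#' @examples
#' delta_enrichment(0.0110, 0.0100)  # 100
#' @export
delta_enrichment <- function(ir_labeled, ir_standard) {
  if (any(ir_standard <= 0, na.rm = TRUE))
    sr_stop("delta_enrichment: standard isotope ratio must be positive")
  (ir_labeled / ir_standard - 1) * 1000
}

#' Pair labeled isotopolog spectra with their natural-abundance standards
#'
#' One bottle per treatment combination of substrate and dilution rate is an
#' unlabeled standard measuring natural 13C abundance; every labeled bottle
#' in the same cell is referenced to it. This joins each labeled spectrum to
#' its cell- and analyte-matched standard and returns the per-bottle
#' enrichment.
#'
#' @param spectra Data frame with columns `substrate`, `dilution_level`,
#'   `analyte`, `ai_m0`, `ai_m1`, `ai_m2`, `is_standard` (logical) and any
#'   identifier columns (e.g. `sequence`), one row per bottle x analyte.
#' @return Data frame of the labeled rows with added columns `ir`,
#'   `ir_standard`, `delta_permil`.
#' @export
pair_with_standard <- function(spectra) {
  need <- c("substrate", "dilution_level", "analyte",
            "ai_m0", "ai_m1", "ai_m2", "is_standard")
  miss <- setdiff(need, names(spectra))
  if (length(miss))
    sr_stop(paste("pair_with_standard: missing columns:", paste(miss, collapse = ", ")))
  ions <- vfa_ions()
  nc <- ions$n_carbons[match(spectra$analyte, ions$analyte)]
  if (anyNA(nc))
    sr_stop(paste("pair_with_standard: unknown analyte:",
                  paste(unique(spectra$analyte[is.na(nc)]), collapse = ", ")))
  spectra$ir <- vapply(seq_len(nrow(spectra)), function(i)
    isotope_ratio(as.numeric(spectra[i, c("ai_m0", "ai_m1", "ai_m2")]), nc[i]),
    numeric(1))
  cell <- paste(spectra$substrate, spectra$dilution_level, spectra$analyte, sep = "/")
  std <- spectra$is_standard
  for (cl in unique(cell)) {
    n_std <- sum(std & cell == cl)
    if (n_std != 1L)
      sr_stop(sprintf("pair_with_standard: cell %s has %d standards (need exactly 1)",
                      cl, n_std), class = "sr_pairing_error")
  }
  std_ir <- spectra$ir[std]
  names(std_ir) <- cell[std]
  out <- spectra[!std, , drop = FALSE]
  out$ir_standard <- unname(std_ir[cell[!std]])
  out$delta_permil <- delta_enrichment(out$ir, out$ir_standard)
  rownames(out) <- NULL
  out
}

#' Binomial isotopolog intensities
#'
#' Expected isotopolog peak intensities for a molecule of `n_carbons`
#' carbons in which each carbon is 13C with probability `p`, truncated at
#' M+2 (higher isotopologs undetected) unless `truncate = FALSE`.
#'
#' @param p Per-carbon 13C probability (natural abundance is 0.0107).
#' @param n_carbons Number of carbons.
#' @param scale Total intensity scale (arbitrary units), default 1e5.
#' @param truncate Keep only M+0..M+2 (default `TRUE`).
#' @return Numeric vector of intensities M+0, M+1, ... .
#' @export
binomial_isotopologs <- function(p, n_carbons, scale = 1e5, truncate = TRUE) {
  if (p < 0 || p >= 0.5) sr_stop("binomial_isotopologs: p must be in [0, 0.5)")
  k <- 0:n_carbons
  ai <- scale * stats::dbinom(k, n_carbons, p)
  if (truncate) ai <- ai[seq_len(min(3L, n_carbons + 1L))]
  ai
}
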