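#' Parameters of the synthetic serial-culture generator
#'
#' Assembles and validates the parameter set of [simulate_experiment()].
#' Defaults emulate the study's conditions: two substrates whose microbial
#' guilds differ mainly in methanogen (archaea) growth rate, so that under
#' the high-concentrate substrate archaea cannot match any of the three
#' dilution rates and wash out, H2 and formate accumulate and CH4 collapses,
#' while under high forage archaea saturate the hydrogenotrophic route and
#' H2 stays low.
#'
#' Growth within a 72-h batch is logistic with maximum specific rate
#' `mu` (h^-1) and carrying capacity `k` (copies/bottle); metabolite
#' production is a per-substrate yield vector (µmol per transfer at full
#' growth) scaled by the realised biomass increment; CH4 is coupled to H2
#' 4:1 (hydrogenotrophic stoichiometry), limited by the archaeal population
#' relative to `archaea_ref`, with unused H2 accumulating in the headspace.
#'
#' @param substrates Named list (`high_forage`, `high_concentrate`) of
#'   per-substrate parameter lists with elements `mu_bacteria`, `mu_archaea`,
#'   `k_bacteria`, `k_archaea`, `yields` (named µmol vector: acetate,
#'   propionate, butyrate, formate, lactate, nh4, h2, co2), `ph_intercept`,
#'   `ph_slope` (pH units per mM total VFA), `eh_she_mv`, `residue_ratio`
#'   (residue dry mass / substrate dry mass).
#' @param archaea_ref Archaeal copies per bottle at which the
#'   hydrogenotrophic capacity saturates (full H2 usage).
#' @param inoculum List: `conc` named mM vector of the rumen inoculum
#'   (acetate, propionate, butyrate, formate, lactate, nh4),
#'   `bacteria_per_g_solids` and `archaea_per_g_solids` (length-2 vectors,
#'   one value per incubation), `solids_content` (g/mL).
#' @param label List: `p_natural` per-carbon 13C natural abundance,
#'   `p_labeled` per-carbon 13C probability in labeled bottles.
#' @param noise List: `sigma_conc` lognormal sigma on concentrations and
#'   isotopolog intensities, `sigma_copies` lognormal sigma on qPCR copies,
#'   `sigma_pressure` Gaussian sigma on gauge pressure (Pa), `air_max`
#'   upper bound of the uniform residual-air fraction drawn per gas sample.
#' @return An object of class `simulation_params` (a validated list).
#' @examples
#' p <- simulation_params()
#' names(p$substrates)
#' @export
simulation_params <- function(
    substrates = list(
      high_forage = list(
        mu_bacteria = 0.40, mu_archaea = 0.12,
        k_bacteria = 4e10, k_archaea = 3e8,
        yields = c(acetate = 2800, propionate = 900, butyrate = 400,
                   formate = 10, lactate = 300, nh4 = 800,
                   h2 = 1200, co2 = 2500),
        ph_intercept = 7.35, ph_slope = 0.006,
        eh_she_mv = -300, residue_ratio = 1.02),
      high_concentrate = list(
        mu_bacteria = 0.45, mu_archaea = 0.03,
        k_bacteria = 4e10, k_archaea = 3e8,
        yields = c(acetate = 1800, propionate = 900, butyrate = 900,
                   formate = 340, lactate = 150, nh4 = 400,
                   h2 = 1500, co2 = 3000),
        ph_intercept = 7.20, ph_slope = 0.006,
        eh_she_mv = -250, residue_ratio = 1.00)),
    archaea_ref = 3.2e8,
    inoculum = list(
      conc = c(acetate = 60, propionate = 20, butyrate = 12,
               formate = 0.2, lactate = 0.5, nh4 = 10),
      bacteria_per_g_solids = c(10^10.6, 10^10.5),
      archaea_per_g_solids = c(10^7.80, 10^6.81),
      solids_content = 0.05),
    label = list(p_natural = 0.0107, p_labeled = 0.0107 * 1.05),
    noise = list(sigma_conc = 0.05, sigma_copies = 0.2,
                 sigma_pressure = 1000, air_max = 0.1)) {
  for (s in substrates) {
    if (s$mu_bacteria <= 0 || s$mu_archaea <= 0)
      sr_stop("simulation_params: growth rates must be positive")
    if (any(s$yields < 0)) sr_stop("simulation_params: yields must be >= 0")
  }
  if (any(unlist(noise) < 0)) sr_stop("simulation_params: noise sigmas must be >= 0")
  if (noise$air_max >= 1) sr_stop("simulation_params: air_max must be < 1")
  out <- list(substrates = substrates, archaea_ref = archaea_ref,
              inoculum = inoculum, label = label, noise = noise)
  class(out) <- "simulation_params"
  out
}

#' Noise-free simulation parameters
#'
#' [simulation_params()] with all noise terms and the residual-air draw set
#' to zero, for exact pipeline-identity checks.
#'
#' @param ... Passed to [simulation_params()].
#' @return A `simulation_params` object.
#' @export
noise_free_params <- function(...) {
  simulation_params(noise = list(sigma_conc = 0, sigma_copies = 0,
                                 sigma_pressure = 0, air_max = 0), ...)
}

# logistic batch growth over `hours` at rate mu toward capacity k
logistic_grow <- function(n0, mu, k, hours) {
  if (n0 <= 0) return(0)
  e <- exp(mu * hours)
  k * n0 * e / (k + n0 * (e - 1))
}

#' Simulate one 72-h batch transfer
#'
#' One step of the serial culture: (a) the guild populations of the donor
#' bottle are diluted by `inoculum_volume / total_volume`; (b) each guild
#' grows logistically for the batch interval; (c) metabolites are produced
#' in proportion to the realised bacterial biomass increment times the
#' substrate yield vector; (d) H2 is routed to CH4 at 4:1 up to the
#' hydrogenotrophic capacity set by the archaeal population, the remainder
#' accumulating; (e) gauge pressure follows from the produced gas via the
#' ideal gas law on top of the CO2 headspace the bottle was sealed under;
#' (f) solute concentrations combine carryover from the donor fluid with new
#' production in the 40-mL volume.
#'
#' This function is deterministic; measurement noise and residual-air
#' dilution are applied by [simulate_experiment()].
#'
#' @param state List with `bacteria`, `archaea` (copies in the donor bottle,
#'   or per bottle already inoculated when `transfer = 1`), `conc` (named mM
#'   vector of the donor fluid) and `transfer` (index of the transfer being
#'   simulated).
#' @param spec A [bottle_spec()].
#' @param sub One per-substrate parameter list from [simulation_params()].
#' @param archaea_ref Hydrogenotrophic saturation abundance.
#' @param first `TRUE` when `state` holds the copies already delivered into
#'   the transfer-1 bottle (no further dilution).
#' @return List with `state` (next donor state) and `truth` (named list of
#'   true quantities for this bottle: copies, productions, gas amounts,
#'   gauge pressure, fractions, pH, Eh, residue mass).
#' @export
simulate_transfer <- function(state, spec, sub, archaea_ref, first = FALSE) {
  dil <- if (first) 1 else spec$inoculum_volume / spec$total_volume
  b0 <- state$bacteria * dil
  a0 <- state$archaea * dil
  b1 <- logistic_grow(b0, sub$mu_bacteria, sub$k_bacteria, spec$interval)
  a1 <- logistic_grow(a0, sub$mu_archaea, sub$k_archaea, spec$interval)
  # growth fraction: realised bacterial increment over the steady-state increment
  full_increment <- sub$k_bacteria * (1 - spec$inoculum_volume / spec$total_volume)
  g <- (b1 - b0) / full_increment
  prod <- sub$yields * g
  h2_prod <- prod[["h2"]]
  usable <- h2_prod * min(1, a1 / archaea_ref)
  ch4 <- usable / 4
  h2_accum <- h2_prod - usable
  co2 <- prod[["co2"]]
  # headspace sealed under O2-free CO2 at 1 atm
  n_base <- sr_constants$atm_pa * spec$headspace_volume * 1e-6 /
    (sr_constants$gas_constant * (spec$temperature + 273.15))
  n_total <- n_base + (ch4 + h2_accum + co2) * 1e-6
  gauge <- n_total * sr_constants$gas_constant * (spec$temperature + 273.15) /
    (spec$headspace_volume * 1e-6) - sr_constants$atm_pa
  frac_ch4 <- ch4 * 1e-6 / n_total
  frac_h2 <- h2_accum * 1e-6 / n_total
  solutes <- c("acetate", "propionate", "butyrate", "formate", "lactate", "nh4")
  conc <- (state$conc[solutes] * spec$inoculum_volume + prod[solutes]) /
    spec$total_volume
  names(conc) <- solutes
  vfa_mm <- sum(conc[c("acetate", "propionate", "butyrate")])
  truth <- list(
    bacteria = b1, archaea = a1,
    production = prod[solutes],
    umol_ch4 = ch4, umol_h2 = h2_accum, umol_co2 = co2,
    h2_produced = h2_prod,
    gauge_pa = gauge, frac_ch4 = frac_ch4, frac_h2 = frac_h2,
    total_mol = n_total,
    ph2_atm = frac_h2 * (gauge + sr_constants$atm_pa) / sr_constants$atm_pa,
    conc = conc,
    ph = sub$ph_intercept - sub$ph_slope * vfa_mm,
    eh_she_mv = sub$eh_she_mv,
    residue_g = spec$substrate_mass * sub$residue_ratio / 1000
  )
  list(state = list(bacteria = b1, archaea = a1, conc = conc,
                    transfer = state$transfer + 1L),
       truth = truth)
}

#' Generate a complete synthetic serial-culture experiment
#'
#' Runs [simulate_transfer()] over the full design grid (by default the
#' study's 2 substrates x 3 dilution levels x 3 sequences x 2 incubations x
#' 8 transfers, 288 bottle-transfers), applies the measurement model
#' (lognormal noise on concentrations, isotopolog intensities and qPCR
#' copies; Gaussian noise on gauge pressure; uniform residual-air dilution
#' of gas-sample fractions) and returns observation tables in the exact
#' input schemas of the analysis modules together with the noise-free
#' ground truth. Output is deterministic given `seed`: all randomness flows
#' from one seeded generator consumed in a fixed loop order.
#'
#' qPCR and residue observations are emitted for the bottles the study
#' lyophilised (incubation 1 transfer 8; incubation 2 transfers 4 and 8);
#' isotopolog spectra for incubation 2 transfer 8, with the third sequence
#' of each treatment cell serving as the unlabeled natural-abundance
#' standard.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @param n_sequences,n_incubations,n_transfers Design dimensions, default
#'   3, 2, 8.
#' @return An object of class `serial_culture_sim`: list of data frames
#'   `design`, `gas`, `metabolites`, `qpcr`, `isotopologs`, `inoculum`,
#'   `ground_truth`, plus `params` and `seed`.
#' @examples
#' sim <- simulate_experiment(noise_free_params(), seed = 1)
#' nrow(sim$design)  # 288
#' @export
simulate_experiment <- function(params = simulation_params(), seed = 1,
                                n_sequences = 3, n_incubations = 2,
                                n_transfers = 8) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(as.integer(seed))
  design <- design_grid(n_sequences, n_incubations, n_transfers)
  lineages <- unique(design[, c("incubation", "substrate", "dilution_level",
                                "sequence", "inoculum_volume_ml",
                                "medium_volume_ml", "substrate_mass_mg")])
  lineages <- lineages[order(lineages$incubation, lineages$substrate,
                             lineages$dilution_level, lineages$sequence), ]
  noise <- params$noise
  inoc <- params$inoculum
  qpcr_points <- list(c(1, 8), c(2, 4), c(2, 8))
  if (n_incubations < 2 || n_transfers < 8)
    qpcr_points <- list(c(1, min(4, n_transfers)), c(1, n_transfers))
  gas <- metab <- qpcr <- truth <- list()
  for (i in seq_len(nrow(lineages))) {
    ln <- lineages[i, ]
    spec <- bottle_spec(ln$inoculum_volume_ml, ln$medium_volume_ml,
                        substrate_mass = ln$substrate_mass_mg)
    sub <- params$substrates[[ln$substrate]]
    inc <- ln$incubation
    state <- list(
      bacteria = copies_inoculated(inoc$bacteria_per_g_solids[inc],
                                   spec$inoculum_volume, inoc$solids_content),
      archaea = copies_inoculated(inoc$archaea_per_g_solids[inc],
                                  spec$inoculum_volume, inoc$solids_content),
      conc = inoc$conc, transfer = 1L)
    for (t in seq_len(n_transfers)) {
      step <- simulate_transfer(state, spec, sub, params$archaea_ref,
                                first = (t == 1L))
      tr <- step$truth
      key <- data.frame(incubation = inc, sequence = ln$sequence,
                        substrate = ln$substrate,
                        dilution_level = ln$dilution_level, transfer = t,
                        stringsAsFactors = FALSE)
      # gas sample: air dilution of fractions, pressure noise on the gauge
      f_air <- if (noise$air_max > 0) stats::runif(1, 0, noise$air_max) else 0
      gauge_obs <- tr$gauge_pa +
        if (noise$sigma_pressure > 0) stats::rnorm(1, 0, noise$sigma_pressure) else 0
      gas[[length(gas) + 1L]] <- cbind(key, data.frame(
        gauge_pressure_pa = gauge_obs,
        frac_ch4 = tr$frac_ch4 * (1 - f_air),
        frac_h2 = tr$frac_h2 * (1 - f_air),
        frac_o2 = sr_constants$o2_in_air * f_air))
      cnoise <- if (noise$sigma_conc > 0)
        stats::rlnorm(length(tr$conc), 0, noise$sigma_conc) else rep(1, length(tr$conc))
      obs_conc <- tr$conc * cnoise
      metab[[length(metab) + 1L]] <- cbind(key, as.data.frame(as.list(obs_conc)),
                                           data.frame(ph = tr$ph,
                                                      eh_she_mv = tr$eh_she_mv))
      sampled <- any(vapply(qpcr_points, function(p)
        p[1] == inc && p[2] == t, logical(1)))
      if (sampled) {
        for (gene in c("bac_16S", "arc_mcrA")) {
          n_true <- if (gene == "bac_16S") tr$bacteria else tr$archaea
          knoise <- if (noise$sigma_copies > 0) stats::rlnorm(1, 0, noise$sigma_copies) else 1
          qpcr[[length(qpcr) + 1L]] <- cbind(key, data.frame(
            gene = gene,
            copies_per_g = n_true / tr$residue_g * knoise,
            residue_mass_g = tr$residue_g))
        }
      }
      truth[[length(truth) + 1L]] <- cbind(key, data.frame(
        bacteria = tr$bacteria, archaea = tr$archaea,
        t(tr$production),
        umol_ch4 = tr$umol_ch4, umol_h2 = tr$umol_h2, umol_co2 = tr$umol_co2,
        gauge_pa = tr$gauge_pa, total_mol = tr$total_mol,
        ph2_atm = tr$ph2_atm, ph = tr$ph, residue_g = tr$residue_g))
      state <- step$state
    }
  }
  iso <- simulate_isotopologs(params, lineages, n_transfers)
  out <- list(design = design,
              gas = do.call(rbind, gas),
              metabolites = do.call(rbind, metab),
              qpcr = do.call(rbind, qpcr),
              isotopologs = iso,
              inoculum = data.frame(
                incubation = seq_len(n_incubations),
                bacteria_per_g_solids = inoc$bacteria_per_g_solids[seq_len(n_incubations)],
                archaea_per_g_solids = inoc$archaea_per_g_solids[seq_len(n_incubations)],
                solids_content = inoc$solids_content,
                t(inoc$conc)),
              ground_truth = do.call(rbind, truth),
              params = params, seed = seed)
  class(out) <- "serial_culture_sim"
  out
}

# isotopolog spectra for the labeled transfer (incubation 2, transfer 8):
# two labeled sequences plus one natural-abundance standard per cell
simulate_isotopologs <- function(params, lineages, n_transfers) {
  inc2 <- lineages[lineages$incubation == max(lineages$incubation), ]
  cells <- unique(inc2[, c("substrate", "dilution_level")])
  ions <- vfa_ions()
  sig <- params$noise$sigma_conc
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    seqs <- sort(unique(inc2$sequence))
    for (s in seqs) {
      is_std <- (s == max(seqs))
      p <- if (is_std) params$label$p_natural else params$label$p_labeled
      for (ai in seq_len(nrow(ions))) {
        intens <- binomial_isotopologs(p, ions$n_carbons[ai])
        if (sig > 0) intens <- intens * stats::rlnorm(length(intens), 0, sig)
        rows[[length(rows) + 1L]] <- data.frame(
          incubation = max(lineages$incubation), sequence = s,
          substrate = cells$substrate[ci],
          dilution_level = cells$dilution_level[ci],
          transfer = n_transfers,
          analyte = ions$analyte[ai],
          ai_m0 = intens[1], ai_m1 = intens[2], ai_m2 = intens[3],
          is_standard = is_std,
          true_p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.serial_culture_sim <- function(x, ...) {
  cat(sprintf("Synthetic serial-culture experiment (seed %s)\n", x$seed))
  cat(sprintf("  %d bottle-transfers; %d gas rows, %d metabolite rows, %d qPCR rows, %d isotopolog rows\n",
              nrow(x$design), nrow(x$gas), nrow(x$metabolites),
              nrow(x$qpcr), nrow(x$isotopologs)))
  invisible(x)
}
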