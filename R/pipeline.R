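#' Write a numeric-safe CSV
#'
#' RFC 4180 CSV writer (UTF-8, '.' decimal, header, empty field for `NA`)
#' that prints doubles with enough digits (`%.17g`) for a lossless
#' write-read round trip of all finite values.
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
sr_write_csv <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      s <- sprintf("%.17g", y[[j]])
      s[is.na(y[[j]])] <- NA_character_
      y[[j]] <- s
    }
  }
  utils::write.csv(y, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = which(vapply(y, is.character, logical(1))))
}

#' Read and validate a CSV table
#'
#' @param path Input file.
#' @param required Character vector of required column names; absence is an
#'   error naming the missing columns.
#' @return Data frame.
#' @export
sr_read_csv <- function(path, required = character()) {
  if (!file.exists(path)) sr_stop(paste("sr_read_csv: file not found:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(x))
  if (length(miss))
    sr_stop(paste0("sr_read_csv: ", path, " missing columns: ",
                   paste(miss, collapse = ", ")))
  x
}

#' Write a simulated experiment as a CSV bundle
#'
#' Writes `design.csv`, `gas.csv`, `metabolites.csv`, `qpcr.csv`,
#' `isotopologs.csv`, `inoculum.csv`, `ground_truth.csv` and a `run_info.txt`
#' provenance note (package version and seed) into `dir`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "serial_culture_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("design", "gas", "metabolites", "qpcr", "isotopologs",
               "inoculum", "ground_truth"))
    sr_write_csv(sim[[nm]], file.path(dir, paste0(nm, ".csv")))
  writeLines(c(paste("package:", "serialrumen",
                     as.character(utils::packageVersion("serialrumen"))),
               paste("seed:", sim$seed)),
             file.path(dir, "run_info.txt"))
  invisible(dir)
}

#' Read a simulated-experiment CSV bundle
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list with the bundle's data frames (no params; class
#'   `serial_culture_bundle`).
#' @export
read_simulation <- function(dir) {
  out <- list(
    design = sr_read_csv(file.path(dir, "design.csv"),
                         c("incubation", "sequence", "substrate",
                           "dilution_level", "inoculum_volume_ml",
                           "medium_volume_ml", "transfer")),
    gas = sr_read_csv(file.path(dir, "gas.csv"),
                      c("gauge_pressure_pa", "frac_ch4", "frac_h2")),
    metabolites = sr_read_csv(file.path(dir, "metabolites.csv"),
                              c("incubation", "sequence", "transfer")),
    qpcr = sr_read_csv(file.path(dir, "qpcr.csv"),
                       c("gene", "copies_per_g", "residue_mass_g")),
    isotopologs = sr_read_csv(file.path(dir, "isotopologs.csv"),
                              c("analyte", "ai_m0", "ai_m1", "ai_m2",
                                "is_standard")),
    inoculum = sr_read_csv(file.path(dir, "inoculum.csv"),
                           c("incubation", "bacteria_per_g_solids",
                             "archaea_per_g_solids", "solids_content")))
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$ground_truth <- sr_read_csv(gt)
  class(out) <- "serial_culture_bundle"
  out
}

# analytes run through the carryover-production arithmetic
production_analytes <- function() {
  c("acetate", "propionate", "butyrate", "formate", "lactate")
}

#' Run the full analysis pipeline on an experiment bundle
#'
#' Executes the analysis stages in order on a simulated or file-based
#' bundle: headspace gas quantification ([gas_amounts()]),
#' carryover-corrected net metabolite production along each lineage
#' ([chain_production()]; ammonium is reported as concentration only),
#' acetate-to-propionate ratio, qPCR copies per bottle with log10 reporting,
#' replication-rate kinetics against the recomputed dilution rate
#' ([replication_rate()]), and 13C enrichment of the isotopolog spectra
#' ([pair_with_standard()]). A stage failure aborts with the stage name.
#'
#' @param bundle A `serial_culture_sim`, a `serial_culture_bundle` from
#'   [read_simulation()], or a directory path containing the CSV bundle.
#' @param solids_content Inoculum solids content (g/mL) used for initial
#'   copies; defaults to the value in the bundle's inoculum table.
#' @return An object of class `serial_culture_results`: list of data frames
#'   `gas`, `production`, `ratios`, `qpcr`, `kinetics`, `isotopes`.
#' @examples
#' sim <- simulate_experiment(noise_free_params(), seed = 1)
#' res <- run_pipeline(sim)
#' names(res)
#' @export
run_pipeline <- function(bundle, solids_content = NULL) {
  if (is.character(bundle)) bundle <- read_simulation(bundle)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      sr_stop(paste0("run_pipeline: stage '", name, "' failed: ",
                     conditionMessage(e)), class = "sr_stage_error"))
  }
  key_cols <- c("incubation", "sequence", "substrate", "dilution_level",
                "transfer")
  gas_res <- stage("gas", cbind(bundle$gas[key_cols],
                                gas_amounts(bundle$gas)))
  inoc <- bundle$inoculum
  if (is.null(solids_content)) solids_content <- inoc$solids_content[1]
  design <- bundle$design
  lv <- unique(design[, c("dilution_level", "inoculum_volume_ml",
                          "medium_volume_ml")])
  met <- bundle$metabolites
  prod <- stage("production", {
    out <- list()
    lineages <- unique(met[, c("incubation", "sequence", "substrate",
                               "dilution_level")])
    for (i in seq_len(nrow(lineages))) {
      ln <- lineages[i, ]
      sel <- met$incubation == ln$incubation & met$sequence == ln$sequence &
        met$substrate == ln$substrate & met$dilution_level == ln$dilution_level
      rows <- met[sel, ]
      v <- lv$inoculum_volume_ml[lv$dilution_level == ln$dilution_level]
      vt <- v + lv$medium_volume_ml[lv$dilution_level == ln$dilution_level]
      for (an in intersect(production_analytes(), names(rows))) {
        ch <- tryCatch(
          chain_production(rows[[an]], rows$transfer,
                           inoculum_conc = inoc[[an]][inoc$incubation == ln$incubation],
                           inoculum_volume = v, total_volume = vt),
          error = function(e) sr_stop(paste0(
            "lineage incubation ", ln$incubation, " ", ln$substrate, "/",
            ln$dilution_level, " sequence ", ln$sequence, ": ",
            conditionMessage(e)), class = "sr_linkage_error"))
        out[[length(out) + 1L]] <- cbind(
          ln, data.frame(analyte = an, transfer = ch$transfer,
                         umol_net = ch$umol_net), row.names = NULL)
      }
    }
    do.call(rbind, out)
  })
  ratios <- stage("ratios", {
    ac <- prod[prod$analyte == "acetate", ]
    pr <- prod[prod$analyte == "propionate", ]
    m <- merge(ac, pr, by = c("incubation", "sequence", "substrate",
                              "dilution_level", "transfer"),
               suffixes = c("_ac", "_pr"))
    m$ac_pr_ratio <- suppressWarnings(
      acetate_propionate_ratio(m$umol_net_ac, m$umol_net_pr))
    m[, c("incubation", "sequence", "substrate", "dilution_level",
          "transfer", "ac_pr_ratio")]
  })
  qp <- stage("qpcr", {
    q <- bundle$qpcr
    q$copies_per_bottle <- copies_per_bottle(q$copies_per_g, q$residue_mass_g)
    q$log10_per_g <- log10(q$copies_per_g)
    q$log10_per_bottle <- ifelse(q$copies_per_bottle > 0,
                                 log10(q$copies_per_bottle), NA_real_)
    q
  })
  kin <- stage("kinetics", {
    q <- qp
    v <- lv$inoculum_volume_ml[match(q$dilution_level, lv$dilution_level)]
    vm <- lv$medium_volume_ml[match(q$dilution_level, lv$dilution_level)]
    per_g0 <- ifelse(q$gene == "bac_16S",
                     inoc$bacteria_per_g_solids[match(q$incubation, inoc$incubation)],
                     inoc$archaea_per_g_solids[match(q$incubation, inoc$incubation)])
    q$n_initial <- copies_inoculated(per_g0, v, solids_content)
    q$n_final <- q$copies_per_bottle
    q$dilution_rate <- average_dilution_rate(v, vm)
    replication_kinetics(q)
  })
  iso <- stage("isotopes", pair_with_standard(bundle$isotopologs))
  out <- list(gas = gas_res, production = prod, ratios = ratios,
              qpcr = qp, kinetics = kin, isotopes = iso)
  class(out) <- "serial_culture_results"
  out
}

#' @export
print.serial_culture_results <- function(x, ...) {
  cat("Serial-culture pipeline results\n")
  for (nm in names(x))
    cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
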