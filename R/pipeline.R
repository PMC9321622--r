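#' @include AllClasses.R utils.R quenching.R binding.R thermo.R fret.R conformation.R antioxidant.R
NULL

#' Pipeline run configuration
#'
#' Builds a validated configuration for [runPipeline()]. Any input path
#' may be `NULL`; only stages whose inputs are present run. All paths
#' must exist at construction time.
#'
#' @param titration long-format titration table (quenching, binding,
#'   thermodynamics)
#' @param competition long-format titration table with a `label` column
#'   (blank plus site markers) for the competition stage
#' @param donor,acceptor FRET donor emission / acceptor molar
#'   absorptivity spectra
#' @param cd CD trace (nm, mdeg)
#' @param ftir FTIR spectrum (cm^-1, absorbance)
#' @param dpph DPPH assay table
#' @param tau0 fluorophore lifetime, s
#' @param kqThreshold diffusion-limit threshold, L/mol/s
#' @param fret a [fretConfig()]
#' @param fretF,fretF0 intensities for the transfer-efficiency step
#' @param cdConcentration,cdResidues,cdPathLength CD parameters
#' @param calorieFactor J/cal for [kcalToKJ()]
#' @param decreaseThreshold competition decision threshold, percent
#' @param seed integer seed recorded in the report
#' @return a list of class `"RunConfig"`
#' @export
runConfig <- function(titration = NULL, competition = NULL,
                      donor = NULL, acceptor = NULL,
                      cd = NULL, ftir = NULL, dpph = NULL,
                      tau0 = 1e-8, kqThreshold = 2e10,
                      fret = fretConfig(), fretF = NULL, fretF0 = NULL,
                      cdConcentration = 2.5e-6, cdResidues = 585,
                      cdPathLength = 0.1, calorieFactor = 4.1868,
                      decreaseThreshold = 50, seed = 1) {
  paths <- list(titration = titration, competition = competition,
                donor = donor, acceptor = acceptor, cd = cd,
                ftir = ftir, dpph = dpph)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("input path does not exist: ", nm, " = ", paths[[nm]])
  if (all(vapply(paths, is.null, logical(1))))
    stop("usage: at least one stage input must be provided")
  stopifnot(tau0 > 0, kqThreshold > 0, calorieFactor > 0)
  structure(list(paths = paths, tau0 = tau0, kqThreshold = kqThreshold,
                 fret = fret, fretF = fretF, fretF0 = fretF0,
                 cdConcentration = cdConcentration,
                 cdResidues = cdResidues, cdPathLength = cdPathLength,
                 calorieFactor = calorieFactor,
                 decreaseThreshold = decreaseThreshold, seed = seed),
            class = "RunConfig")
}

# hash of the config constants plus the content of every input file:
# changes iff a constant or an input changes
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fileHashes <- lapply(config$paths, function(p)
    if (is.null(p)) NULL else unname(tools::md5sum(p)))
  saveRDS(list(constants = config[setdiff(names(config), "paths")],
               files = fileHashes),
          tmp, version = 2)
  unname(tools::md5sum(tmp))
}

.stageLog <- function(quiet, stage, msg)
  if (!quiet) message(sprintf("[%s] %s", stage, msg))

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are configured, in dependency
#' order: quenching, binding and thermodynamics from the titration
#' table; competition from the labelled table; the Forster chain from
#' the spectral pair; CD, FTIR and DPPH independently. A stage failure
#' is recorded in the report (under `errors`) and the remaining stages
#' still run.
#'
#' @param config a [runConfig()]
#' @param quiet suppress stage-tagged progress messages
#' @return a list of class `"Report"` with per-stage records and a
#'   `provenance` entry (inputs, config hash, package version, seed)
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  report <- list(provenance = list(
    inputs = Filter(Negate(is.null), config$paths),
    config_hash = .configHash(config),
    package_version = as.character(utils::packageVersion("SpectroBind")),
    seed = config$seed))
  errors <- list()
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      .stageLog(quiet, stage, paste("FAILED:", conditionMessage(e)))
      NULL
    })
  }

  if (!is.null(config$paths$titration)) {
    report$quenching <- runStage("quench", {
      series <- readTitrationTable(config$paths$titration)
      fits <- lapply(series, sternVolmerFit, tau0 = config$tau0)
      mech <- if (length(fits) >= 2)
        classifyQuenching(fits, config$kqThreshold) else NULL
      .stageLog(quiet, "quench",
                sprintf("%d series; mechanism: %s", length(fits),
                        if (is.null(mech)) "n/a" else mech$mechanism))
      list(fits = lapply(fits, as.list), mechanism = mech)
    })
    report$binding <- runStage("binding", {
      series <- readTitrationTable(config$paths$titration)
      fits <- lapply(series, doubleLogFit)
      .stageLog(quiet, "binding", sprintf("%d series fitted", length(fits)))
      lapply(fits, as.list)
    })
    report$thermo <- runStage("thermo", {
      series <- readTitrationTable(config$paths$titration)
      fits <- lapply(series, doubleLogFit)
      if (length(fits) < 2)
        stop("thermodynamics needs >= 2 temperatures")
      th <- vantHoffFit(vapply(fits, bindingConstant, numeric(1)),
                        vapply(fits, temperature, numeric(1)))
      .stageLog(quiet, "thermo",
                sprintf("dH = %.2f kJ/mol, dS = %.2f J/mol/K, %s",
                        deltaH(th), deltaS(th), forceLabel(th)))
      as.list(th)
    })
  }

  if (!is.null(config$paths$competition)) {
    report$competition <- runStage("compete", {
      series <- readTitrationTable(config$paths$competition)
      labs <- sub("@.*$", "", names(series))
      fits <- lapply(series, doubleLogFit)
      blankIdx <- which(tolower(labs) %in% c("blank", ""))
      if (!length(blankIdx)) stop("competition table needs a 'blank' label")
      markers <- fits[-blankIdx]
      names(markers) <- labs[-blankIdx]
      res <- competitionAnalysis(fits[[blankIdx[1]]], markers,
                                 config$decreaseThreshold)
      .stageLog(quiet, "compete",
                sprintf("assigned: %s", res$assigned_site))
      res
    })
  }

  if (!is.null(config$paths$donor) && !is.null(config$paths$acceptor)) {
    report$fret <- runStage("fret", {
      donor <- readSpectrum(config$paths$donor, kind = "emission")
      acc <- readSpectrum(config$paths$acceptor,
                          kind = "molar_absorptivity")
      f0 <- if (is.null(config$fretF0)) 1 else config$fretF0
      f <- if (is.null(config$fretF)) (1 - 0.1574) * f0 else config$fretF
      res <- fretAnalysis(f, f0, donor, acc, config$fret)
      .stageLog(quiet, "fret",
                sprintf("E = %.4f, R0 = %.4f nm, r = %.4f nm",
                        res@efficiency, res@r0, res@distance))
      as.list(res)
    })
  }

  if (!is.null(config$paths$cd)) {
    report$cd <- runStage("cd", {
      spec <- readSpectrum(config$paths$cd, kind = "ellipticity")
      res <- cdHelixContent(spec, cp = config$cdConcentration,
                            nRes = config$cdResidues,
                            pathLength = config$cdPathLength)
      .stageLog(quiet, "cd", sprintf("alpha-helix %.2f %%",
                                     structureFractions(res)["alpha_helix"]))
      as.list(res)
    })
  }

  if (!is.null(config$paths$ftir)) {
    report$ftir <- runStage("ftir", {
      spec <- readSpectrum(config$paths$ftir, kind = "ftir")
      res <- amideBandFit(spec)
      .stageLog(quiet, "ftir",
                paste(sprintf("%s %.1f%%", names(structureFractions(res)),
                              structureFractions(res)), collapse = ", "))
      c(as.list(res), list(bands = attr(res, "bands")))
    })
  }

  if (!is.null(config$paths$dpph)) {
    report$dpph <- runStage("dpph", {
      assays <- readDpphTable(config$paths$dpph)
      fits <- lapply(assays, function(a)
        fitIC50Assay(a$concentration, a$a_control, a$a_sample))
      out <- list(fits = lapply(fits, as.list))
      if (all(c("free", "complexed") %in% names(fits)))
        out$attenuation <- attenuationReport(fits$free, fits$complexed)
      .stageLog(quiet, "dpph",
                paste(sprintf("%s IC50 = %.4g", names(fits),
                              vapply(fits, ic50, numeric(1))),
                      collapse = "; "))
      out
    })
  }

  if (length(errors)) report$errors <- errors
  structure(report, class = "Report")
}

#' Write a pipeline report
#'
#' Serializes a [runPipeline()] report as machine-readable JSON and a
#' human-readable Markdown summary with per-stage tables. Units: Ksv
#' and Ka in L/mol, Kq in L/mol/s, dH and dG in kJ/mol, dS in J/mol/K,
#' distances in nm, IC50 in ug/mL.
#'
#' @param report a `"Report"` list
#' @param dir output directory
#' @return invisibly, `c(json, markdown)` paths
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "Report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  .writeJson(unclass(report), jsonPath)
  md <- c("# Ligand-protein binding analysis report", "",
          paste0("Package version: ",
                 report$provenance$package_version,
                 " | config hash: ", report$provenance$config_hash), "")
  if (!is.null(report$quenching)) {
    md <- c(md, "## Stern-Volmer quenching", "",
            "| T (K) | Ksv (L/mol) | Kq (L/mol/s) | R | SD |",
            "|---|---|---|---|---|")
    for (f in report$quenching$fits)
      md <- c(md, sprintf("| %g | %.4g | %.4g | %.4f | %.2g |",
                          f$temperature, f$ksv, f$kq, f$r, f$sd))
    if (!is.null(report$quenching$mechanism))
      md <- c(md, "", paste0("Mechanism: **",
                             report$quenching$mechanism$mechanism, "**"))
    md <- c(md, "")
  }
  if (!is.null(report$binding)) {
    md <- c(md, "## Double-log binding", "",
            "| T (K) | Ka (L/mol) | n | R |", "|---|---|---|---|")
    for (f in report$binding)
      md <- c(md, sprintf("| %g | %.4g | %.3f | %.4f |",
                          f$temperature, f$ka, f$n, f$r))
    md <- c(md, "")
  }
  if (!is.null(report$thermo)) {
    t <- report$thermo
    md <- c(md, "## Thermodynamics", "",
            sprintf("dH = %.2f kJ/mol, dS = %.2f J/mol/K, forces: %s",
                    t$dH, t$dS, t$forceLabel), "",
            "| T (K) | dG (dH-TdS, kJ/mol) | dG (-RTlnKa, kJ/mol) |",
            "|---|---|---|")
    for (i in seq_along(t$temperatures))
      md <- c(md, sprintf("| %g | %.2f | %.2f |", t$temperatures[i],
                          t$gibbs[i], t$gibbsFromKa[i]))
    md <- c(md, "")
  }
  if (!is.null(report$competition)) {
    cmp <- report$competition
    md <- c(md, "## Site-marker competition", "",
            "| marker | Ka (L/mol) | decrease (%) |", "|---|---|---|")
    for (i in seq_len(nrow(cmp$markers)))
      md <- c(md, sprintf("| %s | %.4g | %.2f |",
                          cmp$markers$marker[i], cmp$markers$ka[i],
                          cmp$markers$percent_decrease[i]))
    md <- c(md, "", paste0("Assigned: **", cmp$assigned_site, "**"), "")
  }
  if (!is.null(report$fret)) {
    f <- report$fret
    md <- c(md, "## Forster energy transfer", "",
            sprintf("E = %.4f | J = %.4g %s | R0 = %.4f nm | r = %.4f nm",
                    f$efficiency, f$j, f$jUnits, f$r0, f$distance),
            sprintf("valid (r < 7 nm): %s | valid (0.5 R0 < r < 1.5 R0): %s",
                    f$validDistance, f$validRatio), "")
  }
  if (!is.null(report$cd))
    md <- c(md, "## Circular dichroism", "",
            sprintf("alpha-helix: %.2f %%", report$cd$fractions), "")
  if (!is.null(report$ftir)) {
    md <- c(md, "## Amide-I decomposition", "",
            "| component | fraction (%) |", "|---|---|")
    fr <- report$ftir$fractions
    for (nm in names(fr))
      md <- c(md, sprintf("| %s | %.2f |", nm, fr[nm]))
    md <- c(md, "")
  }
  if (!is.null(report$dpph)) {
    md <- c(md, "## DPPH scavenging", "",
            "| condition | IC50 (ug/mL) |", "|---|---|")
    for (nm in names(report$dpph$fits))
      md <- c(md, sprintf("| %s | %.4g |", nm,
                          report$dpph$fits[[nm]]$ic50))
    if (!is.null(report$dpph$attenuation))
      md <- c(md, "",
              sprintf("IC50 ratio (complexed/free): %.3f (%s)",
                      report$dpph$attenuation$ratio,
                      report$dpph$attenuation$direction))
    md <- c(md, "")
  }
  if (!is.null(report$errors)) {
    md <- c(md, "## Stage failures", "")
    for (nm in names(report$errors))
      md <- c(md, paste0("- ", nm, ": ", report$errors[[nm]]))
  }
  mdPath <- file.path(dir, "report.md")
  writeLines(md, mdPath)
  invisible(c(json = jsonPath, markdown = mdPath))
}
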