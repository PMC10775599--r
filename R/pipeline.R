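#' @include synthetic-plates.R synthetic-ocr.R synthetic-degs.R atp-budget.R
#' @include enrichment.R rank-tests.R io.R
NULL

.STAGES <- c("simulate", "quantify", "bioenergetics", "degs", "enrich", "stats")

#' Default pipeline configuration
#'
#' One declarative list holding every tunable of an end-to-end run: the seed,
#' output directory, enabled stages, experiment-design parameters, noise
#' levels, all analysis thresholds (fold change, FDR, FPM, enrichment E and
#' p, term-size window), the stoichiometry constants and the OCR phase
#' summaries. Thresholds live here, never hard-coded in the operations. The
#' configuration round-trips unchanged through YAML
#' ([writeRunConfig()] / [readRunConfig()]).
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outputDir directory the run writes into.
#' @param stages subset of
#'   `c("simulate", "quantify", "bioenergetics", "degs", "enrich", "stats")`.
#' @param ... named overrides of any default entry (partial lists are merged).
#' @return a named list (class `"acidflux_config"`).
#' @export
runConfig <- function(seed = 1L, outputDir = tempfile("acidflux_run_"),
                      stages = .STAGES, ...) {
  cfg <- list(
    seed = as.integer(seed),
    outputDir = outputDir,
    stages = stages,
    design = list(
      replicates = 6L, duration = 2880, cellsPerWell = 1e5, volumeL = 0.002,
      mediumGlucose = 5.5, mediumGlutamine = 2
    ),
    noise = list(plateCV = 0.05, ocrCV = 0.03),
    deg = list(
      nGenes = 15000L, propDE = 0.12, effectMean = 1.2, effectSd = 0.4,
      slope = 0.5, flipProb = 0.05, lactateScale = 0.02, noiseSd = 0
    ),
    thresholds = list(
      fc = 0.59, fdr = 0.05, fpm = 5,
      e = 2.5, p = 0.001, minTerm = 5, maxTerm = 3000
    ),
    stoichiometry = list(
      atpPerGlucoseGlycolysis = 2, atpPerGlucoseOxidation = 30,
      atpPerGlutamine = 10, o2PerGlutamine = 2
    ),
    phaseSummary = list(
      baseline = "last", oligo = "min", fccp = "max", rotAA = "min"
    ),
    inputs = list(plateDir = NULL, ocrFile = NULL, degDir = NULL)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "acidflux_config")
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @param cfg a configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$design$replicates <- as.integer(cfg$design$replicates)
  cfg$deg$nGenes <- as.integer(cfg$deg$nGenes)
  structure(cfg, class = "acidflux_config")
}

.stageInput <- function(cfg, results, key, stage, what) {
  if (!is.null(results[[key]])) {
    return(results[[key]])
  }
  path <- cfg$inputs[[what]]
  if (is.null(path) || !all(file.exists(path))) {
    stop(
      "stage '", stage, "': required input '", what,
      "' not available (enable the 'simulate' stage or provide the file)"
    )
  }
  NULL # caller reads from path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order — synthesize, quantify,
#' bioenergetics, DEG post-processing, enrichment, group statistics — writing
#' per-stage TSV/JSON artifacts and a run manifest (package version, seed,
#' configuration hash, per-stage row counts) into the configured output
#' directory. The run is deterministic given the seed: two runs with the
#' same configuration produce byte-identical manifests. Disabling a stage
#' never changes another stage's outputs; a stage whose inputs are neither
#' in memory (from an enabled `simulate`) nor on disk fails with an error
#' naming the stage.
#'
#' @param cfg a configuration from [runConfig()] (or a YAML path).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(cfg = runConfig()) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  counts <- list()
  design <- experimentDesign(
    replicates = cfg$design$replicates, duration = cfg$design$duration,
    cellsPerWell = cfg$design$cellsPerWell, volumeL = cfg$design$volumeL,
    mediumGlucose = cfg$design$mediumGlucose,
    mediumGlutamine = cfg$design$mediumGlutamine,
    seed = cfg$seed
  )
  truth <- defaultGroundTruth(
    degSlope = cfg$deg$slope, degFlipProb = cfg$deg$flipProb
  )
  k <- stoichiometryConstants(
    atpPerGlucoseGlycolysis = cfg$stoichiometry$atpPerGlucoseGlycolysis,
    atpPerGlucoseOxidation = cfg$stoichiometry$atpPerGlucoseOxidation,
    atpPerGlutamine = cfg$stoichiometry$atpPerGlutamine,
    o2PerGlutamine = cfg$stoichiometry$o2PerGlutamine
  )

  if ("simulate" %in% cfg$stages) {
    sim_dir <- file.path(cfg$outputDir, "simulated")
    dir.create(sim_dir, showWarnings = FALSE)
    res$plates <- lapply(
      stats::setNames(nm = c("glucose", "lactate", "glutamine", "ATP")),
      function(a) {
        pl <- simulatePlateAssay(design, a, truth, noiseCV = cfg$noise$plateCV)
        writeTSV(pl, file.path(sim_dir, paste0("plate_", a, ".tsv")))
        pl
      }
    )
    res$ocr <- simulateOCRTraces(design, truth, noiseCV = cfg$noise$ocrCV)
    writeTSV(res$ocr, file.path(sim_dir, "ocr_traces.tsv"))
    res$degTables <- simulateDEGTables(
      nGenes = cfg$deg$nGenes, propDE = cfg$deg$propDE,
      effectMean = cfg$deg$effectMean, effectSd = cfg$deg$effectSd,
      slope = cfg$deg$slope, flipProb = cfg$deg$flipProb,
      lactateScale = cfg$deg$lactateScale, noiseSd = cfg$deg$noiseSd,
      seed = cfg$seed
    )
    for (nm in names(res$degTables)) {
      writeTSV(res$degTables[[nm]], file.path(sim_dir, paste0("deg_", nm, ".tsv")))
    }
    counts$simulate <- list(
      plates = length(res$plates), ocr_rows = nrow(res$ocr),
      genes = nrow(res$degTables$LA)
    )
  }

  if ("quantify" %in% cfg$stages) {
    if (is.null(res$plates)) {
      pd <- cfg$inputs$plateDir
      if (is.null(pd) || !dir.exists(pd)) {
        stop("stage 'quantify': no plate tables (enable 'simulate' or set inputs$plateDir)")
      }
      files <- list.files(pd, pattern = "^plate_.*\\.tsv$", full.names = TRUE)
      res$plates <- lapply(files, readTSV)
      names(res$plates) <- sub("^plate_(.*)\\.tsv$", "\\1", basename(files))
    }
    medium <- c(
      glucose = cfg$design$mediumGlucose,
      glutamine = cfg$design$mediumGlutamine
    )
    fluxes <- do.call(rbind, lapply(
      intersect(c("glucose", "lactate", "glutamine"), names(res$plates)),
      function(substrate) {
        q <- quantifyPlate(res$plates[[substrate]])
        direction <- if (substrate == "lactate") "production" else "consumption"
        do.call(rbind, lapply(unique(q$condition), function(cn) {
          med <- if (substrate == "lactate") {
            design@lactateBackground[[cn]]
          } else {
            medium[[substrate]]
          }
          d <- mediumDelta(
            mean(q$amount[q$condition == cn]), med, direction,
            substrate = substrate, condition = cn
          )
          fluxNormalize(
            d, design@volumeL, design@duration, design@cellsPerWell,
            substrate = substrate, condition = cn
          )
        }))
      }
    ))
    res$fluxes <- fluxes
    writeTSV(fluxes, file.path(cfg$outputDir, "flux_records.tsv"))
    if (!is.null(res$plates$ATP)) {
      q <- quantifyPlate(res$plates$ATP)
      res$atpContent <- vapply(
        stats::setNames(nm = unique(q$condition)),
        function(cn) mean(q$amount[q$condition == cn]), numeric(1)
      )
    }
    counts$quantify <- list(flux_records = nrow(fluxes))
  }

  if ("bioenergetics" %in% cfg$stages) {
    if (is.null(res$ocr)) {
      of <- cfg$inputs$ocrFile
      if (is.null(of) || !file.exists(of)) {
        stop("stage 'bioenergetics': OCR trace file not available (enable 'simulate' or set inputs$ocrFile)")
      }
      res$ocr <- readTSV(of)
    }
    if (is.null(res$fluxes)) {
      stop("stage 'bioenergetics': flux records not available (enable 'quantify')")
    }
    summ <- unlist(cfg$phaseSummary)
    per_cond <- lapply(
      stats::setNames(nm = unique(res$ocr$condition)),
      function(cn) {
        sub <- res$ocr[res$ocr$condition == cn, ]
        wells <- unique(sub$well)
        params <- lapply(wells, function(w) {
          extractMitoParams(sub[sub$well == w, ], summary = summ)
        })
        # average the per-well parameters on the component scale
        avg <- function(get) mean(vapply(params, get, numeric(1)))
        basal <- avg(basalRespiration)
        leak <- avg(protonLeak)
        maximal <- avg(maximalRespiration)
        new("MitoParams",
          nonMito = avg(nonMitoRespiration), basal = basal,
          atpLinked = basal - leak, protonLeak = leak,
          maximal = maximal, spare = maximal - basal,
          couplingEfficiency = (basal - leak) / basal,
          flags = character()
        )
      }
    )
    res$mitoParams <- per_cond
    atp_content <- res$atpContent
    if (is.null(atp_content)) {
      stop("stage 'bioenergetics': ATP content not available (panel 8 input)")
    }
    budgets <- lapply(names(per_cond), function(cn) {
      fx <- res$fluxes[res$fluxes$condition == cn, ]
      buildATPBudget(fx, per_cond[[cn]], atp_content[[cn]], k, condition = cn)
    })
    names(budgets) <- names(per_cond)
    res$budgets <- budgets
    budget_tab <- do.call(rbind, lapply(budgets, atpBudgetTable))
    writeTSV(budget_tab, file.path(cfg$outputDir, "atp_budget.tsv"))
    jsonlite::write_json(
      lapply(budgets, function(b) as.list(atpBudgetTable(b))),
      file.path(cfg$outputDir, "atp_budget.json"),
      auto_unbox = TRUE, digits = NA
    )
    counts$bioenergetics <- list(conditions = length(budgets))
  }

  if ("degs" %in% cfg$stages) {
    if (is.null(res$degTables)) {
      dd <- cfg$inputs$degDir
      if (is.null(dd) || !dir.exists(dd)) {
        stop("stage 'degs': DEG tables not available (enable 'simulate' or set inputs$degDir)")
      }
      files <- list.files(dd, pattern = "^deg_.*\\.tsv$", full.names = TRUE)
      res$degTables <- lapply(files, readTSV)
      names(res$degTables) <- sub("^deg_(.*)\\.tsv$", "\\1", basename(files))
    }
    th <- cfg$thresholds
    degs <- lapply(res$degTables, filterDEGs,
      fcThreshold = th$fc, fdrThreshold = th$fdr, fpmThreshold = th$fpm
    )
    res$degSets <- lapply(degs, `[[`, "gene_id")
    res$venn <- vennPartition(
      res$degSets$HCl, res$degSets$LA, res$degSets$Na_lactate,
      labels = c("HCl", "LA", "Na_lactate")
    )
    res$concordance <- concordance(res$degTables$LA, res$degTables$HCl)
    writeTSV(
      data.frame(
        region = names(vennCounts(res$venn)),
        n = as.integer(vennCounts(res$venn))
      ),
      file.path(cfg$outputDir, "venn_regions.tsv")
    )
    jsonlite::write_json(
      list(
        deg_counts = lapply(degs, nrow),
        venn = as.list(vennCounts(res$venn)),
        concordance = list(
          fraction_same_sign = fractionSameSign(res$concordance),
          slope = concordanceSlope(res$concordance),
          n_common = res$concordance@nCommon
        )
      ),
      file.path(cfg$outputDir, "deg_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    counts$degs <- lapply(degs, nrow)
  }

  if ("enrich" %in% cfg$stages) {
    if (is.null(res$degSets)) {
      stop("stage 'enrich': DEG sets not available (enable 'degs')")
    }
    set.seed(.substreamSeed(cfg$seed, "terms"))
    universe <- res$degTables$LA$gene_id
    la_degs <- res$degSets$LA
    # synthetic collection: one term seeded with LA DEGs, the rest random
    terms <- c(
      list(acidosis_response = unique(c(
        sample(la_degs, min(120, length(la_degs))),
        sample(universe, 60)
      ))),
      lapply(
        stats::setNames(nm = sprintf("random_term_%02d", 1:20)),
        function(i) sample(universe, sample(20:400, 1))
      )
    )
    res$enrichment <- enrich(
      la_degs, terms, universe,
      minTerm = cfg$thresholds$minTerm, maxTerm = cfg$thresholds$maxTerm,
      pThresh = cfg$thresholds$p, eThresh = cfg$thresholds$e
    )
    writeTSV(res$enrichment, file.path(cfg$outputDir, "enrichment.tsv"))
    counts$enrich <- list(terms_tested = length(terms),
                          terms_passing = nrow(res$enrichment))
  }

  if ("stats" %in% cfg$stages) {
    if (is.null(res$plates)) {
      stop("stage 'stats': quantified plates not available (enable 'simulate')")
    }
    q <- quantifyPlate(res$plates$glucose)
    res$groupTests <- rankTest(q$amount, q$condition)
    writeTSV(res$groupTests, file.path(cfg$outputDir, "group_tests.tsv"))
    counts$stats <- list(comparisons = nrow(res$groupTests))
  }

  cfg_path <- file.path(cfg$outputDir, "config.yaml")
  writeRunConfig(cfg, cfg_path)
  manifest <- list(
    package = "acidflux",
    version = as.character(utils::packageVersion("acidflux")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = cfg$stages,
    counts = counts
  )
  jsonlite::write_json(
    manifest, file.path(cfg$outputDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  res$manifest <- manifest
  invisible(res)
}
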