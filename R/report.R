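#' Forest-plot data table from a screen
#'
#' One row per (outcome, method) with OR, 95\% CI bounds, p, instrument
#' count and verdict — the numbers behind a forest plot. Rendering is left
#' to the caller (the table is \code{ggplot2}- or \code{forestplot}-ready).
#'
#' @param screen result of \code{\link{runForwardScreen}} or
#'   \code{\link{runReverseScreen}}.
#' @return data.frame.
#' @export
forestTable <- function(screen) {
  tab <- screen$table
  if (is.null(tab) || !nrow(tab)) stop("empty screen result")
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    if (tab$status[i] != "ok") next
    det <- screen$details[[i]]
    for (res in det$results) {
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = tab$exposure[i], outcome = tab$outcome[i],
        method = res@method, beta = res@beta, or = res@or,
        or_ci_low = res@orCiLow, or_ci_high = res@orCiHigh,
        pval = res@pval, n_snp = res@nSnp, verdict = tab$verdict[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no successful screen rows")
  do.call(rbind, rows)
}

#' Write / read the package's TSV tables
#'
#' Plain TSV with a header; \code{readResultsTable} round-trips anything
#' \code{writeResultsTable} wrote.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
writeResultsTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.configSelection <- function(cfg) {
  sc <- cfg$selection
  if (is.null(sc)) return(selectionConfig())
  do.call(selectionConfig, sc[intersect(names(sc),
    names(formals(selectionConfig)))])
}

.requireSeed <- function(cfg) {
  if (is.null(cfg$seed)) stop("config validation: 'seed' is required")
  as.integer(cfg$seed)
}

#' Run a pipeline described by a YAML configuration file
#'
#' Subcommands (\code{mode} key): \code{simulate} (pair / triad / ld, per
#' \code{simulate: kind}), \code{screen}, \code{reverse}, \code{mediate},
#' \code{replicate}. Input paths, selection thresholds, estimator and
#' sensitivity options, Bonferroni family size and the mandatory seed all
#' come from the file. Writes the result TSVs, per-pair exclusion logs, a
#' machine-readable run manifest (\code{manifest.yaml}: inputs, config,
#' seed, package version) and a plain-text log with per-stage counts into
#' \code{outDir}.
#'
#' @param configPath YAML file path.
#' @return invisibly, the list of artifact paths written.
#' @export
runFromConfig <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$mode)) stop("config validation: 'mode' is required")
  outDir <- cfg$out_dir
  if (is.null(outDir)) stop("config validation: 'out_dir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- .requireSeed(cfg)
  sel <- .configSelection(cfg)
  written <- character()
  logLines <- c(paste("mode:", cfg$mode), paste("seed:", seed))
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeResultsTable(df, p)
    written <<- c(written, p)
  }

  readTrait <- function(path) readSummaryStats(path)
  if (cfg$mode == "simulate") {
    sc <- do.call(simConfig, c(cfg$simulate$config,
                               list(seed = seed)))
    kind <- cfg$simulate$kind
    if (identical(kind, "ld")) {
      ld <- simulateLD(sc@mSnps, sc@ldBlockSize, sc@ldRho)
      p <- file.path(outDir, "ld.tsv")
      writeLDMatrix(ld, p); written <- c(written, p)
    } else if (identical(kind, "triad")) {
      tr <- simulateTriad(sc)
      for (nm in c("exposure", "mediator", "outcome")) {
        p <- file.path(outDir, paste0(nm, ".tsv"))
        writeSummaryDataset(tr[[nm]], p); written <- c(written, p)
      }
    } else {
      pr <- simulatePair(sc)
      for (nm in c("exposure", "outcome")) {
        p <- file.path(outDir, paste0(nm, ".tsv"))
        writeSummaryDataset(pr[[nm]], p); written <- c(written, p)
      }
    }
  } else if (cfg$mode %in% c("screen", "reverse")) {
    exposure <- readTrait(cfg$exposure)
    outcomes <- lapply(cfg$outcomes, readTrait)
    ld <- readLDMatrix(cfg$ld,
                       if (cfg$mode == "screen") exposure
                       else do.call(rbind,
                         lapply(outcomes, function(d)
                           records(d)[, c("snp_id", "chrom", "pos")])))
    scr <- if (cfg$mode == "screen")
      runForwardScreen(exposure, outcomes, ld, sel, seed = seed,
                       familySize = cfg$family_size %||% length(outcomes),
                       nBoot = cfg$n_boot %||% 1000L,
                       nSim = cfg$n_sim %||% 1000L)
    else
      runReverseScreen(outcomes, exposure, ld, sel, seed = seed,
                       familySize = cfg$family_size %||% length(outcomes),
                       nBoot = cfg$n_boot %||% 1000L,
                       nSim = cfg$n_sim %||% 1000L)
    emit(scr$table, "screen.tsv")
    sens <- do.call(rbind, lapply(scr$details, function(d) d$sensitivity))
    if (!is.null(sens)) emit(sens, "sensitivity.tsv")
    emit(forestTable(scr), "forest.tsv")
    for (nm in names(scr$details)) {
      d <- scr$details[[nm]]
      if (!is.null(d$h))
        emit(exclusionLog(d$h), paste0("exclusions_", nm, ".tsv"))
    }
    logLines <- c(logLines, paste("outcomes:", length(outcomes)))
  } else if (cfg$mode == "mediate") {
    exposure <- readTrait(cfg$exposure)
    outcome <- readTrait(cfg$outcome)
    mediators <- lapply(cfg$mediators, readTrait)
    ld <- readLDMatrix(cfg$ld, exposure)
    ms <- runMediatorScreen(exposure, mediators, outcome, ld, sel,
                            seed = seed,
                            nBoot = cfg$n_boot %||% 1000L,
                            nSim = cfg$n_sim %||% 1000L)
    if (!is.null(ms$stepA)) emit(ms$stepA, "mediator_stepA.tsv")
    if (!is.null(ms$stepB)) emit(ms$stepB, "mediator_stepB.tsv")
    if (!is.null(ms$mediation)) emit(ms$mediation, "mediation.tsv")
    logLines <- c(logLines,
                  vapply(names(ms$log), function(nm)
                    paste0(nm, ": ", ms$log[[nm]]), character(1)))
  } else if (cfg$mode == "replicate") {
    exposure <- readTrait(cfg$exposure)
    replication <- readTrait(cfg$replication)
    ld <- readLDMatrix(cfg$ld, exposure)
    instr <- buildInstruments(exposure, ld, sel)
    rep <- replicateFinding(cfg$primary_beta, instr, replication)
    emit(mrResultsTable(list(rep$result),
                        exposure = traitName(exposure),
                        outcome = traitName(replication)),
         "replication.tsv")
    logLines <- c(logLines, paste("verdict:", rep$verdict))
  } else stop("config validation: unknown mode '", cfg$mode, "'")

  manifest <- list(mode = cfg$mode, seed = seed, config = cfg,
                   package_version =
                     as.character(utils::packageVersion("mrmediate")),
                   written = written)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(c(written, file.path(outDir, c("manifest.yaml", "run.log"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
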