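#' Run an analysis stage as a reproducible pipeline step
#'
#' Single programmatic entry point wiring the stages together. Validates the
#' configuration, executes the requested stage, and writes a report bundle to
#' the output directory: \code{report.json} (full-precision values plus
#' rounded display strings), stage-specific TSV/CSV tables, and
#' \code{manifest.json} echoing the fully resolved configuration and package
#' version so a run can be regenerated exactly. Reports are deterministic
#' given the configuration; only the manifest carries a timestamp. On
#' failure, partial outputs are removed.
#'
#' @param config a list with \code{subcommand} plus stage parameters:
#' \describe{
#'   \item{\code{"clonality"}}{\code{contigs} (path), \code{dialect}
#'     ("tenx"/"airr"), optional \code{key_level} ("nt"/"aa"),
#'     \code{include_vj}, \code{policy}, \code{sample_id}, \code{tissue}.
#'     Calls read / pair / clonotype / summary and, with >= 2 samples, the
#'     shared-clonotype table.}
#'   \item{\code{"parabiosis"}}{\code{cohort} (CSV path or data.frame),
#'     \code{steady} and \code{post} counts, or \code{mean_recruitment_pct};
#'     optional \code{boot}, \code{seed}.}
#'   \item{\code{"photoconversion"}}{\code{samples} (CSV path or
#'     data.frame).}
#'   \item{\code{"signature"}}{\code{de} and \code{signature} (paths or
#'     objects), optional \code{min_fold}, \code{denominator},
#'     \code{fold_threshold}.}
#'   \item{\code{"simulate"}}{\code{what} ("repertoire", "parabiosis",
#'     "photoconversion", "de") plus that generator's arguments.}
#' }
#' @param out output directory (created if needed). \code{NULL} skips file
#'   output and just returns the report.
#' @return the report, invisibly (a named list; also written as JSON when
#'   \code{out} is given).
#' @export
runPipeline <- function(config, out = NULL) {
  if (is.null(config$subcommand))
    stop("config$subcommand is required")
  sub <- match.arg(config$subcommand,
    c("clonality", "parabiosis", "photoconversion", "signature", "simulate"))

  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character()
  emit <- function(df, name, sep = "\t") {
    if (!is.null(out)) {
      p <- file.path(out, name)
      writeFlatTable(df, p, sep = sep)
      written <<- c(written, p)
    }
  }

  report <- tryCatch(
    switch(sub,
      clonality = {
        dialect <- config$dialect %||% "tenx"
        contigs <- if (is.data.frame(config$contigs)) config$contigs
          else readContigTable(config$contigs, dialect,
            sample_id = config$sample_id, tissue = config$tissue)
        paired <- filterPairedProductive(contigs,
          policy = config$policy %||% "dominant")
        reps <- callClonotypesBySample(paired,
          key_level = config$key_level %||% "nt",
          include_vj = config$include_vj %||% TRUE)
        if (length(reps) == 0L) stop("no cells survived pairing")
        summ <- clonalitySummary(reps)
        if (!is.null(out))
          written <- c(written,
            writeClonotypeTable(reps, file.path(out, "clonotypes.tsv")))
        emit(summ, "summary.tsv")
        shared <- NULL
        if (length(reps) >= 2L) {
          shared <- sharedClonotypes(reps, min_samples = 2)
          emit(shared, "shared_clonotypes.tsv")
        }
        list(subcommand = sub,
          parse_report = attr(contigs, "parse_report"),
          filter_report = filterReport(paired),
          summary = summ,
          aggregate = aggregateClonality(summ),
          n_shared_clonotypes = if (is.null(shared)) NA else nrow(shared))
      },
      parabiosis = {
        cohort <- config$cohort
        if (is.character(cohort))
          cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
        est <- estimateRecruitment(cohort,
          steady_state_count = config$steady,
          post_injury_count = config$post,
          mean_recruitment_pct = config$mean_recruitment_pct,
          boot = config$boot %||% FALSE,
          seed = config$seed %||% 1)
        list(subcommand = sub,
          per_mouse_recruitment_pct = perMouseRecruitmentPct(est),
          mean_recruitment_pct = meanRecruitmentPct(est),
          accumulated_count = accumulatedCount(est),
          recruited_count = recruitedCount(est),
          recruited_fraction_of_total_pct = recruitedFractionPct(est),
          ci = if (anyNA(est@ci)) NULL else est@ci,
          display = displayValues(est))
      },
      photoconversion = {
        samples <- config$samples
        if (is.character(samples))
          samples <- utils::read.csv(samples, stringsAsFactors = FALSE)
        ratios <- migrationRatio(samples)
        emit(ratios, "migration_ratios.tsv")
        list(subcommand = sub, ratios = ratios)
      },
      signature = {
        de <- if (is.character(config$de)) readDETable(config$de)
          else config$de
        sig <- if (is.character(config$signature))
          readSignature(config$signature) else config$signature
        res <- signatureConcordance(de, sig,
          min_fold = config$min_fold %||% 1,
          denominator = config$denominator %||% "present")
        fold <- config$fold_threshold %||% 2
        emit(geneVerdicts(res), "gene_verdicts.tsv")
        list(subcommand = sub,
          n_signature_present = res@nSignaturePresent,
          n_concordant = res@nConcordant,
          concordance_pct = concordanceFractionPct(res),
          min_fold = res@minFold, denominator = res@denominator,
          fold_change_counts = list(threshold = fold,
            up = countFoldChangeGenes(de, fold, "up"),
            down = countFoldChangeGenes(de, fold, "down"),
            both = countFoldChangeGenes(de, fold, "both")),
          display = list(concordance_pct =
            roundHalfUp(concordanceFractionPct(res), 1)))
      },
      simulate = {
        what <- match.arg(config$what,
          c("repertoire", "parabiosis", "photoconversion", "de"))
        gen <- switch(what,
          repertoire = simulateRepertoire,
          parabiosis = simulateParabiosis,
          photoconversion = simulatePhotoconversion,
          de = simulateDETable)
        args <- config[setdiff(names(config), c("subcommand", "what"))]
        args$dir <- out
        res <- do.call(gen, args)
        list(subcommand = sub, what = what, truth = res$truth,
          paths = res$paths)
      }),
    error = function(e) {
      if (length(written)) unlink(written)
      stop("pipeline stage '", sub, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })

  if (!is.null(out)) {
    writeJSONReport(report, file.path(out, "report.json"))
    manifest <- list(
      package = "TregTrace",
      version = as.character(utils::packageVersion("TregTrace")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config[!vapply(config, is.data.frame, logical(1))])
    writeJSONReport(manifest, file.path(out, "manifest.json"))
  }
  invisible(report)
}
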