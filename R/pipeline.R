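# ---- end-to-end pipeline ----------------------------------------------------

#' Pipeline configuration
#'
#' Collects input paths and per-stage parameters for [run_pipeline()].
#' Every threshold defaults to the value the individual stage defaults to,
#' so a configuration that names only the inputs runs the standard analysis.
#'
#' @param genome Path to the genome (GenBank, or FASTA with `annotation`).
#' @param annotation Optional GFF3 path (when `genome` is FASTA).
#' @param alignments Path to a SAM/BAM file of transcriptome alignments.
#' @param out_dir Output directory (created if needed).
#' @param ingest An [ingest_params()].
#' @param editing An [editing_params()].
#' @param cover_min,d_min,max_gap,splice_tolerance,min_ir_len Stage
#'   thresholds (see the stage functions).
#' @param log Log progress lines to `stderr`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation = NULL, alignments,
                            out_dir = "plastoscope_out",
                            ingest = ingest_params(),
                            editing = editing_params(),
                            cover_min = 1L, d_min = 1L, max_gap = 0L,
                            splice_tolerance = 0L, min_ir_len = 1000L,
                            log = TRUE) {
  structure(list(genome = genome, annotation = annotation,
                 alignments = alignments, out_dir = out_dir,
                 ingest = ingest, editing = editing,
                 cover_min = as.integer(cover_min),
                 d_min = as.integer(d_min), max_gap = as.integer(max_gap),
                 splice_tolerance = as.integer(splice_tolerance),
                 min_ir_len = as.integer(min_ir_len), log = isTRUE(log)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat YAML document; unknown keys are rejected.  Nested `ingest:` and
#' `editing:` blocks override the corresponding parameter defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("genome", "annotation", "alignments", "out_dir", "ingest",
             "editing", "cover_min", "d_min", "max_gap",
             "splice_tolerance", "min_ir_len", "log")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$ingest)) y$ingest <- do.call(ingest_params, y$ingest)
  if (!is.null(y$editing)) y$editing <- do.call(editing_params, y$editing)
  do.call(pipeline_config, y)
}

plog <- function(config, ...) {
  if (config$log)
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: genome structure detection, read filtering and pileup,
#' coverage profiling, transcription-unit delineation, editing-site calling
#' and intron-splicing scoring.  All reports are written as TSV under
#' `out_dir`, together with a `manifest.json` recording the parameters and
#' the MD5 checksum of every input and output; a rerun on identical inputs
#' is bit-identical (modulo the manifest's timestamp field, which records
#' the input checksums, not the clock).
#'
#' @param config A [pipeline_config()] or the path of a YAML file.
#' @return Invisibly, a list with the in-memory stage results (`structure`,
#'   `pileup`, `profile`, `units`, `edits`, `splicing`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (p in c(config$genome, config$annotation, config$alignments))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  stage <- "read_genome"
  res <- tryCatch({
    plog(config, "reading genome")
    genome <- if (is.null(config$annotation))
      read_plastome(config$genome, "genbank")
    else read_plastome(config$genome, "fasta+gff3", gff3 = config$annotation)

    stage <- "structure"
    plog(config, "detecting quadripartite structure")
    qs <- detect_quadripartite(genome, config$min_ir_len)
    sdf <- if (is.null(qs)) {
      data.frame(region = character(), start = integer(), end = integer(),
                 length = integer())
    } else as.data.frame(qs)
    utils::write.table(sdf, out("structure.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "pileup"
    plog(config, "ingesting alignments")
    reads <- read_alignments(config$alignments)
    reads <- filter_reads(reads, config$ingest)
    pileup <- build_pileup(reads, genome, config$ingest)
    write_pileup_tsv(pileup, out("pileup.tsv"))
    depth <- depth_vector(pileup, genome$length)

    stage <- "coverage"
    plog(config, "profiling coverage")
    profile <- profile_coverage(depth, genome, config$cover_min)
    cov_sum <- data.frame(covered_length = profile$covered_length,
                          genome_length = genome$length,
                          percent_covered = profile$percent_covered,
                          mean_depth = profile$mean_depth,
                          percent_coding = percent_coding(genome))
    utils::write.table(cov_sum, out("coverage_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(profile$per_feature, out("coverage_per_feature.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "units"
    plog(config, "delineating transcription units")
    units <- delineate_units(depth, genome, config$d_min, config$max_gap)
    utils::write.table(unit_report(units, genome), out("units.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "editing"
    plog(config, "calling editing sites")
    edits <- call_editing_sites(pileup, genome, config$editing)
    write_edit_table(edits, out("edits.tsv"))

    stage <- "splicing"
    plog(config, "scoring intron splicing")
    junctions <- extract_junctions(reads)
    splicing <- score_introns(junctions, genome, config$splice_tolerance,
                              depth = depth)
    utils::write.table(splicing, out("splicing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    list(genome = genome, structure = qs, pileup = pileup,
         profile = profile, units = units, edits = edits,
         splicing = splicing)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  reports <- c("structure.tsv", "pileup.tsv", "coverage_summary.tsv",
               "coverage_per_feature.tsv", "units.tsv", "edits.tsv",
               "splicing.tsv")
  inputs <- c(config$genome, config$annotation, config$alignments)
  manifest <- list(
    parameters = config[c("cover_min", "d_min", "max_gap",
                          "splice_tolerance", "min_ir_len")],
    ingest = unclass(config$ingest), editing = unclass(config$editing),
    inputs = as.list(tools::md5sum(inputs)),
    reports = as.list(tools::md5sum(file.path(config$out_dir, reports))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  plog(config, "done: ", length(reports), " reports in ", config$out_dir)
  invisible(c(res, list(manifest = manifest)))
}
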