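#' Assemble a pipeline configuration
#'
#' Collects file paths and every stage threshold into a single
#' serialisable list. Every stated analysis constant is a named key:
#' `mismatch_budget` (3), the novel-candidate `mfe_max` (-20 kcal/mol),
#' the target `min_energy_ratio` (74 percent), `conservation_min`
#' (9 species) and the cleaning length window (18-30 nt).
#'
#' @param reads,genome,known_db,ncrna,transcriptome input file paths
#'   (FASTQ/FASTA); `annotation` optionally a TSV with columns
#'   `transcript_id`, `category`.
#' @param output_dir directory for reports and intermediates.
#' @param prefix species prefix for assigned and novel names.
#' @param mismatch_budget known-assignment edit budget.
#' @param conservation_min species threshold for conserved families.
#' @param cleaning list of [cleaning_params()] arguments.
#' @param novel list of [novel_thresholds()] arguments.
#' @param targets list of [target_thresholds()] arguments.
#' @param seed integer seed recorded in the run summary.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, genome, known_db, ncrna, transcriptome,
                            annotation = NULL, output_dir = "plantmir_out",
                            prefix = "col", mismatch_budget = 3L,
                            conservation_min = 9L,
                            cleaning = list(), novel = list(),
                            targets = list(), seed = 1L) {
  cfg <- list(reads = reads, genome = genome, known_db = known_db,
              ncrna = ncrna, transcriptome = transcriptome,
              annotation = annotation, output_dir = output_dir,
              prefix = prefix, mismatch_budget = as.integer(mismatch_budget),
              conservation_min = as.integer(conservation_min),
              cleaning = cleaning, novel = novel, targets = targets,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes cleaning, ncRNA exclusion, known-miRNA assignment, family
#' quantification and conservation classification, novel miRNA
#' discovery, target prediction and primer design, writing every report
#' into `output_dir`. Deterministic given the configuration.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return (invisibly) a list with all stage results plus `summary`
#'   (named counts per stage).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (p in c("reads", "genome", "known_db", "ncrna", "transcriptome")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      stop("config error: input path missing or unreadable: ", p, call. = FALSE)
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  model <- energy_model()
  params <- do.call(cleaning_params, config$cleaning)
  novel_th <- do.call(novel_thresholds, config$novel)
  target_th <- do.call(target_thresholds, config$targets)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  reads <- run_stage("read input", read_sequence_file(config$reads))
  cleaned <- run_stage("cleaning", clean_library(reads, params))
  tags <- cleaned$tags
  sizes <- size_distribution(tags)

  excl <- run_stage("ncRNA filter", read_sequence_file(config$ncrna, rna = TRUE))
  tags_f <- filter_ncrna(tags, excl)

  db <- run_stage("known assignment", read_sequence_file(config$known_db, rna = TRUE))
  hits <- assign_known(tags_f, db, config$mismatch_budget, config$prefix)
  families <- group_and_quantify(hits, tags_f, config$mismatch_budget)
  presence <- build_presence_table(db)
  families <- classify_conservation(families, presence, config$conservation_min)

  un <- unassigned_tags(tags_f, hits)
  genome <- run_stage("novel discovery", read_sequence_file(config$genome, rna = TRUE))
  novel <- discover_novel(un, genome, model, novel_th, prefix = config$prefix,
                          all_tags = tags_f)

  transcripts <- run_stage("target prediction",
                           read_sequence_file(config$transcriptome, rna = TRUE))
  mirnas <- c(setNames(families$representative_sequence, families$representative),
              setNames(novel$table$sequence, novel$table$name))
  targets <- scan_transcriptome(mirnas, transcripts, target_th, model)

  annotation_summary <- NULL
  if (!is.null(config$annotation) && file.exists(config$annotation)) {
    ann <- read_tabular(config$annotation)
    annotation_summary <- annotate_targets(targets, ann)
  }

  primers <- run_stage("primer design",
                       suppressWarnings(design_primers(mirnas[nchar(mirnas) >= 18])))

  results <- list(report = cleaned$report, over_length = cleaned$over_length,
                  tags = tags, sizes = sizes, tags_filtered = tags_f,
                  ncrna_removed = attr(tags_f, "removed"),
                  hits = hits, families = families, unassigned = un,
                  novel = novel, targets = targets,
                  annotation_summary = annotation_summary, primers = primers)
  results$summary <- list(
    seed = config$seed,
    total_reads = cleaned$report$count[cleaned$report$type == "Total_reads"],
    clean_reads = cleaned$report$count[cleaned$report$type == "Clean_reads"],
    clean_tags = nrow(tags),
    tags_after_ncrna_filter = nrow(tags_f),
    known_hits = nrow(hits),
    known_families = nrow(families),
    conserved_families = sum(families$conserved),
    unassigned_tags = nrow(un),
    novel_mirnas = nrow(novel$table),
    target_sites = nrow(targets),
    primer_sets = if (is.null(primers)) 0L else nrow(primers),
    thresholds = list(mismatch_budget = config$mismatch_budget,
                      mfe_max = novel_th$mfe_max,
                      min_energy_ratio = target_th$min_energy_ratio,
                      conservation_min = config$conservation_min,
                      min_len = params$min_len, max_len = params$max_len))
  write_reports(results, config$output_dir)
  invisible(results)
}

#' Write the pipeline report files
#'
#' Emits, into `outdir`: the cleaning summary, the tag length
#' distribution, the known-miRNA table (one row per assigned tag,
#' ordered by family then decreasing count), the family table with
#' member counts and conservation calls (largest family first), the
#' novel-candidate table, the target table with the bracketed energy
#' ratio, the primer table, precursor structures in dot-bracket form,
#' a GFF3 of precursor loci and a JSON run summary.
#'
#' @param results list from [run_pipeline()].
#' @param outdir output directory.
#' @return (invisibly) the output directory.
#' @export
write_reports <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tabular(results$report, file.path(outdir, "cleaning_report.tsv"))
  write_tabular(results$sizes, file.path(outdir, "size_distribution.tsv"))

  hits <- results$hits
  known_tab <- data.frame(
    family = hits$family, name = hits$assigned_name, length = hits$length,
    count = hits$count, sequence = hits$sequence, homolog = hits$db_name,
    matches = hits$matches, mismatches = hits$mismatches, gaps = hits$gaps,
    stringsAsFactors = FALSE)
  known_tab <- known_tab[order(known_tab$family, -known_tab$count), , drop = FALSE]
  write_tabular(known_tab, file.path(outdir, "known_mirnas.tsv"))

  fam <- results$families
  fam_tab <- fam[order(-fam$n_members, -fam$expression), , drop = FALSE]
  write_tabular(fam_tab, file.path(outdir, "families.tsv"))

  write_tabular(results$novel$table[, c("name", "reads", "sequence", "length", "mfe")],
                file.path(outdir, "novel_mirnas.tsv"))

  tg <- results$targets
  if (nrow(tg)) {
    n_per <- table(tg$mirna_name)
    target_tab <- data.frame(
      mirna_name = tg$mirna_name,
      targets_number = as.integer(n_per[tg$mirna_name]),
      target_accession = tg$transcript_id,
      location = sprintf("%d, %d", tg$start, tg$end),
      free_energy = sprintf("%.2f [%.2f%%]", tg$duplex_energy, tg$energy_ratio),
      stringsAsFactors = FALSE)
  } else {
    target_tab <- data.frame(mirna_name = character(0),
                             targets_number = integer(0),
                             target_accession = character(0),
                             location = character(0),
                             free_energy = character(0))
  }
  write_tabular(target_tab, file.path(outdir, "targets.tsv"))
  if (!is.null(results$annotation_summary)) {
    write_tabular(results$annotation_summary,
                  file.path(outdir, "target_categories.tsv"))
  }
  if (!is.null(results$primers)) {
    write_tabular(results$primers, file.path(outdir, "primers.tsv"))
  }

  cand <- results$novel$candidates
  if (length(cand)) {
    db_lines <- unlist(lapply(names(cand), function(nm) {
      c(paste0(">", nm), cand[[nm]]$precursor, cand[[nm]]$structure$dotbracket,
        sprintf("# MFE %.2f kcal/mol", cand[[nm]]$mfe))
    }))
    writeLines(db_lines, file.path(outdir, "novel_structures.txt"))
    nt <- results$novel$table
    gff <- sprintf("%s\tplantmir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
                   nt$chrom, nt$start, nt$end, nt$strand, nt$name)
    writeLines(c("##gff-version 3", gff), file.path(outdir, "novel_loci.gff3"))
  }
  jsonlite::write_json(results$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
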