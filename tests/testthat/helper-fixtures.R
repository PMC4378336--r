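# Small file fixtures and a scaled-down simulation used by the unit
# tests (the acceptance suite runs the default-scale simulation).

write_tmp_fasta <- function(records, ext = ".fa") {
  f <- tempfile(fileext = ext)
  write_fasta(records, f)
  f
}

write_tmp_fastq <- function(reads) {
  f <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", reads$id), as_dna(reads$sequence),
                             "+", reads$quality)), f)
  f
}

small_sim_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, genome_length = 20000, n_hairpins = 4,
                    n_spoilers = 3, n_known_db = 8, read_depth = 8000,
                    n_transcripts = 4, n_planted_targets = 4, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_sim_config()
      db <- simulate_known_db(cfg)
      gh <- simulate_genome_and_hairpins(cfg)
      lib <- simulate_library(cfg, gh$truth, db)
      cache <<- list(cfg = cfg, db = db, gh = gh, lib = lib)
    }
    cache
  }
})
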