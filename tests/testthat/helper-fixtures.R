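# fixtures are generated in code; nothing is read from disk except files the
# tests themselves write to tempdir()

tiny_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

write_temp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# annotation with one + strand gene and configurable peaks, on one chromosome
tiny_annotation <- function(chrom = "chr1", gene_start = 1000L,
                            gene_end = 2000L, strand = "+",
                            dnase = NULL, atac = NULL) {
  feature_annotation(
    data.frame(gene_id = "g1", chrom = chrom, start = gene_start,
               end = gene_end, strand = strand, stringsAsFactors = FALSE),
    dnase = dnase, atac = atac)
}

# small screen shared by several selection/simulation tests
calibration_config <- function(seed = 101L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 3e5,
             n_genes = 40L, gene_length = c(3000L, 8000L),
             insertions_per_sample = 150, ...)
}

local({
  cache <- new.env(parent = emptyenv())
  cached_sim <<- function() {
    if (is.null(cache$sim)) cache$sim <- simulate_genome(calibration_config())
    cache$sim
  }
})
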