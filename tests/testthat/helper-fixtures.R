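# Small shared fixtures, built in code.

# a compact simulation for fast per-module tests
small_sim_config <- function(seed = 11L, ...) {
  simulation_config(seed = seed, n_chrom = 2L, chrom_length = 60000L,
                    n_genes = 40L, gene_length_range = c(600L, 2000L),
                    n_germline_het = 400L, n_somatic_shared = 60L,
                    n_somatic_private = c(40L, 30L), n_somatic_lowdepth = 10L,
                    aging_list_size = 12L, n_null_sets = 10L, ...)
}

# hand-built two-chromosome reference with known sequence
toy_reference <- function(seqs = c(chr1 = "ACGTACGTACGTACGT",
                                   chr2 = "TTTTCCCCGGGGAAAA")) {
  structure(list(seq = seqs, lengths = nchar(seqs)), class = "ReferenceGenome")
}

# minimal variant table constructor
toy_variants <- function(chrom, pos, ref, alt, ..., ann = NA_character_) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   ann = ann, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  samples <- unique(sub("^gt_", "", grep("^gt_", names(df), value = TRUE)))
  attr(df, "samples") <- samples
  df
}

manifest_keys <- function(manifest, classes) {
  m <- manifest[manifest$class %in% classes, , drop = FALSE]
  paste(m$chrom, m$pos, m$ref, m$alt, sep = ":")
}
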