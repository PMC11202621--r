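test_that("pyrimidine normalization gives the expected channels", {
  ref <- toy_reference(c(chr1 = "AACAA", chr2 = "ATGGA"))
  expect_equal(sbs_channel("chr1", 3, "C", "A", ref), "A[C>A]A")
  # TGG with middle G>A reverse-complements to C[C>T]A
  expect_equal(sbs_channel("chr2", 3, "G", "A", ref), "C[C>T]A")
  expect_error(sbs_channel("chr1", 3, "G", "A", ref), "disagrees")
})

test_that("every channel label round-trips through a constructed variant", {
  # build a genome spelling out each channel's forward context end to end,
  # separated by N spacers so contexts cannot bleed into each other
  labels <- sbs_channels()
  ctx <- vapply(labels, function(l) {
    p <- somaclone:::parse_channel(l)
    paste0(p$five, p$ref, p$three)
  }, character(1))
  seq <- paste(ctx, collapse = "N")
  ref <- structure(list(seq = c(chr1 = seq), lengths = c(chr1 = nchar(seq))),
                   class = "ReferenceGenome")
  for (i in seq_along(labels)) {
    p <- somaclone:::parse_channel(labels[i])
    pos <- (i - 1) * 4 + 2
    expect_equal(sbs_channel("chr1", pos, p$ref, p$alt, ref), labels[i])
    # the same variant planted on the opposite strand maps to the same label
    rc_ref <- chartr("ACGT", "TGCA", p$ref)
    rc_alt <- chartr("ACGT", "TGCA", p$alt)
    rc_seq <- somaclone:::revcomp(seq)
    rc_genome <- structure(list(seq = c(chr1 = rc_seq),
                                lengths = c(chr1 = nchar(rc_seq))),
                           class = "ReferenceGenome")
    rc_pos <- nchar(seq) - pos + 1
    expect_equal(sbs_channel("chr1", rc_pos, rc_ref, rc_alt, rc_genome), labels[i])
  }
})

test_that("spectrum counting conserves totals and drops edge/N contexts", {
  ref <- toy_reference(c(chr1 = "ACGTNACGT"))
  sites <- toy_variants("chr1", c(1, 2, 4, 6, 7), c("A", "C", "T", "A", "C"),
                        c("G", "T", "A", "T", "A"),
                        gt_NT2 = rep("het", 5), dp_NT2 = rep(60L, 5))
  sp <- build_spectrum(sites, ref)
  # pos 1 is at the chromosome edge, pos 4 and 6 have N in context -> dropped
  expect_equal(sp$dropped, 3L)
  expect_equal(sp$total, 2L)
  expect_equal(sp$total + sp$dropped, nrow(sites))
  # indels are ignored entirely, not tallied as dropped
  sites2 <- rbind(sites, toy_variants("chr1", 8, "GT", "G",
                                      gt_NT2 = "het", dp_NT2 = 60L))
  sp2 <- build_spectrum(sites2, ref)
  expect_equal(sp2$total + sp2$dropped, 5L)
})

test_that("six-class collapse matches brute-force label re-aggregation", {
  set.seed(42)
  counts <- stats::setNames(rpois(96, 5), sbs_channels())
  sp <- structure(list(counts = counts, dropped = 0L, total = sum(counts)),
                  class = "Spectrum96")
  six <- collapse_to_six(sp)
  expect_equal(sum(six), 1, tolerance = 1e-12)
  # brute force: parse each label and sum
  brute <- stats::setNames(numeric(6), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  for (l in names(counts)) {
    cls <- paste0(somaclone:::parse_channel(l)$ref, ">",
                  somaclone:::parse_channel(l)$alt)
    brute[cls] <- brute[cls] + counts[l]
  }
  expect_equal(as.numeric(six), as.numeric(brute / sum(brute)), tolerance = 1e-12)
  # degenerate cases
  uni <- structure(list(counts = stats::setNames(rep(1L, 96), sbs_channels()),
                        dropped = 0L, total = 96L), class = "Spectrum96")
  expect_equal(as.numeric(collapse_to_six(uni)), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("cosine similarity matches an independent dot-product computation", {
  x <- stats::setNames(numeric(96), sbs_channels())
  y <- x
  x[1:3] <- c(1, 2, 2)
  y[1:3] <- c(2, 1, 2)
  hand <- (1 * 2 + 2 * 1 + 2 * 2) / (sqrt(1 + 4 + 4) * sqrt(4 + 1 + 4))
  expect_equal(cosine_similarity(x, y), hand, tolerance = 1e-12)
  expect_equal(cosine_similarity(x, x), 1, tolerance = 1e-12)
  z <- stats::setNames(numeric(96), sbs_channels()); z[10] <- 1
  expect_equal(cosine_similarity(x, z), 0)
  expect_error(cosine_similarity(x, numeric(96)), "zero-norm")
})

test_that("flatness is normalized Shannon entropy", {
  uni <- structure(list(counts = stats::setNames(rep(2L, 96), sbs_channels()),
                        dropped = 0L, total = 192L), class = "Spectrum96")
  expect_equal(flatness(uni), 1, tolerance = 1e-12)
  single <- structure(list(counts = stats::setNames(c(5L, rep(0L, 95)),
                                                    sbs_channels()),
                           dropped = 0L, total = 5L), class = "Spectrum96")
  expect_equal(flatness(single), 0)
  two <- structure(list(counts = stats::setNames(c(3L, 3L, rep(0L, 94)),
                                                 sbs_channels()),
                        dropped = 0L, total = 6L), class = "Spectrum96")
  expect_equal(flatness(two), log(2) / log(96), tolerance = 1e-12)
})

test_that("best_match ranks by similarity with name tie-breaks", {
  sigs <- builtin_signatures()
  uni <- structure(list(counts = stats::setNames(rep(1L, 96), sbs_channels()),
                        dropped = 0L, total = 96L), class = "Spectrum96")
  expect_equal(best_match(uni, sigs)$signature[1], "flat")
  ct <- stats::setNames(integer(96), sbs_channels())
  ct[substring(names(ct), 3, 5) == "C>T"] <- 1L
  ct_sp <- structure(list(counts = ct, dropped = 0L, total = sum(ct)),
                     class = "Spectrum96")
  expect_equal(best_match(ct_sp, sigs)$signature[1], "uv_ct")
})

test_that("planted draws from a signature are recovered by the spectrum", {
  cfg <- simulation_config(seed = 97, n_chrom = 2L, chrom_length = 150000L,
                           n_genes = 0L, n_germline_het = 0L,
                           n_somatic_shared = 2000L,
                           n_somatic_private = 0L, n_somatic_lowdepth = 0L,
                           aging_list_size = 0L, signature = "flat")
  sim <- simulate_all(cfg)
  shared <- sim$manifest[sim$manifest$class == "shared", ]
  sp <- build_spectrum(toy_variants(shared$chrom, shared$pos, shared$ref,
                                    shared$alt, gt_NT2 = "het", dp_NT2 = 60L),
                       sim$reference)
  expect_gte(cosine_similarity(sp, builtin_signatures()[, "flat"]), 0.90)
  # empirical channel distribution matches the manifest channels exactly
  expect_equal(as.integer(sp$counts[names(sp$counts)]),
               as.integer(table(factor(shared$channel, levels = sbs_channels()))))
})

test_that("genome reverse-complement leaves the spectrum unchanged", {
  cfg <- small_sim_config(seed = 61)
  sim <- simulate_all(cfg)
  shared <- sim$manifest[sim$manifest$class == "shared", ]
  sites <- toy_variants(shared$chrom, shared$pos, shared$ref, shared$alt,
                        gt_NT2 = "het", dp_NT2 = 60L)
  sp <- build_spectrum(sites, sim$reference)
  rc_seqs <- vapply(sim$reference$seq, somaclone:::revcomp, character(1))
  rc_ref <- structure(list(seq = rc_seqs, lengths = nchar(rc_seqs)),
                      class = "ReferenceGenome")
  lens <- sim$reference$lengths[shared$chrom]
  rc_sites <- toy_variants(shared$chrom, lens - shared$pos + 1L,
                           chartr("ACGT", "TGCA", shared$ref),
                           chartr("ACGT", "TGCA", shared$alt),
                           gt_NT2 = "het", dp_NT2 = 60L)
  rc_sp <- build_spectrum(rc_sites, rc_ref)
  expect_equal(rc_sp$counts, sp$counts)
})
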