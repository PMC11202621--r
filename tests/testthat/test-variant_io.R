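test_that("VCF reading splits multi-allelic records and classifies genotypes", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNT2",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:DP\t1/2:55",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT:DP\t0/1:60",
    "chr1\t300\t.\tG\t<DEL>\t.\tPASS\t.\tGT:DP\t0/1:30",
    "chr1\t400\t.\tT\tA\t.\tPASS\t.\tGT:DP\t./.:."
  ), vcf)
  v <- read_vcf(vcf)
  # the 1/2 record splits into two het rows; symbolic allele is skipped
  expect_equal(nrow(v), 4)
  expect_equal(attr(v, "n_skipped"), 1L)
  first <- v[v$pos == 100, ]
  expect_setequal(first$alt, c("G", "T"))
  expect_equal(first$gt_NT2, c("het", "het"))
  expect_equal(v$gt_NT2[v$pos == 200], "het")
  expect_equal(v$dp_NT2[v$pos == 200], 60L)
  expect_equal(v$gt_NT2[v$pos == 400], "missing")
  expect_error(read_vcf(vcf, "NOPE"), "not present")
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("a 0/1 genotype at a multi-allelic site is het for alt1, hom_ref for alt2", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNT2",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:DP\t0/1:55"
  ), vcf)
  v <- read_vcf(vcf)
  expect_equal(v$gt_NT2[v$alt == "G"], "het")
  expect_equal(v$gt_NT2[v$alt == "T"], "hom_ref")
})

test_that("VCF write/read round-trip preserves site and observation tuples", {
  sim <- simulate_all(small_sim_config())
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, path)
  back <- read_vcf(path)
  cols <- c("chrom", "pos", "ref", "alt", "gt_Donor", "dp_Donor",
            "gt_NT2", "dp_NT2", "gt_NT4", "dp_NT4")
  orig <- sim$variants[order(sim$variants$chrom, sim$variants$pos), cols]
  rownames(orig) <- NULL
  expect_equal(back[, cols], orig)
  expect_equal(nrow(back), nrow(sim$variants))
})

test_that("reference reading is case-folded and queries are 1-based inclusive", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 description", "acgta"), fa)
  g <- read_reference(fa)
  expect_equal(ref_query(g, "chr1", 1, 4), "ACGT")
  expect_equal(ref_query(g, "chr1", 2, 4), "CGT")
  expect_error(ref_query(g, "chr1", 2, 6), "out of range")
  expect_error(ref_query(g, "chrX", 1, 1), "not in reference")
})

test_that("reference genome round-trips through FASTA", {
  sim_ref <- simulate_reference(small_sim_config())
  fa <- tempfile(fileext = ".fa")
  write_reference(sim_ref, fa)
  back <- read_reference(fa)
  expect_equal(back$seq, sim_ref$seq)
})

test_that("gene models round-trip through GFF3 with correct lengths and CDS", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t1030\t.\t+\t.\tID=X;Name=Y",
    "chr1\tsrc\tmRNA\t101\t1030\t.\t+\t.\tID=X.t1;Parent=X",
    "chr1\tsrc\tCDS\t200\t400\t.\t+\t0\tID=X.t1.c;Parent=X.t1",
    "chr1\tsrc\tCDS\t500\t700\t.\t+\t0\tID=X.t1.c;Parent=X.t1"
  ), gff)
  g <- read_gene_models(gff)
  expect_equal(g$length, 930L)
  expect_equal(g$gene_id, "X")
  expect_equal(g$symbol, "Y")
  expect_equal(nrow(g$cds[[1]]), 2)

  sim <- simulate_all(small_sim_config())
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, path)
  back <- read_gene_models(path)
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
  expect_equal(back$length, sim$genes$length)
  expect_true(all(back$start <= back$end))
  # CDS segments inside gene spans
  for (i in seq_len(nrow(back))) {
    segs <- back$cds[[i]]
    expect_true(all(segs[, 1] >= back$start[i] & segs[, 2] <= back$end[i]))
  }
})

test_that("GTF attribute parsing maps gene_id and gene_name", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\tgene\t10\t90\t.\t+\t.\t",
                    "gene_id \"X\"; gene_name \"Y\";"), gtf)
  g <- read_gene_models(gtf)
  expect_equal(g$gene_id, "X")
  expect_equal(g$symbol, "Y")
})

test_that("only the longest transcript's CDS is retained", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=G1",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\tsrc\tCDS\t10\t39\t.\t+\t0\tID=c1;Parent=T1",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=T2;Parent=G1",
    "chr1\tsrc\tCDS\t10\t99\t.\t+\t0\tID=c2;Parent=T2"
  ), gff)
  g <- read_gene_models(gff)
  expect_equal(nrow(g$cds[[1]]), 1)
  expect_equal(unname(g$cds[[1]][1, "end"]), 99)
})

test_that("signature matrix reading validates, reorders and renormalizes", {
  path <- tempfile(fileext = ".tsv")
  sigs <- builtin_signatures()
  # shuffle rows and perturb the column sum within tolerance
  df <- data.frame(Type = rownames(sigs), flat = as.numeric(sigs[, "flat"]),
                   stringsAsFactors = FALSE)
  df <- df[sample(96), ]
  df$flat <- df$flat * 1.0005
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_signature_matrix(path)
  expect_equal(rownames(m), sbs_channels())
  expect_equal(sum(m[, "flat"]), 1, tolerance = 1e-12)
  expect_equal(as.numeric(m[, "flat"]), rep(1 / 96, 96), tolerance = 1e-12)

  # 95 rows is rejected
  utils::write.table(df[-1, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(path), "96")
  # out-of-tolerance sum is rejected
  df$flat <- df$flat * 1.01
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(path), "sum to 1")
})

test_that("population panel reads from TSV and from genotype VCF", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf\tmissing_rate",
               "chr1\t100\tA\tG\t0.25\t0.0",
               "chr1\t200\tC\tT\t0.005\t0.2"), tsv)
  p <- read_population_panel(tsv)
  expect_equal(p$af[p$key == "chr1:100:A:G"], 0.25)

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0\t0/0"
  ), vcf)
  pv <- read_population_panel(vcf)
  expect_equal(pv$af[pv$key == "chr1:100:A:G"], 3 / 8)
  expect_equal(pv$missing_rate[pv$key == "chr1:200:C:T"], 0.25)
  expect_equal(attr(pv, "n_samples"), 4L)
})

test_that("multi-allelic split conserves retained allele count on a synthetic file", {
  # fixture written then re-read: row count equals sum of per-record alts
  vcf <- tempfile(fileext = ".vcf")
  set.seed(5)
  n <- 50
  alts <- vapply(seq_len(n), function(i) {
    paste(sample(setdiff(c("A", "C", "G", "T"), "A"), sample(1:2, 1)),
          collapse = ",")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    sprintf("chr1\t%d\t.\tA\t%s\t.\tPASS\t.\tGT:DP\t0/1:60", seq_len(n) * 10, alts)
  ), vcf)
  v <- read_vcf(vcf)
  expect_equal(nrow(v), sum(lengths(strsplit(alts, ","))))
})
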