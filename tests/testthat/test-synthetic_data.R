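test_that("simulation is fully deterministic under one master seed", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_all(small_sim_config(seed = 5), out_dir = d1)
  s2 <- simulate_all(small_sim_config(seed = 5), out_dir = d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     info = nm)
  }
  s3 <- simulate_all(small_sim_config(seed = 6))
  expect_false(identical(s1$variants, s3$variants))
})

test_that("reference has the configured shape and near-uniform composition", {
  cfg <- small_sim_config()
  ref <- simulate_reference(cfg)
  expect_length(ref$seq, cfg$n_chrom)
  expect_true(all(ref$lengths == cfg$chrom_length))
  counts <- table(strsplit(ref$seq[[1]], NULL)[[1]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  # binomial 3-sigma bound around 1/4
  n <- cfg$chrom_length
  bound <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < bound))
})

test_that("gene placement is non-overlapping with CDS inside spans", {
  cfg <- small_sim_config()
  ref <- simulate_reference(cfg)
  genes <- simulate_gene_models(cfg, ref)
  expect_equal(nrow(genes), cfg$n_genes)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
  }
  for (i in seq_len(nrow(genes))) {
    segs <- genes$cds[[i]]
    expect_true(all(segs[, 1] >= genes$start[i] & segs[, 2] <= genes$end[i]))
    expect_equal(sum(segs[, 2] - segs[, 1] + 1) %% 3, 0)
  }
  expect_true(all(genes$length == genes$end - genes$start + 1))
})

test_that("manifest sites appear in the variant table with stated genotypes", {
  sim <- simulate_all(small_sim_config(seed = 15))
  v <- sim$variants
  vkey <- variant_key(v)
  man <- sim$manifest
  mkey <- paste(man$chrom, man$pos, man$ref, man$alt, sep = ":")
  expect_true(all(mkey %in% vkey))
  m <- match(mkey, vkey)
  # donor is hom_ref at every somatic site, het at germline sites
  somatic <- man$class != "germline"
  expect_true(all(v$gt_Donor[m[somatic]] == "hom_ref"))
  expect_true(all(v$gt_Donor[m[!somatic]] == "het"))
  # shared and lowdepth sites are het in both clones
  both <- man$class %in% c("shared", "lowdepth")
  expect_true(all(v$gt_NT2[m[both]] == "het"))
  expect_true(all(v$gt_NT4[m[both]] == "het"))
  # private sites are het only in their clone
  p2 <- man$class == "private:NT2"
  expect_true(all(v$gt_NT2[m[p2]] == "het"))
  expect_true(all(v$gt_NT4[m[p2]] == "hom_ref"))
  # depth guarantees: passing sites at or above the floor, decoys below
  cfg <- sim$config
  pass <- man$class %in% c("shared", "private:NT2", "private:NT4")
  expect_true(all(v$dp_NT2[m[man$class == "shared"]] >= cfg$depth_pass_floor))
  expect_true(all(v$dp_NT2[m[man$class == "lowdepth"]] <= cfg$lowdepth_ceiling))
  expect_true(all(v$dp_NT4[m[man$class == "lowdepth"]] <= cfg$lowdepth_ceiling))
  # no unplanted clone-specific het exists
  spec2 <- clone_specific_hets(v, "Donor", "NT2")
  expect_true(all(variant_key(spec2) %in% mkey[somatic]))
})

test_that("planted channels follow the configured signature", {
  cfg <- simulation_config(seed = 23, n_chrom = 2L, chrom_length = 100000L,
                           n_genes = 0L, n_germline_het = 0L,
                           n_somatic_shared = 1500L, n_somatic_private = 0L,
                           n_somatic_lowdepth = 0L, aging_list_size = 0L,
                           signature = "uv_ct")
  sim <- simulate_all(cfg)
  man <- sim$manifest
  emp <- table(factor(man$channel, levels = sbs_channels())) / nrow(man)
  sig <- attr(man, "planted_signature")
  expect_gte(cosine_similarity(as.numeric(emp), as.numeric(sig)), 0.95)
  # every planted channel agrees with the genome context at its site
  pick <- sample(nrow(man), 50)
  for (i in pick) {
    expect_equal(sbs_channel(man$chrom[i], man$pos[i], man$ref[i], man$alt[i],
                             sim$reference), man$channel[i])
  }
})

test_that("panel construction exercises absent, rare and high-missing sites", {
  sim <- simulate_all(small_sim_config(seed = 33))
  panel <- sim$panel
  man <- sim$manifest
  shared_keys <- manifest_keys(man, "shared")
  in_panel <- shared_keys %in% panel$key
  cfg <- sim$config
  # exactly the configured colliders are present
  expect_equal(sum(in_panel),
               cfg$n_panel_rare_colliders + cfg$n_panel_missing_colliders)
  coll <- panel[panel$key %in% shared_keys, ]
  expect_equal(sum(coll$af < 0.01), cfg$n_panel_rare_colliders)
  expect_equal(sum(coll$missing_rate > 0.10), cfg$n_panel_missing_colliders)
  expect_true(all(panel$af >= 0 & panel$af <= 1))
  expect_true(all(panel$missing_rate >= 0 & panel$missing_rate <= 1))
  # and the cascade annotates them as designed
  cand <- run_filter_cascade(sim$variants, "Donor", c("NT2", "NT4"), panel)
  miss_keys <- coll$key[coll$missing_rate > 0.10]
  ckey <- variant_key(cand$sites)
  expect_true(all(is.na(cand$sites$population_af[ckey %in% miss_keys])))
  absent <- !(ckey %in% panel$key)
  expect_true(all(cand$sites$population_af[absent] == 0))
  expect_true(all(cand$sites$rare[absent]))
})

test_that("aging list is enriched for mutation-bearing genes at high odds", {
  cfg <- small_sim_config(seed = 43, aging_enrichment_odds = 8)
  sim <- simulate_all(cfg)
  man <- sim$manifest
  mut_genes <- unique(stats::na.omit(man$gene_id[man$class == "shared"]))
  mut_symbols <- sim$genes$symbol[sim$genes$gene_id %in% mut_genes]
  aging <- sim$gene_sets$aging_genes
  in_share <- mean(mut_symbols %in% aging)
  out_share <- mean(setdiff(sim$genes$symbol, mut_symbols) %in% aging)
  expect_gt(in_share, out_share)
  # null odds leave membership roughly independent on average over seeds
  stats_null <- vapply(1:10, function(s) {
    sm <- simulate_all(small_sim_config(seed = 100 + s,
                                        aging_enrichment_odds = 1))
    mg <- unique(stats::na.omit(sm$manifest$gene_id[sm$manifest$class == "shared"]))
    ms <- sm$genes$symbol[sm$genes$gene_id %in% mg]
    aging_enrichment(ms, sm$gene_sets$aging_genes,
                     sm$gene_sets$background)$test$statistic
  }, numeric(1))
  expect_lt(stats::median(stats_null), 3.85)  # chi-sq_0.95 at df 1
})

test_that("set files round-trip through the readers", {
  d <- tempfile()
  sim <- simulate_all(small_sim_config(seed = 53), out_dir = d)
  aging <- read_gene_list(sim$paths$aging_genes)
  expect_setequal(aging, sim$gene_sets$aging_genes)
  sets <- read_gene_sets(sim$paths$gene_sets)
  expect_equal(sets, sim$gene_sets$sets)
  panel <- read_population_panel(sim$paths$panel)
  expect_setequal(panel$key, sim$panel$key)
  m <- match(sim$panel$key, panel$key)
  expect_equal(panel$af[m], sim$panel$af)
})
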