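test_that("generated genomes contain the planned architecture", {
  spec <- synthetic_spec(seed = 42)
  out <- generate_genome(spec)
  g <- out$genome
  types <- vapply(g$features, `[[`, "", "ftype")
  nms <- vapply(g$features, `[[`, "", "name")
  ## 15 PCGs + 2 rRNAs + 25 tRNAs named non-intron features
  expect_equal(sum(types %in% c("PCG", "rRNA", "tRNA")), 42L)
  expect_equal(sum(types == "PCG"), 15L)
  expect_equal(sum(types == "tRNA"), 25L)
  expect_equal(sum(nms == "trnM"), 3L)
  expect_equal(sum(types == "intron"), nrow(spec$intron_plan))
  expect_equal(genome_length(g), spec$genome_length_target)

  ## every PCG starts ATG (or planned alternative) and ends TAA/TAG with
  ## no internal stop under code 4
  for (gene in spec$core_pcgs) {
    cds <- coding_sequence(g, gene)
    expect_true(substr(cds, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG"))
    expect_silent(translate_cds(cds))
  }
})

test_that("the planted nad4L/nad5 overlap is exactly one shared base", {
  g <- generate_genome(synthetic_spec(seed = 5))$genome
  nms <- vapply(g$features, `[[`, "", "name")
  f4L <- g$features[[which(nms == "nad4L")]]
  f5 <- g$features[[which(nms == "nad5")]]
  expect_equal(max(f4L$intervals$end), min(f5$intervals$start))
  ## both genes still translate despite sharing a base
  expect_silent(translate_cds(coding_sequence(g, "nad4L")))
  expect_silent(translate_cds(coding_sequence(g, "nad5")))
})

test_that("generation is byte-identical for a fixed seed", {
  a <- generate_genome(synthetic_spec(seed = 9))
  b <- generate_genome(synthetic_spec(seed = 9))
  expect_identical(a$genome, b$genome)
  expect_identical(a$ground_truth$feature_table, b$ground_truth$feature_table)
  c <- generate_genome(synthetic_spec(seed = 10))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("planted start codons are honored", {
  spec <- small_spec(3)
  spec$start_codons <- c(cob = "TTG", nad5 = "GTG")
  g <- generate_genome(spec)$genome
  ss <- start_stop_codons(g)
  expect_equal(ss$start_codon[ss$gene == "cob"], "TTG")
  expect_equal(ss$start_codon[ss$gene == "nad5"], "GTG")
  expect_true(all(ss$start_ok))
  expect_true(all(ss$stop_ok))
})

test_that("re-extraction reproduces planted structures exactly", {
  out <- generate_genome(small_spec(11))
  g <- out$genome
  ## planted intron table consistent with annotation-derived positions
  ip <- intron_positions(g, "cox1")
  expect_equal(ip$position, c(210L, 450L))
  expect_equal(ip$group, c("I", "II"))
  ## planted region lengths equal the partition exactly
  part <- partition_regions(g)
  expect_equal(part$lengths, out$ground_truth$region_lengths)
})

test_that("zero-rate divergence with empty plans is the identity", {
  out <- generate_genome(small_spec(21))
  spec0 <- small_spec(21)
  spec0$divergence <- c(ts = 0, tv = 0, indel = 0)
  d <- diverge(out$genome, spec0, id = out$genome$id)
  expect_identical(d$genome$sequence, out$genome$sequence)
  expect_identical(d$genome$features, out$genome$features)
})

test_that("divergence preserves translatability and counts events", {
  out <- generate_genome(small_spec(8))
  spec <- small_spec(8)
  spec$divergence <- c(ts = 0.03, tv = 0.015, indel = 0.001)
  d <- diverge(out$genome, spec, id = "sister")
  for (gene in spec$core_pcgs)
    expect_silent(translate_cds(coding_sequence(d$genome, gene)))
  gt <- d$ground_truth
  expect_gt(gt$n_transitions, 0)
  expect_gt(gt$n_transversions, 0)
  ## event record matches the realized sequence difference at
  ## substitution sites (indel-free comparison requires indel-free run)
  spec2 <- spec; spec2$divergence <- c(ts = 0.03, tv = 0.015, indel = 0)
  d2 <- diverge(out$genome, spec2, id = "s2")
  a <- strsplit(out$genome$sequence, "")[[1]]
  b <- strsplit(d2$genome$sequence, "")[[1]]
  diff_pos <- which(a != b)
  expect_setequal(diff_pos, d2$ground_truth$substitutions$genome_pos)
})

test_that("a duplication plan adds one more copy of the tRNA", {
  out <- generate_genome(small_spec(13))
  spec <- small_spec(13)
  spec$divergence <- c(ts = 0, tv = 0, indel = 0)
  spec$rearrangements <- list(list(type = "duplicate", gene = "trnM",
                                   after = "cob"))
  d <- diverge(out$genome, spec, id = "dup")
  n_before <- sum(vapply(out$genome$features, `[[`, "", "name") == "trnM")
  n_after <- sum(vapply(d$genome$features, `[[`, "", "name") == "trnM")
  expect_equal(n_after, n_before + 1L)
})

test_that("transition counts follow the planted rate (binomial check)", {
  ## neutral region: the rns gene is unconstrained under divergence
  spec <- small_spec(17)
  spec$rrnas <- c(rns = 1000L, rnl = 700L)
  out <- generate_genome(spec)
  spec$divergence <- c(ts = 0.05, tv = 0, indel = 0)
  d <- diverge(out$genome, spec, id = "neutral")
  nms <- vapply(out$genome$features, `[[`, "", "name")
  rns <- out$genome$features[[which(nms == "rns")]]
  span <- seq(min(rns$intervals$start), max(rns$intervals$end))
  n_ts <- sum(d$ground_truth$substitutions$genome_pos %in% span)
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.05)
  expect_gte(n_ts, ci[1])
  expect_lte(n_ts, ci[2])
})
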