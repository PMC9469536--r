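## a fixed 72-nt cloverleaf layout shared by the hand-made tRNA tests
trna_layout <- function() {
  paste0(strrep("A", 7), strrep("L", 2), strrep("D", 16), "L",
         strrep("C", 17), strrep("V", 5), strrep("T", 17), strrep("A", 7),
         "L")
}

test_that("variable sites are counted per column and attributed to arms", {
  struct <- trna_layout()
  set.seed(14)
  a <- paste(sample(c("A", "C", "G", "T"), nchar(struct), TRUE),
             collapse = "")
  expect_equal(compare_trnas(a, a, struct)$n_variable, 0L)

  ## one substitution planted in the D arm (position 12)
  b <- a
  substr(b, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 12, 12))[1]
  cmp <- compare_trnas(a, b, struct)
  expect_equal(cmp$n_variable, 1L)
  expect_equal(as.integer(cmp$by_region[["D arm"]]), 1L)

  ## a 1-nt insertion in the extra arm counts there (indel column)
  vpos <- 7 + 2 + 16 + 1 + 17 + 3  # inside the V region
  b2 <- paste0(substr(a, 1, vpos), "A", substr(a, vpos + 1, nchar(a)))
  cmp2 <- compare_trnas(a, b2, struct)
  expect_equal(cmp2$n_variable, 1L)
  expect_equal(as.integer(cmp2$by_region[["extra arm"]]), 1L)
  ## and is ignored when indels are not counted
  expect_equal(compare_trnas(a, b2, struct, count_indels = FALSE)$n_variable,
               0L)

  ## region totals always sum to the overall count
  expect_equal(sum(cmp$by_region), cmp$n_variable)
  expect_error(compare_trnas(a, b, substr(struct, 1, 10)),
               "does not match")
})

test_that("substitution counts are symmetric between the two genomes", {
  struct <- trna_layout()
  set.seed(15)
  a <- paste(sample(c("A", "C", "G", "T"), nchar(struct), TRUE),
             collapse = "")
  b <- a
  for (p in c(3, 30, 55)) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  }
  expect_equal(compare_trnas(a, b, struct)$n_variable,
               compare_trnas(b, a, struct)$n_variable)
})

test_that("genome-level reports aggregate matched tRNA pairs", {
  out <- generate_genome(small_spec(61))
  g <- out$genome
  structs <- out$ground_truth$trna_structures
  ## identical genomes: zero everywhere
  g2 <- g; g2$id <- "twin"
  rep0 <- trna_set_report(g, g2, structs)
  expect_equal(rep0$total_variable_sites, 0)
  expect_equal(rep0$n_trnas_variable, 0L)

  ## diverged sister: counts conserved between region table and total
  sp <- small_spec(61)
  sp$divergence <- c(ts = 0.05, tv = 0.02, indel = 0)
  sis <- diverge(g, sp, id = "sis")$genome
  rep1 <- trna_set_report(g, sis, structs)
  expect_equal(sum(rep1$region_counts), rep1$total_variable_sites)
  expect_equal(sum(rep1$region_percent), 100, tolerance = 1e-9)
  expect_gt(rep1$total_variable_sites, 0)
})

test_that("planted per-arm variation reproduces the reported shares", {
  ## two genomes whose 25 tRNAs differ at 83 planted sites, 20 of them
  ## in the extra arm, touching 23 of the 25 tRNAs: extra-arm share
  ## 20/83 = 24.10%
  out <- generate_genome(synthetic_spec(seed = 83))
  g <- out$genome
  structs <- out$ground_truth$trna_structures
  types <- vapply(g$features, `[[`, "", "ftype")
  tr_idx <- which(types == "tRNA")
  tr_idx <- tr_idx[order(vapply(g$features[tr_idx], function(f)
    min(f$intervals$start), 1L))]
  stopifnot(length(tr_idx) == 25L, length(structs) == 25L)

  ## quotas over the first 23 tRNAs: 20 extra-arm sites (one each for
  ## tRNAs 1-20) and 63 sites in other arms (2 each + 1 extra for 1-17)
  n_extra <- c(rep(1, 20), rep(0, 3))
  n_other <- rep(2, 23) + c(rep(1, 17), rep(0, 6))
  stopifnot(sum(n_extra) == 20, sum(n_extra) + sum(n_other) == 83)

  flip <- c(A = "G", G = "A", C = "T", T = "C", N = "A")
  sq <- strsplit(g$sequence, "")[[1]]
  for (i in 1:23) {
    f <- g$features[[tr_idx[i]]]
    struct <- strsplit(structs[[i]], "")[[1]]
    ## genome position of each coding-strand column; flipping the genome
    ## base flips the coding base on either strand
    gpos <- if (f$strand == "+") seq(f$intervals$start, f$intervals$end)
            else rev(seq(f$intervals$start, f$intervals$end))
    ## pick well-separated interior columns so every planted change is an
    ## isolated substitution column in the pair alignment
    vc <- which(struct == "V")
    oc <- which(struct %in% c("A", "D", "C", "T"))
    oc <- oc[oc > 5 & oc < length(struct) - 5]
    cols <- c(vc[ceiling(length(vc) / 2)][seq_len(n_extra[i])],
              oc[round(seq(1, length(oc), length.out = n_other[i] + 2))][
                -c(1, n_other[i] + 2)])
    for (cp in cols) sq[gpos[cp]] <- flip[[sq[gpos[cp]]]]
  }
  sis <- g
  sis$id <- "planted"
  sis$sequence <- paste(sq, collapse = "")

  rep2 <- trna_set_report(g, sis, structs)
  expect_equal(rep2$total_variable_sites, 83)
  expect_equal(rep2$n_trnas_variable, 23L)
  expect_equal(unname(rep2$region_counts[["extra arm"]]), 20)
  expect_equal(sprintf("%.2f", rep2$region_percent[["extra arm"]]), "24.10")
})
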