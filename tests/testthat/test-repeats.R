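## helper: random sequence with planted duplications
plant_duplication <- function(n, len, seed, mismatches = 0L, invert = FALSE) {
  set.seed(seed)
  x <- sample(c("A", "C", "G", "T"), n, TRUE)
  unit <- sample(c("A", "C", "G", "T"), len, TRUE)
  p1 <- n %/% 4
  p2 <- 3 * (n %/% 4)
  copy <- unit
  if (mismatches > 0) {
    idx <- sample(len, mismatches)
    copy[idx] <- vapply(copy[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  if (invert)
    copy <- rev(c(A = "T", T = "A", C = "G", G = "C")[copy])
  x[p1:(p1 + len - 1)] <- unit
  x[p2:(p2 + len - 1)] <- copy
  list(seq = paste(x, collapse = ""), a = c(p1, p1 + len - 1),
       b = c(p2, p2 + len - 1))
}

covers <- function(hits, iv_a, iv_b, min_frac = 0.9) {
  if (is.null(hits) || !nrow(hits)) return(FALSE)
  ov <- function(s1, e1, s2, e2)
    pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1) / (e2 - s2 + 1)
  any(ov(hits$start_a, hits$end_a, iv_a[1], iv_a[2]) >= min_frac &
        ov(hits$start_b, hits$end_b, iv_b[1], iv_b[2]) >= min_frac)
}

test_that("planted duplications are recovered with correct identity", {
  p <- plant_duplication(10000, 80, seed = 3)
  h <- find_interspersed_repeats(p$seq)
  expect_true(covers(h, p$a, p$b, min_frac = 1))
  ## exact mode reports the duplication at 100% identity
  h100 <- find_interspersed_repeats(p$seq, min_identity = 100)
  exact <- h100[h100$identity == 100, ]
  expect_gte(max(exact$length), 80)

  ## 60-bp duplication with 3 mismatches: identity near 57/60
  p2 <- plant_duplication(10000, 60, seed = 4, mismatches = 3)
  h2 <- find_interspersed_repeats(p2$seq)
  expect_true(covers(h2, p2$a, p2$b))
  best <- h2[which.max(h2$length), ]
  expect_lt(best$identity, 100)
  expect_gte(best$identity, 90)

  ## inverted duplication reported on the minus strand
  p3 <- plant_duplication(10000, 70, seed = 5, invert = TRUE)
  h3 <- find_interspersed_repeats(p3$seq)
  expect_true(covers(h3, p3$a, p3$b))
  expect_true(any(h3$strand == "-"))
})

test_that("exact mode coincides with the exhaustive diagonal oracle", {
  for (seed in c(21, 22, 23)) {
    p <- plant_duplication(1500, sample(50:110, 1), seed = seed)
    h <- find_interspersed_repeats(p$seq, min_len = 50, min_identity = 100)
    orc <- oracle_exact_repeats(p$seq, min_len = 50)
    expect_identical(hit_keys(h), hit_keys(orc))
  }
  ## sequence with no >= 50-bp duplication: both empty
  set.seed(99)
  clean <- paste(sample(c("A", "C", "G", "T"), 1800, TRUE), collapse = "")
  expect_identical(hit_keys(find_interspersed_repeats(clean,
                                                      min_identity = 100)),
                   hit_keys(oracle_exact_repeats(clean, 50)))
})

test_that("hit sets are strand-symmetric and deterministic", {
  p <- plant_duplication(4000, 90, seed = 31, invert = TRUE)
  h1 <- find_interspersed_repeats(p$seq)
  h2 <- find_interspersed_repeats(p$seq)
  expect_identical(h1, h2)
  ## reverse-complementing the genome maps hits accordingly
  n <- nchar(p$seq)
  hr <- find_interspersed_repeats(revcomp(p$seq))
  map_iv <- function(s, e) c(n - e + 1, n - s + 1)
  keys_fwd <- hit_keys(h1)
  mapped <- do.call(rbind, lapply(seq_len(nrow(hr)), function(i) {
    a <- map_iv(hr$start_a[i], hr$end_a[i])
    b <- map_iv(hr$start_b[i], hr$end_b[i])
    if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
    data.frame(start_a = a[1], end_a = a[2], start_b = b[1], end_b = b[2],
               strand = hr$strand[i])
  }))
  expect_identical(sort(hit_keys(mapped)), sort(keys_fwd))
})

test_that("repeat fractions are unions of covered intervals", {
  h <- data.frame(start_a = 101, end_a = 200, start_b = 5101, end_b = 5200)
  expect_equal(repeat_fraction(h, 10000), 2)
  ## overlapping hits counted once
  h2 <- rbind(h, data.frame(start_a = 151, end_a = 250, start_b = 5101,
                            end_b = 5200))
  expect_equal(repeat_fraction(h2, 10000), 2.5)
  expect_equal(repeat_fraction(h[0, ], 10000), 0)
})

test_that("tandem arrays are found with period, copies and span", {
  set.seed(8)
  flank1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  s <- paste0(flank1, strrep("ACGT", 12), flank2)
  tr <- find_tandem_repeats(s)
  hit <- tr[tr$period == 4, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copies, 12, tolerance = 0.3)
  expect_gte(hit$span, 44)
  expect_equal(hit$consensus, "ACGT")

  ## a 24-bp unit x 2 copies spans 48 bp
  set.seed(9)
  unit <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
  s2 <- paste0(flank1, strrep(unit, 2), flank2)
  tr2 <- find_tandem_repeats(s2)
  hit2 <- tr2[tr2$period == 24, ]
  expect_equal(nrow(hit2), 1L)
  ## the 48-bp planted array is reported (chance matches in the flank may
  ## extend the maximal run by a base or two)
  expect_gte(hit2$span, 48)
  expect_lte(hit2$span, 52)
  expect_lte(hit2$start, 401)
  expect_gte(hit2$end, 448)
})

test_that("shared fragments between genomes are found and totalled", {
  set.seed(12)
  mito <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  nuc_bg <- paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")
  ## copy a 500-bp mito segment into the nuclear contig
  frag <- substr(mito, 1001, 1500)
  nuc <- paste0(substr(nuc_bg, 1, 3000), frag, substr(nuc_bg, 3501, 8000))
  sf <- find_shared_fragments(mito, list(nuc1 = nuc))
  expect_gte(nrow(sf), 1L)
  best <- sf[which.max(sf$length), ]
  expect_gte(best$length, 500 * 0.95)
  expect_gte(attr(sf, "total_bp"), 475)

  ## no shared k-mers: empty
  sf0 <- find_shared_fragments(strrep("A", 500), list(strrep("C", 500)))
  expect_equal(nrow(sf0), 0L)
  expect_equal(attr(sf0, "total_bp"), 0L)

  ## two planted fragments: total = sum of lengths
  frag2 <- substr(mito, 4001, 4300)
  nuc2 <- paste0(substr(nuc_bg, 1, 2000), frag,
                 substr(nuc_bg, 2501, 5000), frag2,
                 substr(nuc_bg, 5301, 8000))
  sf2 <- find_shared_fragments(mito, list(nuc2))
  expect_gte(nrow(sf2), 2L)
  expect_gte(attr(sf2, "total_bp"), (500 + 300) * 0.95)
})

test_that("synthetic planted repeats are recovered end to end", {
  out <- generate_genome(synthetic_spec(seed = 77))
  g <- out$genome
  gt <- out$ground_truth$repeats
  h <- find_interspersed_repeats(g)
  for (rid in unique(gt$repeat_id)) {
    cps <- gt[gt$repeat_id == rid, ]
    a <- unlist(cps[1, c("start", "end")])
    b <- unlist(cps[2, c("start", "end")])
    if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
    expect_true(covers(h, a, b), label = paste("repeat", rid))
  }
})
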