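test_that("global alignment is optimal under the stated scoring", {
  a <- align_pair("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$a, "ACGT")
  expect_equal(a$b, "ACGT")

  a2 <- align_pair("ACGT", "ACT")
  expect_equal(a2$score, 1)  # 3 matches - one 1-bp gap (open only)
  expect_equal(gsub("-", "", a2$b), "ACT")
  expect_equal(nchar(a2$a), nchar(a2$b))

  a3 <- align_pair("A", "T")
  expect_equal(a3$score, -1)
  expect_equal(a3$a, "A")
  expect_equal(a3$b, "T")

  ## brute-force optimality on random short pairs
  set.seed(1)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), TRUE),
               collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), TRUE),
               collapse = "")
    expect_equal(align_pair(x, y)$score, oracle_align_score(x, y),
                 info = paste(x, y))
  }
})

test_that("K2P distance matches its closed form and flags saturation", {
  x <- strrep("A", 100)
  expect_equal(k2p(as_alignment(x, x))$d, 0)

  ## 10 transitions among 100 sites, no transversions
  a <- paste0(strrep("A", 90), strrep("A", 10))
  b <- paste0(strrep("A", 90), strrep("G", 10))
  r <- k2p(as_alignment(a, b))
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8), tolerance = 1e-12)
  ## Q = 0 reduces to d = -1/2 ln(1 - 2P)
  expect_equal(r$d, -0.5 * log(1 - 2 * r$P), tolerance = 1e-12)

  ## P = Q = 0.25 is finite; P = 0.4, Q = 0.2 saturates
  mk <- function(nts, ntv, n) {
    a <- rep("A", n); b <- rep("A", n)
    if (nts > 0) b[seq_len(nts)] <- "G"
    if (ntv > 0) b[nts + seq_len(ntv)] <- "C"
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  }
  p <- mk(25, 25, 100)
  expect_true(k2p(as_alignment(p$a, p$b))$defined)
  q <- mk(40, 20, 100)
  expect_false(k2p(as_alignment(q$a, q$b))$defined)

  ## gap and N columns are excluded from sites_used
  r2 <- k2p(as_alignment("ACG-N", "ACGTA"))
  expect_equal(r2$sites_used, 3L)

  ## agreement with an established K80 implementation
  set.seed(7)
  s1 <- paste(sample(c("A","C","G","T"), 300, TRUE), collapse = "")
  v <- strsplit(s1, "")[[1]]
  idx <- sample(300, 30)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A","C","G","T"), b), 1), "")
  s2 <- paste(v, collapse = "")
  mine <- k2p(as_alignment(s1, s2))$d
  bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(s1), "")[[1]],
                              b = strsplit(tolower(s2), "")[[1]]))
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("NG86 classifies simple codon pairs as the code dictates", {
  ident <- nei_gojobori(as_alignment("ATGAAATAA", "ATGAAATAA"))
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_false(ident$ratio_defined)

  ## TTT <-> TTC is synonymous (Phe) under code 4
  r <- nei_gojobori(as_alignment("TTT", "TTC"))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)

  ## site counts sum to 3 x codons when no stop-adjacent exclusions
  r2 <- nei_gojobori(as_alignment("ATGAAACCC", "ATGAAACCC"))
  expect_equal(r2$N + r2$S, 9, tolerance = 1e-9)

  expect_error(nei_gojobori(as_alignment("ATGTAACCC", "ATGTAACCC")),
               "internal stop")
})

test_that("NG86 equals the exhaustive-pathway oracle on random codon pairs", {
  code <- genetic_code_4()
  sense <- names(code$map)[code$map != "*"]
  set.seed(11)
  for (i in 1:60) {
    n_codons <- sample(2:30, 1)
    c1 <- sample(sense, n_codons, TRUE)
    c2 <- c1
    ## mutate a few codons, keeping sense
    for (j in sample(n_codons, max(1, n_codons %/% 3))) {
      c2[j] <- sample(sense, 1)
    }
    s1 <- paste(c1, collapse = ""); s2 <- paste(c2, collapse = "")
    mine <- nei_gojobori(as_alignment(s1, s2))
    orc <- oracle_ng86(s1, s2, code$map)
    expect_equal(mine$N, orc$N, tolerance = 1e-9, info = i)
    expect_equal(mine$S, orc$S, tolerance = 1e-9, info = i)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-9, info = i)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-9, info = i)
  }
})

test_that("per-gene statistics rank genes by planted divergence", {
  out <- generate_genome(small_spec(23, n_pcgs = 3))
  g <- out$genome
  ## two identical genomes: all distances zero
  g2 <- g; g2$id <- "copy"
  st0 <- per_gene_stats(list(g, g2), genes = c("cox1", "cob", "nad5"))
  expect_true(all(st0$mean_k2p == 0))

  ## substitutions planted only in one gene dominate its K2P
  spec <- small_spec(23, n_pcgs = 3)
  spec$divergence <- c(ts = 0, tv = 0, indel = 0)
  sis <- diverge(g, spec, id = "sis")$genome
  cds <- coding_sequence(g, "cob")
  v <- strsplit(cds, "")[[1]]
  set.seed(2)
  tsmap <- c(A = "G", G = "A", C = "T", T = "C")
  stops <- c("TAA", "TAG")
  applied <- 0
  for (p in sample(seq(4, length(v) - 3))) {
    if (applied >= 40) break
    old <- v[p]
    v[p] <- tsmap[[old]]
    ci <- (p - 1) %/% 3
    codon <- paste(v[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (codon %in% stops) v[p] <- old else applied <- applied + 1
  }
  mut <- paste(v, collapse = "")
  expect_silent(translate_cds(mut))
  nms <- vapply(sis$features, `[[`, "", "name")
  fcob <- sis$features[[which(nms == "cob")]]
  sq <- strsplit(sis$sequence, "")[[1]]
  sq[fcob$intervals$start[1]:fcob$intervals$end[1]] <-
    strsplit(mut, "")[[1]][1:(fcob$intervals$end[1] -
                                fcob$intervals$start[1] + 1)]
  sis$sequence <- paste(sq, collapse = "")
  st <- per_gene_stats(list(g, sis), genes = c("cox1", "cob", "nad5"))
  expect_equal(st$gene[which.max(st$mean_k2p)], "cob")
  expect_true(all(st$mean_k2p[st$gene != "cob"] == 0))
})

test_that("purifying regimes give Ka/Ks below one", {
  ## all planted changes synonymous: third-position TTT -> TTC style
  c1 <- rep("TTT", 30)
  c2 <- c1
  c2[c(2, 9, 16, 23, 30)] <- "TTC"
  r <- nei_gojobori(as_alignment(paste(c1, collapse = ""),
                                 paste(c2, collapse = "")))
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$ratio, 0)
  expect_lt(r$ratio, 1)
})

test_that("neighbor joining matches closed forms and recovers topologies", {
  ## 3-taxon closed form
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(sort(unname(bl)), c(1, 1, 3))

  ## zero matrix: all branch lengths zero
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(D0)$edge.length == 0))

  ## undefined distances are an error naming the pair
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- NA
  expect_error(nj_tree(Dn), "a/b")

  ## random additive trees (n <= 8) are recovered exactly
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    Dt <- cophenetic(true)
    Dt <- Dt[sort(rownames(Dt)), sort(colnames(Dt))]
    mine <- nj_tree(Dt)
    expect_equal(phangorn::RF.dist(mine, true), 0, info = i)
    ## ape's NJ agrees on the topology (independent implementation)
    expect_equal(phangorn::RF.dist(mine, ape::nj(Dt)), 0, info = i)
  }
})

test_that("k2p parameter recovery on simulated neutral divergence", {
  ## mean K2P over replicates within 3 SE of the simulated expectation
  ts <- 0.04; tv <- 0.02
  expd <- -0.5 * log((1 - 2 * ts - tv) * sqrt(1 - 2 * tv))
  spec <- small_spec(1)
  base <- generate_genome(spec)
  d_hat <- vapply(1:30, function(r) {
    sp <- spec
    sp$seed <- 1000L + r
    sp$divergence <- c(ts = ts, tv = tv, indel = 0)
    sis <- diverge(base$genome, sp, id = "r")$genome
    k2p(as_alignment(coding_sequence(base$genome, "rns"),
                     coding_sequence(sis, "rns")))$d
  }, 1)
  se <- sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - expd), 3 * se + 1e-12)
})
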