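## Independent oracles used to validate the package's implementations.
## These deliberately use brute-force enumeration rather than the
## package's own code paths.

## ---- exhaustive global alignment score (tiny sequences) -------------
## Enumerates every global alignment by recursion and returns the best
## score under the convention: gap run of length L costs
## open + ext * (L - 1).
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = -2, ext = -0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      g <- if (state == "ga") ext else open
      best <- max(best, g + rec(i + 1, j, "ga"))
    }
    if (j <= length(bv)) {
      g <- if (state == "gb") ext else open
      best <- max(best, g + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

## ---- NG86 by explicit enumeration -----------------------------------
## Independent implementation: explicit loops, explicit permutation
## tables, no shared helpers with the package.
oracle_ng86 <- function(cds1, cds2, code_map) {
  stops <- names(code_map)[code_map == "*"]
  bases <- c("A", "C", "G", "T")
  codons1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  codons2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  site_count <- function(codon) {
    aa <- code_map[[codon]]
    syn <- 0
    nsy <- 0
    for (p in 1:3) {
      muts <- character(0)
      for (b in bases) {
        if (b == substr(codon, p, p)) next
        m <- codon
        substr(m, p, p) <- b
        if (!(m %in% stops)) muts <- c(muts, m)
      }
      if (!length(muts)) next
      fs <- mean(code_map[muts] == aa)
      syn <- syn + fs
      nsy <- nsy + (1 - fs)
    }
    c(syn, nsy)
  }
  all_orders <- function(pos) {
    if (length(pos) == 1) return(list(pos))
    if (length(pos) == 2) return(list(pos, pos[2:1]))
    out <- list()
    for (i in seq_along(pos))
      for (rest in all_orders(pos[-i]))
        out[[length(out) + 1]] <- c(pos[i], rest)
    out
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons1)) {
    c1 <- codons1[k]; c2 <- codons2[k]
    sc1 <- site_count(c1); sc2 <- site_count(c2)
    S <- S + (sc1[1] + sc2[1]) / 2
    N <- N + (sc1[2] + sc2[2]) / 2
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) next
    paths <- all_orders(pos)
    ok <- list(); blocked <- list()
    for (ord in paths) {
      cur <- c1
      steps <- c(0, 0)  # syn, nonsyn
      through_stop <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops) through_stop <- TRUE
        if (code_map[[cur]] == code_map[[nxt]]) steps[1] <- steps[1] + 1
        else steps[2] <- steps[2] + 1
        cur <- nxt
      }
      if (through_stop) blocked[[length(blocked) + 1]] <- steps
      else ok[[length(ok) + 1]] <- steps
    }
    use <- if (length(ok)) ok else blocked
    m <- do.call(rbind, use)
    Sd <- Sd + mean(m[, 1])
    Nd <- Nd + mean(m[, 2])
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd)
}

## ---- exhaustive exact-repeat scan (small sequences) -----------------
## All maximal exact repeated segment pairs >= min_len found by scanning
## every diagonal of the self-comparison matrix (and of the comparison
## against the reverse complement), independent of k-mer seeding.
oracle_exact_repeats <- function(seq, min_len) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  rc <- rev(c(A = "T", T = "A", C = "G", G = "C", N = "N")[x])
  hits <- NULL
  ## same strand: diagonals d >= 1, positions i vs i + d
  for (d in seq_len(n - 1)) {
    if (n - d < min_len) break
    eq <- x[1:(n - d)] == x[(1 + d):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (ri in which(r$values & r$lengths >= min_len)) {
      s <- ends[ri] - r$lengths[ri] + 1
      hits <- rbind(hits, data.frame(
        start_a = s, end_a = ends[ri], start_b = s + d, end_b = ends[ri] + d,
        strand = "+", length = r$lengths[ri]))
    }
  }
  ## opposite strand: x vs reverse complement, all diagonals
  for (t in (-(n - 1)):(n - 1)) {
    ia <- max(1, 1 - t); ib <- ia + t
    len <- min(n - ia, n - ib) + 1
    if (len < min_len) next
    eq <- x[ia:(ia + len - 1)] == rc[ib:(ib + len - 1)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (ri in which(r$values & r$lengths >= min_len)) {
      s_off <- ends[ri] - r$lengths[ri] + 1
      sa <- ia + s_off - 1; ea <- ia + ends[ri] - 1
      sbr <- ib + s_off - 1; ebr <- ib + ends[ri] - 1
      ## map reverse-complement coordinates back to the forward strand
      sb <- n - ebr + 1; eb <- n - sbr + 1
      if (sa == sb && ea == eb) next  # palindromic self-hit
      if (sb < sa) {
        tmp <- c(sa, ea); sa <- sb; ea <- eb; sb <- tmp[1]; eb <- tmp[2]
      }
      hits <- rbind(hits, data.frame(
        start_a = sa, end_a = ea, start_b = sb, end_b = eb,
        strand = "-", length = r$lengths[ri]))
    }
  }
  if (is.null(hits)) return(hits)
  hits <- hits[!duplicated(hits[, c("start_a", "end_a", "start_b", "end_b",
                                    "strand")]), , drop = FALSE]
  hits[order(hits$start_a, hits$start_b), , drop = FALSE]
}

## canonical key set for comparing repeat hit tables
hit_keys <- function(h) {
  if (is.null(h) || !nrow(h)) return(character(0))
  sort(sprintf("%d:%d:%d:%d:%s", h$start_a, h$end_a, h$start_b, h$end_b,
               h$strand))
}
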