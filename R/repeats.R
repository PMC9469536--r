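## Repeat analysis: interspersed repeats by genome self-comparison with a
## seed-and-extend matcher (exact k-mer seeds on both strands, ungapped
## X-drop extension), a simplified tandem-repeat detector, and the same
## seed-and-extend engine applied across genomes to find shared
## (NUMT-like) fragments.

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## ungapped extension around a seed [ia, ia+k-1] / [ib, ib+k-1] of
## sequences xa, xb (character vectors). Exact mode stops at the first
## mismatch; otherwise X-drop keeps the best-scoring endpoints
## (match +1 / mismatch -1, abandoning when the running score falls
## `xdrop` below the maximum).
extend_seed <- function(xa, xb, ia, ib, k, exact, xdrop = 20L) {
  na <- length(xa); nb <- length(xb)
  ## right extension from the seed end
  ra <- ia + k - 1L; rb <- ib + k - 1L
  score <- 0; best <- 0; best_r <- 0L
  step <- 0L
  while (ra + step < na && rb + step < nb) {
    step <- step + 1L
    hit <- xa[ra + step] == xb[rb + step]
    if (exact && !hit) break
    score <- score + if (hit) 1 else -1
    if (score > best) { best <- score; best_r <- step }
    if (!exact && score < best - xdrop) break
    if (exact) best_r <- step
  }
  ## left extension from the seed start
  score <- 0; best <- 0; best_l <- 0L
  step <- 0L
  while (ia - step > 1L && ib - step > 1L) {
    step <- step + 1L
    hit <- xa[ia - step] == xb[ib - step]
    if (exact && !hit) break
    score <- score + if (hit) 1 else -1
    if (score > best) { best <- score; best_l <- step }
    if (!exact && score < best - xdrop) break
    if (exact) best_l <- step
  }
  sa <- ia - best_l; ea <- ia + k - 1L + best_r
  sb <- ib - best_l; eb <- ib + k - 1L + best_r
  len <- ea - sa + 1L
  matches <- sum(xa[sa:ea] == xb[sb:eb])
  list(start_a = sa, end_a = ea, start_b = sb, end_b = eb,
       length = len, identity = 100 * matches / len)
}

## candidate seed pairs from shared k-mers of two sequences (or one
## sequence against itself when self = TRUE, in which case only pairs
## with posA < posB are kept)
seed_pairs <- function(seq_a, seq_b, k, self = FALSE) {
  ka <- kmer_starts(seq_a, k)
  kb <- kmer_starts(seq_b, k)
  ia <- split(seq_along(ka), ka)
  ib <- if (self) ia else split(seq_along(kb), kb)
  shared <- if (self) names(ia)[lengths(ia) > 1L]
            else intersect(names(ia), names(ib))
  if (!length(shared)) return(matrix(integer(0), ncol = 2L))
  out <- lapply(shared, function(km) {
    pa <- ia[[km]]; pb <- ib[[km]]
    grid <- expand.grid(a = pa, b = pb)
    if (self) grid <- grid[grid$a < grid$b, , drop = FALSE]
    as.matrix(grid)
  })
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

## core seed-and-extend over a pair of plain sequences; returns merged
## maximal ungapped hits
seed_extend_hits <- function(seq_a, seq_b, k, min_len, min_identity,
                             self = FALSE) {
  exact <- min_identity >= 100
  pairs <- seed_pairs(seq_a, seq_b, k, self = self)
  if (!nrow(pairs)) return(NULL)
  xa <- s2c(seq_a); xb <- s2c(seq_b)
  hits <- list()
  ## seeds already inside an accepted hit on the same diagonal are skipped
  covered <- list()
  diag_of <- pairs[, 2L] - pairs[, 1L]
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]; d <- diag_of[i]
    key <- as.character(d)
    cv <- covered[[key]]
    if (!is.null(cv) && any(a >= cv[, 1L] & a <= cv[, 2L])) next
    h <- extend_seed(xa, xb, a, b, k, exact = exact)
    covered[[key]] <- rbind(cv, c(h$start_a, h$end_a))
    if (h$length >= min_len && h$identity >= min_identity)
      hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, lapply(hits, as.data.frame))
}

#' Interspersed repeats by genome self-comparison
#'
#' Exact k-mer seeds on both strands are extended without gaps (X-drop;
#' exact extension when `min_identity = 100`). The trivial full-length
#' self-match, symmetric duplicates and palindromic self-hits are
#' removed.
#'
#' @param genome An [annotated_genome()] or DNA string.
#' @param min_len Minimum hit length (bp).
#' @param min_identity Minimum percent identity.
#' @param k Seed k-mer size.
#' @return Data.frame of hits: start_a, end_a, start_b, end_b, strand
#'   (`"+"` direct, `"-"` inverted), length, identity; sorted by
#'   position. `NULL`-safe: zero hits give a 0-row data.frame.
#' @export
find_interspersed_repeats <- function(genome, min_len = 50L,
                                      min_identity = 75, k = 16L) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  n <- nchar(seq)
  empty <- data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      strand = character(), length = integer(),
                      identity = numeric())
  if (n < min_len) return(empty)
  fwd <- seed_extend_hits(seq, seq, k, min_len, min_identity, self = TRUE)
  if (!is.null(fwd)) fwd$strand <- "+"
  rcseq <- revcomp(seq)
  rev <- seed_extend_hits(seq, rcseq, k, min_len, min_identity, self = FALSE)
  if (!is.null(rev)) {
    ## map coordinates on the reverse complement back to forward strand
    sb <- n - rev$end_b + 1L
    eb <- n - rev$start_b + 1L
    rev$start_b <- sb; rev$end_b <- eb
    rev$strand <- "-"
    ## canonical orientation + drop palindromic self-hits and symmetric
    ## duplicates
    flip <- rev$start_b < rev$start_a
    tmp_s <- rev$start_a[flip]; tmp_e <- rev$end_a[flip]
    rev$start_a[flip] <- rev$start_b[flip]; rev$end_a[flip] <- rev$end_b[flip]
    rev$start_b[flip] <- tmp_s; rev$end_b[flip] <- tmp_e
    rev <- rev[!(rev$start_a == rev$start_b & rev$end_a == rev$end_b), ,
               drop = FALSE]
    rev <- rev[!duplicated(rev[, c("start_a", "end_a", "start_b", "end_b")]), ,
               drop = FALSE]
  }
  out <- rbind(fwd, rev)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[!duplicated(out[, c("start_a", "end_a", "start_b", "end_b",
                                 "strand")]), , drop = FALSE]
  out <- out[order(out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a genome covered by repeat hits
#'
#' Union of all hit intervals (both copies), as a percentage of the
#' genome length; overlapping hits are counted once.
#'
#' @param hits A [find_interspersed_repeats()] table.
#' @param genome_length Genome length in bp.
#' @return Percent coverage in `[0, 100]`.
#' @export
repeat_fraction <- function(hits, genome_length) {
  if (is.null(hits) || !nrow(hits)) return(0)
  ir <- IRanges::IRanges(start = c(hits$start_a, hits$start_b),
                         end = c(hits$end_a, hits$end_b))
  100 * sum(IRanges::width(IRanges::reduce(ir))) / genome_length
}

#' Simplified tandem-repeat detection
#'
#' For every candidate period p the sequence is compared with itself at
#' offset p; runs of matching positions are chained into arrays. A
#' mismatch gap is bridged only when it is shorter than the period, the
#' run beyond it is at least four times the gap (score-positive under
#' Tandem Repeats Finder's default match/mismatch weights), and the
#' overall match fraction stays above `min_match`. Overlapping arrays of different
#' periods are deduplicated keeping the highest match fraction, then the
#' longest span, then the smallest period. This is a deliberately simple
#' detector; it reports period, copy number, span and a majority-rule
#' consensus unit, not probabilistic alignment scores.
#'
#' @param genome An [annotated_genome()] or DNA string.
#' @param max_period Largest repeat unit length considered.
#' @param min_copies Minimum (possibly fractional) copy number.
#' @param min_match Minimum match fraction within the array.
#' @param min_span Minimum total array span in bp.
#' @return Data.frame: start, end, period, copies, span, match_fraction,
#'   consensus.
#' @export
find_tandem_repeats <- function(genome, max_period = 200L, min_copies = 2,
                                min_match = 0.8, min_span = 12L) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  x <- s2c(seq)
  n <- length(x)
  arrays <- list()
  for (p in seq_len(min(max_period, n %/% 2L))) {
    m <- x[seq_len(n - p)] == x[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_min <- max(6L, min(12L, ceiling(p * (min_copies - 1) / 2)))
    seed_runs <- which(r$values & r$lengths >= seed_min)
    if (!length(seed_runs)) next
    claimed_to <- 0L
    for (sr in seed_runs) {
      if (starts[sr] <= claimed_to) next
      ## grow left and right over neighboring TRUE runs while the match
      ## fraction stays acceptable and gaps are shorter than the period
      lo <- sr; hi <- sr
      matched <- r$lengths[sr]
      total <- r$lengths[sr]
      repeat {
        grew <- FALSE
        if (hi + 2L <= length(r$lengths) && r$values[hi + 2L]) {
          gap <- r$lengths[hi + 1L]; run <- r$lengths[hi + 2L]
          if (gap < p && run >= 4L * gap &&
              (matched + run) / (total + gap + run) >= min_match) {
            hi <- hi + 2L; matched <- matched + run; total <- total + gap + run
            grew <- TRUE
          }
        }
        if (lo - 2L >= 1L && r$values[lo - 2L]) {
          gap <- r$lengths[lo - 1L]; run <- r$lengths[lo - 2L]
          if (gap < p && run >= 4L * gap &&
              (matched + run) / (total + gap + run) >= min_match) {
            lo <- lo - 2L; matched <- matched + run; total <- total + gap + run
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      s <- starts[lo]; e <- ends[hi]
      claimed_to <- e
      span <- (e + p) - s + 1L
      copies <- span / p
      frac <- matched / total
      if (copies >= min_copies && span >= min_span && frac >= min_match) {
        idx <- s:(e + p)
        cons <- vapply(seq_len(p), function(o) {
          pos <- idx[(seq_along(idx) - 1L) %% p == (o - 1L)]
          names(sort(table(x[pos]), decreasing = TRUE))[1L]
        }, "")
        arrays[[length(arrays) + 1L]] <-
          data.frame(start = s, end = e + p, period = p, copies = copies,
                     span = span, match_fraction = frac,
                     consensus = c2s(cons), stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), span = integer(),
                      match_fraction = numeric(), consensus = character())
  if (!length(arrays)) return(empty)
  out <- do.call(rbind, arrays)
  ## dedup overlapping reports across periods
  out <- out[order(-out$match_fraction, -out$span, out$period), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(out)) > i)
    if (!length(later)) break
    ov <- out$start[later] <= out$end[i] & out$end[later] >= out$start[i]
    keep[later[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared fragments between a mitogenome and nuclear sequences
#'
#' Applies the seed-and-extend engine across genomes to detect NUMT-like
#' fragments present in both the mitochondrial and nuclear genome.
#'
#' @param mito An [annotated_genome()] or DNA string.
#' @param nuclear A list of [annotated_genome()] objects or DNA strings
#'   (nuclear contigs).
#' @param min_len Minimum fragment length (bp).
#' @param min_identity Minimum percent identity.
#' @param k Seed k-mer size.
#' @return Data.frame: nuclear_id, mito_start, mito_end, nuc_start,
#'   nuc_end, strand, length, identity. Attribute `total_bp` is the sum
#'   of fragment lengths.
#' @export
find_shared_fragments <- function(mito, nuclear, min_len = 100L,
                                  min_identity = 75, k = 16L) {
  mseq <- if (inherits(mito, "annotated_genome")) mito$sequence else mito
  if (inherits(nuclear, "annotated_genome") || is.character(nuclear))
    nuclear <- list(nuclear)
  if (!length(nuclear)) stop("empty nuclear sequence set")
  rows <- list()
  for (i in seq_along(nuclear)) {
    nuc <- nuclear[[i]]
    nid <- if (inherits(nuc, "annotated_genome")) nuc$id
           else names(nuclear)[i] %||% paste0("nuc", i)
    if (is.na(nid) || !nzchar(nid)) nid <- paste0("nuc", i)
    nseq <- if (inherits(nuc, "annotated_genome")) nuc$sequence else nuc
    for (strand in c("+", "-")) {
      target <- if (strand == "+") nseq else revcomp(nseq)
      h <- seed_extend_hits(mseq, target, k, min_len, min_identity)
      if (is.null(h)) next
      if (strand == "-") {
        nn <- nchar(nseq)
        sb <- nn - h$end_b + 1L; eb <- nn - h$start_b + 1L
        h$start_b <- sb; h$end_b <- eb
      }
      h$nuclear_id <- nid
      h$strand <- strand
      rows[[length(rows) + 1L]] <- h
    }
  }
  empty <- data.frame(nuclear_id = character(), mito_start = integer(),
                      mito_end = integer(), nuc_start = integer(),
                      nuc_end = integer(), strand = character(),
                      length = integer(), identity = numeric())
  attr(empty, "total_bp") <- 0L
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- data.frame(nuclear_id = out$nuclear_id, mito_start = out$start_a,
                    mito_end = out$end_a, nuc_start = out$start_b,
                    nuc_end = out$end_b, strand = out$strand,
                    length = out$length, identity = out$identity,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("nuclear_id", "mito_start", "mito_end",
                                 "nuc_start", "nuc_end")]), , drop = FALSE]
  out <- out[order(out$nuclear_id, out$mito_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_bp") <- sum(out$length)
  out
}
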