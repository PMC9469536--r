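## Molecular-evolution statistics: Kimura-2-parameter distances,
## Nei-Gojobori (NG86) Ka/Ks with pathway averaging, per-gene summaries
## across a genome set, and a neighbor-joining tree on the combined gene
## set.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) | (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

#' Kimura-2-parameter distance from a pairwise alignment
#'
#' Columns containing a gap or `N` are excluded. With transition
#' proportion P and transversion proportion Q over the remaining sites,
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`. When the logarithm
#' argument is non-positive (saturation) the distance is flagged
#' undefined.
#'
#' @param alignment A [align_pair()]/[as_alignment()] result.
#' @return List with `P`, `Q`, `d`, `sites_used`, `defined`.
#' @export
k2p <- function(alignment) {
  a <- s2c(alignment$a); b <- s2c(alignment$b)
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0L) stop("no comparable sites in alignment")
  diff <- a != b
  ts <- sum(diff & is_transition(a, b))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  d <- if (defined) -0.5 * log(w1 * sqrt(w2)) else NA_real_
  list(P = P, Q = Q, d = d, sites_used = n, defined = defined)
}

## ---- NG86 -----------------------------------------------------------

## per-codon synonymous/nonsynonymous site counts; mutations to stop
## codons are inadmissible and excluded from the per-position denominator
ng_codon_sites <- function(codon, code) {
  aa0 <- code$map[[codon]]
  bases <- c("A", "C", "G", "T")
  syn <- 0; nonsyn <- 0
  ch <- s2c(codon)
  for (pos in 1:3) {
    alt <- bases[bases != ch[pos]]
    muts <- vapply(alt, function(b) {
      x <- ch; x[pos] <- b; c2s(x)
    }, "")
    aas <- code$map[muts]
    valid <- aas != "*"
    denom <- sum(valid)
    if (denom == 0L) next
    syn <- syn + sum(aas[valid] == aa0) / denom
    nonsyn <- nonsyn + sum(aas[valid] != aa0) / denom
  }
  c(syn = syn, nonsyn = nonsyn)
}

## observed differences for one codon pair, averaged over all admissible
## minimal mutational pathways (those avoiding stop codons); if every
## pathway passes through a stop, all pathways are used
ng_codon_diffs <- function(c1, c2, code) {
  pos <- which(s2c(c1) != s2c(c2))
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- switch(k,
                  list(pos),
                  list(pos, rev(pos)),
                  {p <- pos; list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                                  p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])})
  path_counts <- function(order, allow_stops) {
    cur <- s2c(c1); tgt <- s2c(c2)
    syn <- 0; nonsyn <- 0
    for (p in order) {
      aa_from <- code$map[[c2s(cur)]]
      cur[p] <- tgt[p]
      to <- c2s(cur)
      aa_to <- code$map[[to]]
      if (aa_to == "*" && !allow_stops) return(NULL)
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stops = FALSE))
  if (!length(res))
    res <- lapply(perms, path_counts, allow_stops = TRUE)
  m <- do.call(rbind, res)
  colMeans(m)
}

#' Nei-Gojobori (NG86) Ka/Ks for an aligned CDS pair
#'
#' Site counts come from the three single-nucleotide neighbors of each
#' codon under the genetic code, with mutations to stop codons treated as
#' inadmissible; differences at codons that differ by more than one
#' nucleotide are averaged over all admissible minimal pathways.
#' Proportions pN and pS are Jukes-Cantor corrected:
#' `K = -3/4 * ln(1 - 4p/3)`. Codon columns containing a gap are
#' excluded; a trailing stop codon pair is dropped.
#'
#' @param alignment Codon-aligned CDS pair (`pairwise_alignment`), aligned
#'   lengths divisible by 3.
#' @param code Genetic code, see [genetic_code_4()].
#' @return Object of class `kaks_result`: `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `Ka`, `Ks`, `ratio`, `codons_compared`, `defined` flags.
#' @export
nei_gojobori <- function(alignment, code = genetic_code_4()) {
  a <- alignment$a; b <- alignment$b
  if (nchar(a) %% 3L != 0L)
    stop("aligned length ", nchar(a), " is not divisible by 3")
  ca <- split_codons(a); cb <- split_codons(b)
  ## drop a trailing stop codon pair, then exclude gapped/ambiguous codons
  nc <- length(ca)
  if (nc > 0L && !grepl("-", ca[nc], fixed = TRUE) &&
      !grepl("-", cb[nc], fixed = TRUE) &&
      code$map[[ca[nc]]] == "*" && code$map[[cb[nc]]] == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]
  }
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no comparable codons in alignment")
  if (any(code$map[ca] == "*") || any(code$map[cb] == "*"))
    stop("internal stop codon in aligned CDS")
  sites_a <- vapply(ca, ng_codon_sites, c(syn = 0, nonsyn = 0), code = code)
  sites_b <- vapply(cb, ng_codon_sites, c(syn = 0, nonsyn = 0), code = code)
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- vapply(seq_along(ca), function(i)
    ng_codon_diffs(ca[i], cb[i], code), c(syn = 0, nonsyn = 0))
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(c(NA_real_, FALSE))
    c(-0.75 * log(arg), TRUE)
  }
  ks <- jc(pS); ka <- jc(pN)
  ratio_defined <- as.logical(ka[2L]) && as.logical(ks[2L]) && ks[1L] > 0
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 Ka = ka[1L], Ks = ks[1L],
                 ka_defined = as.logical(ka[2L]),
                 ks_defined = as.logical(ks[2L]),
                 ratio = if (ratio_defined) ka[1L] / ks[1L] else NA_real_,
                 ratio_defined = ratio_defined,
                 codons_compared = length(ca)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("N %.2f  S %.2f  Nd %.2f  Sd %.2f  Ka %s  Ks %s  Ka/Ks %s\n",
              x$N, x$S, x$Nd, x$Sd, format(x$Ka, digits = 4),
              format(x$Ks, digits = 4), format(x$ratio, digits = 4)))
  invisible(x)
}

## ---- per-gene summary across a genome set ---------------------------

#' Per-gene evolutionary statistics across a genome set
#'
#' For each gene present in at least two genomes: per-genome CDS lengths,
#' mean GC content and skews of the CDS, and the unweighted mean over all
#' genome pairs of the K2P distance and NG86 Ka, Ks and Ka/Ks. Pairs are
#' aligned with [align_pair()]; the trailing stop codon is removed before
#' Ka/Ks. Genes absent from all genomes are dropped with a warning.
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param genes Gene names to summarize (default the 15 core PCGs).
#' @param code Genetic code.
#' @return Data.frame, one row per gene.
#' @export
per_gene_stats <- function(genomes, genes = CORE_PCGS,
                           code = genetic_code_4()) {
  stopifnot(length(genomes) >= 2L)
  rows <- lapply(genes, function(g) {
    have <- which(vapply(genomes, function(gen)
      length(which_features(gen, g, GENE_LIKE)) > 0L, TRUE))
    if (length(have) < 2L) {
      warning("gene '", g, "' present in fewer than two genomes; omitted")
      return(NULL)
    }
    cds <- lapply(genomes[have], coding_sequence, gene_name = g)
    comps <- lapply(cds, composition_stats)
    pairs <- combn(length(cds), 2L)
    k2ps <- kas <- kss <- ratios <- numeric(0)
    any_undefined <- FALSE
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      aln <- align_pair(cds[[i]], cds[[j]])
      kk <- k2p(aln)
      if (kk$defined) k2ps <- c(k2ps, kk$d) else any_undefined <- TRUE
      if (nchar(aln$a) %% 3L == 0L) {
        ng <- tryCatch(nei_gojobori(aln, code), error = function(e) NULL)
        if (!is.null(ng)) {
          if (ng$ka_defined) kas <- c(kas, ng$Ka) else any_undefined <- TRUE
          if (ng$ks_defined) kss <- c(kss, ng$Ks) else any_undefined <- TRUE
          if (ng$ratio_defined) ratios <- c(ratios, ng$ratio)
        } else any_undefined <- TRUE
      } else any_undefined <- TRUE
    }
    mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
    data.frame(
      gene = g,
      n_genomes = length(have),
      mean_length = mean(vapply(cds, nchar, 1L)),
      length_range = diff(range(vapply(cds, nchar, 1L))),
      mean_gc = mean(vapply(comps, `[[`, 1, "gc_percent")),
      mean_at_skew = mean(vapply(comps, `[[`, 1, "at_skew")),
      mean_gc_skew = mean(vapply(comps, `[[`, 1, "gc_skew")),
      mean_k2p = mean_or_na(k2ps),
      mean_ka = mean_or_na(kas),
      mean_ks = mean_or_na(kss),
      ka_ks = mean_or_na(ratios),
      any_undefined = any_undefined,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  out
}

## ---- neighbor joining -----------------------------------------------

#' Pairwise K2P distance matrix over a genome set
#'
#' Concatenates the listed genes (those present in every genome, in the
#' given order) per genome, aligns each pair and computes the K2P
#' distance.
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param genes Genes to concatenate (default core PCGs).
#' @return Symmetric distance matrix with genome ids as dimnames.
#' @export
k2p_distance_matrix <- function(genomes, genes = CORE_PCGS) {
  ids <- vapply(genomes, `[[`, "", "id")
  shared <- Filter(function(g) all(vapply(genomes, function(gen)
    length(which_features(gen, g, GENE_LIKE)) > 0L, TRUE)), genes)
  if (!length(shared)) stop("no gene shared by all genomes")
  cats <- vapply(genomes, function(gen)
    c2s(vapply(shared, function(g) coding_sequence(gen, g), "")), "")
  n <- length(genomes)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    kk <- k2p(align_pair(cats[i], cats[j]))
    D[i, j] <- D[j, i] <- if (kk$defined) kk$d else NA_real_
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining with deterministic tie-breaking (ties in the
#' Q criterion resolved by taxon order) and negative branch lengths
#' clamped to zero (flagged via the `"clamped"` attribute).
#'
#' @param D Symmetric distance matrix with taxon labels as dimnames.
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 3L) stop("neighbor joining requires at least 3 taxa")
  bad <- which(!is.finite(D) & row(D) < col(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined distances for pair(s): ",
         paste(apply(bad, 1L, function(ij)
           paste(labels[ij[1L]], labels[ij[2L]], sep = "/")), collapse = ", "))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  nodes <- labels
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## smallest Q; ties broken by row-major (taxon order) position
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))))
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    D <- D2
  }
  ## final three nodes
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1L], b1, nodes[2L], b2, nodes[3L], b3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a square PHYLIP distance matrix
#' @param D Distance matrix.
#' @param path Output path.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  invisible(path)
}
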