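## Circular gene-order comparison: rotation/strand normalization,
## conserved-backbone detection (longest common circular subsequence of
## the shared single-copy genes), displaced-gene and doubling
## identification.

#' Extract the circular gene order of a genome
#'
#' Features of the included types sorted by genomic start coordinate.
#' Multi-copy genes are retained with ordinal suffixes in the `copy`
#' column.
#'
#' @param genome An [annotated_genome()].
#' @param include Feature types to include.
#' @return Object of class `gene_order`: data.frame (gene, strand, start,
#'   copy) plus the genome id.
#' @export
extract_order <- function(genome, include = c("PCG", "rRNA", "tRNA")) {
  n <- genome_length(genome)
  idx <- which(vapply(genome$features, `[[`, "", "ftype") %in% include)
  feats <- genome$features[idx]
  if (!length(feats))
    return(structure(list(id = genome$id,
                          table = data.frame(gene = character(),
                                             strand = character(),
                                             start = integer(),
                                             copy = integer())),
                     class = "gene_order"))
  starts <- vapply(feats, function(f) min(f$intervals$start), 1L)
  ord <- order(starts)
  tab <- data.frame(gene = vapply(feats, `[[`, "", "name")[ord],
                    strand = vapply(feats, `[[`, "", "strand")[ord],
                    start = starts[ord], stringsAsFactors = FALSE)
  tab$copy <- stats::ave(seq_len(nrow(tab)), tab$gene,
                         FUN = seq_along)
  rownames(tab) <- NULL
  structure(list(id = genome$id, table = tab), class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d features\n", x$id, nrow(x$table)))
  cat("  ", paste(ifelse(x$table$strand == "-",
                         paste0("-", x$table$gene), x$table$gene),
                  collapse = " "), "\n")
  invisible(x)
}

## longest common subsequence of two (gene, strand) token vectors;
## returns indices into a
lcs_tokens <- function(a, b) {
  na <- length(a); nb <- length(b)
  L <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    eq <- a[i] == b
    L[i + 1L, -1L] <- pmax(L[i, -1L],
                           ifelse(eq, L[i, -(nb + 1L)] + 1L, 0L))
    ## running max over j to enforce monotonicity
    L[i + 1L, ] <- cummax(L[i + 1L, ])
  }
  ## traceback
  keep <- integer(0)
  i <- na; j <- nb
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      keep <- c(i, keep); i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else j <- j - 1L
  }
  keep
}

reflect_order_tokens <- function(genes, strands) {
  list(genes = rev(genes),
       strands = rev(ifelse(strands == "+", "-", "+")))
}

## backbone of shared single-copy genes between two gene_order objects:
## LCS over every rotation of B (and of reflected B); returns gene names
## in the backbone (subset of the shared single-copy set)
circular_backbone <- function(order_a, order_b) {
  ta <- order_a$table; tb <- order_b$table
  single_a <- names(which(table(ta$gene) == 1L))
  single_b <- names(which(table(tb$gene) == 1L))
  shared <- intersect(single_a, single_b)
  if (!length(shared)) stop("no shared single-copy genes between '",
                            order_a$id, "' and '", order_b$id, "'")
  ta <- ta[ta$gene %in% shared, , drop = FALSE]
  tb <- tb[tb$gene %in% shared, , drop = FALSE]
  tok_a <- paste(ta$gene, ta$strand)
  best <- NULL; best_len <- -1L; best_flips <- Inf
  for (reflect in c(FALSE, TRUE)) {
    genes_b <- tb$gene; strands_b <- tb$strand
    if (reflect) {
      rb <- reflect_order_tokens(genes_b, strands_b)
      genes_b <- rb$genes; strands_b <- rb$strands
    }
    nb <- length(genes_b)
    for (rot in seq_len(nb) - 1L) {
      idx <- ((seq_len(nb) - 1L + rot) %% nb) + 1L
      tok_b <- paste(genes_b[idx], strands_b[idx])
      hit <- lcs_tokens(tok_a, tok_b)
      cand <- ta$gene[hit]
      flips <- sum(ta$strand[hit] != if (reflect) "-" else "+") # informational
      if (length(hit) > best_len ||
          (length(hit) == best_len && flips < best_flips) ||
          (length(hit) == best_len && flips == best_flips &&
           !is.null(best) && paste(cand, collapse = ",") <
           paste(best, collapse = ","))) {
        best <- cand; best_len <- length(hit); best_flips <- flips
      }
    }
  }
  list(backbone = best, shared = shared)
}

#' Compare two circular gene orders
#'
#' The conserved backbone is the longest common circular subsequence of
#' the shared single-copy genes (orientation-aware; every rotation and the
#' reflection of the second order are considered). Shared single-copy
#' genes outside the backbone are reported displaced; genes with a higher
#' copy number in one genome are doubling events; genes present in only
#' one genome are private.
#'
#' @param order_a,order_b [extract_order()] results.
#' @return Object of class `rearrangement_report`: `backbone`,
#'   `displaced`, `doubled` (named list per genome), `private` (named
#'   list per genome).
#' @export
compare_orders <- function(order_a, order_b) {
  bb <- circular_backbone(order_a, order_b)
  ta <- order_a$table; tb <- order_b$table
  ca <- table(ta$gene); cb <- table(tb$gene)
  all_genes <- union(names(ca), names(cb))
  na <- setNames(as.integer(ca[all_genes]), all_genes); na[is.na(na)] <- 0L
  nb <- setNames(as.integer(cb[all_genes]), all_genes); nb[is.na(nb)] <- 0L
  doubled_a <- all_genes[na > nb & na >= 2L]
  doubled_b <- all_genes[nb > na & nb >= 2L]
  private_a <- all_genes[na > 0L & nb == 0L]
  private_b <- all_genes[nb > 0L & na == 0L]
  out <- list(backbone = bb$backbone,
              displaced = setdiff(bb$shared, bb$backbone),
              doubled = setNames(list(doubled_a, doubled_b),
                                 c(order_a$id, order_b$id)),
              private = setNames(list(private_a, private_b),
                                 c(order_a$id, order_b$id)))
  structure(out, class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("backbone: %d genes\n", length(x$backbone)))
  cat("displaced:", if (length(x$displaced))
    paste(x$displaced, collapse = ", ") else "none", "\n")
  for (g in names(x$doubled))
    if (length(x$doubled[[g]]))
      cat("doubled in", g, ":", paste(x$doubled[[g]], collapse = ", "), "\n")
  invisible(x)
}

#' Conservation classes of genes across several gene orders
#'
#' Each single-copy shared gene is classified against a majority
#' representative (the most common arrangement in the set):
#' `identical-in-all` when every genome keeps it in the conserved backbone
#' and no genome shows any displacement, `identical-in-majority` when it
#' is in the backbone for more than half of the genomes, `displaced`
#' otherwise. Genes with two or more copies in some genome (and fewer in
#' another) are classified `doubled`.
#'
#' @param orders List of [extract_order()] results (>= 2).
#' @return Data.frame: gene, class.
#' @export
multi_order_summary <- function(orders) {
  stopifnot(length(orders) >= 2L)
  sig <- vapply(orders, function(o) {
    tab <- o$table
    ## rotation-invariant signature: rotate so the lexicographically
    ## smallest gene comes first
    tok <- paste(tab$gene, tab$strand)
    k <- order(tab$gene)[1L]
    c2s(tok[((seq_along(tok) - 1L + k - 1L) %% length(tok)) + 1L])
  }, "")
  rep_idx <- which(sig == names(sort(table(sig), decreasing = TRUE))[1L])[1L]
  ref <- orders[[rep_idx]]
  others <- orders[-rep_idx]
  counts <- lapply(orders, function(o) table(o$table$gene))
  all_genes <- Reduce(union, lapply(counts, names))
  maxc <- vapply(all_genes, function(g)
    max(vapply(counts, function(ct) {
      v <- ct[g]; if (is.na(v)) 0L else as.integer(v)
    }, 1L)), 1L)
  minc <- vapply(all_genes, function(g)
    min(vapply(counts, function(ct) {
      v <- ct[g]; if (is.na(v)) 0L else as.integer(v)
    }, 1L)), 1L)
  doubled <- all_genes[maxc >= 2L & minc < maxc]
  in_backbone <- setNames(rep(0L, length(all_genes)), all_genes)
  any_displacement <- FALSE
  for (o in others) {
    rep_report <- compare_orders(ref, o)
    in_backbone[rep_report$backbone] <- in_backbone[rep_report$backbone] + 1L
    if (length(rep_report$displaced)) any_displacement <- TRUE
  }
  n_comp <- length(others)
  cls <- vapply(all_genes, function(g) {
    if (g %in% doubled) return("doubled")
    if (in_backbone[g] == n_comp && !any_displacement)
      return("identical-in-all")
    if (in_backbone[g] > n_comp / 2) return("identical-in-majority")
    "displaced"
  }, "")
  data.frame(gene = all_genes, class = unname(cls), row.names = NULL,
             stringsAsFactors = FALSE)
}
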