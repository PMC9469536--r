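## Intron position-class (Pcl) homology. An intron inserted between
## coding nucleotides p and p+1 of its host gene has insertion position p;
## introns of a gene family are mapped through a global alignment onto a
## common reference coding sequence and grouped by exact mapped position,
## named "P<position>" -- introns sharing a Pcl are putatively
## orthologous.

#' Intron insertion positions within a host gene
#'
#' The insertion position of an intron is the number of coding nucleotides
#' 5' of it, i.e. the cumulative length of the exons upstream of the
#' intron on the coding strand.
#'
#' @param genome An [annotated_genome()].
#' @param host Host gene name (a PCG or rRNA with annotated exons).
#' @return Data.frame: genome_id, host, ordinal (5'->3'), position,
#'   group, intron name.
#' @export
intron_positions <- function(genome, host) {
  gidx <- which_features(genome, host, ftype = c("PCG", "rRNA", "free_ORF"))
  if (!length(gidx))
    stop("host gene '", host, "' not annotated in '", genome$id, "'")
  hostf <- genome$features[[gidx[1L]]]
  n <- genome_length(genome)
  iidx <- which(vapply(genome$features, function(f)
    identical(f$ftype, "intron") && identical(f$parent, host), TRUE))
  empty <- data.frame(genome_id = character(), host = character(),
                      ordinal = integer(), position = integer(),
                      group = character(), name = character())
  if (!length(iidx)) return(empty)
  ex <- hostf$intervals  # 5'->3' coding order
  exon_lens <- vapply(seq_len(nrow(ex)), function(i)
    interval_length(ex$start[i], ex$end[i], n), 1L)
  cum <- cumsum(exon_lens)
  rows <- lapply(iidx, function(ii) {
    f <- genome$features[[ii]]
    s <- f$intervals$start[1L]
    e <- f$intervals$end[nrow(f$intervals)]
    ## locate the exon immediately 5' of the intron on the coding strand:
    ## for "+" the exon whose end is s - 1; for "-" the exon whose start
    ## is e + 1
    k <- if (hostf$strand == "+") which(ex$end == s - 1L)
         else which(ex$start == e + 1L)
    if (length(k) != 1L)
      stop("intron '", f$name, "' is not flanked by exons of '", host, "'")
    data.frame(genome_id = genome$id, host = host, ordinal = NA_integer_,
               position = cum[k], group = f$group %||% NA_character_,
               name = f$name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  out$ordinal <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Map a coding-sequence position onto a reference through an alignment
#'
#' `position` counts coding nucleotides 5' of an insertion point in the
#' query CDS (0 = before the first nucleotide). The return value is the
#' number of reference nucleotides 5' of the corresponding alignment
#' column. An insertion point falling inside a reference gap maps to the
#' nearest reference position 5' of the gap; the `"in_ref_gap"` attribute
#' flags that case.
#'
#' @param query,reference CDS strings, or `alignment` may be supplied
#'   directly.
#' @param position Integer in `[0, nchar(query)]`.
#' @param alignment Optional precomputed [align_pair()] of query vs
#'   reference (saves realignment when mapping many positions).
#' @return Integer reference position, attribute `in_ref_gap`.
#' @export
map_to_reference <- function(query, reference, position, alignment = NULL) {
  if (is.null(alignment)) alignment <- align_pair(query, reference)
  qa <- s2c(alignment$a); ra <- s2c(alignment$b)
  qlen <- sum(qa != "-")
  if (position < 0L || position > qlen)
    stop("position ", position, " outside [0, ", qlen, "]")
  if (position == 0L) {
    out <- 0L
    attr(out, "in_ref_gap") <- FALSE
    return(out)
  }
  qcum <- cumsum(qa != "-")
  col <- match(position, qcum)  # column holding the position-th query nt
  out <- as.integer(sum(ra[seq_len(col)] != "-"))
  attr(out, "in_ref_gap") <- ra[col] == "-"
  out
}

#' Classify introns of a gene family into position classes (Pcls)
#'
#' For every genome, the host gene's CDS is aligned to the reference CDS
#' and each intron's insertion position is mapped onto the reference.
#' Introns sharing an exact mapped reference position form one Pcl, named
#' `"P<position>"`.
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param host Host gene name (e.g. `"cox1"`).
#' @param reference_cds Reference coding sequence (DNA string), typically
#'   the intron-free CDS of a well-annotated reference species.
#' @param confirm_identity Optional percent-identity threshold. When set,
#'   intron sequences within each multi-member Pcl are aligned pairwise
#'   and the minimum identity is reported (`min_identity` column, with
#'   `identity_ok` flagging Pcls at or above the threshold). Position is
#'   authoritative for class membership; this is a confirmation only.
#' @return Object of class `pcl_matrix`: `matrix` (Pcl x genome logical
#'   presence), `pcls` (per-Pcl position and group), `introns` (per-intron
#'   mapping table).
#' @export
classify_pcls <- function(genomes, host, reference_cds,
                          confirm_identity = NULL) {
  ids <- vapply(genomes, `[[`, "", "id")
  recs <- lapply(genomes, function(g) {
    r <- intron_positions(g, host)
    if (!nrow(r)) return(r)
    aln <- align_pair(coding_sequence(g, host), reference_cds)
    mapped <- vapply(r$position, function(p)
      as.integer(map_to_reference(NULL, NULL, p, alignment = aln)), 1L)
    r$ref_position <- mapped
    r$pcl <- paste0("P", mapped)
    r
  })
  introns <- do.call(rbind, Filter(function(r) nrow(r) > 0L, recs))
  if (is.null(introns))
    introns <- data.frame(genome_id = character(), host = character(),
                          ordinal = integer(), position = integer(),
                          group = character(), name = character(),
                          ref_position = integer(), pcl = character())
  pcl_names <- unique(introns$pcl[order(introns$ref_position)])
  mat <- matrix(FALSE, nrow = length(pcl_names), ncol = length(ids),
                dimnames = list(pcl_names, ids))
  for (i in seq_len(nrow(introns)))
    mat[introns$pcl[i], introns$genome_id[i]] <- TRUE
  pcls <- if (length(pcl_names)) data.frame(
    pcl = pcl_names,
    ref_position = introns$ref_position[match(pcl_names, introns$pcl)],
    group = vapply(pcl_names, function(p) {
      gr <- introns$group[introns$pcl == p]
      gr <- gr[!is.na(gr)]
      if (length(gr)) names(sort(table(gr), decreasing = TRUE))[1L]
      else NA_character_
    }, ""),
    n_members = vapply(pcl_names, function(p) sum(introns$pcl == p), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  ) else data.frame(pcl = character(), ref_position = integer(),
                    group = character(), n_members = integer())
  if (!is.null(confirm_identity) && nrow(pcls)) {
    by_id <- setNames(genomes, ids)
    pcls$min_identity <- vapply(pcls$pcl, function(p) {
      rows <- introns[introns$pcl == p, , drop = FALSE]
      if (nrow(rows) < 2L) return(NA_real_)
      seqs <- vapply(seq_len(nrow(rows)), function(i) {
        g <- by_id[[rows$genome_id[i]]]
        idx <- which(feature_names(g) == rows$name[i])[1L]
        feature_sequence(g, g$features[[idx]])
      }, "")
      prs <- combn(length(seqs), 2L)
      min(vapply(seq_len(ncol(prs)), function(k) {
        aln <- align_pair(seqs[prs[1L, k]], seqs[prs[2L, k]])
        a <- s2c(aln$a); b <- s2c(aln$b)
        100 * sum(a == b) / length(a)
      }, 1))
    }, 1)
    pcls$identity_ok <- is.na(pcls$min_identity) |
      pcls$min_identity >= confirm_identity
  }
  structure(list(matrix = mat, pcls = pcls, introns = introns),
            class = "pcl_matrix")
}

#' @export
print.pcl_matrix <- function(x, ...) {
  cat(sprintf("<pcl_matrix> %d Pcls x %d genomes, %d introns\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$introns)))
  if (nrow(x$pcls)) print(x$pcls)
  invisible(x)
}

#' Sharing summary of a Pcl matrix
#'
#' @param pclmat A [classify_pcls()] result.
#' @return List with `counts` (data.frame pcl, n_genomes, private) and
#'   `private_by_genome` (Pcls detected in exactly one genome, by genome).
#' @export
pcl_sharing_summary <- function(pclmat) {
  m <- pclmat$matrix
  if (!nrow(m))
    return(list(counts = data.frame(pcl = character(), n_genomes = integer(),
                                    private = logical()),
                private_by_genome = setNames(list(), character())))
  counts <- data.frame(pcl = rownames(m), n_genomes = rowSums(m),
                       private = rowSums(m) == 1L, row.names = NULL)
  priv <- lapply(colnames(m), function(g)
    rownames(m)[m[, g] & counts$private])
  names(priv) <- colnames(m)
  list(counts = counts, private_by_genome = priv)
}
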