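## Core data model: annotated circular mitogenomes and their features.
##
## Coordinates are 1-based inclusive throughout (GenBank convention). A
## feature interval with start > end wraps the origin of a circular
## molecule. For multi-exon features the interval list is stored in 5'->3'
## order on the coding strand; minus-strand features therefore list their
## genomically-last exon first.

FEATURE_TYPES <- c("PCG", "rRNA", "tRNA", "intron", "intronic_ORF", "free_ORF")
GENE_LIKE     <- c("PCG", "rRNA", "tRNA", "free_ORF")
CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "rps3")

#' Construct a genome feature
#'
#' A typed feature (gene, intron, ORF) of an annotated mitogenome.
#' Intervals are 1-based inclusive genome coordinates; for circular
#' molecules an interval with `start > end` wraps the origin. Multi-exon
#' features list their intervals in 5'->3' order on the coding strand.
#'
#' @param name Gene symbol, e.g. `"cox1"`, `"rnl"`, `"trnM"`.
#' @param ftype One of `"PCG"`, `"rRNA"`, `"tRNA"`, `"intron"`,
#'   `"intronic_ORF"`, `"free_ORF"`.
#' @param strand `"+"` or `"-"`.
#' @param intervals Two-column matrix or data.frame of (start, end) pairs.
#' @param parent Host gene name; required iff `ftype` is `"intron"` or
#'   `"intronic_ORF"`.
#' @param anticodon Optional anticodon triplet (tRNA only), lowercase.
#' @param group Optional intron group label (`"I"`, `"II"`, `"unknown"`).
#' @return An object of class `mito_feature`.
#' @export
feature <- function(name, ftype, strand = "+", intervals,
                    parent = NA_character_, anticodon = NA_character_,
                    group = NA_character_) {
  stopifnot(is_string(name), ftype %in% FEATURE_TYPES, strand %in% c("+", "-"))
  iv <- as.data.frame(intervals)
  if (ncol(iv) != 2L || nrow(iv) < 1L)
    stop("feature '", name, "': intervals must be a non-empty 2-column table")
  names(iv) <- c("start", "end")
  iv$start <- as.integer(iv$start); iv$end <- as.integer(iv$end)
  if (any(is.na(iv)) || any(iv < 1L))
    stop("feature '", name, "': interval coordinates must be positive integers")
  needs_parent <- ftype %in% c("intron", "intronic_ORF")
  if (needs_parent && (is.na(parent) || !nzchar(parent)))
    stop("feature '", name, "' of type ", ftype, " requires a parent gene")
  if (!needs_parent && !is.na(parent))
    stop("feature '", name, "': parent may only be set for introns/intronic ORFs")
  structure(list(name = name, ftype = ftype, strand = strand,
                 intervals = iv, parent = parent,
                 anticodon = if (is.na(anticodon)) NA_character_ else tolower(anticodon),
                 group = group),
            class = "mito_feature")
}

#' Construct an annotated genome
#'
#' @param id Accession or label, unique within a comparison set.
#' @param sequence DNA string; characters outside `{A,C,G,T,N}` are
#'   normalized to `N` with a warning.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param features List of [feature()] objects.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, topology = "circular",
                             features = list()) {
  stopifnot(is_string(id), is_string(sequence),
            topology %in% c("circular", "linear"))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome '", id, "': empty sequence")
  if (grepl("[^ACGTN]", sequence)) {
    warning("genome '", id, "': non-ACGTN characters normalized to N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  g <- structure(list(id = id, sequence = sequence, topology = topology,
                      features = features),
                 class = "annotated_genome")
  validate_genome(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features\n",
              x$id, format(genome_length(x), big.mark = ","), x$topology,
              length(x$features)))
  if (length(x$features)) {
    tab <- table(vapply(x$features, `[[`, "", "ftype"))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.mito_feature <- function(x, ...) {
  iv <- paste(sprintf("%d-%d", x$intervals$start, x$intervals$end),
              collapse = ";")
  cat(sprintf("<feature> %s [%s] strand %s @ %s\n", x$name, x$ftype,
              x$strand, iv))
  invisible(x)
}

#' Genome length in bp
#' @param genome An [annotated_genome()].
#' @export
genome_length <- function(genome) nchar(genome$sequence)

validate_genome <- function(genome) {
  n <- genome_length(genome)
  for (f in genome$features) {
    if (any(f$intervals$start > n) || any(f$intervals$end > n))
      stop("genome '", genome$id, "': feature '", f$name,
           "' has coordinates beyond sequence length ", n)
    if (genome$topology == "linear" && any(f$intervals$start > f$intervals$end))
      stop("genome '", genome$id, "': wrapped interval in feature '", f$name,
           "' on a linear molecule")
  }
  parents <- vapply(genome$features, `[[`, "", "parent")
  names_all <- vapply(genome$features, `[[`, "", "name")
  missing <- setdiff(parents[!is.na(parents)], names_all)
  if (length(missing))
    stop("genome '", genome$id, "': intron parent gene(s) not annotated: ",
         paste(missing, collapse = ", "))
  invisible(genome)
}

feature_names <- function(genome) vapply(genome$features, `[[`, "", "name")

feature_span_positions <- function(f, n) {
  unique(unlist(lapply(seq_len(nrow(f$intervals)), function(i)
    interval_positions(f$intervals$start[i], f$intervals$end[i], n))))
}

feature_length <- function(f, n) {
  sum(vapply(seq_len(nrow(f$intervals)), function(i)
    interval_length(f$intervals$start[i], f$intervals$end[i], n), 1L))
}

#' Extract the sequence of a feature
#'
#' Concatenates the feature's intervals in listed (5'->3' coding) order,
#' reverse-complementing each segment for minus-strand features. Wrapped
#' intervals on circular molecules are handled transparently.
#'
#' @param genome An [annotated_genome()].
#' @param f A [feature()] belonging to `genome`.
#' @return DNA string.
#' @export
feature_sequence <- function(genome, f) {
  circ <- genome$topology == "circular"
  segs <- vapply(seq_len(nrow(f$intervals)), function(i)
    circ_substr(genome$sequence, f$intervals$start[i], f$intervals$end[i],
                circular = circ), "")
  if (f$strand == "-") segs <- vapply(segs, revcomp, "")
  c2s(segs)
}

## locate features by name (optionally restricted by type); returns indices
which_features <- function(genome, name, ftype = NULL) {
  idx <- which(feature_names(genome) == name)
  if (!is.null(ftype))
    idx <- idx[vapply(genome$features[idx], `[[`, "", "ftype") %in% ftype]
  idx
}

#' Spliced coding/transcript sequence of a gene
#'
#' Concatenates the annotated exons of a gene 5'->3' on the coding strand,
#' reverse-complementing for minus-strand genes. For protein-coding genes
#' this is the CDS; for rRNAs the spliced transcript.
#'
#' @param genome An [annotated_genome()].
#' @param gene_name Gene symbol.
#' @param copy Which copy to use when the gene is multi-copy (genome order).
#' @return DNA string.
#' @export
coding_sequence <- function(genome, gene_name, copy = 1L) {
  idx <- which_features(genome, gene_name, ftype = GENE_LIKE)
  if (!length(idx))
    stop("gene '", gene_name, "' not annotated in genome '", genome$id, "'")
  if (copy > length(idx))
    stop("gene '", gene_name, "' has only ", length(idx), " copies")
  feature_sequence(genome, genome$features[[idx[copy]]])
}

#' Rotate a circular genome
#'
#' Moves the origin so that position `k + 1` of the input becomes position
#' 1. All feature coordinates are remapped; intervals that come to span the
#' new origin become wrapped (start > end) intervals.
#'
#' @param genome A circular [annotated_genome()].
#' @param k Number of positions to rotate (0 <= k < length).
#' @return The rotated genome.
#' @export
rotate_genome <- function(genome, k) {
  stopifnot(genome$topology == "circular")
  n <- genome_length(genome)
  k <- as.integer(k %% n)
  if (k == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, k + 1L, n),
                 substr(genome$sequence, 1L, k))
  remap <- function(p) ((p - 1L - k) %% n) + 1L
  feats <- lapply(genome$features, function(f) {
    f$intervals$start <- remap(f$intervals$start)
    f$intervals$end <- remap(f$intervals$end)
    f
  })
  g <- genome
  g$sequence <- seq2
  g$features <- feats
  g
}
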