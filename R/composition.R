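## Base composition, strand-asymmetry skews, nucleotide-exact region
## partition and the size-variation contribution-rate decomposition.

#' Base composition and strand-asymmetry skews
#'
#' Counts A/C/G/T (N excluded from all denominators), GC and AT content,
#' and the strand skews AT skew = (A - T)/(A + T), GC skew =
#' (G - C)/(G + C). A skew whose denominator is zero is reported as 0 with
#' the corresponding degenerate flag set.
#'
#' @param x DNA string or an [annotated_genome()].
#' @return Object of class `composition_stats` with fields `counts`,
#'   `gc_percent`, `at_percent`, `at_skew`, `gc_skew`,
#'   `at_skew_degenerate`, `gc_skew_degenerate`.
#' @export
composition_stats <- function(x) {
  if (inherits(x, "annotated_genome")) x <- x$sequence
  stopifnot(is_string(x))
  if (nchar(x) == 0L) stop("empty sequence")
  counts <- table(factor(s2c(toupper(x)), levels = c("A", "C", "G", "T", "N")))
  a <- counts[["A"]]; c_ <- counts[["C"]]; g <- counts[["G"]]; t <- counts[["T"]]
  tot <- a + c_ + g + t
  if (tot == 0L) stop("sequence contains no unambiguous bases")
  at_deg <- (a + t) == 0L
  gc_deg <- (g + c_) == 0L
  structure(list(
    counts = c(A = a, C = c_, G = g, T = t, N = counts[["N"]]),
    gc_percent = 100 * (g + c_) / tot,
    at_percent = 100 * (a + t) / tot,
    at_skew = if (at_deg) 0 else (a - t) / (a + t),
    gc_skew = if (gc_deg) 0 else (g - c_) / (g + c_),
    at_skew_degenerate = at_deg,
    gc_skew_degenerate = gc_deg
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("GC %.2f%%  AT %.2f%%  AT skew %.4f  GC skew %.4f\n",
              x$gc_percent, x$at_percent, x$at_skew, x$gc_skew))
  invisible(x)
}

REGION_CLASSES <- c("protein_coding", "intronic", "rna", "intergenic")

#' Construct a region partition by hand
#'
#' Used to rebuild partitions from reported per-class sizes. Class lengths
#' must sum to the genome length.
#'
#' @param protein_coding,intronic,rna,intergenic Class lengths in bp.
#' @return Object of class `region_partition`.
#' @export
region_partition <- function(protein_coding, intronic, rna, intergenic) {
  lens <- c(protein_coding = protein_coding, intronic = intronic,
            rna = rna, intergenic = intergenic)
  if (any(lens < 0)) stop("negative region length")
  n <- sum(lens)
  structure(list(lengths = lens, percent = 100 * lens / n,
                 genome_length = n),
            class = "region_partition")
}

#' Partition a genome into region classes, nucleotide by nucleotide
#'
#' Every position is assigned exactly one of four classes with priority
#' rna exon > protein-coding exon > intron > intergenic, so the class
#' lengths always sum to the genome length. Intronic ORFs and introns of
#' rRNA hosts count as intronic; free-standing ORFs count as protein
#' coding; tRNAs count as RNA; bases shared by overlapping genes are
#' counted once.
#'
#' @param genome An [annotated_genome()].
#' @return Object of class `region_partition`.
#' @export
partition_regions <- function(genome) {
  validate_genome(genome)
  n <- genome_length(genome)
  cls <- integer(n)  # 0 intergenic, 1 intronic, 2 protein_coding, 3 rna
  assign_class <- function(ftypes, value) {
    for (f in genome$features) {
      if (!f$ftype %in% ftypes) next
      cls[feature_span_positions(f, n)] <<- value
    }
  }
  assign_class(c("intron", "intronic_ORF"), 1L)
  assign_class(c("PCG", "free_ORF"), 2L)
  assign_class(c("rRNA", "tRNA"), 3L)
  lens <- tabulate(cls + 1L, nbins = 4L)
  region_partition(protein_coding = lens[3L], intronic = lens[2L],
                   rna = lens[4L], intergenic = lens[1L])
}

#' @export
print.region_partition <- function(x, ...) {
  for (cl in REGION_CLASSES)
    cat(sprintf("  %-15s %9d bp  %6.2f%%\n", cl, x$lengths[[cl]],
                x$percent[[cl]]))
  invisible(x)
}

#' Contribution of each region class to the size difference of two genomes
#'
#' For each class, rate = 100 * (len_B - len_A) / (len(B) - len(A)). Rates
#' are signed and sum to 100% whenever the total size difference is
#' non-zero; with equal total sizes only the per-class differences are
#' reported (rates `NA`).
#'
#' @param partition_a,partition_b [region_partition()] objects of the two
#'   genomes (A = smaller/reference, B = larger/query in the usual report).
#' @return Object of class `contribution_report` with a `table`
#'   data.frame and `total_difference` in bp.
#' @export
contribution_rates <- function(partition_a, partition_b) {
  stopifnot(inherits(partition_a, "region_partition"),
            inherits(partition_b, "region_partition"))
  diffs <- partition_b$lengths - partition_a$lengths
  total <- partition_b$genome_length - partition_a$genome_length
  rates <- if (total != 0) 100 * diffs / total else rep(NA_real_, 4L)
  structure(list(
    table = data.frame(region = REGION_CLASSES,
                       size_difference_bp = as.numeric(diffs[REGION_CLASSES]),
                       contribution_rate_percent = as.numeric(rates[REGION_CLASSES]),
                       row.names = NULL),
    total_difference = total
  ), class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("total size difference: %s bp\n",
              format(x$total_difference, big.mark = ",")))
  print(x$table)
  invisible(x)
}
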