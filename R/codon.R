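## Translation and codon-usage analysis under the mold mitochondrial
## genetic code (translation table 4: TGA = Trp; stops TAA, TAG).

#' The mold mitochondrial genetic code (translation table 4)
#'
#' @return List with `map` (64 codons -> one-letter amino acid, stops as
#'   `"*"`), `stops` (`TAA`, `TAG`) and `starts` (`ATG`, `GTG`, `TTG`).
#' @export
genetic_code_4 <- function() {
  map <- Biostrings::getGeneticCode("4")
  list(map = map,
       stops = names(map)[map == "*"],
       starts = c("ATG", "GTG", "TTG"))
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a CDS under genetic code 4
#'
#' The trailing stop codon (if present) is dropped from the protein. An
#' internal stop is an error reporting the codon position.
#'
#' @param cds DNA string, length divisible by 3.
#' @param code Genetic code, see [genetic_code_4()].
#' @return Protein string.
#' @export
translate_cds <- function(cds, code = genetic_code_4()) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  codons <- split_codons(cds)
  aa <- unname(code$map[codons])
  if (anyNA(aa)) stop("ambiguous codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  stops <- which(aa == "*")
  internal <- stops[stops < length(aa)]
  if (length(internal))
    stop("internal stop codon at codon ", internal[1L])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  c2s(aa)
}

#' Start and stop codons of every annotated protein-coding gene
#'
#' @param genome An [annotated_genome()].
#' @param code Genetic code.
#' @return Data.frame with columns gene, start_codon, stop_codon,
#'   start_ok (start in ATG/GTG/TTG), stop_ok (stop in TAA/TAG).
#' @export
start_stop_codons <- function(genome, code = genetic_code_4()) {
  idx <- which(vapply(genome$features, `[[`, "", "ftype") %in%
                 c("PCG", "free_ORF"))
  rows <- lapply(idx, function(i) {
    f <- genome$features[[i]]
    cds <- feature_sequence(genome, f)
    if (nchar(cds) < 6L)
      stop("gene '", f$name, "': CDS shorter than 6 nt")
    start <- substr(cds, 1L, 3L)
    stop_ <- substr(cds, nchar(cds) - 2L, nchar(cds))
    data.frame(gene = f$name, start_codon = start, stop_codon = stop_,
               start_ok = start %in% code$starts,
               stop_ok = stop_ %in% code$stops,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Codon usage and RSCU for the protein-coding genes of a genome
#'
#' Counts codons over the spliced CDS of the included genes. Genes whose
#' CDS length is not divisible by 3 are excluded with a warning. RSCU of a
#' codon is its count divided by the mean count of its synonymous family.
#' Stop codons are excluded from counts and frequencies by default.
#'
#' @param genome An [annotated_genome()].
#' @param genes Optional character vector restricting the gene set (e.g.
#'   the 15 core PCGs); default all annotated PCGs and free ORFs.
#' @param include_stops Count stop codons too (default `FALSE`).
#' @param code Genetic code.
#' @return Data.frame: codon, amino_acid, count, frequency, rscu; sorted
#'   by descending count. Attribute `codons_counted` holds the total.
#' @export
codon_usage <- function(genome, genes = NULL, include_stops = FALSE,
                        code = genetic_code_4()) {
  idx <- which(vapply(genome$features, `[[`, "", "ftype") %in%
                 c("PCG", "free_ORF"))
  if (!is.null(genes))
    idx <- idx[vapply(genome$features[idx], `[[`, "", "name") %in% genes]
  counts <- setNames(integer(64L), names(code$map))
  for (i in idx) {
    f <- genome$features[[i]]
    cds <- feature_sequence(genome, f)
    if (nchar(cds) %% 3L != 0L) {
      warning("gene '", f$name, "' excluded: CDS length not divisible by 3")
      next
    }
    cc <- table(factor(split_codons(cds), levels = names(code$map)))
    counts <- counts + as.integer(cc)
  }
  aa <- unname(code$map)
  keep <- if (include_stops) rep(TRUE, 64L) else aa != "*"
  tab <- data.frame(codon = names(code$map)[keep], amino_acid = aa[keep],
                    count = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  total <- sum(tab$count)
  tab$frequency <- if (total > 0L) tab$count / total else 0
  fam_mean <- tapply(tab$count, tab$amino_acid, mean)
  tab$rscu <- ifelse(fam_mean[tab$amino_acid] > 0,
                     tab$count / fam_mean[tab$amino_acid], NA_real_)
  tab <- tab[order(-tab$count, tab$codon), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "codons_counted") <- total
  tab
}
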