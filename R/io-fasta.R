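## FASTA input/output (via Biostrings).

#' Read genomes from a FASTA file
#'
#' One [annotated_genome()] per record, with an empty feature list.
#' Sequences are uppercased; IUPAC ambiguity characters outside
#' `{A,C,G,T,N}` are normalized to `N` with a warning. Record ids are the
#' first whitespace-delimited token of the header.
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record (mitogenomes are
#'   circular unless stated otherwise).
#' @return List of [annotated_genome()] objects.
#' @export
read_fasta <- function(path, topology = "circular") {
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      ## whitespace inside sequence lines is stripped by design
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(ss), function(i)
    annotated_genome(ids[i], as.character(ss[[i]]), topology = topology))
}

#' Write genomes to a FASTA file
#' @param genomes A single [annotated_genome()] or a list of them.
#' @param path Output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
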