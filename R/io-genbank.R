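## Minimal GenBank flat-file reader for annotated organellar genomes.
## Handles LOCUS (length + topology), the FEATURES table with join()/
## complement() locations, and the ORIGIN sequence block. CDS features map
## to PCG, rRNA/tRNA/intron keep their class; tRNA names are derived from
## /product="tRNA-Xxx" when no /gene qualifier is present.

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

## parse a GenBank location string into (intervals in coding order, strand)
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  iv <- do.call(rbind, lapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("unsupported GenBank location: ", p)
  }))
  iv <- as.data.frame(iv); names(iv) <- c("start", "end")
  ## complement(join(a..b, c..d)) lists intervals in genome order; coding
  ## order on the minus strand is the reverse
  if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  rownames(iv) <- NULL
  list(intervals = iv, strand = strand)
}

gb_qualifier <- function(quals, key) {
  hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  v <- sub(paste0("^/", key, "="), "", hit[1L])
  gsub('^"|"$', "", v)
}

trna_name_from_product <- function(product) {
  m <- regmatches(product, regexec("tRNA-([A-Za-z]{3})", product))[[1L]]
  if (length(m) < 2L || !(m[2L] %in% names(AA3TO1))) return(NA_character_)
  paste0("trn", AA3TO1[[m[2L]]])
}

#' Read an annotated genome from a GenBank flat file
#'
#' Supports the subset of the format used by organellar genome records:
#' `LOCUS` (length, circular/linear), `FEATURES` with `join(...)` and
#' `complement(...)` locations, and the `ORIGIN` sequence block. Feature
#' classes map as CDS -> PCG, rRNA -> rRNA, tRNA -> tRNA, intron -> intron;
#' other keys are skipped.
#'
#' @param path GenBank flat file.
#' @return An [annotated_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  topology <- if (grepl("circular", locus[1L], ignore.case = TRUE))
    "circular" else "linear"

  ## sequence block
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", c2s(seq_lines)))
  n <- nchar(sequence)

  ## feature block: key lines have a non-blank key at column 6
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("no FEATURES block in ", path)
  flines <- lines[(fstart[1L] + 1L):(o[1L] - 1L)]
  key_at <- grepl("^ {1,10}\\S", flines) & !grepl("^ {12,}", flines)
  idx <- which(key_at)
  features <- list()
  for (i in seq_along(idx)) {
    block <- flines[idx[i]:(if (i < length(idx)) idx[i + 1L] - 1L else length(flines))]
    key <- strsplit(trimws(block[1L]), "\\s+")[[1L]][1L]
    rest <- trimws(sub("^\\s*\\S+\\s*", "", block[1L]))
    body <- trimws(block[-1L])
    ## location may continue over lines until the first qualifier
    qstart <- grep("^/", body)
    loc_extra <- if (length(qstart)) body[seq_len(min(qstart) - 1L)] else body
    quals <- if (length(qstart)) body[min(qstart):length(body)] else character()
    loc <- paste0(rest, paste(loc_extra, collapse = ""))
    if (!key %in% c("CDS", "rRNA", "tRNA", "intron")) next
    pl <- parse_gb_location(loc)
    if (any(pl$intervals > n))
      stop("feature '", key, "' in ", path,
           " has coordinates beyond sequence length ", n)
    gene <- gb_qualifier(quals, "gene")
    product <- gb_qualifier(quals, "product")
    ftype <- switch(key, CDS = "PCG", rRNA = "rRNA", tRNA = "tRNA",
                    intron = "intron")
    name <- gene
    anticodon <- NA_character_
    parent <- NA_character_
    if (key == "tRNA") {
      if (is.na(name) && !is.na(product)) name <- trna_name_from_product(product)
      ac <- gb_qualifier(quals, "anticodon")
      if (!is.na(ac)) {
        m <- regmatches(ac, regexec("seq:([acgtuACGTU]{3})", ac))[[1L]]
        if (length(m) == 2L) anticodon <- tolower(chartr("uU", "tt", m[2L]))
      }
    }
    if (key == "intron") {
      parent <- gene
      name <- paste0(gene %||% "intron", "_intron")
      if (is.na(parent)) stop("intron without /gene qualifier in ", path)
    }
    if (is.na(name) || !nzchar(name))
      name <- if (!is.na(product)) gsub("\\s+", "_", product) else tolower(key)
    features[[length(features) + 1L]] <-
      feature(name, ftype, strand = pl$strand, intervals = pl$intervals,
              parent = parent, anticodon = anticodon)
  }
  annotated_genome(id, sequence, topology = topology, features = features)
}
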