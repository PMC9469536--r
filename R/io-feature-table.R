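## Tab-separated FeatureTable: the package's lossless serialized annotation.
## Columns: genome_id, name, ftype, strand, intervals ("s1-e1;s2-e2"),
## parent, anticodon, group. Missing values are written as ".".

fmt_na <- function(x) ifelse(is.na(x), ".", x)
parse_na <- function(x) ifelse(x == ".", NA_character_, x)

#' Serialize genome annotations to a feature table
#'
#' @param genomes A single [annotated_genome()] or list of them.
#' @param path Output TSV path; `NULL` returns the data.frame only.
#' @return (Invisibly) the feature table data.frame.
#' @export
write_feature_table <- function(genomes, path = NULL) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    if (!length(g$features))
      return(NULL)
    do.call(rbind, lapply(g$features, function(f) {
      data.frame(genome_id = g$id, name = f$name, ftype = f$ftype,
                 strand = f$strand,
                 intervals = paste(sprintf("%d-%d", f$intervals$start,
                                           f$intervals$end), collapse = ";"),
                 parent = f$parent, anticodon = f$anticodon, group = f$group,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(genome_id = character(), name = character(),
                      ftype = character(), strand = character(),
                      intervals = character(), parent = character(),
                      anticodon = character(), group = character())
  if (!is.null(path)) {
    out <- tab
    for (col in c("parent", "anticodon", "group")) out[[col]] <- fmt_na(out[[col]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' Read a feature table
#'
#' @param path TSV written by [write_feature_table()].
#' @return Feature table data.frame (one row per feature).
#' @export
read_feature_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("genome_id", "name", "ftype", "strand", "intervals",
                "parent", "anticodon", "group")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("feature table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("parent", "anticodon", "group"))
    tab[[col]] <- parse_na(tab[[col]])
  bad <- which(!grepl("^\\d+-\\d+(;\\d+-\\d+)*$", tab$intervals))
  if (length(bad))
    stop("malformed interval string at line ", bad[1L] + 1L, " of ", path,
         ": '", tab$intervals[bad[1L]], "'")
  tab
}

parse_intervals <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  iv <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE),
                              as.integer))
  iv <- as.data.frame(iv); names(iv) <- c("start", "end")
  iv
}

#' Attach feature-table rows to a genome
#'
#' Rebuilds the feature list of `genome` from the rows of `table` whose
#' `genome_id` matches. Together with [write_feature_table()] this
#' round-trips annotations losslessly.
#'
#' @param genome An [annotated_genome()] (features are replaced).
#' @param table Data.frame from [read_feature_table()].
#' @return The genome with features attached.
#' @export
set_features <- function(genome, table) {
  rows <- table[table$genome_id == genome$id, , drop = FALSE]
  feats <- lapply(seq_len(nrow(rows)), function(i)
    feature(rows$name[i], rows$ftype[i], strand = rows$strand[i],
            intervals = parse_intervals(rows$intervals[i]),
            parent = rows$parent[i], anticodon = rows$anticodon[i],
            group = rows$group[i]))
  genome$features <- feats
  validate_genome(genome)
  genome
}
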