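## tRNA arm-level variation: count mutational sites between homologous
## tRNAs of two genomes and attribute each to a cloverleaf structural
## region. Structures are inputs -- a per-tRNA region string aligned to
## the sequence, one code per base:
##   A acceptor stem, D D arm, C anticodon arm, V variable (extra) arm,
##   T T arm, L linker/other.

TRNA_REGIONS <- c(A = "acceptor stem", D = "D arm", C = "anticodon arm",
                  V = "extra arm", T = "T arm", L = "linker")

region_factor <- function() factor(character(), levels = TRNA_REGIONS)

#' Per-position variation calls between two homologous tRNAs
#'
#' The two sequences are aligned globally; a variable site is an aligned
#' column whose residues differ. Indel columns count as variable (unless
#' `count_indels = FALSE`) and are attributed to the region of the
#' structured partner (the nearest 5' region of `a` for columns gapped in
#' `a`).
#'
#' @param a,b tRNA sequences (DNA strings).
#' @param structure_a Region string for `a` (same length as `a`), codes
#'   `A D C V T L`.
#' @param count_indels Count indel columns as variable sites.
#' @return List: `n_variable`, `by_region` (named counts over all six
#'   regions), `calls` (per-column data.frame).
#' @export
compare_trnas <- function(a, b, structure_a, count_indels = TRUE) {
  stopifnot(is_string(a), is_string(b), is_string(structure_a))
  if (nchar(structure_a) != nchar(a))
    stop("structure length ", nchar(structure_a),
         " does not match sequence length ", nchar(a))
  aln <- align_pair(a, b)
  ca <- s2c(aln$a); cb <- s2c(aln$b)
  reg <- s2c(toupper(structure_a))
  if (!all(reg %in% names(TRNA_REGIONS)))
    stop("unknown region code(s): ",
         paste(setdiff(unique(reg), names(TRNA_REGIONS)), collapse = ", "))
  apos <- cumsum(ca != "-")
  ## region of each column: region of the a-residue, or for columns gapped
  ## in a the nearest a-residue 5' of the gap (first column falls back to
  ## the first residue's region)
  col_region <- reg[pmax(apos, 1L)]
  variable <- ca != cb
  if (!count_indels) variable <- variable & ca != "-" & cb != "-"
  by_region <- table(factor(TRNA_REGIONS[col_region[variable]],
                            levels = TRNA_REGIONS))
  list(n_variable = sum(variable),
       by_region = by_region,
       calls = data.frame(column = seq_along(ca), a = ca, b = cb,
                          region = TRNA_REGIONS[col_region],
                          variable = variable, stringsAsFactors = FALSE))
}

#' tRNA variation report between two genomes
#'
#' Matches the tRNA sets of the two genomes by name and anticodon
#' (multi-copy tRNAs by genome-order ordinal), runs [compare_trnas()] on
#' each matched pair, and aggregates variable-site counts per cloverleaf
#' region. Unmatched tRNAs are reported separately with a warning.
#'
#' @param genome_a,genome_b [annotated_genome()] objects.
#' @param structures_a Named list of region strings for the tRNAs of
#'   `genome_a`; names are `"<trn>(<anticodon>).<copy>"` (e.g.
#'   `"trnM(cat).2"`), `"<trn>(<anticodon>)"`, or plain tRNA names for
#'   single-copy tRNAs. Copy numbers follow genome order within each
#'   name/anticodon pair.
#' @param count_indels Count indel columns as variable sites.
#' @return Object of class `trna_variation_report`: per-tRNA table,
#'   per-region totals and percentages, total variable sites, number of
#'   variable tRNAs, unmatched tRNAs.
#' @export
trna_set_report <- function(genome_a, genome_b, structures_a,
                            count_indels = TRUE) {
  trnas <- function(g) {
    idx <- which(vapply(g$features, `[[`, "", "ftype") == "tRNA")
    feats <- g$features[idx]
    ord <- order(vapply(feats, function(f) min(f$intervals$start), 1L))
    feats <- feats[ord]
    key <- paste0(vapply(feats, `[[`, "", "name"), "(",
                  vapply(feats, `[[`, "", "anticodon"), ")")
    copy <- stats::ave(seq_along(feats), key, FUN = seq_along)
    names(feats) <- paste0(key, ".", copy)
    feats
  }
  fa <- trnas(genome_a); fb <- trnas(genome_b)
  matched <- intersect(names(fa), names(fb))
  if (!length(matched))
    stop("no tRNAs shared between '", genome_a$id, "' and '", genome_b$id, "'")
  unmatched <- union(setdiff(names(fa), matched), setdiff(names(fb), matched))
  if (length(unmatched))
    warning("unmatched tRNA copies excluded: ",
            paste(unmatched, collapse = ", "))
  region_totals <- setNames(numeric(length(TRNA_REGIONS)), TRNA_REGIONS)
  rows <- lapply(matched, function(nm) {
    sa <- feature_sequence(genome_a, fa[[nm]])
    sb <- feature_sequence(genome_b, fb[[nm]])
    struct <- structures_a[[nm]] %||%
      structures_a[[sub("\\.\\d+$", "", nm)]] %||%
      structures_a[[fa[[nm]]$name]]
    if (is.null(struct))
      stop("no structure supplied for tRNA '", nm, "'")
    cmp <- compare_trnas(sa, sb, struct, count_indels = count_indels)
    region_totals <<- region_totals + as.numeric(cmp$by_region)
    data.frame(trna = nm, length_a = nchar(sa), length_b = nchar(sb),
               n_variable = cmp$n_variable, stringsAsFactors = FALSE)
  })
  per_trna <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total <- sum(per_trna$n_variable)
  structure(list(
    per_trna = per_trna,
    region_counts = region_totals,
    region_percent = if (total > 0) 100 * region_totals / total
                     else region_totals,
    total_variable_sites = total,
    n_trnas_compared = length(matched),
    n_trnas_variable = sum(per_trna$n_variable > 0L),
    unmatched = unmatched
  ), class = "trna_variation_report")
}

#' @export
print.trna_variation_report <- function(x, ...) {
  cat(sprintf("%d variable sites in %d of %d compared tRNAs\n",
              x$total_variable_sites, x$n_trnas_variable,
              x$n_trnas_compared))
  for (r in names(x$region_counts))
    cat(sprintf("  %-14s %4d  %6.2f%%\n", r, x$region_counts[[r]],
                x$region_percent[[r]]))
  invisible(x)
}
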