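## End-to-end comparison pipeline: runs every analysis stage on a genome
## set and writes a deterministic report bundle (TSVs, newick, JSON
## summary). Floating-point values in TSVs are fixed to 4 decimals so
## identical inputs give byte-identical outputs.

fmt_num <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.4f", x)) else x
}

write_tsv_fixed <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) fmt_num(col) else col), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-or-more-genome comparison pipeline
#'
#' Produces the report bundle: composition and skews per genome, region
#' partition and (for two genomes) contribution rates, start/stop codons
#' and codon usage, per-gene K2P/Ka/Ks statistics, gene-order comparison,
#' optional Pcl classification (when a reference CDS is given), repeat
#' and tandem-repeat tables, optional tRNA variation (when structures are
#' given), a neighbor-joining tree for three or more genomes, and a JSON
#' summary. With a single genome only the composition sections are
#' produced (with a warning).
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output and returns the bundle only.
#' @param genes Gene set for evolutionary statistics (default core PCGs).
#' @param pcl_reference Optional reference CDS (DNA string) for intron
#'   position-class analysis.
#' @param pcl_host Host gene for Pcl analysis (default `"cox1"`).
#' @param trna_structures Optional named list of tRNA region strings for
#'   the first genome, enabling the tRNA variation report (two genomes).
#' @param repeat_min_len,repeat_min_identity Repeat-finder thresholds.
#' @return (Invisibly) the report bundle as a named list.
#' @export
run_compare <- function(genomes, out_dir = NULL, genes = CORE_PCGS,
                        pcl_reference = NULL, pcl_host = "cox1",
                        trna_structures = NULL,
                        repeat_min_len = 50L, repeat_min_identity = 75) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  if (!length(genomes)) stop("no genomes supplied")
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  single <- length(genomes) == 1L
  if (single)
    warning("single genome supplied; running composition-only mode")

  bundle <- list()

  ## composition + partition
  comp_rows <- lapply(genomes, function(g) {
    cs <- composition_stats(g)
    part <- partition_regions(g)
    data.frame(genome = g$id, length = genome_length(g),
               gc_percent = cs$gc_percent, at_percent = cs$at_percent,
               at_skew = cs$at_skew, gc_skew = cs$gc_skew,
               protein_coding_bp = part$lengths[["protein_coding"]],
               intronic_bp = part$lengths[["intronic"]],
               rna_bp = part$lengths[["rna"]],
               intergenic_bp = part$lengths[["intergenic"]],
               protein_coding_pct = part$percent[["protein_coding"]],
               intronic_pct = part$percent[["intronic"]],
               rna_pct = part$percent[["rna"]],
               intergenic_pct = part$percent[["intergenic"]],
               stringsAsFactors = FALSE)
  })
  bundle$composition <- do.call(rbind, c(comp_rows,
                                         list(make.row.names = FALSE)))

  if (length(genomes) == 2L) {
    pa <- partition_regions(genomes[[1L]])
    pb <- partition_regions(genomes[[2L]])
    bundle$contribution <- contribution_rates(pa, pb)
    ca <- composition_stats(genomes[[1L]])
    cb <- composition_stats(genomes[[2L]])
    bundle$comparison <- data.frame(
      total_size_difference_bp = pb$genome_length - pa$genome_length,
      gc_gap_percent = abs(cb$gc_percent - ca$gc_percent),
      mean_at_percent = mean(c(ca$at_percent, cb$at_percent)))
  }

  if (!single) {
    ## codons
    bundle$start_stop <- do.call(rbind, c(lapply(genomes, function(g) {
      d <- start_stop_codons(g)
      cbind(genome = g$id, d)
    }), list(make.row.names = FALSE)))
    bundle$codon_usage <- do.call(rbind, c(lapply(genomes, function(g) {
      d <- codon_usage(g)
      cbind(genome = g$id, d)
    }), list(make.row.names = FALSE)))

    ## per-gene evolution
    bundle$gene_stats <- per_gene_stats(genomes, genes = genes)

    ## gene order
    orders <- lapply(genomes, extract_order)
    if (length(genomes) == 2L) {
      rep2 <- compare_orders(orders[[1L]], orders[[2L]])
      bundle$gene_order <- data.frame(
        gene = c(rep2$backbone, rep2$displaced),
        status = c(rep_len("backbone", length(rep2$backbone)),
                   rep_len("displaced", length(rep2$displaced))),
        stringsAsFactors = FALSE)
      bundle$rearrangement <- rep2
    } else {
      bundle$gene_order <- multi_order_summary(orders)
    }

    ## Pcls
    if (!is.null(pcl_reference)) {
      bundle$pcl <- classify_pcls(genomes, pcl_host, pcl_reference)
      bundle$pcl_sharing <- pcl_sharing_summary(bundle$pcl)
    }

    ## tRNA variation (pairwise)
    if (!is.null(trna_structures) && length(genomes) == 2L)
      bundle$trna <- trna_set_report(genomes[[1L]], genomes[[2L]],
                                     trna_structures)

    ## tree
    if (length(genomes) >= 3L) {
      D <- k2p_distance_matrix(genomes, genes = genes)
      bundle$distances <- D
      if (!anyNA(D)) bundle$tree <- nj_tree(D)
    }
  }

  ## repeats per genome
  bundle$repeats <- do.call(rbind, c(lapply(genomes, function(g) {
    h <- find_interspersed_repeats(g, min_len = repeat_min_len,
                                   min_identity = repeat_min_identity)
    if (!nrow(h)) return(NULL)
    cbind(genome = g$id, h)
  }), list(make.row.names = FALSE)))
  bundle$repeat_fraction <- data.frame(
    genome = ids,
    repeat_percent = vapply(genomes, function(g) {
      h <- find_interspersed_repeats(g, min_len = repeat_min_len,
                                     min_identity = repeat_min_identity)
      repeat_fraction(h, genome_length(g))
    }, 1))
  bundle$tandem <- do.call(rbind, c(lapply(genomes, function(g) {
    h <- find_tandem_repeats(g)
    if (!nrow(h)) return(NULL)
    cbind(genome = g$id, h)
  }), list(make.row.names = FALSE)))

  ## write bundle
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(name, df) if (!is.null(df) && nrow(df))
      write_tsv_fixed(df, file.path(out_dir, paste0(name, ".tsv")))
    w("composition", bundle$composition)
    if (!is.null(bundle$contribution))
      w("contribution", bundle$contribution$table)
    if (!is.null(bundle$comparison)) w("comparison", bundle$comparison)
    w("start_stop", bundle$start_stop)
    w("codon_usage", bundle$codon_usage)
    w("gene_stats", bundle$gene_stats)
    w("gene_order", bundle$gene_order)
    w("repeats", bundle$repeats)
    w("repeat_fraction", bundle$repeat_fraction)
    w("tandem", bundle$tandem)
    if (!is.null(bundle$pcl)) {
      w("pcl_introns", bundle$pcl$introns)
      w("pcl_classes", bundle$pcl$pcls)
    }
    if (!is.null(bundle$trna)) {
      w("trna_per_gene", bundle$trna$per_trna)
      regions <- data.frame(region = names(bundle$trna$region_counts),
                            count = as.integer(bundle$trna$region_counts),
                            percent = as.numeric(bundle$trna$region_percent))
      w("trna_regions", regions)
    }
    if (!is.null(bundle$tree))
      ape::write.tree(bundle$tree, file.path(out_dir, "tree.nwk"))
    summary <- list(
      genomes = ids,
      lengths = setNames(vapply(genomes, genome_length, 1L), ids),
      gc_percent = setNames(bundle$composition$gc_percent, ids),
      total_size_difference_bp =
        if (!is.null(bundle$comparison))
          bundle$comparison$total_size_difference_bp else NULL,
      sections = names(bundle))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}
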