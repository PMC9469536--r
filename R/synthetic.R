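## Synthetic annotated mitogenomes with planted ground truth. The
## generator emulates the architecture of a mid-sized fungal
## (Phallomycetidae-like) mitogenome: the 15 core PCGs plus the two
## rRNAs (rns, rnl) and a 25-tRNA set on a circular molecule, group I/II
## introns inserted at named coding positions (some carrying intronic
## ORFs), intergenic spacers at a target GC, planted interspersed
## repeats, and a single 1-bp gene overlap between nad4L and nad5.
## diverge() derives a sister genome by per-site substitution at stated
## transition/transversion rates (coding sites constrained to keep genes
## translatable under code 4), intergenic indels, intron gain/loss and
## gene move/duplication edits, recording every event.

PCG_LENGTHS <- c(atp6 = 762, atp8 = 147, atp9 = 225, cob = 1164,
                 cox1 = 1608, cox2 = 750, cox3 = 810, nad1 = 954,
                 nad2 = 1650, nad3 = 414, nad4 = 1461, nad4L = 270,
                 nad5 = 1983, nad6 = 603, rps3 = 1506)

## the 25-tRNA complement: 2 isoacceptors for Arg/Ser/Leu, 3 copies of
## trnM, one tRNA for each other amino acid
TRNA_SET <- data.frame(
  instance = c("trnA.1", "trnC.1", "trnD.1", "trnE.1", "trnF.1", "trnG.1",
               "trnH.1", "trnI.1", "trnK.1", "trnL.1", "trnL.2", "trnM.1",
               "trnM.2", "trnM.3", "trnN.1", "trnP.1", "trnQ.1", "trnR.1",
               "trnR.2", "trnS.1", "trnS.2", "trnT.1", "trnV.1", "trnW.1",
               "trnY.1"),
  name = c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
           "trnK", "trnL", "trnL", "trnM", "trnM", "trnM", "trnN", "trnP",
           "trnQ", "trnR", "trnR", "trnS", "trnS", "trnT", "trnV", "trnW",
           "trnY"),
  anticodon = c("tgc", "gca", "gtc", "ttc", "gaa", "tcc", "gtg", "gat",
                "ttt", "taa", "tag", "cat", "cat", "cat", "gtt", "tgg",
                "ttg", "acg", "tct", "gct", "tga", "tgt", "tac", "tca",
                "gta"),
  ## trnS(tga) and trnL(tag) carry large extra (variable) arms
  extra_arm = c(5, 4, 5, 4, 5, 4, 5, 4, 5, 4, 18, 5, 5, 5, 4, 5, 4, 5,
                4, 5, 18, 4, 5, 4, 5),
  stringsAsFactors = FALSE
)

DEFAULT_ORDER <- c(
  "cox1", "trnR.1", "nad6", "trnM.1", "rns", "trnW.1", "cox2", "trnA.1",
  "trnE.1", "atp9", "cox3", "trnT.1", "atp8", "nad4L", "nad5", "trnQ.1",
  "nad1", "trnI.1", "trnM.2", "cob", "rps3", "trnY.1", "nad2", "trnL.1",
  "trnF.1", "rnl", "trnV.1", "trnG.1", "atp6", "trnC.1", "trnD.1",
  "trnS.1", "nad3", "trnL.2", "trnH.1", "nad4", "trnK.1", "trnM.3",
  "trnN.1", "trnP.1", "trnR.2", "trnS.2")

DEFAULT_INTRON_PLAN <- data.frame(
  host = c("cox1", "cox1", "cox1", "cob", "cob", "rnl", "rnl", "nad5",
           "cox2", "nad1"),
  position = c(612L, 706L, 821L, 393L, 795L, 1210L, 2455L, 910L, 384L,
               540L),
  length = c(1200L, 1050L, 980L, 1100L, 900L, 1250L, 1000L, 950L, 870L,
             1020L),
  group = c("I", "I", "I", "I", "II", "I", "I", "I", "I", "I"),
  orf = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Specification of a synthetic mitogenome
#'
#' Defaults describe a mid-sized fungal mitogenome: all 15 core PCGs, the
#' two rRNAs, the 25-tRNA complement (three trnM copies; two isoacceptors
#' each for Arg, Ser, Leu), ten group I/II introns with intronic ORFs in
#' named host genes, two planted interspersed repeats, a 1-bp overlap
#' between nad4L and nad5, AT-rich base composition (GC 0.29) and
#' sister-genome divergence at transition/transversion rates 0.02/0.01.
#'
#' @param seed RNG seed; all stochastic choices derive from it.
#' @param genome_length_target Target molecule size (bp).
#' @param core_pcgs Core protein-coding genes to include.
#' @param pcg_lengths Named CDS lengths (bp, multiples of 3, incl. stop).
#' @param rrnas Named lengths of `rns` and `rnl`.
#' @param trnas Data.frame like `TRNA_SET` (instance, name, anticodon,
#'   extra_arm).
#' @param gene_order Circular arrangement (instance ids).
#' @param minus_strand Instances placed on the minus strand.
#' @param intron_plan Data.frame: host, position (nt in host coding
#'   sequence), length, group, orf.
#' @param repeat_plan Data.frame: length, copies, identity (percent).
#' @param overlap_plan List `(gene_a, gene_b, bp)`; `gene_b` must follow
#'   `gene_a` in `gene_order`.
#' @param divergence Named rates `c(ts=, tv=, indel=)` used by
#'   [diverge()].
#' @param intron_gain,intron_loss,rearrangements Edit plans applied by
#'   [diverge()] (see its documentation).
#' @param gc Target GC fraction of generated sequence.
#' @param start_codons Named per-gene start-codon overrides (default ATG).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           genome_length_target = 52000L,
                           core_pcgs = CORE_PCGS,
                           pcg_lengths = PCG_LENGTHS,
                           rrnas = c(rns = 1673L, rnl = 3720L),
                           trnas = TRNA_SET,
                           gene_order = NULL,
                           minus_strand = c("nad6", "trnW.1", "trnC.1"),
                           intron_plan = DEFAULT_INTRON_PLAN,
                           repeat_plan = data.frame(length = c(80L, 60L),
                                                    copies = c(2L, 2L),
                                                    identity = c(100, 95)),
                           overlap_plan = list(gene_a = "nad4L",
                                               gene_b = "nad5", bp = 1L),
                           divergence = c(ts = 0.02, tv = 0.01,
                                          indel = 0.001),
                           intron_gain = NULL, intron_loss = NULL,
                           rearrangements = NULL,
                           gc = 0.29,
                           start_codons = character()) {
  if (is.null(gene_order)) {
    gene_order <- DEFAULT_ORDER
    gene_order <- gene_order[gene_order %in%
                               c(core_pcgs, names(rrnas), trnas$instance)]
  }
  if (any(divergence < 0) || any(divergence[c("ts", "tv")] > 1))
    stop("divergence rates must lie in [0, 1]")
  if (!is.null(intron_plan) && nrow(intron_plan)) {
    bad <- intron_plan$host %in% core_pcgs &
      intron_plan$position > pcg_lengths[intron_plan$host]
    if (any(bad, na.rm = TRUE))
      stop("intron insertion position beyond host coding length: ",
           paste(intron_plan$host[which(bad)], collapse = ", "))
  }
  structure(list(seed = seed, genome_length_target = genome_length_target,
                 core_pcgs = core_pcgs, pcg_lengths = pcg_lengths,
                 rrnas = rrnas, trnas = trnas, gene_order = gene_order,
                 minus_strand = minus_strand, intron_plan = intron_plan,
                 repeat_plan = repeat_plan, overlap_plan = overlap_plan,
                 divergence = divergence, intron_gain = intron_gain,
                 intron_loss = intron_loss, rearrangements = rearrangements,
                 gc = gc, start_codons = start_codons),
            class = "synthetic_spec")
}

codon_sampler <- function(gc, code) {
  sense <- names(code$map)[code$map != "*"]
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(sense, function(cd) prod(pb[s2c(cd)]), 1)
  list(codons = sense, prob = w / sum(w))
}

random_cds <- function(len, gc, code, start = "ATG", stop_codon = NULL) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  cs <- codon_sampler(gc, code)
  internal <- sample(cs$codons, len / 3L - 2L, replace = TRUE,
                     prob = cs$prob)
  stop_cd <- stop_codon %||% sample(c("TAA", "TAG"), 1L, prob = c(0.7, 0.3))
  paste0(start, c2s(internal), stop_cd)
}

## cloverleaf template: acceptor 7, linker 2, D arm 16, linker 1,
## anticodon arm 17 (anticodon at overall positions 34-36), extra arm,
## T arm 17, acceptor 7, discriminator 1
build_trna <- function(anticodon, extra_arm, gc) {
  structure_str <- paste0(strrep("A", 7), strrep("L", 2), strrep("D", 16),
                          "L", strrep("C", 17), strrep("V", extra_arm),
                          strrep("T", 17), strrep("A", 7), "L")
  len <- nchar(structure_str)
  seqv <- s2c(random_dna(len, gc))
  seqv[34:36] <- s2c(toupper(anticodon))
  list(seq = c2s(seqv), structure = structure_str)
}

## build one ordered element (gene with any introns) in coding
## orientation; returns seq plus relative feature records
build_element <- function(inst, spec, code) {
  base <- sub("\\.\\d+$", "", inst)
  strand <- if (inst %in% spec$minus_strand) "-" else "+"
  feats <- list()
  structure_str <- NULL
  if (base %in% spec$core_pcgs) {
    start <- toupper(spec$start_codons[base])
    if (is.na(start)) start <- "ATG"
    ## the overlap donor ends in TAA so its final A doubles as the first
    ## base of the downstream gene's ATG
    stop_codon <- if (!is.null(spec$overlap_plan) &&
                      identical(base, spec$overlap_plan$gene_a)) "TAA"
                  else NULL
    cds <- random_cds(spec$pcg_lengths[[base]], spec$gc, code,
                      start = start, stop_codon = stop_codon)
    plan <- spec$intron_plan
    plan <- if (!is.null(plan)) plan[plan$host == base, , drop = FALSE]
    el <- splice_in_introns(base, cds, plan, spec$gc, code, ftype = "PCG")
    seqc <- el$seq; feats <- el$features
  } else if (base %in% names(spec$rrnas)) {
    rna <- random_dna(spec$rrnas[[base]], spec$gc)
    plan <- spec$intron_plan
    plan <- if (!is.null(plan)) plan[plan$host == base, , drop = FALSE]
    el <- splice_in_introns(base, rna, plan, spec$gc, code, ftype = "rRNA")
    seqc <- el$seq; feats <- el$features
  } else { # tRNA instance
    row <- spec$trnas[spec$trnas$instance == inst, , drop = FALSE]
    if (nrow(row) != 1L) stop("unknown element '", inst, "' in gene order")
    tr <- build_trna(row$anticodon, row$extra_arm, spec$gc)
    seqc <- tr$seq
    structure_str <- tr$structure
    feats <- list(list(name = row$name, ftype = "tRNA",
                       rel = data.frame(start = 1L, end = nchar(seqc)),
                       parent = NA_character_, anticodon = row$anticodon,
                       group = NA_character_))
  }
  list(seq = seqc, strand = strand, features = feats,
       structure = structure_str)
}

## insert planned introns into a coding/transcript sequence; relative
## coordinates are in coding orientation
splice_in_introns <- function(gene, cds, plan, gc, code, ftype) {
  feats <- list()
  if (is.null(plan) || !nrow(plan)) {
    feats[[1L]] <- list(name = gene, ftype = ftype,
                        rel = data.frame(start = 1L, end = nchar(cds)),
                        parent = NA_character_, anticodon = NA_character_,
                        group = NA_character_)
    return(list(seq = cds, features = feats))
  }
  plan <- plan[order(plan$position), , drop = FALSE]
  pieces <- character()
  exon_rel <- NULL
  offset <- 0L
  prev <- 0L
  intron_feats <- list()
  for (k in seq_len(nrow(plan))) {
    exon <- substr(cds, prev + 1L, plan$position[k])
    pieces <- c(pieces, exon)
    exon_rel <- rbind(exon_rel,
                      c(offset + 1L, offset + nchar(exon)))
    offset <- offset + nchar(exon)
    ilen <- plan$length[k]
    iseq <- random_dna(ilen, gc)
    orf_rel <- NULL
    if (isTRUE(plan$orf[k]) && ilen >= 240L) {
      olen <- 3L * ((min(ilen - 60L, 600L)) %/% 3L)
      ostart <- 21L
      oseq <- random_cds(olen, gc, code)
      iseq <- paste0(substr(iseq, 1L, ostart - 1L), oseq,
                     substr(iseq, ostart + olen, ilen))
      orf_rel <- c(offset + ostart, offset + ostart + olen - 1L)
    }
    pieces <- c(pieces, iseq)
    intron_feats[[length(intron_feats) + 1L]] <- list(
      name = paste0(gene, ".i", k), ftype = "intron",
      rel = data.frame(start = offset + 1L, end = offset + nchar(iseq)),
      parent = gene, anticodon = NA_character_, group = plan$group[k])
    if (!is.null(orf_rel))
      intron_feats[[length(intron_feats) + 1L]] <- list(
        name = paste0(gene, ".i", k, ".orf"), ftype = "intronic_ORF",
        rel = data.frame(start = orf_rel[1L], end = orf_rel[2L]),
        parent = gene, anticodon = NA_character_, group = NA_character_)
    offset <- offset + nchar(iseq)
    prev <- plan$position[k]
  }
  last <- substr(cds, prev + 1L, nchar(cds))
  pieces <- c(pieces, last)
  exon_rel <- rbind(exon_rel, c(offset + 1L, offset + nchar(last)))
  exon_rel <- as.data.frame(exon_rel)
  names(exon_rel) <- c("start", "end")
  feats[[1L]] <- list(name = gene, ftype = ftype, rel = exon_rel,
                      parent = NA_character_, anticodon = NA_character_,
                      group = NA_character_)
  list(seq = c2s(pieces), features = c(feats, intron_feats))
}

## map relative (coding-orientation) intervals of an element of length L
## starting at genomic offset `pos` to genome coordinates
rel_to_genomic <- function(rel, strand, L, pos) {
  if (strand == "+") {
    data.frame(start = pos + rel$start, end = pos + rel$end)
  } else {
    data.frame(start = pos + (L - rel$end + 1L),
               end = pos + (L - rel$start + 1L))
  }
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic for a fixed seed: builds every gene, intron and spacer
#' from a single RNG stream in documented order and assembles the circular
#' molecule. All planted structures are returned as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param id Genome id.
#' @return List with `genome` (an [annotated_genome()]) and
#'   `ground_truth` (feature table, planted region lengths, intron table,
#'   repeat copies, tRNA structures, per-element layout).
#' @export
generate_genome <- function(spec, id = "synthA") {
  code <- genetic_code_4()
  with_seed(spec$seed, {
    elements <- lapply(spec$gene_order, build_element, spec = spec,
                       code = code)
    names(elements) <- spec$gene_order
    el_len <- vapply(elements, function(e) nchar(e$seq), 1L)
    overlap_bp <- 0L
    ov <- spec$overlap_plan
    ov_idx <- NA_integer_
    if (!is.null(ov)) {
      ia <- match(ov$gene_a, spec$gene_order)
      ib <- match(ov$gene_b, spec$gene_order)
      if (is.na(ia) || is.na(ib) || ib != ia + 1L)
        stop("overlap_plan genes must be adjacent in gene_order")
      if (ov$gene_a %in% spec$minus_strand ||
          ov$gene_b %in% spec$minus_strand)
        stop("overlap_plan genes must lie on the plus strand")
      overlap_bp <- as.integer(ov$bp)
      ov_idx <- ib
    }
    n_gaps <- length(elements) - as.integer(!is.na(ov_idx))
    budget <- spec$genome_length_target - sum(el_len) + overlap_bp
    if (budget < 2L * n_gaps)
      stop("infeasible packing: features exceed genome_length_target")
    active <- setdiff(seq_along(elements), ov_idx)
    gap_sizes <- integer(length(elements))
    gap_sizes[active] <-
      as.integer(stats::rmultinom(1L, budget - 2L * n_gaps,
                                  rep(1, n_gaps))) + 2L
    ## gap i precedes element i
    gap_seqs <- vapply(gap_sizes, random_dna, "", gc = spec$gc)

    ## plant interspersed repeats inside intergenic gaps
    repeat_truth <- NULL
    if (!is.null(spec$repeat_plan) && nrow(spec$repeat_plan)) {
      rp <- spec$repeat_plan
      for (r in seq_len(nrow(rp))) {
        len <- rp$length[r]; copies <- rp$copies[r]
        unit <- random_dna(len, spec$gc)
        eligible <- which(gap_sizes >= len + 4L)
        if (length(eligible) < copies)
          stop("infeasible packing: not enough intergenic room for repeats")
        slots <- sample(eligible, copies)
        for (ci in seq_along(slots)) {
          gi <- slots[ci]
          copy_seq <- unit
          if (rp$identity[r] < 100) {
            nmut <- round(len * (1 - rp$identity[r] / 100))
            if (ci > 1L && nmut > 0L) {
              pos <- sample(len, nmut)
              cv <- s2c(copy_seq)
              for (p in pos)
                cv[p] <- sample(setdiff(c("A", "C", "G", "T"), cv[p]), 1L)
              copy_seq <- c2s(cv)
            }
          }
          g <- gap_seqs[gi]
          gap_seqs[gi] <- paste0(substr(g, 1L, 2L), copy_seq,
                                 substr(g, 3L + len, nchar(g)))
          repeat_truth <- rbind(repeat_truth,
                                data.frame(repeat_id = r, copy = ci,
                                           gap_index = gi, gap_offset = 3L,
                                           length = len,
                                           identity = if (ci == 1L) 100
                                                      else rp$identity[r]))
        }
        ## mark slots used so two repeats do not collide in one gap
        gap_sizes[slots] <- 0L
      }
    }

    ## assemble
    seq_parts <- character()
    features <- list()
    structures <- list()
    trna_copy_count <- list()
    layout <- NULL
    pos <- 0L
    planted <- c(protein_coding = 0, intronic = 0, rna = 0, intergenic = 0)
    for (i in seq_along(elements)) {
      inst <- spec$gene_order[i]
      el <- elements[[i]]
      gseq <- gap_seqs[i]
      prev_inst <- spec$gene_order[if (i == 1L) length(elements) else i - 1L]
      overlap_here <- !is.null(ov) && identical(prev_inst, ov$gene_a) &&
        identical(inst, ov$gene_b)
      if (overlap_here) {
        gseq <- ""
      }
      seq_parts <- c(seq_parts, gseq)
      planted["intergenic"] <- planted["intergenic"] + nchar(gseq)
      pos <- pos + nchar(gseq)
      L <- nchar(el$seq)
      emitted <- if (el$strand == "+") el$seq else revcomp(el$seq)
      start_off <- pos
      if (overlap_here) {
        ## gene_b starts on the final base(s) of gene_a
        emitted <- substr(emitted, overlap_bp + 1L, L)
        start_off <- pos - overlap_bp
      }
      seq_parts <- c(seq_parts, emitted)
      for (f in el$features) {
        iv <- rel_to_genomic(f$rel, el$strand, L, start_off)
        features[[length(features) + 1L]] <-
          feature(f$name, f$ftype, strand = el$strand, intervals = iv,
                  parent = f$parent, anticodon = f$anticodon,
                  group = f$group)
        bases <- sum(iv$end - iv$start + 1L)
        cls <- switch(f$ftype, PCG = "protein_coding",
                      free_ORF = "protein_coding",
                      rRNA = "rna", tRNA = "rna", NULL)
        if (!is.null(cls)) planted[cls] <- planted[cls] + bases
      }
      ## intron bases = element length minus exon bases
      exon_bases <- sum(vapply(el$features, function(f)
        if (f$ftype %in% c("PCG", "rRNA", "tRNA"))
          sum(f$rel$end - f$rel$start + 1L) else 0L, 1L))
      planted["intronic"] <- planted["intronic"] + (L - exon_bases)
      if (!is.null(el$structure)) {
        f1 <- el$features[[1L]]
        base_key <- paste0(f1$name, "(", f1$anticodon, ")")
        trna_copy_count[[base_key]] <- (trna_copy_count[[base_key]] %||% 0L) + 1L
        structures[[paste0(base_key, ".", trna_copy_count[[base_key]])]] <-
          el$structure
      }
      layout <- rbind(layout, data.frame(instance = inst,
                                         start = start_off + 1L,
                                         end = start_off + L,
                                         strand = el$strand))
      pos <- start_off + L
    }
    planted["protein_coding"] <- planted["protein_coding"] - overlap_bp
    genome <- annotated_genome(id, c2s(seq_parts), topology = "circular",
                               features = features)

    ## resolve planted repeat copy coordinates from the layout
    if (!is.null(repeat_truth)) {
      gap_start <- integer(nrow(layout))
      p <- 0L
      for (i in seq_along(elements)) {
        gap_start[i] <- p + 1L
        p <- layout$end[i]
      }
      repeat_truth$start <- gap_start[repeat_truth$gap_index] +
        repeat_truth$gap_offset - 1L
      repeat_truth$end <- repeat_truth$start + repeat_truth$length - 1L
      repeat_truth$gap_index <- NULL
      repeat_truth$gap_offset <- NULL
    }

    intron_table <- do.call(rbind, lapply(
      unique(c(spec$intron_plan$host)), function(h) {
        if (!h %in% feature_names(genome)) return(NULL)
        intron_positions(genome, h)
      }))

    list(genome = genome,
         ground_truth = list(
           spec = spec,
           feature_table = write_feature_table(genome),
           region_lengths = planted,
           intron_table = intron_table,
           repeats = repeat_truth,
           trna_structures = structures,
           layout = layout))
  })
}
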