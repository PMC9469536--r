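## Derivation of a sister genome from a generated mitogenome: per-site
## substitutions at stated transition/transversion rates (coding sites
## constrained so genes stay translatable under code 4), intergenic
## indels, intron gain/loss, and gene move/duplication edits. Every
## event is recorded in the returned ground truth.

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

## ---- coordinate-shifting edits --------------------------------------

## insert `ins` after position `at` (0 <= at <= n); features entirely
## 3' of the insertion point shift right. Callers must ensure no feature
## interval spans the insertion point (split exons first).
genome_insert <- function(genome, at, ins) {
  L <- nchar(ins)
  if (L == 0L) return(genome)
  n <- genome_length(genome)
  genome$sequence <- paste0(substr(genome$sequence, 1L, at), ins,
                            substr(genome$sequence, at + 1L, n))
  genome$features <- lapply(genome$features, function(f) {
    if (any(f$intervals$start > f$intervals$end))
      stop("cannot edit a genome with wrapped feature intervals")
    if (any(f$intervals$start <= at & f$intervals$end > at))
      stop("insertion point ", at, " splits feature '", f$name, "'")
    f$intervals$start <- ifelse(f$intervals$start > at,
                                f$intervals$start + L, f$intervals$start)
    f$intervals$end <- ifelse(f$intervals$end > at,
                              f$intervals$end + L, f$intervals$end)
    f
  })
  genome
}

## delete [from, to]; features entirely inside the range are removed,
## partial overlaps are an error
genome_delete <- function(genome, from, to) {
  n <- genome_length(genome)
  stopifnot(from >= 1L, to <= n, from <= to)
  L <- to - from + 1L
  keep <- vapply(genome$features, function(f) {
    inside <- f$intervals$start >= from & f$intervals$end <= to
    if (all(inside)) return(FALSE)
    if (any(f$intervals$start <= to & f$intervals$end >= from))
      stop("deletion [", from, ",", to, "] cuts feature '", f$name, "'")
    TRUE
  }, TRUE)
  genome$features <- genome$features[keep]
  genome$features <- lapply(genome$features, function(f) {
    f$intervals$start <- ifelse(f$intervals$start > to,
                                f$intervals$start - L, f$intervals$start)
    f$intervals$end <- ifelse(f$intervals$end > to,
                              f$intervals$end - L, f$intervals$end)
    f
  })
  genome$sequence <- paste0(substr(genome$sequence, 1L, from - 1L),
                            substr(genome$sequence, to + 1L, n))
  genome
}

## genome positions of a feature's bases in coding (5'->3') order
coding_genome_positions <- function(f, n) {
  unlist(lapply(seq_len(nrow(f$intervals)), function(i) {
    p <- interval_positions(f$intervals$start[i], f$intervals$end[i], n)
    if (f$strand == "-") rev(p) else p
  }))
}

## per-position class vector: 0 intergenic, 1 intron, 2 pcg exon, 3 rna;
## plus pcg exon coverage counts
position_classes <- function(genome) {
  n <- genome_length(genome)
  cls <- integer(n)
  cov <- integer(n)
  for (f in genome$features) {
    pos <- feature_span_positions(f, n)
    if (f$ftype %in% c("intron", "intronic_ORF")) cls[pos] <- 1L
  }
  for (f in genome$features) {
    if (!f$ftype %in% c("PCG", "free_ORF")) next
    pos <- feature_span_positions(f, n)
    cls[pos] <- 2L
    cov[pos] <- cov[pos] + 1L
  }
  for (f in genome$features) {
    if (!f$ftype %in% c("rRNA", "tRNA")) next
    cls[feature_span_positions(f, n)] <- 3L
  }
  list(cls = cls, cov = cov)
}

mutate_base <- function(base, type) {
  if (type == "ts") TRANSITION[[base]]
  else sample(setdiff(c("A", "C", "G", "T"),
                      c(base, TRANSITION[[base]])), 1L)
}

## apply substitutions to one protein-coding gene, rejecting changes that
## break translatability (internal stop, invalid start, lost stop);
## rejected changes are resampled among the remaining bases
mutate_pcg <- function(chars, f, n, sel_sites, sel_type, cov, code) {
  gpos <- coding_genome_positions(f, n)
  cds <- chars[gpos]
  if (f$strand == "-") cds <- unname(COMPLEMENT[cds])
  ncod <- length(cds) %/% 3L
  hit <- which(gpos %in% sel_sites & cov[gpos] == 1L)
  events <- NULL
  for (ci in hit) {
    type <- sel_type[[as.character(gpos[ci])]]
    old <- cds[ci]
    cand <- mutate_base(old, type)
    alts <- sample(setdiff(c("A", "C", "G", "T"), c(old, cand)))
    codon_i <- (ci - 1L) %/% 3L + 1L
    valid <- function(b) {
      cd <- cds[(3L * codon_i - 2L):(3L * codon_i)]
      cd[(ci - 1L) %% 3L + 1L] <- b
      cd <- c2s(cd)
      if (codon_i == ncod) return(cd %in% code$stops)
      if (codon_i == 1L) return(cd %in% code$starts)
      code$map[[cd]] != "*"
    }
    accepted <- NA_character_
    for (b in c(cand, alts)) if (valid(b)) { accepted <- b; break }
    if (is.na(accepted)) next
    aa_before <- code$map[[c2s(cds[(3L * codon_i - 2L):(3L * codon_i)])]]
    cds[ci] <- accepted
    aa_after <- code$map[[c2s(cds[(3L * codon_i - 2L):(3L * codon_i)])]]
    actual_type <- if (accepted == TRANSITION[[old]]) "ts" else "tv"
    events <- rbind(events, data.frame(
      gene = f$name, coding_pos = ci, genome_pos = gpos[ci],
      from = old, to = accepted, type = actual_type,
      synonymous = aa_before == aa_after, stringsAsFactors = FALSE))
  }
  out <- cds
  if (f$strand == "-") out <- unname(COMPLEMENT[out])
  chars[gpos] <- out
  list(chars = chars, events = events)
}

## genomic span of a gene block: the gene feature plus its introns and
## intronic ORFs
gene_block_span <- function(genome, gene, copy = 1L) {
  idx <- which_features(genome, gene, GENE_LIKE)
  if (!length(idx)) stop("gene '", gene, "' not found")
  if (copy > length(idx)) stop("gene '", gene, "' has no copy ", copy)
  f <- genome$features[[idx[copy]]]
  members <- idx[copy]
  kids <- which(vapply(genome$features, function(x)
    identical(x$parent, gene), TRUE))
  ## keep only children genomically inside this copy's extent
  ext <- range(c(f$intervals$start, f$intervals$end))
  kids <- kids[vapply(genome$features[kids], function(x)
    min(x$intervals$start) >= ext[1L] && max(x$intervals$end) <= ext[2L],
    TRUE)]
  members <- sort(unique(c(members, kids)))
  spans <- unlist(lapply(genome$features[members], function(x)
    c(x$intervals$start, x$intervals$end)))
  list(from = min(spans), to = max(spans), members = members)
}

#' Derive a diverged sister genome
#'
#' Applies, in order: per-site substitutions at the spec's
#' transition/transversion rates (protein-coding sites are constrained to
#' keep the start codon valid, the stop codon a stop, and no internal
#' stops under genetic code 4; blocked changes are resampled among the
#' remaining bases, and the single overlap base shared by two genes is
#' left untouched), planned intron losses and gains, intergenic indels at
#' the spec's per-site rate, and planned gene move/duplication edits.
#'
#' @param genome An [annotated_genome()] from [generate_genome()]
#'   (features must not wrap the origin).
#' @param spec A [synthetic_spec()]; fields used: `seed`, `divergence`
#'   (`ts`, `tv`, `indel`), `intron_loss` (data.frame host, ordinal),
#'   `intron_gain` (data.frame host, position, length, group),
#'   `rearrangements` (list of `list(type = "move"|"duplicate", gene =,
#'   after =)`).
#' @param id Id of the derived genome.
#' @return List with `genome` and `ground_truth` (per-gene substitution
#'   counts, full substitution/indel/intron/rearrangement event records).
#' @export
diverge <- function(genome, spec, id = paste0(genome$id, "_sister")) {
  code <- genetic_code_4()
  rates <- spec$divergence
  ts <- unname(rates["ts"]); tv <- unname(rates["tv"])
  indel_rate <- unname(rates["indel"])
  with_seed(spec$seed + 1L, {
    g <- genome
    g$id <- id
    n <- genome_length(g)
    pc <- position_classes(g)
    subs_events <- NULL

    ## ---- substitutions ----
    if (ts + tv > 0) {
      u <- runif(n)
      sel <- which(u < ts + tv)
      sel_type_v <- ifelse(runif(length(sel)) < ts / (ts + tv), "ts", "tv")
      sel_type <- as.list(setNames(sel_type_v, sel))
      chars <- s2c(g$sequence)
      ## coding genes first (each reads the current state)
      for (f in g$features) {
        if (!f$ftype %in% c("PCG", "free_ORF")) next
        res <- mutate_pcg(chars, f, n, sel, sel_type, pc$cov, code)
        chars <- res$chars
        subs_events <- rbind(subs_events, res$events)
      }
      ## non-coding sites
      noncoding <- sel[pc$cls[sel] != 2L]
      for (p in noncoding) {
        old <- chars[p]
        if (!old %in% c("A", "C", "G", "T")) next
        newb <- mutate_base(old, sel_type[[as.character(p)]])
        chars[p] <- newb
        cls_name <- c("intergenic", "intron", "pcg", "rna")[pc$cls[p] + 1L]
        subs_events <- rbind(subs_events, data.frame(
          gene = NA_character_, coding_pos = NA_integer_, genome_pos = p,
          from = old, to = newb,
          type = sel_type[[as.character(p)]],
          synonymous = NA, stringsAsFactors = FALSE))
      }
      g$sequence <- c2s(chars)
    }

    ## ---- intron losses ----
    loss_events <- NULL
    if (!is.null(spec$intron_loss) && nrow(spec$intron_loss)) {
      for (k in seq_len(nrow(spec$intron_loss))) {
        host <- spec$intron_loss$host[k]
        ordn <- spec$intron_loss$ordinal[k]
        ip <- intron_positions(g, host)
        if (ordn > nrow(ip)) stop("no intron ", ordn, " in '", host, "'")
        iname <- ip$name[ordn]
        ii <- which(feature_names(g) == iname &
                      vapply(g$features, `[[`, "", "ftype") == "intron")[1L]
        intron <- g$features[[ii]]
        from <- min(intron$intervals$start)
        to <- max(intron$intervals$end)
        ## remove the intron (and any ORF inside it), then merge exons
        g$features <- g$features[-ii]
        g <- genome_delete(g, from, to)
        hi <- which_features(g, host, GENE_LIKE)[1L]
        hostf <- g$features[[hi]]
        iv <- hostf$intervals
        j <- which(iv$end == from - 1L)
        j2 <- which(iv$start == from)
        if (length(j) == 1L && length(j2) == 1L) {
          iv$end[j] <- iv$end[j2]
          iv <- iv[-j2, , drop = FALSE]
          hostf$intervals <- iv
          g$features[[hi]] <- hostf
        }
        loss_events <- rbind(loss_events, data.frame(
          host = host, ordinal = ordn, position = ip$position[ordn],
          length = to - from + 1L, stringsAsFactors = FALSE))
      }
    }

    ## ---- intron gains ----
    gain_events <- NULL
    if (!is.null(spec$intron_gain) && nrow(spec$intron_gain)) {
      for (k in seq_len(nrow(spec$intron_gain))) {
        host <- spec$intron_gain$host[k]
        cp <- spec$intron_gain$position[k]
        ilen <- spec$intron_gain$length[k]
        grp <- spec$intron_gain$group[k]
        hi <- which_features(g, host, GENE_LIKE)[1L]
        hostf <- g$features[[hi]]
        gpos <- coding_genome_positions(hostf, genome_length(g))
        if (cp < 1L || cp >= length(gpos))
          stop("intron gain position ", cp, " outside '", host, "' CDS")
        gp <- gpos[cp]
        at <- if (hostf$strand == "+") gp else gp - 1L
        ## split the exon interval containing the boundary
        iv <- hostf$intervals
        row <- which(iv$start <= at & iv$end > at)
        if (length(row) == 1L) {
          pre <- c(iv$start[row], at)
          post <- c(at + 1L, iv$end[row])
          parts <- if (hostf$strand == "+") rbind(pre, post)
                   else rbind(post, pre)
          iv <- rbind(iv[seq_len(row - 1L), , drop = FALSE],
                      data.frame(start = parts[, 1L], end = parts[, 2L]),
                      iv[-seq_len(row), , drop = FALSE])
          hostf$intervals <- iv
          g$features[[hi]] <- hostf
        }
        iseq <- random_dna(ilen, spec$gc)
        gseq <- if (hostf$strand == "+") iseq else revcomp(iseq)
        g <- genome_insert(g, at, gseq)
        g$features[[length(g$features) + 1L]] <-
          feature(paste0(host, ".gained", k), "intron",
                  strand = hostf$strand,
                  intervals = data.frame(start = at + 1L, end = at + ilen),
                  parent = host, group = grp)
        gain_events <- rbind(gain_events, data.frame(
          host = host, position = cp, length = ilen, group = grp,
          stringsAsFactors = FALSE))
      }
    }

    ## ---- intergenic indels ----
    indel_events <- NULL
    if (indel_rate > 0) {
      pc2 <- position_classes(g)
      runs <- rle(pc2$cls == 0L)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ig <- which(runs$values)
      run_tab <- data.frame(start = starts[ig], end = ends[ig])
      total_ig <- sum(run_tab$end - run_tab$start + 1L)
      k <- stats::rbinom(1L, total_ig, indel_rate)
      if (k > 0L) {
        ri <- sample(nrow(run_tab), k, replace = TRUE,
                     prob = run_tab$end - run_tab$start + 1L)
        picks <- data.frame(
          run = ri,
          pos = as.integer(run_tab$start[ri] +
            floor(runif(k) * (run_tab$end[ri] - run_tab$start[ri] + 1L))),
          len = sample(12L, k, replace = TRUE),
          ins = runif(k) < 0.5)
        picks <- picks[order(-picks$pos), , drop = FALSE]
        for (e in seq_len(nrow(picks))) {
          p <- picks$pos[e]; L <- picks$len[e]
          if (picks$ins[e]) {
            ins <- random_dna(L, spec$gc)
            g <- genome_insert(g, p, ins)
            indel_events <- rbind(indel_events, data.frame(
              type = "insertion", position = p, length = L))
          } else {
            to <- min(p + L - 1L, run_tab$end[picks$run[e]])
            if (to < p) next
            g <- genome_delete(g, p, to)
            indel_events <- rbind(indel_events, data.frame(
              type = "deletion", position = p, length = to - p + 1L))
          }
        }
      }
    }

    ## ---- rearrangement edits ----
    rearr_events <- NULL
    if (!is.null(spec$rearrangements)) {
      for (ed in spec$rearrangements) {
        stopifnot(ed$type %in% c("move", "duplicate"))
        blk <- gene_block_span(g, ed$gene, copy = ed$copy %||% 1L)
        blk_seq <- substr(g$sequence, blk$from, blk$to)
        blk_feats <- lapply(g$features[blk$members], function(f) {
          f$intervals$start <- f$intervals$start - blk$from + 1L
          f$intervals$end <- f$intervals$end - blk$from + 1L
          f
        })
        if (ed$type == "move") {
          g$features <- g$features[-blk$members]
          g <- genome_delete(g, blk$from, blk$to)
        }
        tgt <- gene_block_span(g, ed$after)
        at <- tgt$to + 2L  # two spacer bases past the target block
        if (at > genome_length(g)) at <- genome_length(g)
        pcc <- position_classes(g)
        if (pcc$cls[min(at, genome_length(g))] != 0L ||
            pcc$cls[min(at + 1L, genome_length(g))] != 0L) {
          ## walk forward to the next intergenic position
          cand <- which(pcc$cls == 0L)
          cand <- cand[cand > tgt$to]
          if (!length(cand)) cand <- which(pcc$cls == 0L)
          at <- cand[1L]
        }
        g <- genome_insert(g, at, blk_seq)
        for (f in blk_feats) {
          f$intervals$start <- f$intervals$start + at
          f$intervals$end <- f$intervals$end + at
          g$features[[length(g$features) + 1L]] <- f
        }
        rearr_events <- rbind(rearr_events, data.frame(
          type = ed$type, gene = ed$gene, after = ed$after,
          new_start = at + 1L, length = nchar(blk_seq),
          stringsAsFactors = FALSE))
      }
    }

    g$features <- lapply(g$features, function(f) {
      f$intervals$start <- as.integer(f$intervals$start)
      f$intervals$end <- as.integer(f$intervals$end)
      f
    })
    validate_genome(g)
    per_gene <- if (!is.null(subs_events)) {
      coding <- subs_events[!is.na(subs_events$gene), , drop = FALSE]
      if (nrow(coding)) {
        agg <- lapply(split(coding, coding$gene), function(d) data.frame(
          gene = d$gene[1L],
          transitions = sum(d$type == "ts"),
          transversions = sum(d$type == "tv"),
          synonymous = sum(d$synonymous),
          nonsynonymous = sum(!d$synonymous), stringsAsFactors = FALSE))
        do.call(rbind, c(agg, list(make.row.names = FALSE)))
      } else NULL
    } else NULL

    list(genome = g,
         ground_truth = list(
           substitutions = subs_events,
           per_gene = per_gene,
           n_transitions = sum(subs_events$type == "ts"),
           n_transversions = sum(subs_events$type == "tv"),
           intron_losses = loss_events,
           intron_gains = gain_events,
           indels = indel_events,
           rearrangements = rearr_events))
  })
}
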