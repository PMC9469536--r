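test_that("intron insertion positions are cumulative exon lengths", {
  ## exons 300 + 600 with one intron between
  seqc <- strrep("ACGT", 500)  # 2000 bp
  g <- annotated_genome("i1", seqc, features = list(
    feature("h", "PCG", "+", data.frame(start = c(1, 401),
                                        end = c(300, 1000))),
    feature("h.i1", "intron", "+", data.frame(start = 301, end = 400),
            parent = "h", group = "I")))
  ip <- intron_positions(g, "h")
  expect_equal(ip$position, 300L)

  ## three exons 100/200/300: positions 100 and 300
  g2 <- annotated_genome("i2", seqc, features = list(
    feature("h", "PCG", "+", data.frame(start = c(1, 151, 401),
                                        end = c(100, 350, 700))),
    feature("h.i1", "intron", "+", data.frame(start = 101, end = 150),
            parent = "h"),
    feature("h.i2", "intron", "+", data.frame(start = 351, end = 400),
            parent = "h")))
  expect_equal(intron_positions(g2, "h")$position, c(100L, 300L))

  ## intron-free gene: empty record list
  g3 <- annotated_genome("i3", seqc, features = list(
    feature("h", "PCG", "+", data.frame(start = 1, end = 300))))
  expect_equal(nrow(intron_positions(g3, "h")), 0L)

  ## minus-strand host: positions counted on the coding strand
  g4 <- annotated_genome("i4", seqc, features = list(
    feature("h", "PCG", "-", data.frame(start = c(401, 1),
                                        end = c(1000, 300))),
    feature("h.i1", "intron", "-", data.frame(start = 301, end = 400),
            parent = "h")))
  expect_equal(intron_positions(g4, "h")$position, 600L)
})

test_that("positions map through alignments onto the reference", {
  ref <- strrep("ACGTG", 200)  # 1000 nt
  ## identical sequences: identity mapping
  expect_equal(as.integer(map_to_reference(ref, ref, 612)), 612L)
  expect_equal(as.integer(map_to_reference(ref, ref, 0)), 0L)

  ## reference with a 3-nt deletion 5' of the site: ref pos = query - 3
  query <- ref
  ref_del <- paste0(substr(ref, 1, 99), substr(ref, 103, 1000))
  expect_equal(as.integer(map_to_reference(query, ref_del, 612)), 609L)

  ## query insertion relative to the reference: site inside the ref gap
  ## maps to the nearest reference position 5' of the gap, flagged
  q_ins <- paste0(substr(ref, 1, 200), "TTTTTTTT", substr(ref, 201, 1000))
  m <- map_to_reference(q_ins, ref, 204)
  expect_equal(as.integer(m), 200L)
  expect_true(attr(m, "in_ref_gap"))

  expect_error(map_to_reference(ref, ref, 1200), "outside")

  ## monotone in the query position for a fixed alignment
  aln <- align_pair(q_ins, ref)
  mapped <- vapply(0:250, function(p)
    as.integer(map_to_reference(NULL, NULL, p, alignment = aln)), 1L)
  expect_true(all(diff(mapped) >= 0))
})

test_that("classification groups introns by mapped position", {
  base <- generate_genome(small_spec(41))
  g <- base$genome
  ref <- coding_sequence(g, "cox1")
  ## the genome's own introns classify at their raw positions
  pm_self <- classify_pcls(list(g), "cox1", ref)
  expect_equal(pm_self$pcls$pcl, paste0("P", c(210, 450)))

  ## a diverged sister shares the Pcls despite sequence divergence
  sp <- small_spec(41)
  sp$divergence <- c(ts = 0.02, tv = 0.01, indel = 0)
  sis <- diverge(g, sp, id = "sis")$genome
  pm <- classify_pcls(list(g, sis), "cox1", ref)
  expect_equal(nrow(pm$matrix), 2L)
  expect_true(all(pm$matrix))

  ## genome with no introns: all-absent column
  sp0 <- small_spec(43, introns = FALSE)
  g0 <- generate_genome(sp0)$genome
  g0$id <- "bare"
  pm2 <- classify_pcls(list(g, g0), "cox1", ref)
  expect_false(any(pm2$matrix[, "bare"]))
})

test_that("orthologous introns in one Pcl confirm by sequence identity", {
  base <- generate_genome(small_spec(53))
  g <- base$genome
  ref <- coding_sequence(g, "cox1")
  sp <- small_spec(53)
  sp$divergence <- c(ts = 0.02, tv = 0.01, indel = 0)
  sis <- diverge(g, sp, id = "sis")$genome
  pm <- classify_pcls(list(g, sis), "cox1", ref, confirm_identity = 80)
  shared <- pm$pcls[pm$pcls$n_members == 2L, ]
  expect_true(all(shared$min_identity >= 80))
  expect_true(all(shared$identity_ok))
  expect_true(all(is.na(pm$pcls$min_identity[pm$pcls$n_members == 1L])))
})

test_that("sharing summaries count genomes and flag private Pcls", {
  base <- generate_genome(small_spec(47))
  g <- base$genome
  ref <- coding_sequence(g, "cox1")
  sp <- small_spec(47)
  sp$divergence <- c(ts = 0.01, tv = 0.005, indel = 0)
  sp$intron_gain <- data.frame(host = "cox1", position = 44L,
                               length = 150L, group = "II")
  sis <- diverge(g, sp, id = "withP44")$genome
  pm <- classify_pcls(list(g, sis), "cox1", ref)
  sh <- pcl_sharing_summary(pm)
  expect_equal(sh$counts$n_genomes[sh$counts$pcl == "P210"], 2)
  expect_equal(sh$counts$n_genomes[sh$counts$pcl == "P44"], 1)
  expect_equal(sh$private_by_genome$withP44, "P44")
  expect_length(sh$private_by_genome[[g$id]], 0L)
})
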