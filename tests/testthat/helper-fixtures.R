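## Fixtures built in code: tiny hand-made genomes, a small synthetic
## spec factory, and a minimal GenBank record.

## a 60-bp genome with one spliced plus-strand gene and one minus-strand
## tRNA, used across the model tests
tiny_genome <- function() {
  seq <- paste0("ATGAAATTTGGGTAAACGTACGTACGTACG",
                "TTTTAAACCCGGGTTTACGTACGTACGTAC")  # 60 bp
  annotated_genome(
    "tiny", seq, topology = "circular",
    features = list(
      feature("gX", "PCG", "+", data.frame(start = c(1, 10), end = c(6, 15))),
      feature("gX.i1", "intron", "+", data.frame(start = 7, end = 9),
              parent = "gX", group = "I"),
      feature("trnM", "tRNA", "-", data.frame(start = 31, end = 40),
              anticodon = "cat")))
}

## small, fast synthetic spec (a few kb) for property tests
small_spec <- function(seed, n_pcgs = 3L, introns = TRUE) {
  pcgs <- c("cox1", "cob", "nad5", "atp6", "nad1")[seq_len(n_pcgs)]
  plan <- if (introns)
    data.frame(host = pcgs[1L], position = c(210L, 450L),
               length = c(150L, 180L), group = c("I", "II"),
               orf = c(FALSE, FALSE))
  else NULL
  synthetic_spec(
    seed = seed,
    genome_length_target = 9000L,
    core_pcgs = pcgs,
    pcg_lengths = PCG_LENGTHS_SMALL[pcgs],
    rrnas = c(rns = 700L, rnl = 900L),
    trnas = mitocompare:::TRNA_SET[c(1L, 12L, 24L), ],
    minus_strand = c("trnW.1"),
    intron_plan = plan,
    repeat_plan = NULL,
    overlap_plan = NULL,
    divergence = c(ts = 0.02, tv = 0.01, indel = 0))
}

PCG_LENGTHS_SMALL <- c(cox1 = 900L, cob = 600L, nad5 = 750L,
                       atp6 = 450L, nad1 = 600L)

random_spec <- function(seed) {
  set.seed(seed)
  n_pcgs <- sample(2:4, 1L)
  introns <- runif(1) < 0.6
  sp <- small_spec(seed, n_pcgs = n_pcgs, introns = introns)
  sp$genome_length_target <- as.integer(sample(7000:11000, 1L))
  sp
}

## minimal GenBank flat file exercising join, complement, tRNA naming
## and intron features
genbank_fixture <- function(path) {
  seq60 <- "atgaaatttgggtaaacgtacgtacgtacgttttaaacccgggtttacgtacgtacgtac"
  lines <- c(
    "LOCUS       TEST0001                60 bp    DNA     circular PLN 01-JAN-2022",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"synthetic construct\"",
    "     CDS             join(1..6,10..15)",
    "                     /gene=\"gX\"",
    "                     /product=\"hypothetical protein\"",
    "     intron          7..9",
    "                     /gene=\"gX\"",
    "     tRNA            complement(31..40)",
    "                     /product=\"tRNA-Met\"",
    "                     /anticodon=\"(pos:34..36,aa:Met,seq:cat)\"",
    "     rRNA            complement(join(41..45,50..55))",
    "                     /gene=\"rns\"",
    "ORIGIN      ",
    paste0("        1 ", paste(substring(seq60, seq(1, 60, 10),
                                         pmin(seq(10, 69, 10), 60)),
                               collapse = " ")),
    "//")
  writeLines(lines, path)
  path
}
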