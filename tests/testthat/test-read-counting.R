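# helper: write a SAM and convert to indexed BAM
make_bam <- function(lines) {
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_header <- c("@HD\tVN:1.6\tSO:coordinate",
                "@SQ\tSN:chr19\tLN:58617616")

sam_line <- function(qname, flag, pos, seq, rname = "chr19") {
  cigar <- if (flag == 4L) "*" else paste0(nchar(seq), "M")
  if (flag == 4L) { rname <- "*"; pos <- 0L }
  paste(qname, flag, rname, pos, "60", cigar, "*", "0", "0", seq, "*",
        sep = "\t")
}

kir_region <- "chr19:54025634-55084318"

test_that("region extraction keeps in-region and (optionally) unmapped reads", {
  bam <- make_bam(c(
    sam_header,
    sam_line("out1", 0L, 1000L, "ACGTACGTAA"),
    sam_line("in1", 0L, 54100000L, "AAAACCCCGG"),
    sam_line("in2", 0L, 54200000L, "CCCCGGGGTT"),
    sam_line("in3", 0L, 55000000L, "GGGGTTTTAA"),
    sam_line("out2", 0L, 58000000L, "TTTTAAAACC"),
    sam_line("un1", 4L, 0L, "ACACACACAC")
  ))
  rs <- extract_candidate_reads(bam, kir_region, include_unmapped = TRUE)
  expect_length(rs$reads, 4L)
  expect_setequal(rs$reads, c("AAAACCCCGG", "CCCCGGGGTT", "GGGGTTTTAA",
                              "ACACACACAC"))
  rs2 <- extract_candidate_reads(bam, kir_region, include_unmapped = FALSE)
  expect_length(rs2$reads, 3L)
})

test_that("secondary alignments and duplicate records collapse to one per segment", {
  bam <- make_bam(c(
    sam_header,
    sam_line("r1", 0L, 54100000L, "AAAACCCCGG"),
    sam_line("r1", 256L, 54150000L, "AAAACCCCGG"),  # secondary: skipped
    sam_line("r2", 99L, 54200000L, "CCCCGGGGTT"),   # mate 1
    sam_line("r2", 147L, 54200050L, "GGGGTTTTAA")   # mate 2: separate segment
  ))
  rs <- extract_candidate_reads(bam, kir_region, include_unmapped = FALSE)
  expect_length(rs$reads, 3L)
})

test_that("an absent contig is reported with the available ones", {
  bam <- make_bam(c(sam_header, sam_line("r1", 0L, 54100000L, "AAAACCCCGG")))
  expect_error(extract_candidate_reads(bam, "chrX:1-100"), "chr19")
})

test_that("extracted reads match the simulator truth placed in a BAM", {
  cfg <- simulation_config(seed = 9, n_samples = 2, n_background_genes = 2,
                           mean_depth = 3)
  lib <- simulate_allele_library(cfg)
  truth <- simulate_cohort(cfg)
  rs <- simulate_reads(lib, truth, cfg)[[1]]
  pos <- 54100000L + seq_along(rs$reads) * 200L
  bam <- make_bam(c(
    sam_header,
    vapply(seq_along(rs$reads), function(i)
      sam_line(sprintf("sim%05d", i), 0L, pos[i], rs$reads[i]), character(1))
  ))
  got <- extract_candidate_reads(bam, kir_region, include_unmapped = FALSE)
  expect_equal(sort(got$reads), sort(rs$reads))
})

test_that("single-window and overlapping-window counting are exact", {
  idx <- structure(list(k = 8L, per_gene = list(G = canonical_kmer("AAAATTTT")),
                        provenance = "x"), class = "kir_kmer_index")
  ct <- count_kmers(kir_read_set("s", "AAAATTTT"), idx)
  expect_equal(unname(ct$counts), 1L)
  expect_equal(unname(ct$reads_with_hit), 1L)

  idx4 <- structure(list(k = 4L, per_gene = list(G = canonical_kmer("AAAA")),
                         provenance = "x"), class = "kir_kmer_index")
  ct2 <- count_kmers(kir_read_set("s", "AAAAA"), idx4)
  expect_equal(unname(ct2$counts), 2L)  # two overlapping windows

  ct3 <- count_kmers(kir_read_set("s", character(0)), idx4)
  expect_true(all(ct3$counts == 0L))
  expect_true(all(ct3$reads_with_hit == 0L))
  expect_equal(ct3$n_reads, 0L)
})

test_that("reads shorter than k contribute nothing; k mismatch errors", {
  idx <- structure(list(k = 8L, per_gene = list(G = canonical_kmer("AAAATTTT")),
                        provenance = "x"), class = "kir_kmer_index")
  ct <- count_kmers(kir_read_set("s", c("AAA", "AAAATTTT")), idx)
  expect_equal(unname(ct$counts), 1L)
  bg <- structure(list(k = 6L, per_gene = list(B = "AAAAAA"), max_per_gene = 1L),
                  class = "kir_background_kmers")
  expect_error(count_kmers(kir_read_set("s", "AAAATTTT"), idx, bg),
               "does not match")
})

test_that("counts equal the naive sliding-window oracle on random reads", {
  set.seed(77)
  lib <- random_toy_library(n_genes = 3, n_alleles = 2, len = 120,
                            shared_fraction = 0.4)
  for (k in c(10L, 31L, 35L)) {  # covers packed (k<=32) and string paths
    idx <- extract_unique_kmers(lib, k)
    alleles <- unlist(lib$genes, use.names = FALSE)
    reads <- vapply(1:80, function(i) {
      al <- sample(alleles, 1)
      start <- sample.int(nchar(al) - 49L, 1)
      r <- substr(al, start, start + 49L)
      if (runif(1) < 0.5) oracle_revcomp(r) else r
    }, character(1))
    ct <- count_kmers(kir_read_set("s", reads), idx)
    ora <- oracle_count_kmers(reads, idx$per_gene, k)
    expect_equal(ct$counts[names(ora$counts)], ora$counts,
                 info = paste("k =", k))
    expect_equal(ct$reads_with_hit, ora$reads_with_hit, info = paste("k =", k))
  }
})

test_that("counting is strand-symmetric and additive over read batches", {
  set.seed(78)
  lib <- random_toy_library(n_genes = 3, n_alleles = 2, len = 150)
  idx <- extract_unique_kmers(lib, 12)
  alleles <- unlist(lib$genes, use.names = FALSE)
  reads <- vapply(1:60, function(i) {
    al <- sample(alleles, 1)
    start <- sample.int(nchar(al) - 39L, 1)
    substr(al, start, start + 39L)
  }, character(1))

  ct <- count_kmers(kir_read_set("s", reads), idx)
  ct_rc <- count_kmers(kir_read_set("s", revcomp(reads)), idx)
  expect_equal(ct$counts, ct_rc$counts)
  expect_equal(ct$reads_with_hit, ct_rc$reads_with_hit)

  a <- count_kmers(kir_read_set("s", reads[1:30]), idx)
  b <- count_kmers(kir_read_set("s", reads[31:60]), idx)
  expect_equal(a$counts + b$counts, ct$counts)
  expect_equal(a$reads_with_hit + b$reads_with_hit, ct$reads_with_hit)
})

test_that("per-gene aggregation is the mean including zero-count k-mers", {
  idx <- structure(list(k = 4L,
                        per_gene = list(G1 = c("AAAA", "AAAC", "AAAG"),
                                        G2 = c("AATT", "AATC"),
                                        G0 = character(0)),
                        provenance = "x"), class = "kir_kmer_index")
  ct <- structure(list(sample_id = "s", k = 4L,
                       counts = c(AAAA = 2L, AAAC = 2L, AAAG = 2L,
                                  AATT = 0L, AATC = 4L),
                       reads_with_hit = c(G1 = 3L, G2 = 2L, G0 = 0L),
                       n_reads = 10L), class = "kir_kmer_counts")
  agg <- aggregate_gene_counts(ct, idx)
  expect_equal(agg, c(G1 = 2, G2 = 2))  # zero-k-mer gene absent
})

test_that("per-gene frequency scales with true copy number on simulation", {
  study <- small_study()
  f <- study$freqs[, "KIR2DL1"]
  tr <- study$truth$copies[, "KIR2DL1"]
  ratio <- mean(f[tr == 2]) / mean(f[tr == 1])
  expect_lt(abs(ratio - 2), 0.1)  # doubling within 5%
})
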