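test_that("k-mer index reports positions on both strands", {
  idx <- build_index(c(chr1 = "ACGTACGT"), k = 4L)
  hits <- lookup_kmer(idx, "ACGT")
  plus <- hits[hits$strand == "+", ]
  expect_setequal(plus$pos, c(0L, 4L))
  # ACGT is its own reverse complement here: minus-strand rows mirror plus
  minus <- hits[hits$strand == "-", ]
  expect_setequal(minus$pos, c(0L, 4L))
  asym <- build_index(c(chr1 = "AAACCC"), k = 3L)
  expect_equal(lookup_kmer(asym, "GGG")$strand, "-")
  expect_equal(lookup_kmer(asym, "GGG")$pos, 3L) # CCC sits at offset 3
  expect_equal(nrow(lookup_kmer(asym, "GTG")), 0L)
})

test_that("index construction validates its input", {
  expect_error(build_index(character(0)), "empty genome")
  expect_error(build_index(c(chr1 = "ACGTNACGT"), k = 4L),
               "position 5")
})

test_that("index agrees with a naive full scan on random sequence", {
  seq10k <- withr::with_seed(101L, random_dna(10000L))
  k <- 12L
  idx <- build_index(c(chr1 = seq10k), k = k)
  kmers <- substring(seq10k, 1:(10000L - k + 1L), k:10000L)
  probe <- withr::with_seed(102L, sample(unique(kmers), 40L))
  for (km in probe) {
    naive <- which(kmers == km) - 1L
    got <- lookup_kmer(idx, km)
    expect_setequal(got$pos[got$strand == "+"], naive)
  }
})

test_that("degenerate palindromic pair multimaps across tandem repeats", {
  genome <- c(chr1 = strrep("ACGT", 5L))
  idx <- build_index(genome, k = 8L)
  pair <- list(read_id = "r1", mate1 = "ACGTACGT",
               mate2 = revcomp("ACGTACGT"))
  par <- mapper_params(k = 8L, insert_min = 8L, insert_max = 8L)
  hs <- find_hits(pair, idx, par)
  expect_equal(hs$status, "MULTI")
  expect_setequal(unique(hs$hits$start), c(0L, 4L, 8L, 12L))
})

test_that("the mismatch cap excludes reads just over threshold", {
  gene <- withr::with_seed(31L, random_dna(400L))
  genome <- planted_genome(gene, copies = 1L)
  idx <- build_index(genome, k = 15L)
  par <- mapper_params(insert_min = 100L, insert_max = 400L)
  pr <- pair_from_gene(gene, 100L)
  ok <- find_hits(pr, idx, par)
  expect_equal(ok$status, "UNIQUE")
  expect_equal(ok$hits$mismatches, 0L)
  # 6 substitutions in mate1 (cap is 5, summed over the pair)
  pr6 <- pr
  pr6$mate1 <- corrupt_at(pr$mate1, 30:35)
  expect_equal(find_hits(pr6, idx, par)$status, "UNMAPPED")
  # exactly at the cap the pair is retained
  pr5 <- pr
  pr5$mate1 <- corrupt_at(pr$mate1, 30:34)
  at_cap <- find_hits(pr5, idx, par)
  expect_equal(at_cap$status, "UNIQUE")
  expect_equal(at_cap$hits$mismatches, 5L)
})

test_that("over-cap multimapping empties the hit list", {
  gene <- withr::with_seed(32L, random_dna(300L))
  genome <- planted_genome(gene, copies = 11L)
  idx <- build_index(genome, k = 15L)
  par <- mapper_params(insert_min = 100L, insert_max = 320L)
  pr <- pair_from_gene(gene, 100L)
  hs <- find_hits(pr, idx, par)
  expect_equal(hs$status, "TOO_MANY")
  expect_equal(nrow(hs$hits), 0L)
  expect_equal(hs$n_qualifying, 11L)
  # with a higher cap the same pair is MULTI at 11 loci
  hs2 <- find_hits(pr, idx, mapper_params(max_multimap = 20L,
                                          insert_min = 100L,
                                          insert_max = 320L))
  expect_equal(hs2$status, "MULTI")
  expect_equal(nrow(hs2$hits), 11L)
})

test_that("mapper equals the brute-force oracle on error-free reads", {
  gp <- generate_genome_pair(genome_pair_spec(
    seed = 44L, n_chromosomes_host = 1L, n_chromosomes_parasite = 1L,
    n_genes_per_chromosome = 5L, gene_length = 700L,
    intergenic_length = 120L, divergence = 0.03, paralog_fraction = 0.2,
    conserved_fraction = 0.2, host_private_fraction = 0.2,
    parasite_private_fraction = 0.2))
  genome <- concat_genomes(gp$host, gp$parasite)
  idx <- build_index(genome, k = 15L)
  par <- mapper_params()
  reads <- merge_libraries(
    simulate_library(gp$host, gp$annotations_host,
                     library_spec(n_pairs = 40L, read_length = 150L,
                                  error_rate = 0, seed = 1L), "host"),
    simulate_library(gp$parasite, gp$annotations_parasite,
                     library_spec(n_pairs = 40L, read_length = 100L,
                                  error_rate = 0, seed = 2L), "parasite"),
    seed = 3L)
  for (i in seq_len(nrow(reads))) {
    got <- find_hits(reads[i, ], idx, par)
    want <- oracle_placements(reads$mate1[i], reads$mate2[i], genome, par)
    if (nrow(want) > par$max_multimap) {
      expect_equal(got$status, "TOO_MANY")
    } else {
      expect_equal(hit_key(got$hits), want)
    }
  }
})

test_that("raising the caps never shrinks a read's hit set", {
  gp <- generate_genome_pair(genome_pair_spec(
    seed = 45L, n_genes_per_chromosome = 4L, gene_length = 600L,
    divergence = 0.02))
  idx <- build_index(gp$host, k = 15L, tag = "host")
  reads <- simulate_library(gp$host, gp$annotations_host,
                            library_spec(n_pairs = 30L, read_length = 120L,
                                         error_rate = 0.01, seed = 4L),
                            "host")
  loose <- mapper_params(max_mismatch = 8L, max_multimap = 50L)
  strict <- mapper_params(max_mismatch = 3L, max_multimap = 50L)
  for (i in seq_len(nrow(reads))) {
    hs_s <- find_hits(reads[i, ], idx, strict)
    hs_l <- find_hits(reads[i, ], idx, loose)
    keys <- function(h) paste(h$chromosome, h$start, h$strand)
    expect_true(all(keys(hs_s$hits) %in% keys(hs_l$hits)))
  }
})

test_that("mapping is deterministic", {
  gp <- generate_genome_pair(genome_pair_spec(seed = 46L))
  idx1 <- build_index(gp$host, k = 15L, tag = "host")
  idx2 <- build_index(gp$host, k = 15L, tag = "host")
  reads <- simulate_library(gp$host, gp$annotations_host,
                            library_spec(n_pairs = 25L, seed = 5L), "host")
  m1 <- map_reads(reads, idx1, keep_hits = TRUE)
  m2 <- map_reads(reads[rev(seq_len(nrow(reads))), ], idx2,
                  keep_hits = TRUE)
  m2 <- m2[match(m1$read_id, m2$read_id), ]
  expect_equal(m1$status, m2$status)
  expect_equal(m1$n_hits, m2$n_hits)
})

test_that("SAM output round-trips through ingestion", {
  gp <- generate_genome_pair(genome_pair_spec(seed = 47L,
                                              paralog_fraction = 0.2))
  idx <- build_index(gp$host, k = 15L, tag = "host")
  reads <- simulate_library(gp$host, gp$annotations_host,
                            library_spec(n_pairs = 25L, seed = 6L), "host")
  hs <- lapply(seq_len(nrow(reads)), function(i)
    find_hits(reads[i, ], idx))
  sam <- file.path(withr::local_tempdir(), "out.sam")
  write_sam(reads, hs, idx, sam)
  back <- ingest_alignments(sam, default_tag = "host")
  expect_equal(length(back), nrow(reads))
  back <- back[match(reads$read_id, vapply(back, `[[`, "", "read_id"))]
  for (i in seq_along(hs)) {
    if (hs[[i]]$status == "UNMAPPED") {
      expect_equal(back[[i]]$status, "UNMAPPED")
    } else {
      expect_equal(hit_key(back[[i]]$hits), hit_key(hs[[i]]$hits))
    }
  }
})

test_that("ingestion rejects unknown reference names", {
  sam <- file.path(withr::local_tempdir(), "bad.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100",
               paste("r1", 99, "chrX", 1, 255, "10M", "=", 50, 0,
                     strrep("A", 10), "*", sep = "\t")), sam)
  expect_error(ingest_alignments(sam), "unknown reference")
})
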