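test_that("genome concatenation namespaces without collisions", {
  host <- c(chr1 = "ACGT", chr2 = "GGCC")
  par <- c(chr1 = "TTAA")
  comb <- concat_genomes(host, par)
  expect_setequal(names(comb), c("host::chr1", "host::chr2",
                                 "parasite::chr1"))
  expect_equal(sum(nchar(comb)), sum(nchar(host)) + sum(nchar(par)))
  expect_equal(genome_tag(c("host::chr1", "parasite::chr1")),
               c("host", "parasite"))
})

# a gene present identically in both genomes: step-1 capture either order
two_genome_fixture <- function(seed = 61L, copies_host = 1L,
                               copies_par = 1L) {
  gene <- withr::with_seed(seed, random_dna(300L))
  list(gene = gene,
       host = planted_genome(gene, copies_host, name = "chr1",
                             seed = seed + 1L),
       par = planted_genome(gene, copies_par, name = "chr1",
                            seed = seed + 2L))
}

test_that("step-1 capture depends on the order and skips genome two", {
  fx <- two_genome_fixture()
  par <- mapper_params(insert_min = 100L, insert_max = 320L)
  idx_h <- build_index(fx$host, par$k, tag = "host")
  idx_p <- build_index(fx$par, par$k, tag = "parasite")
  pr <- pair_from_gene(fx$gene, 100L, id = "read000001|host|G|1")
  reads <- data.frame(read_id = pr$read_id, organism = "host",
                      gene_id = "G", start = 1L, strand = "+",
                      mate1 = pr$mate1, mate2 = pr$mate2,
                      stringsAsFactors = FALSE)
  hf <- assign_sequential(reads, idx_h, idx_p, par, "host_first")
  expect_equal(hf$category, "UNIQUE_HOST")
  expect_equal(hf$hits_parasite, 0L)
  pf <- assign_sequential(reads, idx_p, idx_h, par, "parasite_first")
  expect_equal(pf$category, "UNIQUE_PARASITE")
  expect_error(assign_sequential(reads, idx_p, idx_h, par, "host_first"),
               "inconsistent")
})

test_that("without cross-mapping both orders agree with per-genome mapping", {
  gp <- generate_genome_pair(genome_pair_spec(
    seed = 62L, n_genes_per_chromosome = 5L, gene_length = 600L,
    paralog_fraction = 0, conserved_fraction = 0,
    host_private_fraction = 1, parasite_private_fraction = 1))
  par <- mapper_params()
  idx_h <- build_index(gp$host, par$k, tag = "host")
  idx_p <- build_index(gp$parasite, par$k, tag = "parasite")
  reads <- merge_libraries(
    simulate_library(gp$host, gp$annotations_host,
                     library_spec(n_pairs = 100L, error_rate = 0,
                                  seed = 1L), "host"),
    simulate_library(gp$parasite, gp$annotations_parasite,
                     library_spec(n_pairs = 100L, read_length = 100L,
                                  error_rate = 0, seed = 2L), "parasite"),
    seed = 3L)
  hf <- assign_sequential(reads, idx_h, idx_p, par, "host_first")
  pf <- assign_sequential(reads, idx_p, idx_h, par, "parasite_first")
  # per-genome brute-force oracle: where does each read qualify?
  host_hit <- par_hit <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    host_hit[i] <- nrow(oracle_placements(reads$mate1[i], reads$mate2[i],
                                          gp$host, par)) > 0
    par_hit[i] <- nrow(oracle_placements(reads$mate1[i], reads$mate2[i],
                                         gp$parasite, par)) > 0
  }
  expect_true(all(!(host_hit & par_hit))) # no cross-mapping by design
  for (out in list(hf, pf)) {
    assigned_host <- out$category %in% c("UNIQUE_HOST", "MULTI_HOST")
    assigned_par <- out$category %in% c("UNIQUE_PARASITE",
                                        "MULTI_PARASITE")
    expect_equal(assigned_host, host_hit)
    expect_equal(assigned_par, par_hit)
  }
  expect_equal(sum(hf$category %in% c("UNIQUE_HOST", "MULTI_HOST")),
               sum(reads$organism == "host" & host_hit))
})

test_that("combined partition rule distinguishes two-side from multi", {
  fx <- two_genome_fixture(seed = 63L, copies_host = 1L, copies_par = 1L)
  par <- mapper_params(insert_min = 100L, insert_max = 320L)
  comb <- build_index(concat_genomes(fx$host, fx$par), par$k)
  pr <- pair_from_gene(fx$gene, 100L)
  reads <- data.frame(read_id = pr$read_id, organism = "host",
                      gene_id = "G", start = 1L, strand = "+",
                      mate1 = pr$mate1, mate2 = pr$mate2,
                      stringsAsFactors = FALSE)
  out <- assign_combined(reads, comb, par)
  expect_equal(out$category, "TWO_SIDE")
  expect_equal(out$hits_host, 1L)
  expect_equal(out$hits_parasite, 1L)
  # three host-only copies: MULTI_HOST
  fx3 <- two_genome_fixture(seed = 64L, copies_host = 3L, copies_par = 0L)
  comb3 <- build_index(concat_genomes(
    fx3$host, c(chr1 = withr::with_seed(1L, random_dna(2000L)))), par$k)
  pr3 <- pair_from_gene(fx3$gene, 100L)
  reads3 <- reads
  reads3$mate1 <- pr3$mate1; reads3$mate2 <- pr3$mate2
  out3 <- assign_combined(reads3, comb3, par)
  expect_equal(out3$category, "MULTI_HOST")
  expect_equal(out3$hits_host, 3L)
})

test_that("the multimap cap counts hits jointly across genomes (cap boundary)", {
  fx <- two_genome_fixture(seed = 65L, copies_host = 6L, copies_par = 6L)
  par <- mapper_params(insert_min = 100L, insert_max = 320L)
  idx_h <- build_index(fx$host, par$k, tag = "host")
  idx_p <- build_index(fx$par, par$k, tag = "parasite")
  comb <- build_index(concat_genomes(fx$host, fx$par), par$k)
  pr <- pair_from_gene(fx$gene, 100L)
  reads <- data.frame(read_id = pr$read_id, organism = "host",
                      gene_id = "G", start = 1L, strand = "+",
                      mate1 = pr$mate1, mate2 = pr$mate2,
                      stringsAsFactors = FALSE)
  # brute-force check of the planted locus counts
  expect_equal(nrow(oracle_placements(pr$mate1, pr$mate2, fx$host, par)),
               6L)
  expect_equal(nrow(oracle_placements(pr$mate1, pr$mate2, fx$par, par)),
               6L)
  # combined: 12 joint hits > 10 -> unmapped; sequential: 6 <= 10 -> multi
  expect_equal(assign_combined(reads, comb, par)$category, "UNMAPPED")
  expect_equal(assign_sequential(reads, idx_h, idx_p, par,
                                 "host_first")$category, "MULTI_HOST")
})

test_that("categories partition the library and strategies agree under the cap", {
  b <- shared_bench()
  n <- nrow(b$reads)
  for (out in b$outcomes) {
    expect_equal(nrow(out), n)
    expect_equal(sum(table(out$category)), n)
  }
  # conditional strategy equivalence: for reads whose joint hit count is
  # within the cap (all combined-retained reads), TWO_SIDE under the
  # combined strategy is the same thing as step-1 capture in both orders
  hf <- b$outcomes$host_first
  pf <- b$outcomes$parasite_first
  comb <- b$outcomes$combined
  expect_identical(hf$read_id, comb$read_id)
  joint_ok <- comb$category != "UNMAPPED"
  two_side <- comb$category == "TWO_SIDE"
  step1_both <- hf$step %in% 1L &
    pf$step[match(hf$read_id, pf$read_id)] %in% 1L
  expect_equal(two_side[joint_ok], step1_both[joint_ok])
  # a read unmapped in both genomes individually is unmapped everywhere
  unm <- comb$category == "UNMAPPED" & comb$hits_host == 0L &
    comb$hits_parasite == 0L &
    hf$category == "UNMAPPED"
  expect_true(all(pf$category[unm] == "UNMAPPED"))
})
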