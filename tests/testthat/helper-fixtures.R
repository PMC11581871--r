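# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# a moderate full-pipeline benchmark reused by evaluation/report/acceptance
# tests; ~450 read pairs over two ~10 kb genomes
shared_bench <- function() {
  if (is.null(fixture_env$bench)) {
    fixture_env$bench <- run_dual_benchmark(
      genome_pair_spec(n_chromosomes_host = 2L, n_chromosomes_parasite = 2L,
                       n_genes_per_chromosome = 6L, gene_length = 700L,
                       intergenic_length = 150L, divergence = 0.08,
                       paralog_fraction = 0.10, conserved_fraction = 0.10,
                       host_private_fraction = 0.15,
                       parasite_private_fraction = 0.15),
      library_spec(n_pairs = 250L, read_length = 150L),
      library_spec(n_pairs = 200L, read_length = 100L),
      seed = 11L)
  }
  fixture_env$bench
}

# a tiny genome with one planted gene sequence repeated `copies` times,
# separated by random spacers; returns list(genome=, gene=)
planted_genome <- function(gene, copies, spacer = 100L, name = "chr1",
                           seed = 99L) {
  withr::with_seed(seed, {
    pieces <- character(0)
    for (i in seq_len(copies))
      pieces <- c(pieces, random_dna(spacer), gene)
    pieces <- c(pieces, random_dna(spacer))
    stats::setNames(paste(pieces, collapse = ""), name)
  })
}

# read pair spanning the full gene body: mate1 = 5' end, mate2 = revcomp 3'
pair_from_gene <- function(gene, read_length, id = "read000001|host|G|1") {
  L <- nchar(gene)
  list(read_id = id,
       mate1 = substr(gene, 1L, read_length),
       mate2 = revcomp(substr(gene, L - read_length + 1L, L)))
}

# substitute bases at given 1-based positions (cyclic A->C->G->T->A)
corrupt_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[positions] <- nxt[ch[positions]]
  paste(ch, collapse = "")
}

# A genome pair with 10 "host" reads planted only in the parasite genome
# (emulating host-assembly gaps): those reads must land in the host
# one-side set under every strategy.
planted_one_side_fixture <- function() {
  if (!is.null(fixture_env$one_side)) return(fixture_env$one_side)
  gp <- generate_genome_pair(genome_pair_spec(
    seed = 71L, n_genes_per_chromosome = 5L, gene_length = 600L,
    divergence = 0.2, paralog_fraction = 0, conserved_fraction = 0,
    host_private_fraction = 1, parasite_private_fraction = 1))
  par <- mapper_params()
  host_lib <- simulate_library(gp$host, gp$annotations_host,
                               library_spec(n_pairs = 60L, error_rate = 0,
                                            seed = 1L), "host")
  par_lib <- simulate_library(gp$parasite, gp$annotations_parasite,
                              library_spec(n_pairs = 60L,
                                           read_length = 100L,
                                           error_rate = 0, seed = 2L),
                              "parasite")
  # plant: 10 "host" reads drawn from parasite genes (the host assembly
  # simply lacks their locus)
  ghost <- simulate_library(gp$parasite, gp$annotations_parasite,
                            library_spec(n_pairs = 10L, read_length = 100L,
                                         error_rate = 0, seed = 3L),
                            "parasite")
  ghost$read_id <- sub("\\|parasite\\|", "|host|", ghost$read_id)
  ghost$read_id <- sub("^read", "ghost", ghost$read_id)
  ghost$organism <- "host"
  reads <- merge_libraries(rbind(as.data.frame(host_lib),
                                 as.data.frame(ghost)), par_lib, seed = 4L)
  truth <- stats::setNames(reads$organism, reads$read_id)
  idx_h <- build_index(gp$host, par$k, tag = "host")
  idx_p <- build_index(gp$parasite, par$k, tag = "parasite")
  comb <- build_index(concat_genomes(gp$host, gp$parasite), par$k)
  labels <- list(
    host_first = label_assignments(
      assign_sequential(reads, idx_h, idx_p, par, "host_first"), truth),
    parasite_first = label_assignments(
      assign_sequential(reads, idx_p, idx_h, par, "parasite_first"),
      truth),
    combined = label_assignments(assign_combined(reads, comb, par), truth))
  fixture_env$one_side <- list(gp = gp, reads = reads, labels = labels,
                               params = par, idx_h = idx_h, idx_p = idx_p,
                               ghost_ids = ghost$read_id)
  fixture_env$one_side
}
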