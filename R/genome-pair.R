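#' Specification of a synthetic host/parasite genome pair
#'
#' Describes the homology structure of two interacting genomes at desk
#' scale: a set of single-exon genes per chromosome, separated by random
#' intergenic spacers. Homologous gene pairs differ at each position
#' independently with probability `divergence`; a configurable fraction of
#' pairs is copied verbatim (the organelle-like, ultra-conserved class that
#' drives two-side cross-mapping); a fraction of each genome's genes is
#' private (random sequence, no homolog — the one-side cross-mapping and
#' genome-incompleteness analogue); and a fraction of each genome's gene
#' slots holds within-genome paralog copies (the multimapping source).
#'
#' @param seed Integer seed; all downstream randomness is derived from it.
#' @param n_chromosomes_host,n_chromosomes_parasite Number of chromosomes.
#' @param n_genes_per_chromosome Genes per chromosome.
#' @param gene_length Gene length in bp (single exon). Must comfortably
#'   exceed twice the read length of any library simulated from it.
#' @param intergenic_length Length of the random spacer before, between and
#'   after genes.
#' @param divergence Per-base substitution probability between the two
#'   copies of a (non-conserved) homologous gene pair.
#' @param paralog_fraction Fraction of each genome's gene slots occupied by
#'   a duplicate of another gene of the same genome.
#' @param paralog_divergence Per-base substitution probability between a
#'   paralog copy and its source gene.
#' @param conserved_fraction Fraction of gene slots holding homologous
#'   pairs copied with divergence exactly 0.
#' @param host_private_fraction,parasite_private_fraction Fraction of gene
#'   slots holding genes with no homolog in the other genome.
#' @return An object of class `genome_pair_spec`.
#' @export
genome_pair_spec <- function(seed = 1L,
                             n_chromosomes_host = 2L,
                             n_chromosomes_parasite = 2L,
                             n_genes_per_chromosome = 10L,
                             gene_length = 1000L,
                             intergenic_length = 200L,
                             divergence = 0.10,
                             paralog_fraction = 0.10,
                             paralog_divergence = 0.02,
                             conserved_fraction = 0.05,
                             host_private_fraction = 0.10,
                             parasite_private_fraction = 0.10) {
  spec <- list(
    seed = check_positive_int(seed, "seed"),
    n_chromosomes_host = check_positive_int(n_chromosomes_host,
                                            "n_chromosomes_host"),
    n_chromosomes_parasite = check_positive_int(n_chromosomes_parasite,
                                                "n_chromosomes_parasite"),
    n_genes_per_chromosome = check_positive_int(n_genes_per_chromosome,
                                                "n_genes_per_chromosome"),
    gene_length = check_positive_int(gene_length, "gene_length"),
    intergenic_length = check_positive_int(intergenic_length,
                                           "intergenic_length"),
    divergence = check_fraction(divergence, "divergence"),
    paralog_fraction = check_fraction(paralog_fraction, "paralog_fraction"),
    paralog_divergence = check_fraction(paralog_divergence,
                                        "paralog_divergence"),
    conserved_fraction = check_fraction(conserved_fraction,
                                        "conserved_fraction"),
    host_private_fraction = check_fraction(host_private_fraction,
                                           "host_private_fraction"),
    parasite_private_fraction = check_fraction(parasite_private_fraction,
                                               "parasite_private_fraction"))
  for (org in c("host", "parasite")) {
    priv <- spec[[paste0(org, "_private_fraction")]]
    tot <- spec$conserved_fraction + priv + spec$paralog_fraction
    if (tot > 1)
      stop("configuration error: conserved_fraction + ", org,
           "_private_fraction + paralog_fraction exceeds 1", call. = FALSE)
  }
  structure(spec, class = "genome_pair_spec")
}

# product-string vocabulary; conserved loci get organelle-flavoured names
.product_conserved <- c("conserved ribosomal protein", "rRNA-like conserved locus",
                        "cytochrome oxidase subunit", "photosystem core protein",
                        "elongation factor homolog")
.product_shared <- c("protein kinase family protein", "transcription factor",
                     "transporter-like protein", "cell wall enzyme",
                     "metabolic enzyme", "stress response protein")

#' Generate a host/parasite genome pair with known homology structure
#'
#' Deterministic for a fixed spec (including its seed). Gene sequences are
#' stored in transcript orientation; minus-strand genes appear reverse
#' complemented in the chromosome sequence. Gene intervals never overlap.
#'
#' @param spec A [genome_pair_spec()].
#' @return An object of class `genome_pair`: a list with named chromosome
#'   sequences `host` and `parasite`, annotation data frames
#'   `annotations_host` / `annotations_parasite` (gene_id, chromosome,
#'   1-based start/end, strand, product, role), the `homology` truth table
#'   (host_gene, parasite_gene, realised per-base divergence), and the
#'   `paralogs` table (organism, gene_id, source_gene).
#' @export
generate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "genome_pair_spec"))
  withr::with_seed(spec$seed, .generate_genome_pair(spec))
}

.generate_genome_pair <- function(spec) {
  n_h <- spec$n_chromosomes_host * spec$n_genes_per_chromosome
  n_p <- spec$n_chromosomes_parasite * spec$n_genes_per_chromosome
  glen <- spec$gene_length

  n_priv_h <- round(spec$host_private_fraction * n_h)
  n_priv_p <- round(spec$parasite_private_fraction * n_p)
  n_para_h <- round(spec$paralog_fraction * n_h)
  n_para_p <- round(spec$paralog_fraction * n_p)
  # homologous pairs fill whatever capacity both sides have left
  n_hom <- min(n_h - n_priv_h - n_para_h, n_p - n_priv_p - n_para_p)
  n_cons <- min(round(spec$conserved_fraction * min(n_h, n_p)), n_hom)
  n_div <- n_hom - n_cons

  # shared (transcript-orientation) sequences for homologous pairs
  base <- vapply(seq_len(n_hom), function(i) random_dna(glen), character(1))
  host_hom <- base
  par_hom <- c(base[seq_len(n_cons)],
               vapply(base[seq_len(n_div) + n_cons], mutate_bases,
                      character(1), rate = spec$divergence))
  realized <- vapply(seq_len(n_hom), function(i)
    hamming(host_hom[i], par_hom[i]) / glen, numeric(1))

  build_side <- function(org, n_total, n_chr, n_hom_side, hom_seqs,
                         n_priv, n_para, pair_product) {
    prefix <- if (org == "host") "Hg" else "Pg"
    ids <- sprintf("%s%04d", prefix, seq_len(n_total))
    n_extra_priv <- n_total - n_hom_side - n_priv - n_para
    roles <- c(rep("conserved", n_cons), rep("homolog", n_hom_side - n_cons),
               rep("private", n_priv + n_extra_priv), rep("paralog", n_para))
    seqs <- character(n_total)
    seqs[seq_len(n_hom_side)] <- hom_seqs
    priv_idx <- which(roles == "private")
    seqs[priv_idx] <- vapply(priv_idx, function(i) random_dna(glen),
                             character(1))
    para_idx <- which(roles == "paralog")
    src_pool <- which(roles != "paralog")
    para_src <- if (length(para_idx))
      src_pool[sample.int(length(src_pool), length(para_idx), replace = TRUE)]
    else integer(0)
    seqs[para_idx] <- vapply(seq_along(para_idx), function(j)
      mutate_bases(seqs[para_src[j]], spec$paralog_divergence), character(1))

    products <- character(n_total)
    products[seq_len(n_hom_side)] <- pair_product
    products[priv_idx] <- sprintf("hypothetical protein %s", ids[priv_idx])
    products[para_idx] <- products[para_src]

    # scatter roles across chromosome slots so conserved/paralog loci are
    # not clustered at one end of one chromosome
    slot <- sample.int(n_total)
    pos_in_chr <- integer(n_total)
    chrom <- character(n_total)
    for (i in seq_len(n_total)) {
      s <- slot[i] - 1L
      chrom[i] <- sprintf("chr%d", s %/% spec$n_genes_per_chromosome + 1L)
      pos_in_chr[i] <- s %% spec$n_genes_per_chromosome + 1L
    }
    start <- (pos_in_chr - 1L) * (glen + spec$intergenic_length) +
      spec$intergenic_length + 1L
    strand <- sample(c("+", "-"), n_total, replace = TRUE)

    ann <- data.frame(gene_id = ids, chromosome = chrom, start = start,
                      end = start + glen - 1L, strand = strand,
                      product = products, role = roles,
                      stringsAsFactors = FALSE)
    list(ann = ann, seqs = stats::setNames(seqs, ids),
         paralogs = if (length(para_idx))
           data.frame(organism = org, gene_id = ids[para_idx],
                      source_gene = ids[para_src], stringsAsFactors = FALSE)
         else
           data.frame(organism = character(0), gene_id = character(0),
                      source_gene = character(0)))
  }

  pair_product <- c(
    sprintf("%s %d", sample(.product_conserved, n_cons, replace = TRUE),
            seq_len(n_cons)),
    sprintf("%s %d", sample(.product_shared, n_div, replace = TRUE),
            seq_len(n_div)))
  host <- build_side("host", n_h, spec$n_chromosomes_host, n_hom, host_hom,
                     n_priv_h, n_para_h, pair_product)
  parasite <- build_side("parasite", n_p, spec$n_chromosomes_parasite,
                         n_hom, par_hom, n_priv_p, n_para_p, pair_product)

  assemble <- function(side, n_chr) {
    chroms <- stats::setNames(vector("list", n_chr),
                              sprintf("chr%d", seq_len(n_chr)))
    for (cn in names(chroms)) {
      genes <- side$ann[side$ann$chromosome == cn, , drop = FALSE]
      genes <- genes[order(genes$start), , drop = FALSE]
      pieces <- character(0)
      cursor <- 1L
      for (i in seq_len(nrow(genes))) {
        gap <- genes$start[i] - cursor
        pieces <- c(pieces, random_dna(gap))
        gseq <- side$seqs[[genes$gene_id[i]]]
        if (genes$strand[i] == "-") gseq <- revcomp(gseq)
        pieces <- c(pieces, gseq)
        cursor <- genes$end[i] + 1L
      }
      pieces <- c(pieces, random_dna(spec$intergenic_length))
      chroms[[cn]] <- paste(pieces, collapse = "")
    }
    unlist(chroms)
  }

  homology <- if (n_hom)
    data.frame(host_gene = host$ann$gene_id[seq_len(n_hom)],
               parasite_gene = parasite$ann$gene_id[seq_len(n_hom)],
               divergence = realized, stringsAsFactors = FALSE)
  else
    data.frame(host_gene = character(0), parasite_gene = character(0),
               divergence = numeric(0))

  out <- list(host = assemble(host, spec$n_chromosomes_host),
              parasite = assemble(parasite, spec$n_chromosomes_parasite),
              annotations_host = host$ann,
              annotations_parasite = parasite$ann,
              homology = homology,
              paralogs = rbind(host$paralogs, parasite$paralogs),
              spec = spec)
  class(out) <- "genome_pair"
  out
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("Synthetic host/parasite genome pair\n")
  cat(sprintf("  host:     %d chromosome(s), %d genes, %s bp\n",
              length(x$host), nrow(x$annotations_host),
              format(sum(nchar(x$host)), big.mark = ",")))
  cat(sprintf("  parasite: %d chromosome(s), %d genes, %s bp\n",
              length(x$parasite), nrow(x$annotations_parasite),
              format(sum(nchar(x$parasite)), big.mark = ",")))
  cat(sprintf("  homologous pairs: %d (%d conserved), paralog copies: %d\n",
              nrow(x$homology), sum(x$homology$divergence == 0),
              nrow(x$paralogs)))
  if (nrow(x$homology))
    cat(sprintf("  mean realised divergence (non-conserved): %.4f\n",
                mean(x$homology$divergence[x$homology$divergence > 0])))
  invisible(x)
}

#' Extract transcript sequences for one side of a genome pair
#'
#' Minus-strand transcripts are the reverse complement of the genomic
#' interval, per GFF3 convention.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annotations Annotation data frame as in [generate_genome_pair()].
#' @return Named character vector of transcript sequences.
#' @export
gene_transcripts <- function(genome, annotations) {
  bad <- setdiff(annotations$chromosome, names(genome))
  if (length(bad))
    stop("annotation references unknown chromosome(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tx <- substring(genome[annotations$chromosome], annotations$start,
                  annotations$end)
  neg <- annotations$strand == "-"
  tx[neg] <- revcomp(tx[neg])
  stats::setNames(tx, annotations$gene_id)
}

#' Write a genome pair to FASTA and GFF3
#'
#' Produces `host.fasta`, `parasite.fasta`, `host.gff3`, `parasite.gff3`
#' under `dir`. Coordinates in the GFF3 are 1-based inclusive; `ID` and
#' `product` attributes are carried on every gene feature.
#'
#' @param pair A `genome_pair`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "genome_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (org in c("host", "parasite")) {
    fa <- file.path(dir, paste0(org, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair[[org]]), fa)
    ann <- pair[[paste0("annotations_", org)]]
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chromosome,
      ranges = IRanges::IRanges(ann$start, ann$end),
      strand = ann$strand)
    gr$type <- "gene"
    gr$source <- "dualmapsim"
    gr$ID <- ann$gene_id
    gr$product <- ann$product
    gff <- file.path(dir, paste0(org, ".gff3"))
    rtracklayer::export(gr, gff, format = "gff3")
    paths <- c(paths, fa, gff)
  }
  invisible(paths)
}
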