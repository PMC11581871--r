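#' Specification of a simulated paired-end read library
#'
#' Defaults mirror a typical short-read dual RNA-seq setup: 150 nt reads
#' for the host library, 100 nt for the parasite library (set
#' `read_length` accordingly), a 300 +/- 30 bp fragment size and a small
#' per-base substitution error rate. Reads shorter than 75 nt are not
#' representable: libraries are assumed to be quality-trimmed upstream.
#'
#' @param n_pairs Number of read pairs to simulate.
#' @param read_length Length of both mates, in nt (>= 75).
#' @param fragment_length_mean,fragment_length_sd Fragment (insert) size
#'   distribution in bp; fragments are clamped to the gene body.
#' @param error_rate Per-base substitution probability (0 <= rate < 0.1).
#' @param seed Integer seed.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_pairs = 2000L, read_length = 150L,
                         fragment_length_mean = 300, fragment_length_sd = 30,
                         error_rate = 0.005, seed = 1L) {
  n_pairs <- check_positive_int(n_pairs, "n_pairs")
  read_length <- check_positive_int(read_length, "read_length")
  if (read_length < 75L)
    stop("configuration error: `read_length` must be >= 75 nt", call. = FALSE)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.1)
    stop("configuration error: `error_rate` must be in [0, 0.1)",
         call. = FALSE)
  if (read_length > fragment_length_mean)
    stop("configuration error: `read_length` exceeds `fragment_length_mean`",
         call. = FALSE)
  structure(list(n_pairs = n_pairs, read_length = read_length,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 error_rate = error_rate,
                 seed = check_positive_int(seed, "seed")),
            class = "library_spec")
}

#' Simulate a paired-end read library from annotated genes
#'
#' Fragments are drawn uniformly along gene bodies (in transcript
#' orientation, i.e. minus-strand genes contribute reverse-complemented
#' sequence), mate 1 reads the fragment's 5' end and mate 2 is the reverse
#' complement of its 3' end (FR orientation). Sequencing errors are
#' independent per-base substitutions. The true origin is encoded in the
#' read name as `readNNNNNN|<organism>|<gene_id>|<start>` so that ground
#' truth survives FASTQ round trips without sidecar files.
#'
#' @param genome Named character vector of chromosome sequences (one side
#'   of a [generate_genome_pair()] result).
#' @param annotations Annotation data frame for the same side.
#' @param spec A [library_spec()].
#' @param organism `"host"` or `"parasite"`; recorded in read names.
#' @param weights Optional per-gene sampling weights (default uniform over
#'   eligible genes), named by gene_id or in annotation order.
#' @return A data.frame of class `read_library` with columns `read_id`,
#'   `organism`, `gene_id`, `start` (1-based on the transcript), `strand`,
#'   `mate1`, `mate2`.
#' @export
simulate_library <- function(genome, annotations, spec,
                             organism = c("host", "parasite"),
                             weights = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  organism <- match.arg(organism)
  tx <- gene_transcripts(genome, annotations)
  len <- nchar(tx)
  short <- len < spec$read_length
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than read_length excluded: ",
            paste(names(tx)[short], collapse = ", "), call. = FALSE)
    tx <- tx[!short]
    len <- len[!short]
  }
  if (!length(tx))
    stop("no gene is long enough to support fragments of read_length ",
         spec$read_length, call. = FALSE)
  if (!is.null(weights)) {
    if (!is.null(names(weights))) weights <- weights[names(tx)]
    if (length(weights) != length(tx) || anyNA(weights))
      stop("`weights` must cover every eligible gene", call. = FALSE)
  }
  gstrand <- stats::setNames(annotations$strand, annotations$gene_id)[names(tx)]

  withr::with_seed(spec$seed, {
    gi <- sample.int(length(tx), spec$n_pairs, replace = TRUE, prob = weights)
    frag <- round(stats::rnorm(spec$n_pairs, spec$fragment_length_mean,
                               spec$fragment_length_sd))
    frag <- pmax(spec$read_length, pmin(frag, len[gi]))
    start <- 1L + floor(stats::runif(spec$n_pairs) * (len[gi] - frag + 1))
    fragseq <- substring(tx[gi], start, start + frag - 1L)
    mate1 <- substring(fragseq, 1L, spec$read_length)
    mate2 <- revcomp(substring(fragseq, frag - spec$read_length + 1L, frag))
    if (spec$error_rate > 0) {
      mate1 <- vapply(mate1, mutate_bases, character(1),
                      rate = spec$error_rate, USE.NAMES = FALSE)
      mate2 <- vapply(mate2, mutate_bases, character(1),
                      rate = spec$error_rate, USE.NAMES = FALSE)
    }
    out <- data.frame(
      read_id = sprintf("read%06d|%s|%s|%d", seq_len(spec$n_pairs),
                        organism, names(tx)[gi], start),
      organism = organism,
      gene_id = names(tx)[gi],
      start = as.integer(start),
      strand = unname(gstrand[gi]),
      mate1 = mate1, mate2 = mate2,
      stringsAsFactors = FALSE)
    class(out) <- c("read_library", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

#' Parse ground-truth origin out of read identifiers
#'
#' @param read_id Character vector of `readNNNNNN|org|gene|start` names.
#' @return data.frame with columns `read_id`, `organism`, `gene_id`,
#'   `start`.
#' @export
parse_read_id <- function(read_id) {
  parts <- strsplit(read_id, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("unparseable read id(s): ", paste(utils::head(read_id[bad], 3L),
                                           collapse = ", "), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(read_id = read_id, organism = m[, 2L], gene_id = m[, 3L],
             start = as.integer(m[, 4L]), stringsAsFactors = FALSE)
}

#' Merge two read libraries into one dual RNA-seq sample
#'
#' Emulates pooling one replicate of the host library with the matching
#' replicate of the parasite library. The merge is content-preserving and
#' the order is shuffled deterministically by `seed`.
#'
#' @param host_lib,parasite_lib `read_library` data frames.
#' @param seed Integer seed driving the shuffle.
#' @return A `read_library` data.frame with
#'   `nrow(host_lib) + nrow(parasite_lib)` rows.
#' @export
merge_libraries <- function(host_lib, parasite_lib, seed = 1L) {
  merged <- rbind(as.data.frame(host_lib), as.data.frame(parasite_lib))
  dup <- merged$read_id[duplicated(merged$read_id)]
  if (length(dup))
    stop("duplicate read id(s) across libraries: ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "), call. = FALSE)
  merged <- withr::with_seed(seed, merged[sample.int(nrow(merged)), ,
                                          drop = FALSE])
  rownames(merged) <- NULL
  class(merged) <- c("read_library", "data.frame")
  merged
}

#' Write a read library as paired FASTQ plus a truth table
#'
#' Writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq` (constant 'I' base
#' qualities; quality modelling is out of scope) and `<prefix>_truth.tsv`
#' with columns read_id, organism, gene_id, start, strand.
#'
#' @param lib A `read_library`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_read_library <- function(lib, prefix) {
  r1 <- paste0(prefix, "_R1.fastq")
  r2 <- paste0(prefix, "_R2.fastq")
  tr <- paste0(prefix, "_truth.tsv")
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(lib[[paste0("mate", mate)]])
    names(seqs) <- lib$read_id
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, if (mate == 1) r1 else r2,
                                format = "fastq", qualities = qual)
  }
  utils::write.table(lib[c("read_id", "organism", "gene_id", "start",
                           "strand")],
                     tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(r1, r2, tr))
}

#' Read a paired FASTQ library back into a read_library
#'
#' Origin fields are reconstructed from the encoded read names.
#'
#' @param r1,r2 Paths to the mate FASTQ files.
#' @return A `read_library` data.frame.
#' @export
read_read_library <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  ids1 <- sub("\\s.*$", "", names(s1))
  ids2 <- sub("\\s.*$", "", names(s2))
  if (!identical(ids1, ids2))
    stop("mate FASTQ files are not name-collated", call. = FALSE)
  truth <- parse_read_id(ids1)
  out <- data.frame(read_id = ids1, organism = truth$organism,
                    gene_id = truth$gene_id, start = truth$start,
                    strand = NA_character_,
                    mate1 = as.character(s1), mate2 = as.character(s2),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_library", "data.frame")
  out
}
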