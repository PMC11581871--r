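#' Extract one-side cross-mapped read sets
#'
#' One-side cross-mapped reads originate in one organism but map only to
#' the other's genome — typically a signature of assembly incompleteness.
#' In the sequential strategy they are the step-2 false negatives:
#' `S-FN_h2` of the host-first run for the host, `S-FN_p2` of the
#' parasite-first run for the parasite. In the combined strategy they are
#' the `C-FN` reads minus the two-side roster (reads hitting only the
#' wrong genome).
#'
#' @param labels For `strategy = "sequential"` the host-first run's
#'   labels; for `"combined"` the combined run's labels.
#' @param strategy `"sequential"` or `"combined"`.
#' @param labels_parasite_first The parasite-first run's labels (required
#'   for the sequential extraction).
#' @return list with character-vector elements `host` and `parasite` of
#'   read ids.
#' @export
extract_one_side <- function(labels, strategy = c("sequential", "combined"),
                             labels_parasite_first = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "sequential") {
    if (is.null(labels_parasite_first))
      stop("sequential one-side extraction requires the parasite-first ",
           "run's labels (`labels_parasite_first`)", call. = FALSE)
    if (!identical(unique(labels$order), "host_first"))
      stop("`labels` must come from the host-first sequential run",
           call. = FALSE)
    if (!identical(unique(labels_parasite_first$order), "parasite_first"))
      stop("`labels_parasite_first` must come from the parasite-first run",
           call. = FALSE)
    list(host = labels$read_id[labels$label_host == "S-FN_h2"],
         parasite = labels_parasite_first$read_id[
           labels_parasite_first$label_parasite == "S-FN_p2"])
  } else {
    if (!identical(unique(labels$strategy), "combined"))
      stop("`labels` must come from the combined run", call. = FALSE)
    two <- labels$read_id[labels$category == "TWO_SIDE"]
    list(host = setdiff(labels$read_id[labels$label_host == "C-FN_h"], two),
         parasite = setdiff(
           labels$read_id[labels$label_parasite == "C-FN_p"], two))
  }
}

#' Remap one-side cross-mapped reads under relaxed filters
#'
#' The one-side set is remapped to its own organism's genome with a more
#' permissive mismatch cap (the relaxed mode doubles the strict cap of 5
#' to 10). The recovered fraction separates over-stringent filtering
#' (recoverable) from genuine absence of a mappable locus, e.g. assembly
#' gaps (unrecoverable).
#'
#' @param one_side_ids Character vector of read ids.
#' @param reads The `read_library` the ids refer to.
#' @param own_index `seed_index` of the reads' own genome.
#' @param relaxed_params [mapper_params()] with the relaxed caps.
#' @param strict_params Optional strict-mode params; if supplied, the
#'   relaxed mismatch cap must not be lower.
#' @return list of class `remap_result`: `n`, `n_remapped`, `rate`
#'   (`NA` for an empty input set, never 0).
#' @export
relaxed_remap <- function(one_side_ids, reads, own_index,
                          relaxed_params = mapper_params(max_mismatch = 10L),
                          strict_params = NULL) {
  if (!is.null(strict_params) &&
      relaxed_params$max_mismatch < strict_params$max_mismatch)
    stop("relaxed max_mismatch is below the strict cap", call. = FALSE)
  if (!length(one_side_ids))
    return(structure(list(n = 0L, n_remapped = 0L, rate = NA_real_),
                     class = "remap_result"))
  sub <- reads[match(one_side_ids, reads$read_id), , drop = FALSE]
  if (anyNA(sub$read_id))
    stop("one_side_ids contains read id(s) absent from `reads`",
         call. = FALSE)
  m <- map_reads(sub, own_index, relaxed_params)
  n_ok <- sum(m$status %in% c("UNIQUE", "MULTI"))
  structure(list(n = length(one_side_ids), n_remapped = n_ok,
                 rate = n_ok / length(one_side_ids)),
            class = "remap_result")
}

#' @export
print.remap_result <- function(x, ...) {
  cat(sprintf("relaxed remap: %d/%d recovered (rate %s)\n", x$n_remapped,
              x$n, ifelse(is.na(x$rate), "NA",
                          sprintf("%.4f", x$rate))))
  invisible(x)
}

#' Two-side cross-mapped reads from the two sequential orders
#'
#' A read that maps validly in both genomes is assigned in step 1 of both
#' sequential orders; intersecting the first-step labels of the two runs
#' therefore identifies the two-side roster without a combined mapping:
#' host-origin reads labelled `S-TP_h1` (host-first) and `S-FN_h1`
#' (parasite-first); parasite-origin reads labelled `S-TP_p1`
#' (parasite-first) and `S-FN_p1` (host-first).
#'
#' @param labels_host_first,labels_parasite_first The two runs' labels
#'   over the same merged library.
#' @return list with read-id vectors `host` and `parasite`.
#' @export
intersect_two_side_sequential <- function(labels_host_first,
                                          labels_parasite_first) {
  if (!setequal(labels_host_first$read_id, labels_parasite_first$read_id))
    stop("the two runs cover different read universes", call. = FALSE)
  hf <- labels_host_first; pf <- labels_parasite_first
  list(host = intersect(hf$read_id[hf$label_host == "S-TP_h1"],
                        pf$read_id[pf$label_host == "S-FN_h1"]),
       parasite = intersect(pf$read_id[pf$label_parasite == "S-TP_p1"],
                            hf$read_id[hf$label_parasite == "S-FN_p1"]))
}

#' Two-side cross-mapped reads from the combined run
#'
#' @param labels The combined run's `assignment_labels`.
#' @return list with read-id vectors `host` and `parasite`, split by
#'   origin organism.
#' @export
two_side_combined <- function(labels) {
  if (!identical(unique(labels$strategy), "combined"))
    stop("`labels` must come from the combined run", call. = FALSE)
  two <- labels$category == "TWO_SIDE"
  list(host = labels$read_id[two & labels$origin == "host"],
       parasite = labels$read_id[two & labels$origin == "parasite"])
}

#' Summarise a read set over annotated loci (union-mode counting)
#'
#' Gene-level counting with union-mode semantics: a read pair counts for a
#' gene only if every retained placement overlaps exactly that one
#' annotated gene (either mate's aligned interval counts as overlap).
#' Pairs whose placements overlap no gene at all are `no_feature`; pairs
#' overlapping more than one gene — within one placement, or different
#' genes across placements, or a mix of genic and intergenic placements —
#' are `ambiguous`. The three groups partition the read set.
#'
#' @param read_ids Character vector of read ids to summarise.
#' @param reads The `read_library` the ids refer to.
#' @param index `seed_index` of the genome whose loci are being examined.
#' @param annotations Annotation data frame for that genome.
#' @param params [mapper_params()] used to obtain the placements.
#' @return data.frame with columns `gene_id`, `product`, `count`,
#'   including `no_feature` / `ambiguous` rows (product `NA`), counts
#'   summing to `length(read_ids)`.
#' @export
summarize_loci <- function(read_ids, reads, index, annotations,
                           params = mapper_params()) {
  plain <- sub("^(host|parasite)::", "", index$chrom$name)
  bad <- setdiff(annotations$chromosome, plain)
  if (length(bad))
    stop("annotation chromosome(s) absent from the genome index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  genes <- GenomicRanges::GRanges(factor(annotations$chromosome,
                                         levels = plain),
                                  IRanges::IRanges(annotations$start,
                                                   annotations$end))
  res <- stats::setNames(character(length(read_ids)), read_ids)
  if (!length(read_ids)) {
    return(data.frame(gene_id = character(0), product = character(0),
                      count = integer(0)))
  }
  sub <- reads[match(read_ids, reads$read_id), , drop = FALSE]
  if (anyNA(sub$read_id))
    stop("read id(s) absent from `reads`", call. = FALSE)
  m <- map_reads(sub, index, params, keep_hits = TRUE)
  hitlist <- attr(m, "hits")
  L1 <- nchar(sub$mate1); L2 <- nchar(sub$mate2)
  for (i in seq_along(read_ids)) {
    h <- hitlist[[i]]
    if (!nrow(h)) { res[i] <- "no_feature"; next }
    chrom <- sub("^(host|parasite)::", "", h$chromosome)
    iv <- GenomicRanges::GRanges(
      factor(rep(chrom, 2L), levels = plain),
      IRanges::IRanges(c(h$start + 1L, h$mate2_start + 1L),
                       c(h$start + L1[i], h$mate2_start + L2[i])))
    ov <- GenomicRanges::findOverlaps(iv, genes)
    hit_of <- rep(seq_len(nrow(h)), 2L)[S4Vectors::queryHits(ov)]
    gene_of <- annotations$gene_id[S4Vectors::subjectHits(ov)]
    per_hit <- lapply(seq_len(nrow(h)), function(j)
      unique(gene_of[hit_of == j]))
    genes_all <- unique(unlist(per_hit))
    n_per_hit <- lengths(per_hit)
    if (length(genes_all) == 0L) {
      res[i] <- "no_feature"
    } else if (length(genes_all) == 1L && all(n_per_hit == 1L)) {
      res[i] <- genes_all
    } else {
      res[i] <- "ambiguous"
    }
  }
  tab <- table(res)
  out <- data.frame(gene_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$product <- annotations$product[match(out$gene_id,
                                           annotations$gene_id)]
  out <- out[order(-out$count, out$gene_id), c("gene_id", "product",
                                               "count")]
  rownames(out) <- NULL
  out
}
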