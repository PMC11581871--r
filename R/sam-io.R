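#' Write mapper results as a minimal SAM file
#'
#' One pair of records per retained hit (secondary flag set beyond the
#' first), MAPQ 255, full-length `M` CIGAR, per-mate `NM` and per-pair
#' `NH` tags. Unmapped pairs are emitted with the unmapped flags so the
#' file round-trips through [ingest_alignments()] losslessly.
#'
#' @param reads `read_library` rows the hit sets were computed from.
#' @param hitsets List of [find_hits()] results, parallel to `reads`.
#' @param index The `seed_index` the hits refer to (for \code{@SQ} lines).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_sam <- function(reads, hitsets, index, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index$chrom$name,
                     index$chrom$length), con)
  for (i in seq_along(hitsets)) {
    hs <- hitsets[[i]]
    m1 <- reads$mate1[i]; m2 <- reads$mate2[i]
    if (!nrow(hs$hits)) {
      writeLines(sprintf("%s\t77\t*\t0\t0\t*\t*\t0\t0\t%s\t*", hs$read_id,
                         m1), con)
      writeLines(sprintf("%s\t141\t*\t0\t0\t*\t*\t0\t0\t%s\t*", hs$read_id,
                         m2), con)
      next
    }
    nh <- nrow(hs$hits)
    for (j in seq_len(nh)) {
      h <- hs$hits[j, ]
      sec <- if (j > 1L) 256L else 0L
      minus <- h$strand == "-"
      f1 <- 1L + 2L + 64L + sec + if (minus) 16L else 32L
      f2 <- 1L + 2L + 128L + sec + if (minus) 32L else 16L
      s1 <- if (minus) revcomp(m1) else m1
      s2 <- if (minus) m2 else revcomp(m2)
      p1 <- h$start + 1L
      p2 <- h$mate2_start + 1L
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                         hs$read_id, f1, h$chromosome, p1, nchar(m1), p2,
                         s1, h$mm_mate1, nh), con)
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                         hs$read_id, f2, h$chromosome, p2, nchar(m2), p1,
                         s2, h$mm_mate2, nh), con)
    }
  }
  invisible(file)
}

#' Ingest externally produced SAM/BAM alignments
#'
#' Lets alignments produced by any paired-end mapper flow through the same
#' downstream accounting as the built-in mapper. Records are grouped by
#' read name in memory (so the input need not be name-sorted); secondary
#' records are collapsed into a single hit list per pair; per-pair
#' mismatch counts are the summed mate `NM` tags.
#'
#' @param path SAM or BAM file.
#' @param default_tag Genome tag for unprefixed reference names; prefixed
#'   (`host::`/`parasite::`) names are resolved by [genome_tag()].
#' @return List of `hit_set` objects, one per read pair, in first-seen
#'   read order.
#' @export
ingest_alignments <- function(path, default_tag = NA_character_) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    # htslib downgrades unknown RNAMEs to unmapped with a warning;
    # surface them as the error they are before converting
    lines <- readLines(path)
    sq <- sub("\\t.*$", "",
              sub("^@SQ\\tSN:", "", lines[startsWith(lines, "@SQ")]))
    rec <- lines[!startsWith(lines, "@")]
    rname <- vapply(strsplit(rec, "\t", fixed = TRUE), `[[`, "", 3L)
    bad <- setdiff(rname, c("*", sq))
    if (length(bad))
      stop("unknown reference name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!length(hdr))
    stop("input has no @SQ header lines", call. = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mpos"),
    tag = c("NM", "NH"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rn <- as.character(rec$rname)
  known <- is.na(rn) | rn %in% names(hdr)
  if (!all(known))
    stop("unknown reference name(s): ",
         paste(unique(rn[!known]), collapse = ", "), call. = FALSE)
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(rec$qname))
  df <- data.frame(qname = rec$qname, flag = rec$flag, rname = rn,
                   pos = rec$pos, mpos = rec$mpos, nm = nm,
                   stringsAsFactors = FALSE)
  first_seen <- df$qname[!duplicated(df$qname)]
  out <- vector("list", length(first_seen))
  names(out) <- first_seen
  empty_hits <- data.frame(genome_tag = character(0),
                           chromosome = character(0), start = integer(0),
                           strand = character(0), mate2_start = integer(0),
                           mismatches = integer(0), mm_mate1 = integer(0),
                           mm_mate2 = integer(0))
  for (qn in first_seen) {
    g <- df[df$qname == qn, , drop = FALSE]
    mapped <- g[bitwAnd(g$flag, 4L) == 0L, , drop = FALSE]
    m1 <- mapped[bitwAnd(mapped$flag, 64L) == 64L, , drop = FALSE]
    m2 <- mapped[bitwAnd(mapped$flag, 128L) == 128L, , drop = FALSE]
    if (!nrow(m1)) {
      out[[qn]] <- structure(list(read_id = qn, status = "UNMAPPED",
                                  hits = empty_hits, n_qualifying = 0L),
                             class = "hit_set")
      next
    }
    mate2_nm <- vapply(seq_len(nrow(m1)), function(j) {
      hit2 <- which(m2$rname == m1$rname[j] & m2$pos == m1$mpos[j])
      if (length(hit2)) m2$nm[hit2[1L]] else NA_integer_
    }, integer(1))
    mate2_pos <- m1$mpos
    strand <- ifelse(bitwAnd(m1$flag, 16L) == 16L, "-", "+")
    hits <- data.frame(
      genome_tag = genome_tag(m1$rname, default_tag),
      chromosome = m1$rname, start = m1$pos - 1L, strand = strand,
      mate2_start = mate2_pos - 1L,
      mismatches = m1$nm + mate2_nm,
      mm_mate1 = m1$nm, mm_mate2 = mate2_nm,
      stringsAsFactors = FALSE)
    hits <- hits[order(hits$chromosome, hits$start, hits$strand), ,
                 drop = FALSE]
    hits <- hits[!duplicated(paste(hits$chromosome, hits$start,
                                   hits$strand)), , drop = FALSE]
    rownames(hits) <- NULL
    n <- nrow(hits)
    out[[qn]] <- structure(
      list(read_id = qn, status = if (n == 1L) "UNIQUE" else "MULTI",
           hits = hits, n_qualifying = n),
      class = "hit_set")
  }
  unname(out)
}
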