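#' Mapper filter parameters
#'
#' The two filters mirror the familiar short-read aligner knobs: a read
#' pair is retained only if its number of qualifying placements does not
#' exceed `max_multimap` (default 10) and a placement qualifies only if
#' the summed mismatch count over both mates does not exceed
#' `max_mismatch` (default 5; the relaxed remapping mode uses 10). The
#' mismatch cap applies to the pair total, one consistent knob.
#'
#' @param k Seed (k-mer) length for candidate generation; with
#'   `max_mismatch <= 5`, `k <= 15` and mates of at least 100 nt every
#'   qualifying mate is guaranteed a clean k-mer by pigeonhole, so
#'   candidate generation is exhaustive under the strict caps.
#' @param max_multimap Maximum reported placements per read pair.
#' @param max_mismatch Maximum summed mismatches per read pair.
#' @param insert_min,insert_max Allowed outer fragment span in bp.
#' @return An object of class `mapper_params`.
#' @export
mapper_params <- function(k = 15L, max_multimap = 10L, max_mismatch = 5L,
                          insert_min = 100L, insert_max = 500L) {
  k <- check_positive_int(k, "k")
  if (k < 8L) stop("configuration error: `k` must be >= 8", call. = FALSE)
  max_multimap <- check_positive_int(max_multimap, "max_multimap")
  if (!is.numeric(max_mismatch) || max_mismatch < 0)
    stop("configuration error: `max_mismatch` must be >= 0", call. = FALSE)
  if (insert_min > insert_max)
    stop("configuration error: `insert_min` exceeds `insert_max`",
         call. = FALSE)
  structure(list(k = k, max_multimap = as.integer(max_multimap),
                 max_mismatch = as.integer(max_mismatch),
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max)),
            class = "mapper_params")
}

#' Build an exact k-mer index over a genome
#'
#' Positions are 0-based. The index stores forward-strand k-mers; minus
#' strand occurrences are resolved by looking up the reverse complement
#' (see [lookup_kmer()]), which is how the mapper consults it.
#'
#' @param genome Named character vector of chromosome sequences over
#'   \{A,C,G,T\}.
#' @param k Seed length.
#' @param tag Optional genome tag (`"host"`/`"parasite"`) recorded on
#'   hits found against this index; for a concatenated genome the tag is
#'   derived per chromosome from the `host::`/`parasite::` name prefix.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(genome, k = 15L, tag = NA_character_) {
  if (!length(genome) || any(!nzchar(genome)))
    stop("empty genome: at least one non-empty chromosome is required",
         call. = FALSE)
  if (is.null(names(genome)) || anyNA(names(genome)) ||
      anyDuplicated(names(genome)))
    stop("chromosomes must have unique names", call. = FALSE)
  k <- check_positive_int(k, "k")
  for (cn in names(genome)) {
    bad <- regexpr("[^ACGT]", genome[[cn]])
    if (bad > 0)
      stop("non-ACGT character in ", cn, " at position ", bad, call. = FALSE)
  }
  lens <- nchar(genome)
  offsets <- c(0L, cumsum(as.integer(lens)))[seq_along(genome)]
  env <- new.env(hash = TRUE, parent = emptyenv())
  allk <- character(0)
  allp <- integer(0)
  for (i in seq_along(genome)) {
    L <- lens[[i]]
    if (L < k) next
    km <- substring(genome[[i]], 1:(L - k + 1L), k:L)
    allk <- c(allk, km)
    allp <- c(allp, offsets[i] + 0:(L - k))
  }
  tab <- split(allp, allk)
  list2env(tab, envir = env)
  structure(list(k = k, env = env,
                 chrom = data.frame(name = names(genome),
                                    length = as.integer(lens),
                                    offset = as.integer(offsets),
                                    stringsAsFactors = FALSE),
                 raw = lapply(genome, charToRaw),
                 tag = tag),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("k-mer seed index (k = %d): %d chromosome(s), %s bp%s\n",
              x$k, nrow(x$chrom),
              format(sum(x$chrom$length), big.mark = ","),
              if (is.na(x$tag)) "" else paste0(", tag = ", x$tag)))
  invisible(x)
}

#' Look up one k-mer in a seed index
#'
#' @param index A `seed_index`.
#' @param kmer A single k-mer of the index's k.
#' @return data.frame with columns `chromosome`, `pos` (0-based) and
#'   `strand`; minus-strand rows report forward-strand coordinates of
#'   reverse-complement occurrences.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  res <- list()
  for (st in c("+", "-")) {
    key <- if (st == "+") kmer else revcomp(kmer)
    g <- index$env[[key]]
    if (is.null(g)) next
    ci <- findInterval(g, index$chrom$offset)
    res[[st]] <- data.frame(chromosome = index$chrom$name[ci],
                            pos = g - index$chrom$offset[ci], strand = st,
                            stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(chromosome = character(0), pos = integer(0),
                      strand = character(0)))
  do.call(rbind, unname(res))
}

# mismatch counts of a raw pattern placed at 0-based positions pos0 of a
# raw chromosome; vectorised over positions, looped over pattern length
mm_at <- function(craw, patraw, pos0) {
  mm <- integer(length(pos0))
  if (!length(pos0)) return(mm)
  for (j in seq_along(patraw)) {
    mm <- mm + (craw[pos0 + j] != patraw[j])
  }
  mm
}

# candidate (chrom index, 0-based start) anchors for `pattern` from its
# clean k-mers; returns list(ci=, s=)
anchor_starts <- function(pattern, index) {
  k <- index$k
  L <- nchar(pattern)
  if (L < k) return(list(ci = integer(0), s = integer(0)))
  km <- substring(pattern, 1:(L - k + 1L), k:L)
  pos <- mget(km, envir = index$env, ifnotfound = list(NULL))
  ng <- lengths(pos)
  if (!sum(ng)) return(list(ci = integer(0), s = integer(0)))
  g <- unlist(pos, use.names = FALSE)
  o <- rep.int(seq_along(pos) - 1L, ng)
  cidx <- findInterval(g, index$chrom$offset)
  loc <- g - index$chrom$offset[cidx] - o
  ok <- loc >= 0L & loc + L <= index$chrom$length[cidx]
  ci <- cidx[ok]; s <- loc[ok]
  keep <- !duplicated(ci * 2^40 + s)
  list(ci = ci[keep], s = s[keep])
}

# all qualifying placements of (left, right) patterns on one strand
# orientation: left at s, right at r >= s, outer span (r + Lr - s) within
# [insert_min, insert_max], mm(left) + mm(right) <= cap.
# Placements are keyed by the mate-1 position downstream: when mate 1 is
# the left pattern (`key_side = "left"`) the alternatives for the right
# mate collapse to the best one per s; when mate 1 is the right pattern
# every qualifying r is a distinct placement and all are kept.
# Returns data.frame(ci, s, r, mm, mm_left, mm_right).
strand_placements <- function(left, right, index, params,
                              key_side = c("left", "right")) {
  key_side <- match.arg(key_side)
  Ll <- nchar(left); Lr <- nchar(right)
  imin <- max(params$insert_min, Ll, Lr)
  imax <- params$insert_max
  empty <- data.frame(ci = integer(0), s = integer(0), r = integer(0),
                      mm = integer(0), mm_left = integer(0),
                      mm_right = integer(0))
  if (imax < imin) return(empty)
  cap <- params$max_mismatch
  lraw <- charToRaw(left); rraw <- charToRaw(right)
  aL <- anchor_starts(left, index)
  aR <- anchor_starts(right, index)
  out <- list()
  for (cidx in unique(c(aL$ci, aR$ci))) {
    clen <- index$chrom$length[cidx]
    craw <- index$raw[[cidx]]
    S <- aL$s[aL$ci == cidx]
    rA <- aR$s[aR$ci == cidx]
    if (length(rA)) {
      # left starts implied by each right anchor, one per allowed span
      Sr <- unlist(lapply(rA, function(r)
        seq.int(r + Lr - imax, r + Lr - imin)), use.names = FALSE)
      S <- c(S, Sr)
    }
    S <- sort(unique(S[S >= 0L & S + Ll <= clen]))
    if (!length(S)) next
    mmL <- mm_at(craw, lraw, S)
    keep <- mmL <= cap
    S <- S[keep]; mmL <- mmL[keep]
    if (!length(S)) next
    # right-mate windows for surviving left starts
    Rwin <- lapply(S, function(s) {
      r <- seq.int(s + imin - Lr, s + imax - Lr)
      r[r >= s & r >= 0L & r + Lr <= clen]
    })
    Rall <- sort(unique(unlist(Rwin, use.names = FALSE)))
    if (!length(Rall)) next
    mmRall <- mm_at(craw, rraw, Rall)
    sv <- iv <- rv <- tv <- lv <- integer(0)
    for (i in seq_along(S)) {
      rs <- Rwin[[i]]
      if (!length(rs)) next
      mr <- mmRall[match(rs, Rall)]
      tot <- mmL[i] + mr
      ok <- which(tot <= cap)
      if (!length(ok)) next
      if (key_side == "left") ok <- ok[which.min(tot[ok])]
      sv <- c(sv, rep.int(S[i], length(ok))); rv <- c(rv, rs[ok])
      tv <- c(tv, tot[ok])
      lv <- c(lv, rep.int(mmL[i], length(ok))); iv <- c(iv, mr[ok])
    }
    if (length(sv))
      out[[length(out) + 1L]] <- data.frame(
        ci = cidx, s = sv, r = rv, mm = tv, mm_left = lv, mm_right = iv)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Find all qualifying placements of a read pair
#'
#' Candidate loci come from clean (error-free) k-mer anchors in either
#' mate, extended to a full contiguous Hamming comparison of both mates in
#' FR orientation within the allowed insert span. A placement qualifies if
#' the summed mismatches of the two mates do not exceed
#' `params$max_mismatch`. If only one mate has a qualifying placement the
#' pair is unmapped (mate-discard rule); if qualifying placements exceed
#' `params$max_multimap` the pair is reported `TOO_MANY` with its hit list
#' emptied, and counts as unmapped downstream. Identical placements are
#' deduplicated by (chromosome, mate-1 start, strand). No best-hit
#' selection is performed: all qualifying hits up to the cap are retained.
#'
#' @param pair A single-row `read_library` data.frame, or any list with
#'   elements `read_id`, `mate1`, `mate2`.
#' @param index A [build_index()] result.
#' @param params A [mapper_params()].
#' @return A list of class `hit_set`: `read_id`, `status` (one of
#'   `UNMAPPED`, `UNIQUE`, `MULTI`, `TOO_MANY`), and `hits`, a data.frame
#'   with columns `genome_tag`, `chromosome`, `start` (0-based position of
#'   mate 1), `strand`, `mate2_start`, `mismatches`, `mm_mate1`,
#'   `mm_mate2`.
#' @export
find_hits <- function(pair, index, params = mapper_params()) {
  m1 <- pair$mate1[[1L]]; m2 <- pair$mate2[[1L]]
  if (nchar(m1) < index$k || nchar(m2) < index$k)
    stop("mate shorter than seed length k = ", index$k, call. = FALSE)
  plus <- strand_placements(m1, revcomp(m2), index, params, "left")
  minus <- strand_placements(m2, revcomp(m1), index, params, "right")
  hits <- rbind(
    if (nrow(plus)) data.frame(ci = plus$ci, start = plus$s,
                               mate2_start = plus$r, strand = "+",
                               mismatches = plus$mm, mm_mate1 = plus$mm_left,
                               mm_mate2 = plus$mm_right),
    if (nrow(minus)) data.frame(ci = minus$ci, start = minus$r,
                                mate2_start = minus$s, strand = "-",
                                mismatches = minus$mm,
                                mm_mate1 = minus$mm_right,
                                mm_mate2 = minus$mm_left))
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(genome_tag = character(0), chromosome = character(0),
                       start = integer(0), strand = character(0),
                       mate2_start = integer(0), mismatches = integer(0),
                       mm_mate1 = integer(0), mm_mate2 = integer(0))
    return(structure(list(read_id = pair$read_id[[1L]], status = "UNMAPPED",
                          hits = hits, n_qualifying = 0L),
                     class = "hit_set"))
  }
  # dedupe identical placements (palindromic overlaps) by key, keep min mm
  key <- paste(hits$ci, hits$start, hits$strand)
  hits <- hits[order(key, hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$ci, hits$start, hits$strand)), ,
               drop = FALSE]
  chromnames <- index$chrom$name[hits$ci]
  hits <- data.frame(genome_tag = genome_tag(chromnames, index$tag),
                     chromosome = chromnames, start = hits$start,
                     strand = hits$strand, mate2_start = hits$mate2_start,
                     mismatches = hits$mismatches,
                     mm_mate1 = hits$mm_mate1, mm_mate2 = hits$mm_mate2,
                     stringsAsFactors = FALSE)
  n <- nrow(hits)
  status <- if (n == 1L) "UNIQUE" else if (n <= params$max_multimap)
    "MULTI" else "TOO_MANY"
  if (status == "TOO_MANY") hits <- hits[0L, , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(read_id = pair$read_id[[1L]], status = status, hits = hits,
                 n_qualifying = n),
            class = "hit_set")
}

#' Map genome-namespaced chromosome names back to their genome tag
#'
#' Chromosomes of a concatenated genome are prefixed `host::` /
#' `parasite::`; the tag inverts that prefixing. Unprefixed names fall
#' back to `default`.
#'
#' @param chromosome Character vector of chromosome names.
#' @param default Tag for unprefixed names.
#' @return Character vector of `"host"`/`"parasite"` (or `default`).
#' @export
genome_tag <- function(chromosome, default = NA_character_) {
  tag <- rep(default, length(chromosome))
  tag[startsWith(chromosome, "host::")] <- "host"
  tag[startsWith(chromosome, "parasite::")] <- "parasite"
  tag
}

#' Map every read pair of a library
#'
#' Convenience loop over [find_hits()] returning one row per pair.
#'
#' @param reads A `read_library` data.frame.
#' @param index A `seed_index`.
#' @param params A [mapper_params()].
#' @param keep_hits Keep each pair's hit table (as a list attached as the
#'   `"hits"` attribute, named by read_id)?
#' @return data.frame with columns `read_id`, `status`, `n_hits`,
#'   `n_host`, `n_parasite`.
#' @export
map_reads <- function(reads, index, params = mapper_params(),
                      keep_hits = FALSE) {
  ids <- reads$read_id; m1 <- reads$mate1; m2 <- reads$mate2
  hs <- lapply(seq_len(nrow(reads)), function(i)
    find_hits(list(read_id = ids[i], mate1 = m1[i], mate2 = m2[i]),
              index, params))
  out <- data.frame(
    read_id = vapply(hs, `[[`, character(1), "read_id"),
    status = vapply(hs, `[[`, character(1), "status"),
    n_hits = vapply(hs, function(h) nrow(h$hits), integer(1)),
    n_host = vapply(hs, function(h)
      sum(h$hits$genome_tag == "host", na.rm = TRUE), integer(1)),
    n_parasite = vapply(hs, function(h)
      sum(h$hits$genome_tag == "parasite", na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  if (keep_hits)
    attr(out, "hits") <- stats::setNames(lapply(hs, `[[`, "hits"),
                                         out$read_id)
  out
}
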