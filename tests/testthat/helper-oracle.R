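# Independent brute-force placement oracle.
#
# Enumerates every (chromosome, position, strand) placement of a read pair
# by a rolling full-genome Hamming profile -- no k-mer seeding, no shared
# code with the mapper's candidate generation.

# mismatch count of `pat` at every 0-based start of `craw`
oracle_mm_profile <- function(craw, pat) {
  P <- charToRaw(pat)
  n <- length(craw) - length(P) + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_along(P)) mm <- mm + (craw[j:(j + n - 1L)] != P[j])
  mm
}

oracle_placements <- function(mate1, mate2, genome, params) {
  rows <- list()
  for (cn in names(genome)) {
    craw <- charToRaw(genome[[cn]])
    for (st in c("+", "-")) {
      left <- if (st == "+") mate1 else mate2
      right <- if (st == "+") revcomp(mate2) else revcomp(mate1)
      Ll <- nchar(left); Lr <- nchar(right)
      imin <- max(params$insert_min, Ll, Lr)
      imax <- params$insert_max
      if (imax < imin) next
      mmL <- oracle_mm_profile(craw, left)
      mmR <- oracle_mm_profile(craw, right)
      for (s in seq_along(mmL) - 1L) {
        if (mmL[s + 1L] > params$max_mismatch) next
        rs <- seq.int(s + imin - Lr, s + imax - Lr)
        rs <- rs[rs >= s & rs >= 0L & rs + Lr <= length(craw)]
        if (!length(rs)) next
        tot <- mmL[s + 1L] + mmR[rs + 1L]
        if (min(tot) > params$max_mismatch) next
        if (st == "+") {
          # placement keyed by mate 1 (= left): alternatives collapse
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = cn, start = s, strand = st,
            mismatches = min(tot), stringsAsFactors = FALSE)
        } else {
          # mate 1 is the right pattern: every qualifying r is a placement
          ok <- tot <= params$max_mismatch
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = cn, start = rs[ok], strand = st,
            mismatches = tot[ok], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(chromosome = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$start, out$strand, out$mismatches), ,
             drop = FALSE]
  out <- out[!duplicated(out[c("chromosome", "start", "strand")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical form of a mapper hit table for comparison against the oracle
hit_key <- function(hits) {
  h <- hits[order(hits$chromosome, hits$start, hits$strand),
            c("chromosome", "start", "strand", "mismatches"), drop = FALSE]
  rownames(h) <- NULL
  h
}
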