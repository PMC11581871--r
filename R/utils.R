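#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Only the
#' uppercase/lowercase ACGT alphabet is handled; this is all the simulator
#' ever emits (no ambiguity codes, no indels).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# i.i.d. uniform nucleotide sequence of length n (single string)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-base substitution with probability `rate`; substituted bases are drawn
# uniformly from the three alternatives. Returns the mutated string.
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    repl <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1L),
                   character(1), USE.NAMES = FALSE)
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Fraction in [0,1] check with informative error naming the field
check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("configuration error: `", field, "` must be a fraction in [0, 1]",
         call. = FALSE)
  x
}

check_positive_int <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop("configuration error: `", field, "` must be a positive integer",
         call. = FALSE)
  as.integer(x)
}
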