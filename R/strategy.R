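#' Concatenate host and parasite genomes into one namespaced reference
#'
#' Every chromosome name is prefixed `host::` / `parasite::` so the two
#' name spaces cannot collide and the genome of origin of any hit can be
#' recovered exactly by [genome_tag()]. Sequences are unchanged.
#'
#' @param host_genome,parasite_genome Named character vectors of
#'   chromosome sequences.
#' @return Named character vector of the combined reference.
#' @export
concat_genomes <- function(host_genome, parasite_genome) {
  c(stats::setNames(host_genome, paste0("host::", names(host_genome))),
    stats::setNames(parasite_genome,
                    paste0("parasite::", names(parasite_genome))))
}

.categories <- c("UNIQUE_HOST", "MULTI_HOST", "UNIQUE_PARASITE",
                 "MULTI_PARASITE", "TWO_SIDE", "UNMAPPED")

.category_of <- function(status, organism) {
  ifelse(status == "UNIQUE", paste0("UNIQUE_", toupper(organism)),
         ifelse(status == "MULTI", paste0("MULTI_", toupper(organism)),
                "UNMAPPED"))
}

#' Sequential assignment: map to one genome, rescue leftovers on the other
#'
#' Step 1 maps every pair against the first genome; pairs mapping uniquely
#' or multiply are assigned to the first organism and the second genome is
#' never consulted for them (greedy, no second look). Unmapped and
#' over-cap pairs are forwarded to step 2 against the second genome; pairs
#' failing both are `UNMAPPED`.
#'
#' @param reads Merged `read_library`.
#' @param first_index,second_index `seed_index` objects built over the two
#'   genomes, tagged (`tag = "host"` / `"parasite"`) consistently with
#'   `order`.
#' @param params [mapper_params()] shared by both steps.
#' @param order `"host_first"` or `"parasite_first"`.
#' @return data.frame of class `assignment_set` with columns `read_id`,
#'   `strategy`, `order`, `category`, `step` (1, 2 or NA), `hits_host`,
#'   `hits_parasite`.
#' @export
assign_sequential <- function(reads, first_index, second_index,
                              params = mapper_params(),
                              order = c("host_first", "parasite_first")) {
  order <- match.arg(order)
  first_org <- if (order == "host_first") "host" else "parasite"
  second_org <- setdiff(c("host", "parasite"), first_org)
  if (!is.na(first_index$tag) && first_index$tag != first_org)
    stop("order `", order, "` is inconsistent with first_index tag `",
         first_index$tag, "`", call. = FALSE)
  if (!is.na(second_index$tag) && second_index$tag != second_org)
    stop("order `", order, "` is inconsistent with second_index tag `",
         second_index$tag, "`", call. = FALSE)
  if (first_index$k != second_index$k)
    stop("the two indexes must share the same seed length k", call. = FALSE)

  step1 <- map_reads(reads, first_index, params)
  assigned1 <- step1$status %in% c("UNIQUE", "MULTI")
  category <- rep("UNMAPPED", nrow(reads))
  step <- rep(NA_integer_, nrow(reads))
  hits_first <- step1$n_hits
  hits_second <- integer(nrow(reads))
  category[assigned1] <- .category_of(step1$status[assigned1], first_org)
  step[assigned1] <- 1L
  hits_first[!assigned1] <- 0L

  if (any(!assigned1)) {
    step2 <- map_reads(reads[!assigned1, , drop = FALSE], second_index,
                       params)
    assigned2 <- step2$status %in% c("UNIQUE", "MULTI")
    idx2 <- which(!assigned1)
    category[idx2[assigned2]] <- .category_of(step2$status[assigned2],
                                              second_org)
    step[idx2[assigned2]] <- 2L
    hits_second[idx2] <- ifelse(assigned2, step2$n_hits, 0L)
  }

  out <- data.frame(
    read_id = reads$read_id, strategy = "sequential", order = order,
    category = category, step = step,
    hits_host = if (first_org == "host") hits_first else hits_second,
    hits_parasite = if (first_org == "host") hits_second else hits_first,
    stringsAsFactors = FALSE)
  class(out) <- c("assignment_set", "data.frame")
  out
}

#' Combined assignment: one competitive mapping on the concatenated genome
#'
#' A single [find_hits()] pass per pair over the concatenated reference,
#' with the multimap cap applied to the total hit count across both
#' genomes jointly (that is what a single aligner invocation on a
#' concatenated reference does). Retained hits are partitioned by genome
#' tag: all-host or all-parasite pairs are assigned by locus count; pairs
#' with hits on both sides are `TWO_SIDE`; pairs with no retained hits
#' (including over-cap pairs) are `UNMAPPED`.
#'
#' @param reads Merged `read_library`.
#' @param combined_index `seed_index` over [concat_genomes()] output.
#' @param params [mapper_params()].
#' @return data.frame of class `assignment_set` (see
#'   [assign_sequential()]); `order` is `"NA"`.
#' @export
assign_combined <- function(reads, combined_index,
                            params = mapper_params()) {
  if (!any(startsWith(combined_index$chrom$name, "host::")) ||
      !any(startsWith(combined_index$chrom$name, "parasite::")))
    stop("combined_index must be built over concat_genomes() output",
         call. = FALSE)
  m <- map_reads(reads, combined_index, params)
  category <- ifelse(
    m$n_hits == 0L, "UNMAPPED",
    ifelse(m$n_host > 0L & m$n_parasite > 0L, "TWO_SIDE",
           ifelse(m$n_host > 0L,
                  ifelse(m$n_host == 1L, "UNIQUE_HOST", "MULTI_HOST"),
                  ifelse(m$n_parasite == 1L, "UNIQUE_PARASITE",
                         "MULTI_PARASITE"))))
  out <- data.frame(read_id = reads$read_id, strategy = "combined",
                    order = NA_character_, category = category,
                    step = ifelse(category == "UNMAPPED", NA_integer_, 1L),
                    hits_host = m$n_host, hits_parasite = m$n_parasite,
                    stringsAsFactors = FALSE)
  class(out) <- c("assignment_set", "data.frame")
  out
}

#' Write an assignment set as TSV
#'
#' @param outcomes An `assignment_set`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_assignments <- function(outcomes, file) {
  utils::write.table(as.data.frame(outcomes), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
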