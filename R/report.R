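#' Assemble a mapping-statistics row from category counts
#'
#' The row mirrors the benchmark report layout: processed reads, unique /
#' multiple counts per organism, the two-side column (combined strategy
#' only) and unmapped, with each category also expressed as a percentage
#' of processed reads. `mapped` excludes two-side cross-mapped reads: the
#' mapped total counts only reads attributed to exactly one organism.
#'
#' @param unique_host,multi_host,unique_parasite,multi_parasite,two_side,unmapped
#'   Category counts (read pairs).
#' @param processed Total processed pairs; defaults to the category sum
#'   and a mismatch is an error (the categories partition the library).
#' @param interaction,replicate,strategy,order Optional identifiers.
#' @return One-row data.frame of class `run_row`.
#' @export
run_row_from_counts <- function(unique_host, multi_host, unique_parasite,
                                multi_parasite, unmapped, two_side = 0L,
                                processed = NULL, interaction = NA,
                                replicate = NA, strategy = NA, order = NA) {
  total <- unique_host + multi_host + unique_parasite + multi_parasite +
    two_side + unmapped
  if (is.null(processed)) processed <- total
  if (processed != total)
    stop("category counts (", total, ") do not sum to processed reads (",
         processed, ")", call. = FALSE)
  mapped <- unique_host + multi_host + unique_parasite + multi_parasite
  row <- data.frame(
    interaction = interaction, replicate = replicate, strategy = strategy,
    order = order, processed = processed,
    unique_host = unique_host, multi_host = multi_host,
    unique_parasite = unique_parasite, multi_parasite = multi_parasite,
    two_side = two_side, unmapped = unmapped, mapped = mapped,
    mapped_percent = 100 * mapped / processed,
    pct_unique_host = 100 * unique_host / processed,
    pct_multi_host = 100 * multi_host / processed,
    pct_unique_parasite = 100 * unique_parasite / processed,
    pct_multi_parasite = 100 * multi_parasite / processed,
    pct_two_side = 100 * two_side / processed,
    pct_unmapped = 100 * unmapped / processed,
    stringsAsFactors = FALSE)
  class(row) <- c("run_row", "data.frame")
  row
}

#' Tabulate one assignment run into a mapping-statistics row
#'
#' @param outcomes An `assignment_set`.
#' @param interaction,replicate Optional identifiers carried into the row.
#' @return One-row data.frame of class `run_row` (see
#'   [run_row_from_counts()]).
#' @export
tabulate_run <- function(outcomes, interaction = NA, replicate = NA) {
  n <- function(cat) sum(outcomes$category == cat)
  run_row_from_counts(
    unique_host = n("UNIQUE_HOST"), multi_host = n("MULTI_HOST"),
    unique_parasite = n("UNIQUE_PARASITE"),
    multi_parasite = n("MULTI_PARASITE"),
    two_side = n("TWO_SIDE"), unmapped = n("UNMAPPED"),
    interaction = interaction, replicate = replicate,
    strategy = outcomes$strategy[1L], order = outcomes$order[1L])
}

#' Average mapping-statistics rows over replicates
#'
#' Counts are averaged arithmetically; percentage fields are recomputed as
#' mean count over mean processed (not as the mean of the row
#' percentages), which is the only convention under which averaged counts
#' and averaged percentages stay mutually consistent. `*_M` fields render
#' the means in millions, rounded to 2 decimals.
#'
#' @param rows `run_row` data.frames rbind-ed together (or a list).
#' @return One-row data.frame of class `replicate_summary`.
#' @export
average_replicates <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  if (!nrow(rows)) stop("no rows to average", call. = FALSE)
  grp <- unique(rows[c("interaction", "strategy", "order")])
  if (nrow(grp) > 1L)
    stop("rows mix (interaction, strategy, order) groupings", call. = FALSE)
  cnt <- c("processed", "unique_host", "multi_host", "unique_parasite",
           "multi_parasite", "two_side", "unmapped", "mapped")
  means <- colMeans(rows[cnt])
  out <- data.frame(interaction = grp$interaction, strategy = grp$strategy,
                    order = grp$order, n_replicates = nrow(rows),
                    stringsAsFactors = FALSE)
  for (f in cnt) {
    out[[f]] <- means[[f]]
    out[[paste0(f, "_M")]] <- round(means[[f]] / 1e6, 2)
    if (f != "processed")
      out[[paste0("pct_", f)]] <- 100 * means[[f]] / means[["processed"]]
  }
  out$mapped_percent <- out$pct_mapped
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' Category-flow edge list for a run (Sankey-style accounting)
#'
#' Two levels of edges: the merged library splits into host-assigned,
#' parasite-assigned, two-side and unmapped pools, and each organism pool
#' splits into its unique/multiple categories. Edge weights are read
#' counts (and millions); totals are conserved at every node.
#'
#' @param outcomes An `assignment_set`.
#' @return data.frame with columns `from`, `to`, `reads`, `millions`.
#' @export
flow_table <- function(outcomes) {
  if (!nrow(outcomes))
    return(data.frame(from = character(0), to = character(0),
                      reads = integer(0), millions = numeric(0)))
  n <- function(cat) sum(outcomes$category == cat)
  host <- n("UNIQUE_HOST") + n("MULTI_HOST")
  par <- n("UNIQUE_PARASITE") + n("MULTI_PARASITE")
  edges <- data.frame(
    from = c("merged", "merged", "merged", "merged",
             "host_assigned", "host_assigned",
             "parasite_assigned", "parasite_assigned"),
    to = c("host_assigned", "parasite_assigned", "two_side", "unmapped",
           "unique_host", "multi_host", "unique_parasite",
           "multi_parasite"),
    reads = c(host, par, n("TWO_SIDE"), n("UNMAPPED"),
              n("UNIQUE_HOST"), n("MULTI_HOST"),
              n("UNIQUE_PARASITE"), n("MULTI_PARASITE")),
    stringsAsFactors = FALSE)
  edges <- edges[edges$reads > 0L | edges$from == "merged", , drop = FALSE]
  edges$millions <- round(edges$reads / 1e6, 2)
  rownames(edges) <- NULL
  edges
}

#' Bundled published mapping-count tables
#'
#' Plain-text copies of the per-replicate read and mapping counts of the
#' Arabidopsis/tomato versus dodder dual RNA-seq benchmark libraries
#' (labelled by ENA run accession), used to exercise the report arithmetic
#' on realistic magnitudes: per-replicate library sizes before/after
#' pre-processing, sequential-strategy category counts (both orders) and
#' combined-strategy category counts including the two-side column.
#'
#' @param table One of `"libraries"`, `"sequential"`, `"combined"`.
#' @return data.frame.
#' @export
published_counts <- function(table = c("libraries", "sequential",
                                       "combined")) {
  table <- match.arg(table)
  f <- system.file("extdata", paste0(table, "_counts.tsv"),
                   package = "dualmapsim", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}
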