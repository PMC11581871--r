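#' Run the full dual RNA-seq separation benchmark on synthetic data
#'
#' End-to-end pipeline: generate a genome pair, simulate host and parasite
#' libraries, merge them, assign the merged reads by the sequential
#' strategy in both orders and by the combined strategy, label every pair
#' against the known truth, compute the per-organism evaluation metrics,
#' and quantify one-side (with relaxed remapping) and two-side
#' cross-mapping including gene-level summaries of the two-side loci.
#'
#' All randomness flows from `seed` (generator and library seeds are
#' derived from it deterministically).
#'
#' @param genome_spec A [genome_pair_spec()]; its `seed` is overwritten
#'   from `seed`.
#' @param host_library,parasite_library [library_spec()]s; seeds likewise
#'   derived from `seed`.
#' @param params Strict-mode [mapper_params()].
#' @param relaxed_params Relaxed-mode params for the one-side remap.
#' @param seed Master integer seed.
#' @param verbose Log per-stage read counts via [message()]?
#' @return An object of class `dual_benchmark`; see Details.
#' @details The returned list contains `genome_pair`, the merged `reads`,
#'   per-run `outcomes` and `labels` (named `host_first`,
#'   `parasite_first`, `combined`), the per-run `metrics` table, per-run
#'   mapping-statistics `rows`, the `crossmap` summary (one-side sets and
#'   remap rates, two-side rosters from both routes, two-side host locus
#'   table) and the combined-run `flow` edge list.
#' @export
run_dual_benchmark <- function(genome_spec = genome_pair_spec(),
                               host_library = library_spec(read_length = 150L),
                               parasite_library = library_spec(
                                 n_pairs = 1500L, read_length = 100L),
                               params = mapper_params(),
                               relaxed_params = mapper_params(
                                 max_mismatch = 10L),
                               seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  genome_spec$seed <- seed
  host_library$seed <- seed + 1L
  parasite_library$seed <- seed + 2L

  if (genome_spec$gene_length < 2L * max(host_library$read_length,
                                         parasite_library$read_length))
    stop("gene_length must be at least twice the longest read length",
         call. = FALSE)

  pair <- generate_genome_pair(genome_spec)
  say("genome pair: host %d bp, parasite %d bp, %d homologous pairs",
      sum(nchar(pair$host)), sum(nchar(pair$parasite)),
      nrow(pair$homology))

  host_lib <- simulate_library(pair$host, pair$annotations_host,
                               host_library, "host")
  par_lib <- simulate_library(pair$parasite, pair$annotations_parasite,
                              parasite_library, "parasite")
  reads <- merge_libraries(host_lib, par_lib, seed = seed + 3L)
  say("merged library: %d + %d = %d read pairs", nrow(host_lib),
      nrow(par_lib), nrow(reads))
  truth <- stats::setNames(reads$organism, reads$read_id)

  idx_host <- build_index(pair$host, params$k, tag = "host")
  idx_par <- build_index(pair$parasite, params$k, tag = "parasite")
  idx_comb <- build_index(concat_genomes(pair$host, pair$parasite),
                          params$k)

  outcomes <- list(
    host_first = assign_sequential(reads, idx_host, idx_par, params,
                                   "host_first"),
    parasite_first = assign_sequential(reads, idx_par, idx_host, params,
                                       "parasite_first"),
    combined = assign_combined(reads, idx_comb, params))
  labels <- lapply(outcomes, label_assignments, truth = truth)
  for (nm in names(outcomes))
    say("%s: %s", nm,
        paste(names(table(outcomes[[nm]]$category)),
              table(outcomes[[nm]]$category), collapse = ", "))

  metrics <- do.call(rbind, lapply(labels, run_metrics))
  rownames(metrics) <- NULL
  rows <- do.call(rbind, lapply(names(outcomes), function(nm)
    tabulate_run(outcomes[[nm]], interaction = "synthetic",
                 replicate = 1L)))

  one_side_seq <- extract_one_side(labels$host_first, "sequential",
                                   labels$parasite_first)
  one_side_com <- extract_one_side(labels$combined, "combined")
  remap <- list(
    sequential = list(
      host = relaxed_remap(one_side_seq$host, reads, idx_host,
                           relaxed_params, params),
      parasite = relaxed_remap(one_side_seq$parasite, reads, idx_par,
                               relaxed_params, params)),
    combined = list(
      host = relaxed_remap(one_side_com$host, reads, idx_host,
                           relaxed_params, params),
      parasite = relaxed_remap(one_side_com$parasite, reads, idx_par,
                               relaxed_params, params)))

  two_seq <- intersect_two_side_sequential(labels$host_first,
                                           labels$parasite_first)
  two_com <- two_side_combined(labels$combined)
  two_host_all <- union(two_seq$host, two_seq$parasite)
  loci <- summarize_loci(two_host_all, reads, idx_host,
                         pair$annotations_host, params)
  say("two-side: sequential %d, combined %d",
      length(two_seq$host) + length(two_seq$parasite),
      length(two_com$host) + length(two_com$parasite))

  structure(list(genome_pair = pair, reads = reads, truth = truth,
                 outcomes = outcomes, labels = labels, metrics = metrics,
                 rows = rows,
                 crossmap = list(one_side_sequential = one_side_seq,
                                 one_side_combined = one_side_com,
                                 remap = remap,
                                 two_side_sequential = two_seq,
                                 two_side_combined = two_com,
                                 two_side_host_loci = loci),
                 flow = flow_table(outcomes$combined),
                 params = params, seed = seed),
            class = "dual_benchmark")
}

#' @export
print.dual_benchmark <- function(x, ...) {
  cat("Dual RNA-seq read-separation benchmark (synthetic)\n")
  cat(sprintf("  merged library: %d read pairs (seed %d)\n", nrow(x$reads),
              x$seed))
  cat("\nMapping statistics (read pairs):\n")
  cols <- c("strategy", "order", "unique_host", "multi_host",
            "unique_parasite", "multi_parasite", "two_side", "unmapped")
  print(as.data.frame(x$rows)[cols], row.names = FALSE)
  cat("\nEvaluation metrics:\n")
  print(x$metrics, row.names = FALSE, digits = 5)
  ts <- x$crossmap$two_side_sequential
  tc <- x$crossmap$two_side_combined
  cat(sprintf("\nTwo-side cross-mapped pairs: %d (sequential intersection), %d (combined)\n",
              length(ts$host) + length(ts$parasite),
              length(tc$host) + length(tc$parasite)))
  invisible(x)
}

#' @export
summary.dual_benchmark <- function(object, ...) {
  print(object)
  cat("\nTwo-side host loci (union-mode counts):\n")
  print(utils::head(object$crossmap$two_side_host_loci, 10L),
        row.names = FALSE)
  rem <- object$crossmap$remap
  for (strat in names(rem))
    for (org in names(rem[[strat]])) {
      r <- rem[[strat]][[org]]
      cat(sprintf("one-side %s/%s: n=%d, remap rate %s\n", strat, org,
                  r$n, ifelse(is.na(r$rate), "NA",
                              sprintf("%.2f%%", 100 * r$rate))))
    }
  invisible(object)
}

#' Write the benchmark's tabular outputs as TSV files
#'
#' Emits the per-strategy assignment tables, the metrics table, the
#' mapping-statistics rows, the one-/two-side cross-map summaries, the
#' two-side locus table and the flow edge list under `dir`.
#'
#' @param bench A `dual_benchmark`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_tables <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  paths <- c(
    vapply(names(bench$outcomes), function(nm)
      w(bench$outcomes[[nm]], sprintf("assignments_%s.tsv", nm)),
      character(1)),
    w(bench$metrics, "metrics.tsv"),
    w(bench$rows, "mapping_statistics.tsv"),
    w(data.frame(
      set = rep(c("one_side_sequential", "one_side_combined",
                  "two_side_sequential", "two_side_combined"),
                times = c(
                  lengths(bench$crossmap$one_side_sequential) |> sum(),
                  lengths(bench$crossmap$one_side_combined) |> sum(),
                  lengths(bench$crossmap$two_side_sequential) |> sum(),
                  lengths(bench$crossmap$two_side_combined) |> sum())),
      organism = c(
        rep(names(bench$crossmap$one_side_sequential),
            lengths(bench$crossmap$one_side_sequential)),
        rep(names(bench$crossmap$one_side_combined),
            lengths(bench$crossmap$one_side_combined)),
        rep(names(bench$crossmap$two_side_sequential),
            lengths(bench$crossmap$two_side_sequential)),
        rep(names(bench$crossmap$two_side_combined),
            lengths(bench$crossmap$two_side_combined))),
      read_id = c(unlist(bench$crossmap$one_side_sequential,
                         use.names = FALSE),
                  unlist(bench$crossmap$one_side_combined,
                         use.names = FALSE),
                  unlist(bench$crossmap$two_side_sequential,
                         use.names = FALSE),
                  unlist(bench$crossmap$two_side_combined,
                         use.names = FALSE))),
      "crossmap_reads.tsv"),
    w(bench$crossmap$two_side_host_loci, "two_side_host_loci.tsv"),
    w(bench$flow, "flow.tsv"))
  invisible(paths)
}
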