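test_that("published per-replicate counts reproduce the printed percentages", {
  seq_tab <- published_counts("sequential")
  r1 <- seq_tab[seq_tab$interaction == "Arabidopsis-Cuscuta" &
                  seq_tab$replicate == 1 & seq_tab$order == "host_first", ]
  row <- run_row_from_counts(r1$unique_host, r1$multi_host,
                             r1$unique_parasite, r1$multi_parasite,
                             r1$unmapped)
  expect_equal(row$processed, 33950197)
  expect_equal(row$mapped, 33127593)
  expect_equal(round(row$mapped_percent, 2), 97.58)
  expect_equal(round(row$pct_unique_host), 55)
  expect_equal(round(row$pct_multi_host), 1)
  expect_equal(round(row$pct_unique_parasite), 38)
  expect_equal(round(row$pct_multi_parasite), 3)
  expect_equal(round(row$pct_unmapped), 2)
  # every published sequential row reproduces its printed mapped percent
  printed <- c(97.58, 98.14, 97.26, 97.58, 98.14, 97.26,
               89.29, 90.94, 88.62, 89.29, 90.94, 88.62)
  got <- vapply(seq_len(nrow(seq_tab)), function(i) {
    r <- seq_tab[i, ]
    round(run_row_from_counts(r$unique_host, r$multi_host,
                              r$unique_parasite, r$multi_parasite,
                              r$unmapped)$mapped_percent, 2)
  }, numeric(1))
  expect_equal(got, printed)
})

test_that("combined-strategy counts keep two-side out of the mapped total", {
  comb <- published_counts("combined")
  r1 <- comb[comb$interaction == "Arabidopsis-Cuscuta" &
               comb$replicate == 1, ]
  row <- run_row_from_counts(r1$unique_host, r1$multi_host,
                             r1$unique_parasite, r1$multi_parasite,
                             r1$unmapped, two_side = r1$two_side)
  expect_equal(row$processed, 33950197)
  expect_equal(row$mapped, 33079535)
  expect_equal(round(row$mapped_percent, 2), 97.44)
  expect_equal(round(row$pct_unique_host, 1), 54.7)
  expect_equal(round(row$pct_two_side, 2), 0.01)
  expect_error(run_row_from_counts(1, 1, 1, 1, 1, processed = 10),
               "do not sum")
})

test_that("merged library sizes equal the sum of the published inputs", {
  libs <- published_counts("libraries")
  seq_tab <- published_counts("sequential")
  pre <- stats::setNames(libs$preprocessed_reads, libs$ena_run)
  expect_equal(unname(pre["SRR22559142"] + pre["SRR12763776"]), 33950197)
  for (i in seq_len(nrow(seq_tab)))
    expect_equal(unname(pre[seq_tab$host_run[i]] +
                          pre[seq_tab$parasite_run[i]]),
                 seq_tab$processed[i])
})

test_that("replicate averages use mean count over mean processed", {
  seq_tab <- published_counts("sequential")
  hf <- seq_tab[seq_tab$interaction == "Arabidopsis-Cuscuta" &
                  seq_tab$order == "host_first", ]
  rows <- do.call(rbind, lapply(seq_len(3L), function(i)
    run_row_from_counts(hf$unique_host[i], hf$multi_host[i],
                        hf$unique_parasite[i], hf$multi_parasite[i],
                        hf$unmapped[i], interaction = "AC",
                        strategy = "sequential", order = "host_first",
                        replicate = i)))
  avg <- average_replicates(rows)
  expect_equal(avg$unique_host_M, 18.99)
  expect_equal(round(avg$pct_unique_host, 2), 54.49)
  expect_equal(avg$processed, mean(hf$processed))
  # single row: summary equals the row
  one <- average_replicates(rows[1L, ])
  expect_equal(one$unique_host, rows$unique_host[1L])
  expect_equal(one$pct_unique_host, rows$pct_unique_host[1L])
  # three equal rows: summary equals any row
  same <- average_replicates(rows[c(1L, 1L, 1L), ])
  expect_equal(same$unique_host, rows$unique_host[1L])
  expect_error(average_replicates(rbind(rows, within(rows[1L, ],
                                                     order <- "x"))),
               "mix")
})

test_that("tabulated synthetic runs agree with their outcome tables", {
  b <- shared_bench()
  for (run in names(b$outcomes)) {
    out <- b$outcomes[[run]]
    row <- tabulate_run(out)
    expect_equal(row$processed, nrow(out))
    expect_equal(row$unique_host, sum(out$category == "UNIQUE_HOST"))
    expect_equal(row$two_side, sum(out$category == "TWO_SIDE"))
    expect_equal(row$unique_host + row$multi_host + row$unique_parasite +
                   row$multi_parasite + row$two_side + row$unmapped,
                 row$processed)
  }
})

test_that("flow edges conserve totals and match the tabulated counts", {
  b <- shared_bench()
  out <- b$outcomes$combined
  fl <- flow_table(out)
  first <- fl[fl$from == "merged", ]
  expect_equal(sum(first$reads), nrow(out))
  row <- tabulate_run(out)
  expect_equal(first$reads[first$to == "host_assigned"],
               row$unique_host + row$multi_host)
  expect_equal(sum(fl$reads[fl$from == "parasite_assigned"]),
               first$reads[first$to == "parasite_assigned"])
  expect_equal(flow_table(out[0L, ]),
               data.frame(from = character(0), to = character(0),
                          reads = integer(0), millions = numeric(0)))
})

test_that("run rows survive a TSV round trip", {
  b <- shared_bench()
  rows <- b$rows
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(rows), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  for (cn in c("processed", "unique_host", "multi_host", "unique_parasite",
               "multi_parasite", "two_side", "unmapped", "mapped"))
    expect_equal(back[[cn]], rows[[cn]])
  expect_equal(back$mapped_percent, rows$mapped_percent,
               tolerance = 1e-10)
})

test_that("benchmark tables and config are written and read back", {
  b <- shared_bench()
  d <- withr::local_tempdir()
  paths <- write_benchmark_tables(b, d)
  expect_true(all(file.exists(paths)))
  asg <- utils::read.delim(file.path(d, "assignments_host_first.tsv"))
  expect_equal(nrow(asg), nrow(b$reads))
  expect_true(all(c("read_id", "strategy", "order", "category",
                    "hits_host", "hits_parasite") %in% names(asg)))
  cfgf <- file.path(d, "config.yaml")
  write_benchmark_config(b$genome_pair$spec,
                         library_spec(seed = 2L),
                         library_spec(read_length = 100L, seed = 3L),
                         b$params, cfgf)
  cfg <- read_benchmark_config(cfgf)
  expect_equal(cfg$genome, b$genome_pair$spec)
  expect_equal(cfg$mapper, b$params)
  expect_equal(cfg$parasite_library$read_length, 100L)
})
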