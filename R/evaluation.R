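#' Truth-aware labeling of assignment outcomes
#'
#' Every read pair's outcome is translated into the dual label taxonomy:
#' each assignment event carries a host-reference label and a
#' parasite-reference alias of the same event (e.g. a host-origin pair
#' assigned to the host in step 1 of a host-first sequential run is
#' `S-TP_h1` for the host reference and `S-TN_p1` for the parasite
#' reference). The numeric subscript is the mapping step at which the pair
#' was assigned. In the combined run a `TWO_SIDE` pair counts against its
#' origin organism (`C-FN` for the origin, `C-FP` for the other). Pairs
#' unmapped in every genome are `UNMAPPED_BOTH` on both sides.
#'
#' @param outcomes An `assignment_set`.
#' @param truth Named character vector mapping read_id to origin organism
#'   (`"host"`/`"parasite"`), or a `read_library` / data.frame with
#'   `read_id` and `organism` columns.
#' @return data.frame of class `assignment_labels` with columns `read_id`,
#'   `strategy`, `order`, `origin`, `category`, `label_host`,
#'   `label_parasite`.
#' @export
label_assignments <- function(outcomes, truth) {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$organism, truth$read_id)
  missing <- setdiff(outcomes$read_id, names(truth))
  if (length(missing))
    stop("read id(s) absent from truth: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  origin <- unname(truth[outcomes$read_id])
  stopifnot(all(origin %in% c("host", "parasite")))

  to_host <- outcomes$category %in% c("UNIQUE_HOST", "MULTI_HOST")
  to_par <- outcomes$category %in% c("UNIQUE_PARASITE", "MULTI_PARASITE")
  two <- outcomes$category == "TWO_SIDE"
  unm <- outcomes$category == "UNMAPPED"

  lh <- rep(NA_character_, nrow(outcomes))
  lp <- rep(NA_character_, nrow(outcomes))
  strat <- outcomes$strategy

  seq_i <- strat == "sequential"
  if (any(seq_i)) {
    step <- outcomes$step
    sub <- ifelse(is.na(step), "", as.character(step))
    host_orig <- origin == "host"
    lh[seq_i & to_host & host_orig] <-
      paste0("S-TP_h", sub[seq_i & to_host & host_orig])
    lp[seq_i & to_host & host_orig] <-
      paste0("S-TN_p", sub[seq_i & to_host & host_orig])
    lh[seq_i & to_host & !host_orig] <-
      paste0("S-FP_h", sub[seq_i & to_host & !host_orig])
    lp[seq_i & to_host & !host_orig] <-
      paste0("S-FN_p", sub[seq_i & to_host & !host_orig])
    lh[seq_i & to_par & !host_orig] <-
      paste0("S-TN_h", sub[seq_i & to_par & !host_orig])
    lp[seq_i & to_par & !host_orig] <-
      paste0("S-TP_p", sub[seq_i & to_par & !host_orig])
    lh[seq_i & to_par & host_orig] <-
      paste0("S-FN_h", sub[seq_i & to_par & host_orig])
    lp[seq_i & to_par & host_orig] <-
      paste0("S-FP_p", sub[seq_i & to_par & host_orig])
  }

  com_i <- strat == "combined"
  if (any(com_i)) {
    host_orig <- origin == "host"
    wrong_h <- to_par | two
    wrong_p <- to_host | two
    lh[com_i & host_orig & to_host] <- "C-TP_h"
    lp[com_i & host_orig & to_host] <- "C-TN_p"
    lh[com_i & host_orig & wrong_h] <- "C-FN_h"
    lp[com_i & host_orig & wrong_h] <- "C-FP_p"
    lh[com_i & !host_orig & to_par] <- "C-TN_h"
    lp[com_i & !host_orig & to_par] <- "C-TP_p"
    lh[com_i & !host_orig & wrong_p] <- "C-FP_h"
    lp[com_i & !host_orig & wrong_p] <- "C-FN_p"
  }

  lh[unm] <- "UNMAPPED_BOTH"
  lp[unm] <- "UNMAPPED_BOTH"
  stopifnot(!anyNA(lh), !anyNA(lp))

  out <- data.frame(read_id = outcomes$read_id, strategy = strat,
                    order = outcomes$order, origin = origin,
                    category = outcomes$category,
                    label_host = lh, label_parasite = lp,
                    stringsAsFactors = FALSE)
  class(out) <- c("assignment_labels", "data.frame")
  out
}

#' Aggregate labels into a per-organism confusion matrix
#'
#' Pairs unmapped in every genome are excluded from all four cells: the
#' metrics measure the quality of the assignments actually made. By
#' construction of the dual labels, TP(host) = TN(parasite) and
#' FP(host) = FN(parasite); this duality is verified and a violation is an
#' internal error.
#'
#' @param labels An `assignment_labels` data.frame from a single
#'   (strategy, order) run.
#' @param organism `"host"` or `"parasite"`.
#' @return A list of class `confusion_counts`: `organism`, `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(labels, organism = c("host", "parasite")) {
  organism <- match.arg(organism)
  runs <- unique(paste(labels$strategy, labels$order))
  if (length(runs) > 1L)
    stop("labels mix runs: ", paste(runs, collapse = " / "), call. = FALSE)
  side <- if (organism == "host") labels$label_host else labels$label_parasite
  other <- if (organism == "host") labels$label_parasite else labels$label_host
  tally <- function(x, cls) sum(grepl(paste0("-", cls, "_"), x, fixed = TRUE))
  counts <- list(organism = organism,
                 TP = tally(side, "TP"), FP = tally(side, "FP"),
                 TN = tally(side, "TN"), FN = tally(side, "FN"))
  stopifnot(counts$TP == tally(other, "TN"),
            counts$FP == tally(other, "FN"))
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (%s): TP=%d FP=%d TN=%d FN=%d\n",
              x$organism, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Evaluation metrics from a confusion matrix
#'
#' precision = TP/(TP+FP); sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP); accuracy = (TP+TN)/(TP+TN+FP+FN).
#' An undefined (0/0) metric is reported as `NA`, never as 0 or 1.
#'
#' @param counts A [confusion_counts()] result (or any list with TP, FP,
#'   TN, FN).
#' @return A list of class `metric_set`: `precision`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0))
      stop("negative confusion counts", call. = FALSE)
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    structure(list(precision = ratio(TP, TP + FP),
                   sensitivity = ratio(TP, TP + FN),
                   specificity = ratio(TN, TN + FP),
                   accuracy = ratio(TP + TN, TP + TN + FP + FN)),
              class = "metric_set")
  })
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("precision %s  sensitivity %s  specificity %s  accuracy %s\n",
              format(x$precision, digits = 7),
              format(x$sensitivity, digits = 7),
              format(x$specificity, digits = 7),
              format(x$accuracy, digits = 7)))
  invisible(x)
}

#' Per-organism metric table for one labelled run
#'
#' @param labels An `assignment_labels` data.frame (single run).
#' @return One-row data.frame with the eight per-organism metrics plus
#'   strategy/order identifiers, mirroring a per-replicate metrics table
#'   row.
#' @export
run_metrics <- function(labels) {
  row <- list(strategy = labels$strategy[1L], order = labels$order[1L])
  for (org in c("host", "parasite")) {
    m <- compute_metrics(confusion_counts(labels, org))
    names(m) <- paste0(names(m), "_", org)
    row <- c(row, m)
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}
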