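#' @title Long-format symptom records and the data cube
#' @description Helpers to validate long-format ordinal symptom records
#'   (person, week, item, score), apply the QIDS recoding rules, assemble the
#'   complete persons x items x times data cube, and compute sum scores.
#' @name cube_io
NULL

#' Canonical item order of the recoded 12-item QIDS
#'
#' The 16 QIDS items collapse to 12: the hyposomnia items 1-3 are merged into
#' one item (maximum score), and the mutually exclusive appetite (6, 7) and
#' weight (8, 9) pairs are merged likewise. The order below is the display
#' order used for all symptom-mode outputs.
#' @return character vector of the 12 recoded item ids.
#' @export
qids_item_order <- function() {
  c("1-3", "4", "5", "6/7", "8/9", "10", "11", "12", "13", "14", "15", "16")
}

#' Descriptive labels for the recoded QIDS items
#' @return named character vector keyed by recoded item id.
#' @export
qids_item_labels <- function() {
  c("1-3" = "Hyposomnia", "4" = "Hypersomnia", "5" = "Feeling sad",
    "6/7" = "Changed appetite", "8/9" = "Changed weight",
    "10" = "Concentration", "11" = "View of myself",
    "12" = "Thoughts of death/suicide", "13" = "General interest",
    "14" = "Energy level", "15" = "Psychomotor retardation",
    "16" = "Psychomotor agitation")
}

validate_records <- function(records, allowed_scores) {
  stopifnot(is.data.frame(records))
  need <- c("person_id", "time", "item", "score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_hetcube("records lack required columns: %s", paste(miss, collapse = ", "),
                 class = "hetcube_invalid_input")
  bad <- which(!(records$score %in% allowed_scores))
  if (length(bad)) {
    b <- records[bad[1L], ]
    stop_hetcube(
      "invalid score %s for person %s, time %s, item %s (allowed: %s)",
      format(b$score), b$person_id, b$time, b$item,
      paste(allowed_scores, collapse = ","),
      class = "hetcube_invalid_input")
  }
  key <- paste(records$person_id, records$time, records$item, sep = "\r")
  if (anyDuplicated(key))
    stop_hetcube("duplicate (person, time, item) records present",
                 class = "hetcube_invalid_input")
  invisible(records)
}

#' Merge the rarely endorsed top category into category 2
#'
#' Scores on the raw 4-point scale (0,1,2,3) are collapsed to a 3-point scale
#' (0,1,2) by replacing every 3 with 2; all other scores are unchanged.
#'
#' @param records data frame with columns `person_id`, `time`, `item`, `score`.
#' @return the records with scores on the 0-2 scale; row count unchanged.
#' @export
merge_top_category <- function(records) {
  validate_records(records, allowed_scores = 0:3)
  records$score <- ifelse(records$score == 3L, 2L, as.integer(records$score))
  records
}

#' Collapse composite QIDS items by the maximum rule
#'
#' Items 1, 2 and 3 (sleep-onset, mid-nocturnal and early-morning insomnia)
#' become one hyposomnia item `"1-3"` holding the highest of the three scores.
#' The mutually exclusive pairs 6/7 (appetite) and 8/9 (weight) are collapsed
#' the same way. If both members of a mutually-exclusive pair are nonzero for
#' some person-time the maximum still applies but a warning is raised, since
#' the instrument forbids that pattern. The output has exactly 12 items per
#' person-time, ordered as [qids_item_order()]. Idempotent on already-recoded
#' records.
#'
#' @param records data frame of 0-2 scores with raw item ids `"1"`..`"16"`
#'   (or already-recoded ids, in which case it is the identity).
#' @return recoded records, canonically sorted.
#' @export
recode_items <- function(records) {
  validate_records(records, allowed_scores = 0:2)
  records$item <- as.character(records$item)
  if (all(records$item %in% qids_item_order())) {
    return(sort_records(records))  # already recoded: idempotence
  }
  groups <- list("1-3" = c("1", "2", "3"), "6/7" = c("6", "7"), "8/9" = c("8", "9"))
  keep <- c("4", "5", "10", "11", "12", "13", "14", "15", "16")
  known <- c(unlist(groups), keep)
  unknown <- setdiff(unique(records$item), known)
  if (length(unknown))
    stop_hetcube("unknown item ids: %s", paste(unknown, collapse = ", "),
                 class = "hetcube_invalid_input")
  all_pt <- unique(paste(records$person_id, records$time, sep = "\r"))
  out <- records[records$item %in% keep, , drop = FALSE]
  for (new_id in names(groups)) {
    members <- groups[[new_id]]
    sub <- records[records$item %in% members, , drop = FALSE]
    tab <- table(paste(sub$person_id, sub$time, sep = "\r"))
    if (!setequal(names(tab), all_pt) || any(tab != length(members)))
      stop_hetcube("incomplete data: constituent of item %s missing for some person-time",
                   new_id, class = "hetcube_incomplete_data")
    if (new_id %in% c("6/7", "8/9")) {
      nz <- tapply(sub$score > 0, list(sub$person_id, sub$time), sum)
      if (any(nz > 1, na.rm = TRUE))
        warning(sprintf("items %s: both members nonzero for %d person-time(s); maximum rule applied",
                        new_id, sum(nz > 1, na.rm = TRUE)))
    }
    agg <- stats::aggregate(score ~ person_id + time, data = sub, FUN = max)
    agg$item <- new_id
    out <- rbind(out, agg[, c("person_id", "time", "item", "score")])
  }
  sort_records(out)
}

sort_records <- function(records) {
  items <- qids_item_order()
  io <- match(records$item, items)
  io[is.na(io)] <- length(items) + seq_len(sum(is.na(io)))  # non-QIDS items last, stable
  ord <- order(as.character(records$person_id), records$time, io)
  rec <- records[ord, c("person_id", "time", "item", "score"), drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Assemble the persons x items x times data cube
#'
#' Builds a complete three-mode array from long records. Every
#' (person, item, time) cell must be present exactly once: the multiway
#' decomposition cannot handle missing data, so incomplete persons must be
#' dropped upstream, never imputed.
#'
#' @param records long records (recoded or generic items).
#' @param item_order optional character vector fixing the item axis order;
#'   defaults to [qids_item_order()] when all items belong to it, otherwise
#'   sorted unique items.
#' @return a `data_cube`: numeric n x m x T array with dimnames
#'   `persons`, `items`, `times`.
#' @export
build_cube <- function(records, item_order = NULL) {
  stopifnot(is.data.frame(records))
  records$item <- as.character(records$item)
  persons <- sort(unique(as.character(records$person_id)))
  times <- sort(unique(as.numeric(records$time)))
  items <- item_order %||% (
    if (all(records$item %in% qids_item_order()))
      intersect(qids_item_order(), unique(records$item))
    else sort(unique(records$item)))
  n <- length(persons); m <- length(items); TT <- length(times)
  if (n < 2 || m < 2 || TT < 2)
    stop_hetcube("cube needs at least 2 levels per mode (got %d x %d x %d)",
                 n, m, TT, class = "hetcube_invalid_input")
  i <- match(as.character(records$person_id), persons)
  j <- match(records$item, items)
  t <- match(as.numeric(records$time), times)
  if (anyNA(j))
    stop_hetcube("records contain items outside item_order",
                 class = "hetcube_invalid_input")
  x <- array(NA_real_, dim = c(n, m, TT),
             dimnames = list(persons = persons, items = items, times = times))
  x[cbind(i, j, t)] <- records$score
  if (anyNA(x)) {
    nm <- sum(is.na(x))
    stop_hetcube(
      "%d missing (person, item, time) cell(s): the three-mode decomposition cannot handle missing data; drop incomplete persons first",
      nm, class = "hetcube_missing_data")
  }
  if (nrow(records) != n * m * TT)
    stop_hetcube("duplicate (person, item, time) records",
                 class = "hetcube_invalid_input")
  structure(x, class = c("data_cube", "array"))
}

#' Per-person sum-score trajectories
#'
#' Sums the m recoded item scores at each person-time, the severity outcome
#' used by the growth-curve models.
#'
#' @param cube a `data_cube` of integer ordinal scores.
#' @return n x T integer matrix with person/time dimnames.
#' @export
sum_scores <- function(cube) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  if (max(abs(cube - round(cube))) > 1e-9)
    stop_hetcube("sum scores are defined only on integer ordinal cubes",
                 class = "hetcube_invalid_input")
  out <- apply(cube, c(1, 3), sum)
  dimnames(out) <- dimnames(cube)[c(1, 3)]
  out
}

#' Flatten a cube back to long records
#' @param cube a `data_cube`.
#' @return data frame with columns `person_id`, `time`, `item`, `score`,
#'   canonically sorted; `build_cube()` on the result restores the cube.
#' @export
cube_to_records <- function(cube) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  dn <- dimnames(cube)
  g <- expand.grid(person_id = dn[[1]], item = dn[[2]], time = as.numeric(dn[[3]]),
                   stringsAsFactors = FALSE)
  g$score <- as.vector(cube)
  sort_records(g[, c("person_id", "time", "item", "score")])
}

#' Read long-format records from CSV
#' @param path CSV with header columns `person_id,time,item,score`.
#' @return validated records data frame.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(person_id = "character", item = "character"))
  need <- c("person_id", "time", "item", "score")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop_hetcube("CSV lacks required columns: %s", paste(miss, collapse = ", "),
                 class = "hetcube_invalid_input")
  sort_records(rec[, need])
}

#' Write long-format records to CSV
#'
#' Canonically sorted so that write-read-write is byte stable.
#' @param records records data frame.
#' @param path output CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(sort_records(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
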