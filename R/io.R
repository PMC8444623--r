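#' Write a cohort to a directory of plain-text files
#'
#' One TSV per subject and phase (`sub-XXX_phase-<phase>.tsv`; rows are
#' nodes, first column `node_id`, remaining columns volumes), plus
#' `participants.tsv` (subject, group, age, sex, education, suvr,
#' memory, accuracy), `parcellation.tsv` and, for synthetic cohorts,
#' `truth.json` (ground truth; written alongside but never read by the
#' analysis functions).
#'
#' @param cohort a `memnet_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    for (ph in names(s$phases)) {
      dat <- s$phases[[ph]]$data
      df <- data.frame(node_id = rownames(dat), dat, check.names = FALSE)
      colnames(df)[-1L] <- paste0("v", seq_len(ncol(dat)))
      utils::write.table(df, file.path(dir, sprintf("%s_phase-%s.tsv",
                                                    s$subject, ph)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(participants(cohort), file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$parcellation))
    utils::write.table(cohort$parcellation, file.path(dir, "parcellation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$planted_partition <- as.list(tr$planted_partition)
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a node time-series TSV
#'
#' Auto-detects orientation: a `node_id` first column (or a
#' non-numeric first column) means rows are nodes; otherwise rows are
#' volumes and the header holds node ids.
#'
#' @param path TSV file.
#' @return nodes-by-volumes numeric matrix with node-id row names.
#' @export
read_node_timeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  first <- df[[1L]]
  if (names(df)[1L] == "node_id" || is.character(first) || is.factor(first)) {
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(first)
  } else {
    m <- t(as.matrix(df))
  }
  colnames(m) <- NULL
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("NA/NaN cells in ", path)
  m
}

#' Load a cohort from a directory
#'
#' Reads `participants.tsv` and one phase TSV per subject and phase.
#' Ground truth (`truth.json`), if present, is deliberately not loaded;
#' use [read_truth()] in evaluation code.
#'
#' @param dir cohort directory written by [write_cohort()] (or with the
#'   same layout).
#' @param phases phase names to load.
#' @param parcellation optional parcellation table; when given, node
#'   counts and ids of every file are validated against it.
#' @param tr_seconds repetition time recorded on the loaded phases.
#' @return a `memnet_cohort` (with `truth = NULL`).
#' @export
load_cohort <- function(dir, phases = c("encoding", "maintenance", "retrieval"),
                        parcellation = NULL, tr_seconds = 3) {
  pfile <- file.path(dir, "participants.tsv")
  if (!file.exists(pfile)) stop("missing ", pfile)
  pt <- utils::read.delim(pfile, stringsAsFactors = FALSE)
  req <- c("subject", "group", "age", "sex", "education", "suvr", "memory",
           "accuracy")
  miss <- setdiff(req, names(pt))
  if (length(miss)) stop("participants.tsv lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(parcellation)) {
    pq <- file.path(dir, "parcellation.tsv")
    if (file.exists(pq)) parcellation <- utils::read.delim(pq, stringsAsFactors = FALSE)
  }
  subjects <- lapply(seq_len(nrow(pt)), function(i) {
    sid <- pt$subject[i]
    ph_list <- lapply(phases, function(ph) {
      f <- file.path(dir, sprintf("%s_phase-%s.tsv", sid, ph))
      if (!file.exists(f)) stop("missing phase file ", f)
      m <- read_node_timeseries(f)
      if (!is.null(parcellation)) {
        if (nrow(m) != nrow(parcellation))
          stop("subject ", sid, ": ", nrow(m), " nodes in ", basename(f),
               " but parcellation has ", nrow(parcellation))
        if (!identical(rownames(m), parcellation$node_id))
          m <- m[parcellation$node_id, , drop = FALSE]
      }
      phase_bold(m, phase = ph, tr_seconds = tr_seconds, subject = sid)
    })
    names(ph_list) <- phases
    c(as.list(pt[i, req]), list(phases = ph_list))
  })
  structure(list(subjects = subjects, truth = NULL,
                 parcellation = parcellation, config = NULL),
            class = "memnet_cohort")
}

#' Read the ground-truth file of a synthetic cohort
#'
#' @param dir cohort directory.
#' @return list as stored in `truth.json`.
#' @export
read_truth <- function(dir) {
  f <- file.path(dir, "truth.json")
  if (!file.exists(f)) stop("no truth.json in ", dir)
  tr <- jsonlite::read_json(f, simplifyVector = TRUE)
  tr$planted_partition <- unlist(tr$planted_partition)
  tr
}
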