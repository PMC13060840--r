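#' Dataset curation configuration
#'
#' Defaults follow the curation protocol: entries longer than 256 residues
#' are dropped, training sequences with more than 70 percent identity to any
#' test sequence are excluded, training crops are 256 residues long, and
#' apo-holo evaluation targets require a pair RMSD above 4.0 A with each
#' conformer's baseline RMSD above 2.5 A.
#'
#' @param max_residues length filter threshold (strict `>` drops).
#' @param similarity_threshold percent identity above which a training entry
#'   is excluded.
#' @param crop_length random crop window length N_res.
#' @param pair_rmsd_min apo-holo pair RMSD lower bound (strict `>` keeps).
#' @param conformer_rmsd_min per-conformer baseline RMSD lower bound.
#' @param dr bin width used when pairing P(r) curves with crops.
#' @param seed integer seed for random cropping.
#' @return object of class `curation_config`.
#' @export
curation_config <- function(max_residues = 256, similarity_threshold = 70,
                            crop_length = 256, pair_rmsd_min = 4.0,
                            conformer_rmsd_min = 2.5, dr = 0.5, seed = 1) {
  stopifnot(max_residues > 0, similarity_threshold > 0, crop_length > 0,
            pair_rmsd_min > 0, conformer_rmsd_min > 0)
  structure(list(max_residues = as.integer(max_residues),
                 similarity_threshold = similarity_threshold,
                 crop_length = as.integer(crop_length),
                 pair_rmsd_min = pair_rmsd_min,
                 conformer_rmsd_min = conformer_rmsd_min,
                 dr = dr, seed = as.integer(seed)),
            class = "curation_config")
}

#' Split a multi-model structure file into conformers
#'
#' Reads a deposited multi-model file (e.g. a solution-NMR entry) and
#' returns one structure per MODEL block, order preserved. Models whose
#' sequences disagree raise a malformed-ensemble error.
#'
#' @param path PDB (or mmCIF, single-model) file path.
#' @param id entry identifier (default: file base name).
#' @return a `conformer_ensemble`.
#' @export
split_models <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  res <- read_structure(path)
  if (inherits(res, "saxs_structure")) {
    conformer_ensemble(list(res), id = id)
  } else {
    res$id <- id
    res
  }
}

#' Length-filter ensembles
#'
#' Drops every ensemble whose residue count exceeds `max_residues`
#' (strict `>`), logging a per-entry reason.
#'
#' @param ensembles list of `conformer_ensemble`s.
#' @param config a `curation_config`.
#' @return list with `kept` (ensembles) and `report` (data.frame of
#'   entry, length, kept, reason).
#' @export
filter_length <- function(ensembles, config = curation_config()) {
  lens <- vapply(ensembles, function(e) n_residues(e$models[[1]]), integer(1))
  keep <- lens <= config$max_residues
  report <- data.frame(
    entry = vapply(ensembles, function(e) e$id, character(1)),
    length = lens,
    kept = keep,
    reason = ifelse(keep, "",
                    sprintf("length %d > %d", lens, config$max_residues)),
    stringsAsFactors = FALSE
  )
  list(kept = ensembles[keep], report = report)
}

#' Percent sequence identity from optimal global alignment
#'
#' Needleman-Wunsch global alignment with unit match score, zero mismatch
#' score and linear gap penalty -1; identity is the number of identical
#' aligned positions divided by the alignment length (gaps included), times
#' 100. Because co-optimal alignments can differ in match count, the
#' traceback uses a fixed tie-break (diagonal, then gap-in-second, then
#' gap-in-first) and the two sequences are ordered canonically first, making
#' the measure deterministic and symmetric.
#'
#' @param a,b non-empty one-letter sequences.
#' @return percent identity in [0, 100].
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(a)
  b <- toupper(b)
  if (a > b) {
    tmp <- a
    a <- b
    b <- tmp
  }
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  s <- matrix(0, n + 1, m + 1)
  s[1, ] <- -(0:m)
  s[, 1] <- -(0:n)
  for (i in seq_len(n)) {
    match_row <- (x[i] == y) * 1
    for (j in seq_len(m)) {
      s[i + 1, j + 1] <- max(s[i, j] + match_row[j],
                             s[i, j + 1] - 1, s[i + 1, j] - 1)
    }
  }
  # traceback with fixed tie-break: diagonal > gap in y > gap in x
  i <- n
  j <- m
  matches <- 0L
  alen <- 0L
  while (i > 0 || j > 0) {
    alen <- alen + 1L
    if (i > 0 && j > 0 &&
        s[i + 1, j + 1] == s[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1
      j <- j - 1
    } else if (i > 0 && s[i + 1, j + 1] == s[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * matches / alen
}

#' Exclude training entries similar to test entries
#'
#' A training entry is excluded when its identity to ANY test sequence
#' exceeds the threshold (strict `>`).
#'
#' @param train_seqs named character vector of training sequences.
#' @param test_seqs character vector of test sequences.
#' @param config a `curation_config`.
#' @return list with `kept` (names), `excluded` (names) and `report`
#'   (data.frame of entry, max_identity, closest_test, kept).
#' @export
exclude_similar <- function(train_seqs, test_seqs, config = curation_config()) {
  if (is.null(names(train_seqs))) {
    names(train_seqs) <- paste0("train", seq_along(train_seqs))
  }
  rows <- lapply(names(train_seqs), function(nm) {
    ids <- vapply(test_seqs, function(ts) sequence_identity(train_seqs[[nm]], ts),
                  numeric(1))
    best <- which.max(ids)
    data.frame(entry = nm, max_identity = ids[best],
               closest_test = best,
               kept = ids[best] <= config$similarity_threshold,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(kept = report$entry[report$kept],
       excluded = report$entry[!report$kept],
       report = report)
}

#' Randomly crop a structure to a contiguous residue window
#'
#' Picks a uniform random start under the given seed and keeps
#' `crop_length` contiguous residues (1-based, inclusive window ends);
#' structures no longer than the crop length are returned whole.
#'
#' @param structure a `saxs_structure`.
#' @param config a `curation_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with `structure` (cropped) and `window` c(start, end) in
#'   residue positions.
#' @export
crop_random <- function(structure, config = curation_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  resk <- unique(structure$atoms[, c("chain", "resno")])
  len <- nrow(resk)
  if (len <= config$crop_length) {
    return(list(structure = structure, window = c(1L, len)))
  }
  set.seed(seed)
  start <- sample.int(len - config$crop_length + 1L, 1)
  end <- start + config$crop_length - 1L
  sel_res <- resk[start:end, , drop = FALSE]
  keep <- paste(structure$atoms$chain, structure$atoms$resno) %in%
    paste(sel_res$chain, sel_res$resno)
  cropped <- structure
  cropped$atoms <- structure$atoms[keep, , drop = FALSE]
  cropped$sequence <- derive_sequence(cropped$atoms)
  list(structure = cropped, window = c(start, end))
}

#' Build training records for one conformer ensemble
#'
#' One record per model: the model is cropped (all models share the same
#' crop window so the ensemble stays aligned) and its P(r) is computed from
#' exactly the cropped coordinates, giving a (structure, profile) pair with
#' full provenance.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param config a `curation_config`.
#' @return list of records, each with `entry`, `model_id`, `window`,
#'   `structure` and `pr` (normalized `pr_curve`).
#' @export
build_training_records <- function(ensemble, config = curation_config()) {
  first <- crop_random(ensemble$models[[1]], config)
  window <- first$window
  lapply(seq_along(ensemble$models), function(m) {
    s <- ensemble$models[[m]]
    resk <- unique(s$atoms[, c("chain", "resno")])
    sel <- resk[window[1]:min(window[2], nrow(resk)), , drop = FALSE]
    keep <- paste(s$atoms$chain, s$atoms$resno) %in% paste(sel$chain, sel$resno)
    cs <- s
    cs$atoms <- s$atoms[keep, , drop = FALSE]
    cs$sequence <- derive_sequence(cs$atoms)
    list(entry = ensemble$id, model_id = s$model_id, window = window,
         structure = cs,
         pr = compute_pr(cs, dr = config$dr, normalize = TRUE))
  })
}

#' Select apo-holo evaluation targets
#'
#' Keeps a candidate pair iff its length is at most `max_residues`, the
#' apo-holo pair RMSD exceeds `pair_rmsd_min`, and each conformer's
#' precomputed baseline RMSD exceeds `conformer_rmsd_min` (all strict).
#'
#' @param candidates data.frame with columns `entry`, `length`, `pair_rmsd`,
#'   `conformer_rmsd_apo`, `conformer_rmsd_holo` (per-conformer columns may
#'   be replaced by a single `conformer_rmsd`).
#' @param config a `curation_config`.
#' @return the selected rows, with a `kept` logical column added to the full
#'   table in attribute `"report"`.
#' @export
select_apo_holo_targets <- function(candidates, config = curation_config()) {
  conf_cols <- intersect(c("conformer_rmsd", "conformer_rmsd_apo",
                           "conformer_rmsd_holo"), names(candidates))
  if (!length(conf_cols)) stop("candidates need a conformer RMSD column")
  conf_ok <- Reduce(`&`, lapply(conf_cols, function(cc)
    candidates[[cc]] > config$conformer_rmsd_min))
  kept <- candidates$length <= config$max_residues &
    candidates$pair_rmsd > config$pair_rmsd_min & conf_ok
  report <- candidates
  report$kept <- kept
  out <- candidates[kept, , drop = FALSE]
  attr(out, "report") <- report
  out
}
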