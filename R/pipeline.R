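# The cascade duplicate search: bucket by residue count m, prefilter on the
# 9-component average invariant, confirm on the full invariant, report.
# The Chebyshev lower bound (average distance <= full distance) makes the
# prefilter exact: no pair within the threshold can be lost.

#' Group chains into buckets of equal residue count
#'
#' The residue count m is the simplest integer invariant; chains of
#' different m are never compared.
#'
#' @param chains list of `backbone_chain` objects.
#' @return Named list (names = m) of lists of chains.
#' @export
group_by_length <- function(chains) {
  if (length(chains) == 0L) return(structure(list(), names = character(0)))
  split(chains, vapply(chains, function(ch) ch$m, integer(1)))
}

#' Prefilter a bucket on the average invariant
#'
#' Exact Chebyshev range search on the 9 average coordinates: chains are
#' sorted on the first coordinate, a sliding window bounds the scan, and the
#' full 9-coordinate check decides.  Returns exactly the pairs whose average
#' invariants are within `t` in every coordinate — a guaranteed superset of
#' the pairs whose full invariants are within `t`.
#'
#' @param brains n x 9 matrix of average invariants (one row per chain).
#' @param t threshold in Angstrom.
#' @return Two-column integer matrix of candidate row pairs (i < j).
#' @export
brain_prefilter <- function(brains, t) {
  brains <- as.matrix(brains)
  n <- nrow(brains)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  ord <- order(brains[, 1L])
  s <- brains[ord, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && s[j, 1L] - s[i, 1L] <= t) {
      if (max(abs(s[j, ] - s[i, ])) <= t) {
        pairs[[length(pairs) + 1L]] <- sort(c(ord[i], ord[j]))
      }
      j <- j + 1L
    }
  }
  if (!length(pairs)) return(matrix(integer(0), 0L, 2L))
  unique(do.call(rbind, pairs))
}

#' Confirm candidate pairs on the full invariant
#'
#' @param chains list of `backbone_chain` (one bucket, equal m).
#' @param bris list of their `bri_matrix` objects (same order).
#' @param candidates two-column index matrix from [brain_prefilter()].
#' @param t threshold in Angstrom.
#' @param exclude_same_entry drop pairs whose chains share an entry id.
#' @return Data frame of confirmed duplicate pairs: entry/chain ids of both
#'   partners, `m`, `d_brain`, `d_bri` (with `d_brain <= d_bri <= t`).
#' @export
confirm_duplicates <- function(chains, bris, candidates, t,
                               exclude_same_entry = TRUE) {
  rows <- list()
  brains <- lapply(bris, compute_brain)
  if (nrow(candidates)) {
    for (r in seq_len(nrow(candidates))) {
      i <- candidates[r, 1L]; j <- candidates[r, 2L]
      a <- chains[[i]]; b <- chains[[j]]
      if (exclude_same_entry && a$entry_id == b$entry_id) next
      if (a$entry_id == b$entry_id && a$chain_id == b$chain_id) next
      d <- bri_distance(bris[[i]], bris[[j]])
      if (d <= t) {
        rows[[length(rows) + 1L]] <- data.frame(
          entry1 = a$entry_id, chain1 = a$chain_id,
          entry2 = b$entry_id, chain2 = b$chain_id,
          m = a$m, d_brain = brain_distance(brains[[i]], brains[[j]]),
          d_bri = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(entry1 = character(0), chain1 = character(0),
               entry2 = character(0), chain2 = character(0),
               m = integer(0), d_brain = numeric(0), d_bri = numeric(0))
}

#' Forensic comparison of two chains of equal length
#'
#' The per-pair statistics of a duplicate report: the maximum Euclidean
#' deviation over the 3m corresponding trace atoms in the raw deposited
#' coordinate frames (no superposition — duplicates share their deposition
#' frame, and a uniform 0.001 Angstrom axis shift is visible only this way)
#' and the count of residue positions whose amino-acid codes differ (a
#' relabelled duplicate has untouched coordinates but a nonzero count).
#'
#' @param a,b `backbone_chain` objects with equal m; pairing is positional
#'   (residue k to residue k).
#' @param meta optional named list carried through to the report
#'   (resolution1, rfree1, resolution2, rfree2).
#' @param superpose also compute the maximum deviation after optimal
#'   superposition (`max_dev_superposed`).
#' @return One-row data frame of class `pair_report`: ids, `n_residues`,
#'   `n_diff_res`, metadata, `max_dev`, `d_brain`, `d_bri`.
#' @export
compare_pair_details <- function(a, b, meta = list(), superpose = FALSE) {
  if (a$m != b$m) {
    stop_dupscan("chains have different residue counts", "dupscan_length_mismatch")
  }
  ca_ <- chain_coords(a); cb_ <- chain_coords(b)
  max_dev <- sqrt(max(rowSums((ca_ - cb_)^2)))
  bri_a <- compute_bri(a); bri_b <- compute_bri(b)
  out <- data.frame(
    entry1 = a$entry_id, chain1 = a$chain_id,
    entry2 = b$entry_id, chain2 = b$chain_id,
    n_residues = a$m, n_diff_res = sum(a$aa != b$aa),
    resolution1 = if (is.null(meta$resolution1)) NA_real_ else meta$resolution1,
    rfree1 = if (is.null(meta$rfree1)) NA_real_ else meta$rfree1,
    resolution2 = if (is.null(meta$resolution2)) NA_real_ else meta$resolution2,
    rfree2 = if (is.null(meta$rfree2)) NA_real_ else meta$rfree2,
    d_brain = brain_distance(compute_brain(bri_a), compute_brain(bri_b)),
    d_bri = bri_distance(bri_a, bri_b),
    max_dev = max_dev, stringsAsFactors = FALSE)
  if (superpose) {
    fit <- kabsch_superpose(ca_, cb_)
    moved <- apply_rigid_motion(ca_, fit$motion)
    out$max_dev_superposed <- sqrt(max(rowSums((moved - cb_)^2)))
  }
  class(out) <- c("pair_report", "data.frame")
  out
}

#' Run the full cascade over a set of cleaned chains
#'
#' @param chains list of `backbone_chain` objects.
#' @param policy a [filter_policy()]; `policy$threshold` is the duplicate
#'   cut-off t.
#' @param meta optional data frame of per-entry metadata (columns entry_id,
#'   resolution, r_free) merged into the reports.
#' @return Data frame of pair reports (class `pair_report`), sorted by
#'   (entry1, entry2, chain1, chain2); zero rows if no duplicates.
#' @export
scan_chains <- function(chains, policy = filter_policy(), meta = NULL) {
  t <- policy$threshold
  buckets <- group_by_length(chains)
  reports <- list()
  for (bk in buckets) {
    if (length(bk) < 2L) next
    bris <- lapply(bk, compute_bri)
    brains <- t(vapply(bris, compute_brain, numeric(9)))
    cand <- brain_prefilter(brains, t)
    confirmed <- confirm_duplicates(bk, bris, cand, t,
                                    exclude_same_entry = policy$exclude_same_entry)
    if (!nrow(confirmed)) next
    for (r in seq_len(nrow(confirmed))) {
      ia <- which(vapply(bk, function(ch)
        ch$entry_id == confirmed$entry1[r] & ch$chain_id == confirmed$chain1[r],
        logical(1)))[1L]
      ib <- which(vapply(bk, function(ch)
        ch$entry_id == confirmed$entry2[r] & ch$chain_id == confirmed$chain2[r],
        logical(1)))[1L]
      mrow <- list()
      if (!is.null(meta)) {
        m1 <- meta[meta$entry_id == confirmed$entry1[r], , drop = FALSE]
        m2 <- meta[meta$entry_id == confirmed$entry2[r], , drop = FALSE]
        if (nrow(m1)) mrow[c("resolution1", "rfree1")] <-
            list(m1$resolution[1L], m1$r_free[1L])
        if (nrow(m2)) mrow[c("resolution2", "rfree2")] <-
            list(m2$resolution[1L], m2$r_free[1L])
      }
      reports[[length(reports) + 1L]] <-
        compare_pair_details(bk[[ia]], bk[[ib]], meta = mrow,
                             superpose = policy$superpose)
    }
  }
  out <- if (length(reports)) do.call(rbind, reports) else {
    empty <- compare_pair_details(generate_backbone(2), generate_backbone(2))
    empty[0L, , drop = FALSE]
  }
  out <- out[order(out$entry1, out$entry2, out$chain1, out$chain2), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_report", "data.frame")
  out
}

#' Scan a directory of structure files for duplicate chains
#'
#' Reads every `.pdb`/`.ent`/`.cif` file (optionally gzipped), keeps entries
#' in scope (resolution, group-deposition flag), cleans chains, and runs the
#' cascade.  When an entry is present in both PDB and mmCIF form only one
#' dialect is scanned (PDB preferred) so twins do not report against each
#' other.
#'
#' @param dir directory of structure files.
#' @param policy a [filter_policy()].
#' @return List of class `scan_result`: `pairs` (pair reports), `report`
#'   (corpus filter report), `manifest` (per-file inventory, config
#'   snapshot, counts, wall time).
#' @export
scan_corpus <- function(dir, policy = filter_policy()) {
  t0 <- Sys.time()
  files <- list.files(dir, pattern = "\\.(pdb|ent|cif|mmcif)(\\.gz)?$",
                      full.names = TRUE, ignore.case = TRUE)
  stem <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "", basename(files),
              ignore.case = TRUE)
  is_pdb <- grepl("\\.(pdb|ent)(\\.gz)?$", files, ignore.case = TRUE)
  keep <- is_pdb | !(stem %in% stem[is_pdb])
  files <- files[keep]
  inventory <- data.frame(file = files, status = NA_character_,
                          n_chains_kept = 0L, stringsAsFactors = FALSE)
  chains <- list()
  reports <- list()
  meta <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    rec <- tryCatch(read_structure(f), dupscan_error = function(e) e)
    if (inherits(rec, "error")) {
      inventory$status[i] <- paste0("parse_error: ", conditionMessage(rec))
      next
    }
    ok <- withCallingHandlers(
      in_scope(rec, policy),
      dupscan_missing_resolution = function(w) invokeRestart("muffleWarning"))
    if (!ok) { inventory$status[i] <- "out_of_scope"; next }
    cl <- clean_chains(rec, policy)
    chains <- c(chains, cl$chains)
    reports[[length(reports) + 1L]] <- cl$report
    meta[[length(meta) + 1L]] <- data.frame(
      entry_id = rec$entry_id,
      resolution = rec$metadata$resolution,
      r_free = if (is.null(rec$metadata$r_free)) NA_real_ else rec$metadata$r_free,
      stringsAsFactors = FALSE)
    inventory$status[i] <- "ok"
    inventory$n_chains_kept[i] <- length(cl$chains)
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    clean_chains(structure(list(entry_id = "none",
                                atoms = data.frame(chain = character(0)),
                                metadata = list()),
                           class = "structure_record"), policy)$report
  class(report) <- c("filter_report", "data.frame")
  meta_df <- if (length(meta)) unique(do.call(rbind, meta)) else NULL
  pairs <- scan_chains(chains, policy, meta = meta_df)
  manifest <- list(
    config = unclass(policy)[c("max_resolution", "threshold", "min_residues",
                               "occupancy_scope", "exclude_same_entry",
                               "exclude_group_depositions", "superpose")],
    inputs = inventory,
    filter_counts = as.list(filter_counts(report)),
    n_pairs = nrow(pairs),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("dupscan")))
  structure(list(pairs = pairs, report = report, manifest = manifest),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d file(s), %d clean chain(s), %d pair(s)\n",
              nrow(x$manifest$inputs),
              x$manifest$filter_counts$kept + x$manifest$filter_counts$trimmed,
              nrow(x$pairs)))
  invisible(x)
}

#' Write pair reports to CSV
#'
#' Columns: id1, chain1, id2, chain2, n_residues, n_diff_res, resolution1,
#' rfree1, resolution2, rfree2, d_brain, d_bri, max_dev (plus
#' max_dev_superposed when present), rows sorted by (id1, id2, chain1,
#' chain2).
#'
#' @param pairs a `pair_report` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(pairs, path) {
  out <- as.data.frame(pairs)
  names(out)[names(out) == "entry1"] <- "id1"
  names(out)[names(out) == "entry2"] <- "id2"
  cols <- c("id1", "chain1", "id2", "chain2", "n_residues", "n_diff_res",
            "resolution1", "rfree1", "resolution2", "rfree2",
            "d_brain", "d_bri", "max_dev",
            intersect("max_dev_superposed", names(out)))
  out <- out[order(out$id1, out$id2, out$chain1, out$chain2), cols,
             drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_scan_report()]
#' @param path CSV path.
#' @return Data frame with the report columns.
#' @export
read_scan_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id1 = "character", id2 = "character",
                                 chain1 = "character", chain2 = "character"))
}
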