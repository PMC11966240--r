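# Reading PDB/mmCIF entries and extracting clean backbone chains.
#
# Atom parsing is delegated to bio3d (read.pdb / read.cif) with altloc and
# insertion codes preserved; header metadata (resolution, R_free, method,
# group-deposition flag) is parsed directly from the file since bio3d does
# not expose it.

#' Cleaning and scanning policy
#'
#' @param max_resolution entries with worse (larger) resolution are out of
#'   scope; default 4.0 Angstrom.
#' @param threshold near-duplicate cut-off t on the Chebyshev invariant
#'   distance, Angstrom; default 0.01.
#' @param min_residues minimum residues a cleaned chain must retain.
#' @param occupancy_scope `"any"` rejects a chain if any atom of its
#'   amino-acid residues has partial occupancy or an altloc; `"mainchain"`
#'   restricts the check to the N, CA, C atoms.
#' @param require_o also require the carbonyl O for residue completeness
#'   (off by default: the invariant uses only the N, CA, C trace).
#' @param allowed_residues residue names accepted as standard amino acids;
#'   everything else (including MSE) counts as nonstandard.
#' @param exclude_same_entry drop confirmed pairs whose two chains belong to
#'   the same entry.
#' @param exclude_group_depositions treat group depositions as out of scope.
#' @param superpose also report the Kabsch-superposed maximum deviation.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(max_resolution = 4.0, threshold = 0.01,
                          min_residues = 2,
                          occupancy_scope = c("any", "mainchain"),
                          require_o = FALSE,
                          allowed_residues = AA3_STANDARD,
                          exclude_same_entry = TRUE,
                          exclude_group_depositions = TRUE,
                          superpose = FALSE) {
  if (threshold <= 0) stop_dupscan("threshold must be > 0", "dupscan_bad_input")
  if (max_resolution <= 0) stop_dupscan("max_resolution must be > 0", "dupscan_bad_input")
  structure(list(max_resolution = max_resolution, threshold = threshold,
                 min_residues = min_residues,
                 occupancy_scope = match.arg(occupancy_scope),
                 require_o = require_o, allowed_residues = allowed_residues,
                 exclude_same_entry = exclude_same_entry,
                 exclude_group_depositions = exclude_group_depositions,
                 superpose = superpose),
            class = "filter_policy")
}

# transparently gunzip to a temp file when needed
maybe_gunzip <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile(fileext = sub("\\.gz$", "", paste0("_", basename(path))))
  con <- gzfile(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "raw", n = 64 * 1024^2)
  writeBin(raw, tmp)
  tmp
}

parse_pdb_header <- function(lines) {
  res <- NA_real_; rfree <- NA_real_
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(hit)) {
    txt <- sub("^REMARK +2 +RESOLUTION\\.", "", hit[1L])
    num <- regmatches(txt, regexpr("[0-9]+\\.?[0-9]*", txt))
    if (length(num)) res <- as.numeric(num)
  }
  hit <- grep("^REMARK   3   FREE R VALUE *:", lines, value = TRUE)
  if (length(hit)) {
    num <- regmatches(hit[1L], regexpr("[0-9]*\\.[0-9]+", hit[1L]))
    if (length(num)) rfree <- as.numeric(num)
  }
  method <- sub("^EXPDTA *", "", grep("^EXPDTA", lines, value = TRUE)[1L])
  title <- paste(trimws(sub("^TITLE +[0-9]* *", "",
                            grep("^TITLE", lines, value = TRUE))), collapse = " ")
  grp <- any(grepl("GROUP DEPOSITION", lines[startsWith(lines, "REMARK")])) ||
    any(grepl("GROUP DEPOSITION", lines[startsWith(lines, "KEYWDS")]))
  id <- NA_character_
  hd <- grep("^HEADER", lines, value = TRUE)
  if (length(hd) && nchar(hd[1L]) >= 66) id <- trimws(substr(hd[1L], 63, 66))
  list(entry_id = id, resolution = res, r_free = rfree,
       method = if (is.na(method)) NA_character_ else trimws(method),
       title = title, group_deposition = grp)
}

cif_scalar <- function(lines, tag) {
  hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  val <- trimws(sub(paste0("^", tag), "", hit[1L]))
  gsub("^['\"]|['\"]$", "", val)
}

parse_cif_header <- function(lines) {
  num <- function(x) suppressWarnings(as.numeric(x))
  list(entry_id = cif_scalar(lines, "_entry.id"),
       resolution = num(cif_scalar(lines, "_refine.ls_d_res_high")),
       r_free = num(cif_scalar(lines, "_refine.ls_R_factor_R_free")),
       method = cif_scalar(lines, "_exptl.method"),
       title = cif_scalar(lines, "_struct.title"),
       group_deposition = any(grepl("^_pdbx_deposit_group\\.", lines)))
}

#' Read a structure entry from a PDB or mmCIF file
#'
#' First model only; altloc markers and insertion codes are preserved so the
#' cleaning filters can see them.  Gzipped files are accepted transparently.
#'
#' @param path file path (`.pdb`, `.ent`, `.cif`, optionally `.gz`).
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return An object of class `structure_record`: list with `entry_id`,
#'   `atoms` (data frame: type, eleno, elety, alt, resid, chain, resno,
#'   insert, x, y, z, o, b, elesy) and `metadata` (resolution, r_free,
#'   method, title, group_deposition).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_dupscan(paste0("file not found: ", path), "dupscan_parse_error")
  }
  local <- maybe_gunzip(path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(local))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else stop_dupscan(paste0("cannot infer format of ", path,
                               " (use format = 'pdb' or 'mmcif')"),
                        "dupscan_unsupported_format")
  }
  lines <- readLines(local, warn = FALSE)
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(local, rm.alt = FALSE, rm.insert = FALSE,
                        verbose = FALSE)
      } else {
        bio3d::read.cif(local, rm.alt = FALSE, rm.insert = FALSE,
                        verbose = FALSE)
      }),
    error = function(e) {
      where <- ""
      if (format == "pdb") {                 # name the offending line
        idx <- grep("^(ATOM  |HETATM)", lines)
        for (i in idx) {
          xyz <- suppressWarnings(as.numeric(
            c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))))
          if (any(is.na(xyz))) { where <- paste0(" at line ", i); break }
        }
      }
      stop_dupscan(paste0("cannot parse ", path, where, ": ",
                          conditionMessage(e)),
                   "dupscan_parse_error")
    })
  atoms <- parsed$atom[, c("type", "eleno", "elety", "alt", "resid", "chain",
                           "resno", "insert", "x", "y", "z", "o", "b",
                           "elesy")]
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad)) {
    where <- if (format == "pdb") {
      atom_lines <- grep("^(ATOM|HETATM)", lines)
      paste0("line ", atom_lines[bad[1L]])
    } else paste0("atom record ", atoms$eleno[bad[1L]])
    stop_dupscan(paste0("malformed coordinate field in ", path, " at ", where),
                 "dupscan_parse_error")
  }
  atoms$o[is.na(atoms$o)] <- 1
  meta <- if (format == "pdb") parse_pdb_header(lines) else parse_cif_header(lines)
  entry_id <- meta$entry_id
  if (is.na(entry_id) || !nzchar(entry_id)) {
    entry_id <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                    basename(path), ignore.case = TRUE)
  }
  structure(list(entry_id = tolower(entry_id), atoms = atoms,
                 metadata = meta[c("resolution", "r_free", "method", "title",
                                   "group_deposition")]),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s: %d atoms, %d chain(s), resolution %s\n",
              x$entry_id, nrow(x$atoms),
              length(unique(x$atoms$chain)),
              ifelse(is.na(x$metadata$resolution), "NA",
                     format(x$metadata$resolution))))
  invisible(x)
}

#' Is an entry within scanning scope?
#'
#' @param s a `structure_record`.
#' @param policy a [filter_policy()].
#' @return `TRUE` iff the entry's resolution is at most
#'   `policy$max_resolution` and (when group depositions are excluded) it is
#'   not flagged as a group deposition.  A missing resolution places the
#'   entry out of scope with a classed warning.
#' @export
in_scope <- function(s, policy = filter_policy()) {
  res <- s$metadata$resolution
  if (is.null(res) || is.na(res)) {
    warn_dupscan(paste0("entry ", s$entry_id,
                        " has no resolution record; treated as out of scope"),
                 "dupscan_missing_resolution")
    return(FALSE)
  }
  if (res > policy$max_resolution) return(FALSE)
  if (policy$exclude_group_depositions && isTRUE(s$metadata$group_deposition)) {
    return(FALSE)
  }
  TRUE
}

#' Extract clean backbone chains from a structure record
#'
#' Applies the cleaning cascade chain by chain.  A chain is rejected when it
#' has (a) no standard amino-acid residues (`nonprotein`); (b) partial
#' occupancy or an altloc marker on an atom within the configured scope
#' (`partial_occupancy`); (c) non-consecutive residue numbering or insertion
#' codes (`nonconsecutive_numbering`); (d) an interior residue missing N, CA
#' or C (`missing_mainchain`) — incomplete residues only at the termini are
#' trimmed and the shortened chain kept; (e) a nonstandard amino acid
#' (`nonstandard_residue`); or (f) fewer than `policy$min_residues` residues
#' after trimming (`too_short`).  Nothing raises: every problem is a report
#' category.
#'
#' @param s a `structure_record`.
#' @param policy a [filter_policy()].
#' @return List with `chains` (list of `backbone_chain`) and `report` (a
#'   `filter_report` data frame: entry_id, chain_id, outcome
#'   kept/rejected/trimmed, category, n_residues, n_trimmed_front,
#'   n_trimmed_back — one row per input chain).
#' @export
clean_chains <- function(s, policy = filter_policy()) {
  atoms <- s$atoms
  chains <- list()
  rows <- list()
  note <- function(chain_id, outcome, category = NA_character_,
                   n_residues = 0L, front = 0L, back = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      entry_id = s$entry_id, chain_id = chain_id, outcome = outcome,
      category = category, n_residues = n_residues,
      n_trimmed_front = front, n_trimmed_back = back,
      stringsAsFactors = FALSE)
  }
  water <- c("HOH", "DOD", "WAT")
  for (cid in unique(atoms$chain)) {
    ca <- atoms[atoms$chain %in% cid, , drop = FALSE]
    # residues in file order; amino-acid-like = standard name or has a CA atom
    key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert), ca$resid)
    resgrp <- split(ca, factor(key, levels = unique(key)))
    is_aa <- vapply(resgrp, function(r) {
      rn <- r$resid[1L]
      !(rn %in% water) && (rn %in% policy$allowed_residues ||
                             any(r$elety == "CA"))
    }, logical(1))
    aa_res <- resgrp[is_aa]
    n_std <- sum(vapply(aa_res, function(r)
      r$resid[1L] %in% policy$allowed_residues, logical(1)))
    if (length(aa_res) == 0L || n_std == 0L) {
      note(cid, "rejected", "nonprotein"); next
    }
    occ_atoms <- do.call(rbind, aa_res)
    if (policy$occupancy_scope == "mainchain") {
      occ_atoms <- occ_atoms[occ_atoms$elety %in% c("N", "CA", "C"), ,
                             drop = FALSE]
    }
    if (any(occ_atoms$o < 1 - 1e-6) || any(!is.na(occ_atoms$alt))) {
      note(cid, "rejected", "partial_occupancy"); next
    }
    resno <- vapply(aa_res, function(r) r$resno[1L], integer(1))
    has_insert <- any(vapply(aa_res, function(r) any(!is.na(r$insert)),
                             logical(1)))
    if (has_insert || any(diff(resno) != 1L)) {
      note(cid, "rejected", "nonconsecutive_numbering"); next
    }
    need <- c("N", "CA", "C", if (policy$require_o) "O")
    complete <- vapply(aa_res, function(r) all(need %in% r$elety), logical(1))
    nres <- length(aa_res)
    first <- which(complete)[1L]
    last <- rev(which(complete))[1L]
    if (!any(complete)) { note(cid, "rejected", "missing_mainchain"); next }
    if (any(!complete[first:last])) {
      note(cid, "rejected", "missing_mainchain"); next
    }
    front <- first - 1L; back <- nres - last
    aa_res <- aa_res[first:last]
    resno <- resno[first:last]
    nonstd <- vapply(aa_res, function(r)
      !(r$resid[1L] %in% policy$allowed_residues), logical(1))
    if (any(nonstd)) { note(cid, "rejected", "nonstandard_residue"); next }
    if (length(aa_res) < policy$min_residues) {
      note(cid, "rejected", "too_short"); next
    }
    pick <- function(r, ety) {
      a <- r[r$elety == ety, , drop = FALSE][1L, ]
      c(a$x, a$y, a$z)
    }
    nmat <- t(vapply(aa_res, pick, numeric(3), ety = "N"))
    camat <- t(vapply(aa_res, pick, numeric(3), ety = "CA"))
    cmat <- t(vapply(aa_res, pick, numeric(3), ety = "C"))
    aa1 <- unname(AA321[vapply(aa_res, function(r) r$resid[1L], character(1))])
    ch <- backbone_chain(s$entry_id, cid, resno, aa1, nmat, camat, cmat)
    chains[[paste0(s$entry_id, "_", cid)]] <- ch
    note(cid, if (front + back > 0L) "trimmed" else "kept",
         n_residues = ch$m, front = front, back = back)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entry_id = character(0), chain_id = character(0),
               outcome = character(0), category = character(0),
               n_residues = integer(0), n_trimmed_front = integer(0),
               n_trimmed_back = integer(0))
  class(report) <- c("filter_report", "data.frame")
  list(chains = chains, report = report)
}

#' Corpus-level counts of a filter report
#' @param report a `filter_report` (possibly rbind-ed over entries).
#' @return Named integer vector: kept, trimmed and each rejection category.
#' @export
filter_counts <- function(report) {
  cats <- c("kept", "trimmed", "nonprotein", "partial_occupancy",
            "nonconsecutive_numbering", "missing_mainchain",
            "nonstandard_residue", "too_short")
  out <- stats::setNames(integer(length(cats)), cats)
  out["kept"] <- sum(report$outcome == "kept")
  out["trimmed"] <- sum(report$outcome == "trimmed")
  rej <- table(report$category[report$outcome == "rejected"])
  out[names(rej)] <- as.integer(rej)
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", nrow(x), "chain(s)\n")
  print(filter_counts(x))
  invisible(x)
}
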