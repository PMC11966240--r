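# The backbone rigid invariant (BRI) and its column average (Brain).
#
# For a chain of m residues the invariant is an m x 9 matrix: row i (i >= 2)
# holds the coordinates of residue i's N, CA, C atoms expressed in the frame
# of residue i-1; row 1 holds residue 1's own atoms in its own frame, which
# forces five structural zeros and makes the matrix exactly m x 9.  Equal
# up to rigid motion <=> equal invariant; the map inverts uniquely; mirror
# images differ in the sign of the out-of-plane (z) columns.

BRI_COLS <- c("N.x", "N.y", "N.z", "CA.x", "CA.y", "CA.z", "C.x", "C.y", "C.z")

#' Compute the backbone rigid invariant of a chain
#'
#' @param chain a `backbone_chain` of m >= 2 residues.
#' @return An m x 9 matrix of class `bri_matrix` (columns
#'   `N.x', N.y', N.z', CA.x', CA.y', CA.z', C.x', C.y', C.z'`, Angstrom)
#'   with attributes `entry_id` and `chain_id`.  Row 1 follows the canonical
#'   first-residue convention: `(|N-CA|, 0, 0, 0, 0, 0, (C-CA).e1,
#'   (C-CA).e2, 0)` with `(C-CA).e2 > 0`.
#' @details Runs in time linear in m: one frame and three projections per
#'   residue.
#' @export
compute_bri <- function(chain) {
  if (!inherits(chain, "backbone_chain")) {
    stop_dupscan("compute_bri expects a backbone_chain", "dupscan_bad_input")
  }
  m <- chain$m
  out <- matrix(0, m, 9L, dimnames = list(NULL, BRI_COLS))
  f1 <- tryCatch(
    build_frame(chain$n[1L, ], chain$ca[1L, ], chain$c[1L, ]),
    dupscan_degenerate_frame = function(e) {
      stop_dupscan(paste0("degenerate frame at residue ", chain$resno[1L]),
                   "dupscan_degenerate_frame")
    })
  v <- chain$c[1L, ] - chain$ca[1L, ]
  out[1L, ] <- c(vnorm(chain$n[1L, ] - chain$ca[1L, ]), 0, 0,
                 0, 0, 0,
                 sum(v * f1$e1), sum(v * f1$e2), 0)
  if (m >= 2L) {
    for (i in 2:m) {
      f <- tryCatch(
        build_frame(chain$n[i - 1L, ], chain$ca[i - 1L, ], chain$c[i - 1L, ]),
        dupscan_degenerate_frame = function(e) {
          stop_dupscan(
            paste0("degenerate frame at residue ", chain$resno[i - 1L]),
            "dupscan_degenerate_frame")
        })
      out[i, 1:3] <- express_in_frame(chain$n[i, ], f)
      out[i, 4:6] <- express_in_frame(chain$ca[i, ], f)
      out[i, 7:9] <- express_in_frame(chain$c[i, ], f)
    }
  }
  structure(out, class = c("bri_matrix", "matrix", "array"),
            entry_id = chain$entry_id, chain_id = chain$chain_id)
}

as_bri <- function(x, entry_id = "", chain_id = "") {
  x <- as.matrix(x)
  if (ncol(x) != 9L) stop_dupscan("a BRI matrix has 9 columns", "dupscan_bad_input")
  dimnames(x) <- list(NULL, BRI_COLS)
  structure(x, class = c("bri_matrix", "matrix", "array"),
            entry_id = entry_id, chain_id = chain_id)
}

#' Column average of a backbone rigid invariant
#'
#' The 9-component average invariant used as the fast cascade prefilter: by
#' averaging, a difference of d in one coordinate of the averages forces a
#' difference of at least d in the same coordinate of the full matrices.
#'
#' @param bri a `bri_matrix`.
#' @return Named numeric vector of length 9 (Angstrom): the arithmetic mean
#'   of each column, all rows weighted equally.
#' @export
compute_brain <- function(bri) {
  colMeans(unclass(bri))
}

#' Chebyshev distance between two invariant matrices
#'
#' @param a,b `bri_matrix` objects for chains of equal residue count.
#' @return Maximum absolute entrywise difference, in Angstrom.
#' @export
bri_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop_dupscan("BRI matrices have different dimensions (unequal m)",
                 "dupscan_dimension_mismatch")
  }
  max(abs(unclass(a) - unclass(b)))
}

#' Chebyshev distance between two average invariants
#'
#' Always a lower bound on [bri_distance()] of the source matrices.
#'
#' @param a,b length-9 numeric vectors.
#' @return Maximum absolute componentwise difference, in Angstrom.
#' @export
brain_distance <- function(a, b) {
  max(abs(as.numeric(a) - as.numeric(b)))
}

#' Invert an invariant matrix back to backbone coordinates
#'
#' Places residue 1 in the canonical pose encoded by row 1 (CA at the
#' origin, N on +x, C in the xy-plane with positive y) and then grows the
#' chain: for each i >= 2, builds the frame of the already-reconstructed
#' residue i-1 and places residue i's atoms from row i.  The result
#' reproduces the original chain exactly up to rigid motion.
#'
#' @param bri a `bri_matrix` whose first row satisfies the canonical
#'   convention (entries 2, 3, 4, 5, 6, 9 zero; entry 8 positive).
#' @param entry_id,chain_id identifiers for the rebuilt chain (default: the
#'   attributes carried by `bri`).
#' @return A `backbone_chain` in canonical pose, amino-acid codes `"X"`,
#'   numbering `1..m`.
#' @export
reconstruct_backbone <- function(bri,
                                 entry_id = attr(bri, "entry_id"),
                                 chain_id = attr(bri, "chain_id")) {
  b <- unclass(as.matrix(bri))
  m <- nrow(b)
  if (m < 2L) stop_dupscan("invariant has fewer than 2 rows", "dupscan_chain_too_short")
  r1 <- b[1L, ]
  if (max(abs(r1[c(2, 3, 4, 5, 6, 9)])) > 1e-9 || r1[8L] <= 0) {
    stop_dupscan("row 1 violates the canonical first-residue convention",
                 "dupscan_invalid_row_one")
  }
  n <- ca <- cc <- matrix(0, m, 3L)
  n[1L, ] <- c(r1[1L], 0, 0)
  ca[1L, ] <- c(0, 0, 0)
  cc[1L, ] <- c(r1[7L], r1[8L], 0)
  for (i in 2:m) {
    f <- build_frame(n[i - 1L, ], ca[i - 1L, ], cc[i - 1L, ])
    n[i, ] <- frame_to_global(b[i, 1:3], f)
    ca[i, ] <- frame_to_global(b[i, 4:6], f)
    cc[i, ] <- frame_to_global(b[i, 7:9], f)
  }
  backbone_chain(if (is.null(entry_id)) "" else entry_id,
                 if (is.null(chain_id)) "" else chain_id,
                 seq_len(m), rep("X", m), n, ca, cc)
}

#' Invariant of the mirror-image chain
#'
#' Point reflection flips the handedness of every residue frame, so the
#' out-of-plane (z) local coordinates change sign for rows >= 2 while the
#' in-plane ones are untouched; row 1's chirality-bearing entries are zero
#' by convention and stay put.  A chain equals its mirror invariant exactly
#' when the backbone is achiral (planar).
#'
#' @param bri a `bri_matrix`.
#' @return The `bri_matrix` of the point-reflected chain.
#' @export
mirror_bri <- function(bri) {
  out <- unclass(as.matrix(bri))
  if (nrow(out) >= 2L) {
    out[-1L, c(3L, 6L, 9L)] <- -out[-1L, c(3L, 6L, 9L)]
  }
  as_bri(out, attr(bri, "entry_id"), attr(bri, "chain_id"))
}

#' Write an invariant matrix to a TSV file
#'
#' Format: comment lines `#entry`, `#chain`, `#m`, then a header line with
#' the nine column names and one row per residue at 6 decimal places.
#'
#' @param bri a `bri_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bri <- function(bri, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#entry\t", attr(bri, "entry_id")),
               paste0("#chain\t", attr(bri, "chain_id")),
               paste0("#m\t", nrow(bri)),
               paste(BRI_COLS, collapse = "\t")), con)
  body <- apply(unclass(bri), 1L, function(r)
    paste(sprintf("%.6f", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an invariant matrix written by [write_bri()]
#' @param path TSV file path.
#' @return A `bri_matrix`.
#' @export
read_bri <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kv <- strsplit(meta, "\t", fixed = TRUE)
  get <- function(key) {
    hit <- vapply(kv, function(x) x[[1L]] == paste0("#", key), logical(1))
    if (any(hit)) kv[[which(hit)[1L]]][2L] else ""
  }
  body <- lines[!startsWith(lines, "#")]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  as_bri(as.matrix(dat), get("entry"), get("chain"))
}
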