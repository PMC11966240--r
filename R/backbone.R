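# BackboneChain: the ordered N/CA/C trace of one protein chain.

#' Construct a backbone chain
#'
#' The container the invariant is computed on: the ordered main-chain trace
#' (N, CA, C) of one protein chain with strictly consecutive residue
#' numbering.
#'
#' @param entry_id entry identifier (e.g. a 4-character accession).
#' @param chain_id chain identifier.
#' @param resno integer vector of residue numbers; must increase by exactly 1.
#' @param aa character vector of 1-letter amino-acid codes.
#' @param n,ca,c m x 3 coordinate matrices (Angstrom) of the N, CA and C
#'   atoms, one row per residue, same order as `resno`.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(entry_id, chain_id, resno, aa, n, ca, c) {
  n <- as.matrix(n); ca <- as.matrix(ca); c <- as.matrix(c)
  m <- length(resno)
  if (m < 2L) {
    stop_dupscan("a backbone chain needs at least 2 residues",
                 "dupscan_chain_too_short")
  }
  if (length(aa) != m || nrow(n) != m || nrow(ca) != m || nrow(c) != m) {
    stop_dupscan("resno, aa and coordinate matrices must agree in length",
                 "dupscan_length_mismatch")
  }
  if (any(diff(as.integer(resno)) != 1L)) {
    stop_dupscan("residue numbers must increase by exactly 1",
                 "dupscan_nonconsecutive")
  }
  if (!all(is.finite(n), is.finite(ca), is.finite(c))) {
    stop_dupscan("non-finite backbone coordinates", "dupscan_bad_coords")
  }
  structure(list(entry_id = as.character(entry_id),
                 chain_id = as.character(chain_id),
                 resno = as.integer(resno), aa = as.character(aa),
                 n = unname(n), ca = unname(ca), c = unname(c), m = m),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> %s_%s: %d residues (%d..%d)\n",
              x$entry_id, x$chain_id, x$m, x$resno[1L], x$resno[x$m]))
  invisible(x)
}

#' Flattened trace coordinates of a chain
#'
#' @param chain a `backbone_chain`.
#' @return A 3m x 3 matrix: rows are N1, CA1, C1, N2, CA2, C2, ...
#' @export
chain_coords <- function(chain) {
  m <- chain$m
  out <- matrix(0, 3L * m, 3L)
  idx <- 3L * (seq_len(m) - 1L)
  out[idx + 1L, ] <- chain$n
  out[idx + 2L, ] <- chain$ca
  out[idx + 3L, ] <- chain$c
  out
}

# rebuild a chain from flattened 3m x 3 coords, keeping labels
coords_to_chain <- function(chain, coords) {
  m <- chain$m
  idx <- 3L * (seq_len(m) - 1L)
  backbone_chain(chain$entry_id, chain$chain_id, chain$resno, chain$aa,
                 coords[idx + 1L, , drop = FALSE],
                 coords[idx + 2L, , drop = FALSE],
                 coords[idx + 3L, , drop = FALSE])
}

#' Apply a rigid motion to a whole chain
#' @param chain a `backbone_chain`.
#' @param motion a `rigid_motion`.
#' @return The moved `backbone_chain`.
#' @export
transform_chain <- function(chain, motion) {
  coords_to_chain(chain, apply_rigid_motion(chain_coords(chain), motion))
}

#' Point-reflect a chain through the origin
#'
#' Produces the mirror image (an improper transformation); used to test and
#' demonstrate chirality discrimination.
#'
#' @param chain a `backbone_chain`.
#' @return The reflected `backbone_chain`.
#' @export
reflect_chain <- function(chain) {
  ch <- chain
  ch$n <- -ch$n; ch$ca <- -ch$ca; ch$c <- -ch$c
  ch
}

#' Extract a contiguous subchain
#' @param chain a `backbone_chain`.
#' @param from,to first and last residue positions (1-based indices into the
#'   residue list, not residue numbers).
#' @return The `backbone_chain` covering positions `from..to`, original
#'   residue numbering retained.
#' @export
subchain <- function(chain, from, to) {
  idx <- seq.int(from, to)
  backbone_chain(chain$entry_id, chain$chain_id, chain$resno[idx],
                 chain$aa[idx],
                 chain$n[idx, , drop = FALSE],
                 chain$ca[idx, , drop = FALSE],
                 chain$c[idx, , drop = FALSE])
}
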