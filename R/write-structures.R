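# Writers for synthetic entries: PDB (wwPDB v3.3 columns) and mmCIF
# (full 21-column atom_site loop).  Both dialects serialise coordinates at
# 3 decimals and occupancy/B at 2, so a PDB file and its mmCIF twin parse
# back field-for-field identical.

AA3_STANDARD <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
AA1_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G",
                  "H", "I", "L", "K", "M", "F", "P", "S",
                  "T", "W", "Y", "V")
names(AA3_STANDARD) <- AA1_STANDARD
AA321 <- structure(AA1_STANDARD, names = AA3_STANDARD)

# flat atom table for one chain, optionally degraded to violate one
# cleaning-filter category
chain_atom_table <- function(chain, tweak = NULL) {
  m <- chain$m
  tab <- data.frame(
    resno = rep(chain$resno, each = 3L),
    resid = rep(AA3_STANDARD[chain$aa], each = 3L),
    chain = chain$chain_id,
    elety = rep(c("N", "CA", "C"), m),
    alt = "",
    x = numeric(3L * m), y = numeric(3L * m), z = numeric(3L * m),
    o = 1.00, b = 15.00,
    elesy = rep(c("N", "C", "C"), m),
    stringsAsFactors = FALSE)
  idx <- 3L * (seq_len(m) - 1L)
  coords <- chain_coords(chain)
  tab$x <- coords[, 1L]; tab$y <- coords[, 2L]; tab$z <- coords[, 3L]
  if (!is.null(tweak)) {
    tab <- switch(tweak,
      partial_occupancy = { tab$o[2L] <- 0.50; tab },
      nonconsecutive = {
        tab$resno[tab$resno >= 3L] <- tab$resno[tab$resno >= 3L] + 1L
        tab
      },
      missing_mainchain = tab[-(idx[min(5L, m - 1L)] + 1L), ],   # interior N
      nonstandard = { tab$resid[tab$resno == 2L] <- "MSE"; tab },
      nonprotein = data.frame(
        resno = seq_len(m), resid = "HOH", chain = chain$chain_id,
        elety = "O", alt = "", x = coords[idx + 2L, 1L],
        y = coords[idx + 2L, 2L], z = coords[idx + 2L, 3L],
        o = 1.00, b = 15.00, elesy = "O", stringsAsFactors = FALSE),
      too_short = tab[tab$resno == 1L, ],
      stop_dupscan(paste("unknown tweak:", tweak), "dupscan_bad_input"))
  }
  tab
}

#' Write a backbone chain as a PDB-format entry
#'
#' @param chain a `backbone_chain`.
#' @param path output file.
#' @param resolution,r_free fabricated header values (`REMARK 2` /
#'   `REMARK 3`); `NA` resolution omits the remark.
#' @param group_deposition write a `REMARK 999 GROUP DEPOSITION` flag line.
#' @param title optional TITLE text.
#' @param tweak internal: degrade the chain to violate one cleaning-filter
#'   category (used by [emit_corpus()]).
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, resolution = 2.0, r_free = NA,
                            group_deposition = FALSE, title = NULL,
                            tweak = NULL) {
  tab <- chain_atom_table(chain, tweak)
  hdr <- c(sprintf("HEADER    SYNTHETIC BACKBONE                      01-JAN-26   %s",
                   toupper(chain$entry_id)),
           if (!is.null(title)) sprintf("TITLE     %s", toupper(title)),
           "EXPDTA    X-RAY DIFFRACTION",
           if (is.finite(resolution))
             sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution)
           else "REMARK   2 RESOLUTION. NOT APPLICABLE.",
           if (is.finite(r_free))
             sprintf("REMARK   3   FREE R VALUE                     : %.4f", r_free),
           if (group_deposition) "REMARK 999 GROUP DEPOSITION")
  name4 <- ifelse(nchar(tab$elety) < 4L,
                  sprintf(" %-3s", tab$elety), tab$elety)
  rec <- sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(tab)), name4, tab$alt, tab$resid, tab$chain,
                 tab$resno, tab$x, tab$y, tab$z, tab$o, tab$b, tab$elesy)
  writeLines(c(hdr, rec, "END"), path)
  invisible(path)
}

#' Write a backbone chain as an mmCIF entry
#'
#' Emits the full wwPDB `atom_site` column set plus `_refine` and `_exptl`
#' metadata; a group deposition is flagged with `_pdbx_deposit_group`.
#'
#' @inheritParams write_chain_pdb
#' @return `path`, invisibly.
#' @export
write_chain_cif <- function(chain, path, resolution = 2.0, r_free = NA,
                            group_deposition = FALSE, title = NULL,
                            tweak = NULL) {
  tab <- chain_atom_table(chain, tweak)
  hdr <- c(sprintf("data_%s", toupper(chain$entry_id)),
           sprintf("_entry.id %s", toupper(chain$entry_id)),
           "_exptl.method 'X-RAY DIFFRACTION'",
           if (!is.null(title)) sprintf("_struct.title '%s'", title),
           if (is.finite(resolution))
             sprintf("_refine.ls_d_res_high %.2f", resolution),
           if (is.finite(r_free))
             sprintf("_refine.ls_R_factor_R_free %.4f", r_free),
           if (group_deposition) c("_pdbx_deposit_group.group_id G_100",
                                   "_pdbx_deposit_group.group_type 'changed state'"),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  grp <- ifelse(tab$resid %in% c(AA3_STANDARD, "MSE"), "ATOM", "HETATM")
  alt <- ifelse(tab$alt == "", ".", tab$alt)
  rec <- sprintf("%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
                 grp, seq_len(nrow(tab)), tab$elesy, tab$elety, alt,
                 tab$resid, tab$chain, tab$resno, tab$x, tab$y, tab$z,
                 tab$o, tab$b, tab$resno, tab$resid, tab$chain, tab$elety)
  writeLines(c(hdr, rec, "#"), path)
  invisible(path)
}
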