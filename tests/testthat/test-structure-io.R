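# minimal hand-written two-residue entry in both dialects
minimal_pdb <- c(
  "HEADER    PROTEIN                                 01-JAN-20   1XYZ",
  "EXPDTA    X-RAY DIFFRACTION",
  "REMARK   2 RESOLUTION.    2.20 ANGSTROMS.",
  "REMARK   3   FREE R VALUE                     : 0.2460",
  "ATOM      1  N   ALA A   1       1.458   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
  "ATOM      3  C   ALA A   1      -0.551   1.422   0.000  1.00 10.00           C",
  "ATOM      4  O   ALA A   1      -1.700   1.600   0.300  1.00 10.00           O",
  "ATOM      5  N   GLY A   2       0.100   2.400   0.300  1.00 10.00           N",
  "ATOM      6  CA  GLY A   2      -0.300   3.800   0.500  1.00 10.00           C",
  "ATOM      7  C   GLY A   2      -1.800   3.950   0.700  1.00 10.00           C",
  "ATOM      8  O   GLY A   2      -2.500   3.000   1.000  1.00 10.00           O",
  "END")

minimal_cif_of <- function(pdb_lines) {
  atoms <- pdb_lines[startsWith(pdb_lines, "ATOM")]
  rec <- vapply(atoms, function(l) {
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            as.integer(substr(l, 7, 11)), trimws(substr(l, 77, 78)),
            trimws(substr(l, 13, 16)), substr(l, 18, 20), substr(l, 22, 22),
            as.integer(substr(l, 23, 26)), as.numeric(substr(l, 31, 38)),
            as.numeric(substr(l, 39, 46)), as.numeric(substr(l, 47, 54)),
            as.numeric(substr(l, 55, 60)), as.numeric(substr(l, 61, 66)),
            as.integer(substr(l, 23, 26)), substr(l, 18, 20),
            substr(l, 22, 22), trimws(substr(l, 13, 16)))
  }, character(1))
  c("data_1XYZ", "_entry.id 1XYZ", "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_d_res_high 2.20", "_refine.ls_R_factor_R_free 0.2460",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
             "label_comp_id", "label_asym_id", "label_entity_id",
             "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
             "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
             "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    unname(rec), "#")
}

write_fixture <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a minimal PDB entry parses with atoms, header and metadata", {
  rec <- read_structure(write_fixture(minimal_pdb, ".pdb"))
  expect_s3_class(rec, "structure_record")
  expect_identical(rec$entry_id, "1xyz")
  expect_identical(nrow(rec$atoms), 8L)
  expect_identical(unique(rec$atoms$chain), "A")
  expect_equal(rec$metadata$resolution, 2.2)
  expect_equal(rec$metadata$r_free, 0.246)
  expect_false(rec$metadata$group_deposition)
})

test_that("the mmCIF dialect parses field-for-field identically", {
  p <- read_structure(write_fixture(minimal_pdb, ".pdb"))
  q <- read_structure(write_fixture(minimal_cif_of(minimal_pdb), ".cif"))
  shared <- c("elety", "resid", "chain", "resno", "x", "y", "z", "o", "b")
  expect_identical(p$atoms[, shared], q$atoms[, shared])
  expect_equal(p$metadata$resolution, q$metadata$resolution)
  expect_equal(p$metadata$r_free, q$metadata$r_free)
  cp <- clean_chains(p); cq <- clean_chains(q)
  expect_identical(length(cp$chains), 1L)
  expect_identical(cp$chains[[1]]$n, cq$chains[[1]]$n)
  expect_equal(unclass(compute_bri(cp$chains[[1]])),
               unclass(compute_bri(cq$chains[[1]])), ignore_attr = TRUE)
})

test_that("gzipped files are read transparently", {
  plain <- write_fixture(minimal_pdb, ".pdb")
  gz <- withr::local_tempfile(fileext = ".pdb.gz")
  con <- gzfile(gz, "w"); writeLines(minimal_pdb, con); close(con)
  expect_identical(read_structure(gz)$atoms, read_structure(plain)$atoms)
})

test_that("a malformed coordinate field raises a parse error naming the line", {
  bad <- minimal_pdb
  bad[6] <- sub("   0.000   0.000   0.000", "   abc      0.000   0.000", bad[6])
  err <- expect_error(read_structure(write_fixture(bad, ".pdb")),
                      class = "dupscan_parse_error")
  expect_match(conditionMessage(err), "line 6")   # the damaged file line
})

test_that("each cleaning filter category fires on its fixture", {
  base <- generate_backbone(10, seed = 71, torsions = "random", entry_id = "tst1")
  cases <- list(partial_occupancy = "partial_occupancy",
                nonconsecutive = "nonconsecutive_numbering",
                missing_mainchain = "missing_mainchain",
                nonstandard = "nonstandard_residue",
                nonprotein = "nonprotein",
                too_short = "too_short")
  for (tweak in names(cases)) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_chain_pdb(base, path, tweak = tweak)
    cl <- clean_chains(read_structure(path))
    expect_identical(length(cl$chains), 0L, label = tweak)
    expect_identical(cl$report$outcome, "rejected", label = tweak)
    expect_identical(cl$report$category, cases[[tweak]], label = tweak)
  }
})

test_that("terminal residues lacking main-chain atoms are trimmed, not fatal", {
  base <- generate_backbone(10, seed = 72, torsions = "random", entry_id = "tst2")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(base, path)
  lines <- readLines(path)
  first_n <- grep("^ATOM ", lines)[1]     # residue 1's N atom
  writeLines(lines[-first_n], path)
  cl <- clean_chains(read_structure(path))
  expect_identical(length(cl$chains), 1L)
  expect_identical(cl$chains[[1]]$m, 9L)
  expect_identical(cl$chains[[1]]$resno[1], 2L)
  expect_identical(cl$report$outcome, "trimmed")
  expect_identical(cl$report$n_trimmed_front, 1L)
  expect_identical(cl$report$n_trimmed_back, 0L)
})

test_that("cleaning is idempotent and conserves chains", {
  base <- generate_backbone(12, seed = 73, torsions = "random", entry_id = "tst3")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(base, path)
  rec <- read_structure(path)
  cl <- clean_chains(rec)
  expect_identical(nrow(cl$report), length(unique(rec$atoms$chain)))
  expect_identical(cl$report$outcome, "kept")
  expect_equal(cl$chains[[1]]$n, base$n, tolerance = 1e-3)
  counts <- filter_counts(cl$report)
  expect_identical(sum(counts), nrow(cl$report))
})

test_that("scope rules follow resolution and the group-deposition flag", {
  base <- generate_backbone(5, seed = 74, entry_id = "tst4")
  mk <- function(...) {
    path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
    write_chain_pdb(base, path, ...)
    read_structure(path)
  }
  expect_true(in_scope(mk(resolution = 2.2)))
  expect_false(in_scope(mk(resolution = 4.5)))
  expect_false(in_scope(mk(resolution = 1.5, group_deposition = TRUE)))
  expect_true(in_scope(mk(resolution = 1.5, group_deposition = TRUE),
                       filter_policy(exclude_group_depositions = FALSE)))
  expect_warning(out <- in_scope(mk(resolution = NA)),
                 class = "dupscan_missing_resolution")
  expect_false(out)
})
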