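# Deterministic synthetic backbones and corpora with known ground truth.
#
# Chains are built from internal coordinates (bond lengths, bond angles,
# torsions) with the standard three-atom placement rule, so every emitted
# chain has exactly the stated covalent geometry regardless of the torsion
# draw, planted deviations are exactly known, and the default helix is
# exactly periodic.

#' Ideal backbone geometry parameters
#'
#' Bond lengths in Angstrom, angles and torsions in degrees.  Defaults are
#' standard peptide values: N-CA 1.458, CA-C 1.525, C-N 1.329; N-CA-C 111.2,
#' CA-C-N 116.2, C-N-CA 121.7; alpha-helical torsions phi -57, psi -47,
#' omega 180.
#'
#' @param b_n_ca,b_ca_c,b_c_n bond lengths.
#' @param ang_n_ca_c,ang_ca_c_n,ang_c_n_ca bond angles.
#' @param phi,psi,omega backbone torsions used when `torsions = "helix"`.
#' @return A named list of geometry parameters.
#' @export
ideal_geometry <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                           ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                           ang_c_n_ca = 121.7,
                           phi = -57, psi = -47, omega = 180) {
  g <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
            ang_n_ca_c = ang_n_ca_c, ang_ca_c_n = ang_ca_c_n,
            ang_c_n_ca = ang_c_n_ca, phi = phi, psi = psi, omega = omega)
  if (any(unlist(g[1:3]) <= 0) ||
      any(unlist(g[4:6]) <= 1) || any(unlist(g[4:6]) >= 179)) {
    stop_dupscan("degenerate geometry: bond lengths must be positive and bond angles strictly inside (1, 179) degrees",
                 "dupscan_degenerate_geometry")
  }
  g
}

# run code with a seeded, restored RNG state (identical draws per seed)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# place atom d given atoms a-b-c, bond |c-d|, angle b-c-d, torsion a-b-c-d
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- bond * c(cos(pi - ang),
                 sin(pi - ang) * cos(tor),
                 sin(pi - ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  nrm <- cross3(ab, bc)
  nn <- vnorm(nrm)
  if (nn < 1e-12) {
    stop_dupscan("collinear reference atoms in internal-coordinate placement",
                 "dupscan_degenerate_geometry")
  }
  nrm <- nrm / nn
  m2 <- cross3(nrm, bc)
  as.numeric(c + d2[1L] * bc + d2[2L] * m2 + d2[3L] * nrm)
}

#' Generate a synthetic backbone chain
#'
#' @param m number of residues (>= 2).
#' @param geometry parameter list from [ideal_geometry()].
#' @param seed integer seed; a fixed seed gives bitwise-identical output.
#'   Only consumed when `torsions = "random"` or for the sequence draw.
#' @param torsions `"helix"` for the fixed (phi, psi, omega) of `geometry`
#'   (an exactly periodic chain), or `"random"` for per-residue torsions
#'   drawn uniformly (phi in (-150, -40), psi in (-70, 160)) — irregular but
#'   still ideal covalent geometry.
#' @param entry_id,chain_id identifiers for the chain.
#' @return A `backbone_chain` with numbering `1..m`, random standard
#'   amino-acid sequence, full occupancy implied.
#' @export
generate_backbone <- function(m, geometry = ideal_geometry(), seed = NULL,
                              torsions = c("helix", "random"),
                              entry_id = "synt", chain_id = "A") {
  torsions <- match.arg(torsions)
  if (m < 2L) stop_dupscan("m must be >= 2", "dupscan_chain_too_short")
  g <- geometry
  with_seed(seed, {
    phi <- if (torsions == "helix") rep(g$phi, m) else stats::runif(m, -150, -40)
    psi <- if (torsions == "helix") rep(g$psi, m) else stats::runif(m, -70, 160)
    aa <- sample(AA1_STANDARD, m, replace = TRUE)
    n <- ca <- cc <- matrix(0, m, 3L)
    ang <- g$ang_n_ca_c * pi / 180
    n[1L, ] <- c(g$b_n_ca, 0, 0)
    ca[1L, ] <- c(0, 0, 0)
    cc[1L, ] <- g$b_ca_c * c(cos(ang), sin(ang), 0)
    for (i in seq_len(m - 1L)) {
      n[i + 1L, ] <- place_atom(n[i, ], ca[i, ], cc[i, ],
                                g$b_c_n, g$ang_ca_c_n, psi[i])
      ca[i + 1L, ] <- place_atom(ca[i, ], cc[i, ], n[i + 1L, ],
                                 g$b_n_ca, g$ang_c_n_ca, g$omega)
      cc[i + 1L, ] <- place_atom(cc[i, ], n[i + 1L, ], ca[i + 1L, ],
                                 g$b_ca_c, g$ang_n_ca_c, phi[i + 1L])
    }
    backbone_chain(entry_id, chain_id, seq_len(m), aa, n, ca, cc)
  })
}

#' Derive a duplicate or decoy from a chain
#'
#' Emulates the ways a deposition can duplicate another: verbatim coordinate
#' copy, sub-threshold coordinate noise, residue relabelling with untouched
#' coordinates, a disguising rigid motion, or (as a decoy) the mirror image.
#'
#' @param chain a `backbone_chain`.
#' @param mode one of `"exact"`, `"perturb"`, `"label_swap"`, `"mirror"`,
#'   `"rigid_copy"`, `"x_shift"`.
#' @param delta for `"perturb"`: each atom displaced by an independent random
#'   vector drawn uniformly in the ball of radius `delta` Angstrom (hard
#'   bound, not probabilistic); for `"x_shift"`: every x coordinate shifted
#'   by exactly `delta`.
#' @param k for `"label_swap"`: number of residue codes changed (coordinates
#'   untouched).
#' @param seed integer seed for the random modes.
#' @param entry_id entry identifier of the derived chain.
#' @return A `backbone_chain`.
#' @export
make_duplicate <- function(chain, mode = c("exact", "perturb", "label_swap",
                                           "mirror", "rigid_copy", "x_shift"),
                           delta = 0, k = 0, seed = NULL,
                           entry_id = chain$entry_id) {
  mode <- match.arg(mode)
  out <- with_seed(seed, switch(mode,
    exact = chain,
    perturb = {
      coords <- chain_coords(chain)
      na <- nrow(coords)
      dir <- matrix(stats::rnorm(3L * na), na, 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      rad <- delta * stats::runif(na)^(1 / 3)
      coords_to_chain(chain, coords + dir * rad)
    },
    label_swap = {
      ch <- chain
      pos <- sample(chain$m, k)
      for (p in pos) {
        ch$aa[p] <- sample(setdiff(AA1_STANDARD, ch$aa[p]), 1L)
      }
      ch
    },
    mirror = reflect_chain(chain),
    rigid_copy = transform_chain(chain, random_rigid_motion()),
    x_shift = {
      ch <- chain
      ch$n[, 1L] <- ch$n[, 1L] + delta
      ch$ca[, 1L] <- ch$ca[, 1L] + delta
      ch$c[, 1L] <- ch$c[, 1L] + delta
      ch
    }))
  out$entry_id <- as.character(entry_id)
  out
}

#' Specification of a synthetic corpus
#'
#' @param n_chains number of independent base chains.
#' @param length_range inclusive range residue counts are drawn from.
#' @param geometry parameters from [ideal_geometry()].
#' @param delta perturbation radius (Angstrom) for planted perturbed
#'   duplicates.  Default 0.0005, below the last printed digit of deposited
#'   coordinates: the invariant amplifies coordinate noise by its
#'   (empirical) continuity constant, so planted duplicates must sit well
#'   under `threshold / C` to be duplicates by construction.
#' @param n_exact,n_perturbed,n_label_swap,n_rigid numbers of planted
#'   duplicate entries of each category.
#' @param n_mirror number of mirror decoys (must not be reported).
#' @param n_far number of far-perturbed decoys (perturbation `far_delta`).
#' @param far_delta perturbation radius for decoys (default 10x `delta`).
#' @param label_swap_k residue codes changed in each label-swap duplicate.
#' @param filter_violations also emit one chain violating each cleaning
#'   filter category.
#' @param seed integer seed; fixed seed gives a byte-identical corpus.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 10, length_range = c(60, 120),
                         geometry = ideal_geometry(), delta = 0.0005,
                         n_exact = 2, n_perturbed = 2, n_label_swap = 1,
                         n_rigid = 1, n_mirror = 2, n_far = 2,
                         far_delta = 10 * 0.01, label_swap_k = 9,
                         filter_violations = TRUE, seed = 1) {
  if (delta < 0) stop_dupscan("delta must be >= 0", "dupscan_bad_input")
  structure(list(n_chains = n_chains, length_range = length_range,
                 geometry = geometry, delta = delta, n_exact = n_exact,
                 n_perturbed = n_perturbed, n_label_swap = n_label_swap,
                 n_rigid = n_rigid, n_mirror = n_mirror, n_far = n_far,
                 far_delta = far_delta, label_swap_k = label_swap_k,
                 filter_violations = filter_violations, seed = seed),
            class = "fixture_spec")
}

#' Emit a synthetic corpus to disk
#'
#' Writes one PDB file and one mmCIF twin per synthetic entry, with
#' fabricated headers (resolution, R_free), plus a ground-truth JSON listing
#' every planted duplicate pair and decoy.  With `filter_violations = TRUE`
#' the corpus additionally contains one chain per cleaning-filter category
#' (partial occupancy, nonconsecutive numbering, missing main-chain atom,
#' nonstandard residue, nonprotein, too short) and one out-of-scope entry
#' each for low resolution and for group deposition.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return List with `files` (paths written), `truth` (data frame of planted
#'   pairs: entry ids, chain ids, category, planted max deviation) and
#'   `truth_path`.
#' @export
emit_corpus <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    nb <- spec$n_chains
    lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]), nb,
                   replace = TRUE)
    entries <- list()   # name -> list(chain, resolution, r_free, group, remark)
    eid <- function(i) sprintf("s%03d", i)
    base <- vector("list", nb)
    k <- 0L
    for (i in seq_len(nb)) {
      k <- k + 1L
      ch <- generate_backbone(lens[i], spec$geometry,
                              seed = sample.int(1e6, 1), torsions = "random",
                              entry_id = eid(k))
      # quantise to the wire precision (3 decimals) before planting, so the
      # emitted files carry exactly the in-memory coordinates
      ch$n <- round(ch$n, 3); ch$ca <- round(ch$ca, 3); ch$c <- round(ch$c, 3)
      base[[i]] <- ch
      entries[[eid(k)]] <- list(chain = ch,
                                resolution = round(stats::runif(1, 1.2, 3.6), 2),
                                r_free = round(stats::runif(1, 0.18, 0.30), 4),
                                group = FALSE)
    }
    truth <- list()
    plant <- function(mode, count, delta = 0, kk = 0, decoy = FALSE) {
      # distinct sources within a category so decoys never coincide
      srcs <- sample(nb, count, replace = count > nb)
      for (j in seq_len(count)) {
        k <<- k + 1L
        src <- base[[srcs[j]]]
        dup <- make_duplicate(src, mode, delta = delta, k = kk,
                              seed = sample.int(1e6, 1), entry_id = eid(k))
        src_meta <- entries[[src$entry_id]]
        entries[[eid(k)]] <<- list(chain = dup,
                                   resolution = src_meta$resolution,
                                   r_free = round(stats::runif(1, 0.18, 0.30), 4),
                                   group = FALSE)
        planted_dev <- switch(mode,
          exact = 0, label_swap = 0, x_shift = delta,
          rigid_copy = NA_real_, mirror = NA_real_,
          perturb = {     # deviation as the written files will carry it
            dd <- round(chain_coords(dup), 3) - chain_coords(src)
            sqrt(max(rowSums(dd^2)))
          })
        truth[[length(truth) + 1L]] <<- data.frame(
          entry1 = src$entry_id, chain1 = src$chain_id,
          entry2 = eid(k), chain2 = dup$chain_id,
          category = mode, is_decoy = decoy,
          planted_max_dev = planted_dev, stringsAsFactors = FALSE)
      }
    }
    plant("exact", spec$n_exact)
    plant("perturb", spec$n_perturbed, delta = spec$delta)
    plant("label_swap", spec$n_label_swap, kk = spec$label_swap_k)
    plant("rigid_copy", spec$n_rigid)
    plant("mirror", spec$n_mirror, decoy = TRUE)
    plant("perturb", spec$n_far, delta = spec$far_delta, decoy = TRUE)

    if (isTRUE(spec$filter_violations)) {
      viol <- generate_backbone(20, spec$geometry, seed = sample.int(1e6, 1),
                                torsions = "random")
      add_entry <- function(ch, ...) {
        k <<- k + 1L
        ch$entry_id <- eid(k)
        entries[[eid(k)]] <<- c(list(chain = ch),
                                list(resolution = 2.0, r_free = 0.22,
                                     group = FALSE), list(...))
        eid(k)
      }
      add_entry(viol, tweak = "partial_occupancy")
      add_entry(viol, tweak = "nonconsecutive")
      add_entry(viol, tweak = "missing_mainchain")
      add_entry(viol, tweak = "nonstandard")
      add_entry(viol, tweak = "nonprotein")
      add_entry(viol, tweak = "too_short")
      add_entry(viol, resolution = 4.5)               # out of scope
      k <- k + 1L
      entries[[eid(k)]] <- list(chain = viol, resolution = 1.5, r_free = 0.2,
                                group = TRUE)
      entries[[eid(k)]]$chain$entry_id <- eid(k)
    }

    files <- character(0)
    for (name in names(entries)) {
      e <- entries[[name]]
      pdb <- file.path(out_dir, paste0(name, ".pdb"))
      cif <- file.path(out_dir, paste0(name, ".cif"))
      write_chain_pdb(e$chain, pdb, resolution = e$resolution,
                      r_free = e$r_free, group_deposition = isTRUE(e$group),
                      tweak = e$tweak)
      write_chain_cif(e$chain, cif, resolution = e$resolution,
                      r_free = e$r_free, group_deposition = isTRUE(e$group),
                      tweak = e$tweak)
      files <- c(files, pdb, cif)
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(entry1 = character(0), chain1 = character(0),
                 entry2 = character(0), chain2 = character(0),
                 category = character(0), is_decoy = logical(0),
                 planted_max_dev = numeric(0))
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(truth_df, truth_path, dataframe = "rows",
                         digits = NA, pretty = TRUE, na = "null")
    list(files = files, truth = truth_df, truth_path = truth_path)
  })
}
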