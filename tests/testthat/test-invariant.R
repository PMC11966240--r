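test_that("row 1 encodes residue 1's internal geometry with the forced zeros", {
  ang <- 111.2 * pi / 180
  ch <- generate_backbone(4, ideal_geometry(), seed = 1)
  b <- compute_bri(ch)
  expect_equal(unname(b[1, ]),
               c(1.458, 0, 0, 0, 0, 0,
                 1.525 * cos(ang), 1.525 * sin(ang), 0),
               tolerance = 1e-12)
  expect_true(all(b[1, c(2, 3, 5, 6, 9)] == 0))
  expect_gt(b[1, 8], 0)
})

test_that("the invariant is invariant under random rigid motions", {
  set.seed(10)
  ch <- random_chain(30, seed = 5)
  b <- compute_bri(ch)
  for (i in 1:20) {
    moved <- transform_chain(ch, random_rigid_motion())
    expect_lt(bri_distance(b, compute_bri(moved)), 1e-9)
  }
})

test_that("the invariant matches an independent frame-projection oracle", {
  for (seed in c(3, 14, 15)) {
    ch <- random_chain(4, seed)
    expect_equal(unclass(compute_bri(ch)), oracle_bri(ch),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # also for the periodic helix
  hx <- generate_backbone(4, seed = 1)
  expect_equal(unclass(compute_bri(hx)), oracle_bri(hx),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate frames and short chains are classed errors", {
  ch <- random_chain(5, seed = 8)
  ch$n[2, ] <- ch$ca[2, ]   # coincident N and CA in residue 2
  expect_error(compute_bri(ch), "residue 2", class = "dupscan_degenerate_frame")
  expect_error(backbone_chain("x", "A", 1, "A",
                              matrix(0, 1, 3), matrix(0, 1, 3), matrix(0, 1, 3)),
               class = "dupscan_chain_too_short")
})

test_that("column averages match a brute-force summation oracle", {
  set.seed(11)
  m <- matrix(rnorm(45), 5, 9)
  b <- dupscan:::as_bri(m)
  means <- vapply(1:9, function(k) sum(m[, k]) / 5, numeric(1))
  expect_equal(unname(compute_brain(b)), means)
  same <- dupscan:::as_bri(matrix(rep(m[1, ], 3), 3, 9, byrow = TRUE))
  expect_equal(unname(compute_brain(same)), unname(m[1, ]))
  two <- dupscan:::as_bri(rbind(rep(0, 9), rep(9, 9)))
  expect_equal(unname(compute_brain(two)), rep(4.5, 9))
})

test_that("Chebyshev distances match exhaustive oracles and obey the lower bound", {
  set.seed(12)
  a <- dupscan:::as_bri(matrix(rnorm(90), 10, 9))
  b <- dupscan:::as_bri(matrix(rnorm(90), 10, 9))
  expect_equal(bri_distance(a, a), 0)
  shifted <- a; shifted[4, 7] <- shifted[4, 7] + 0.5
  expect_equal(bri_distance(a, dupscan:::as_bri(shifted)), 0.5)
  exhaustive <- max(vapply(1:10, function(i)
    max(abs(a[i, ] - b[i, ])), numeric(1)))
  expect_equal(bri_distance(a, b), exhaustive)
  expect_error(bri_distance(a, dupscan:::as_bri(matrix(0, 3, 9))),
               class = "dupscan_dimension_mismatch")

  v <- compute_brain(a); w <- v; w[3] <- w[3] + 0.01
  expect_equal(brain_distance(v, v), 0)
  expect_equal(brain_distance(v, w), 0.01)
  for (seed in 1:10) {
    c1 <- random_chain(12, seed); c2 <- random_chain(12, seed + 100)
    b1 <- compute_bri(c1); b2 <- compute_bri(c2)
    expect_lte(brain_distance(compute_brain(b1), compute_brain(b2)),
               bri_distance(b1, b2) + 1e-12)
  }
})

test_that("reconstruction inverts the invariant up to rigid motion", {
  set.seed(13)
  for (seed in c(21, 22, 23)) {
    ch <- random_chain(sample(5:60, 1), seed)
    b <- compute_bri(ch)
    rec <- reconstruct_backbone(b)
    fit <- kabsch_superpose(chain_coords(rec), chain_coords(ch))
    expect_lt(fit$rmsd, 1e-8)
    moved <- apply_rigid_motion(chain_coords(rec), fit$motion)
    expect_lt(sqrt(max(rowSums((moved - chain_coords(ch))^2))), 1e-8)
    expect_lt(bri_distance(compute_bri(rec), b), 1e-9)
  }
  bad <- unclass(compute_bri(random_chain(5, 1)))
  bad[1, 2] <- 0.1
  expect_error(reconstruct_backbone(dupscan:::as_bri(bad)),
               class = "dupscan_invalid_row_one")
})

test_that("mirror_bri equals the invariant of the reflected chain", {
  for (seed in c(31, 32)) {
    ch <- random_chain(15, seed)
    b <- compute_bri(ch)
    expect_equal(unclass(mirror_bri(b)), unclass(compute_bri(reflect_chain(ch))),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_gt(bri_distance(b, mirror_bri(b)), 0)
  }
  # planar backbone: achiral fixed point
  planar <- unclass(compute_bri(random_chain(6, 33)))
  planar[, c(3, 6, 9)] <- 0
  pb <- dupscan:::as_bri(planar)
  expect_equal(unclass(mirror_bri(pb)), unclass(pb), ignore_attr = TRUE)
  # helix fixtures are strongly chiral
  hx <- compute_bri(generate_backbone(30, seed = 2))
  expect_gt(bri_distance(hx, mirror_bri(hx)), 0.1)
})

test_that("interior subchain rows equal the parent rows exactly", {
  ch <- random_chain(40, seed = 41)
  parent <- unclass(compute_bri(ch))
  sub <- subchain(ch, 10, 25)
  rows <- unclass(compute_bri(sub))
  expect_identical(rows[2:16, ], parent[11:25, ])
  expect_false(isTRUE(all.equal(rows[1, ], parent[10, ])))
})

test_that("perturbations move the invariant by a stable constant multiple", {
  ch <- random_chain(50, seed = 51)
  b <- compute_bri(ch)
  cs <- vapply(c(1e-3, 1e-4, 1e-5), function(delta) {
    pert <- make_duplicate(ch, "perturb", delta = delta, seed = 52)
    bri_distance(b, compute_bri(pert)) / delta
  }, numeric(1))
  expect_lt(max(cs) / min(cs), 5)
})

test_that("invariant TSV serialisation round-trips", {
  ch <- random_chain(9, seed = 61)
  b <- compute_bri(ch)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bri(b, path)
  lines <- readLines(path)
  expect_identical(lines[1:3], c(paste0("#entry\t", ch$entry_id),
                                 paste0("#chain\tA"), "#m\t9"))
  back <- read_bri(path)
  expect_equal(unclass(back), unclass(b), tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(attr(back, "entry_id"), ch$entry_id)
})
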