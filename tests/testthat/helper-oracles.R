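# Shared helpers and independent oracles.  The oracles deliberately take a
# different computational route from the package code they check.

# Gram-Schmidt frame oracle: orthonormalise (n-ca, c-ca) directly
gs_frame <- function(n, ca, c) {
  u <- n - ca
  v <- c - ca
  q1 <- u / sqrt(sum(u^2))
  w <- v - sum(v * q1) * q1
  q2 <- w / sqrt(sum(w^2))
  q3 <- c(q1[2] * q2[3] - q1[3] * q2[2],
          q1[3] * q2[1] - q1[1] * q2[3],
          q1[1] * q2[2] - q1[2] * q2[1])
  list(origin = ca, e1 = q1, e2 = q2, e3 = q3)
}

# invariant oracle: frames by Gram-Schmidt, projections by solving the
# linear system rather than dot products
oracle_bri <- function(chain) {
  m <- chain$m
  out <- matrix(0, m, 9)
  f1 <- gs_frame(chain$n[1, ], chain$ca[1, ], chain$c[1, ])
  nv <- chain$n[1, ] - chain$ca[1, ]
  cv <- chain$c[1, ] - chain$ca[1, ]
  out[1, ] <- c(sqrt(sum(nv^2)), 0, 0, 0, 0, 0,
                sum(cv * f1$e1), sum(cv * f1$e2), 0)
  for (i in 2:m) {
    f <- gs_frame(chain$n[i - 1, ], chain$ca[i - 1, ], chain$c[i - 1, ])
    basis <- cbind(f$e1, f$e2, f$e3)
    loc <- function(p) as.numeric(solve(basis, p - f$origin))
    out[i, ] <- c(loc(chain$n[i, ]), loc(chain$ca[i, ]), loc(chain$c[i, ]))
  }
  out
}

random_chain <- function(m, seed) {
  generate_backbone(m, seed = seed, torsions = "random",
                    entry_id = sprintf("r%03d", seed %% 1000))
}

max_pair_dev <- function(a, b) {
  sqrt(max(rowSums((chain_coords(a) - chain_coords(b))^2)))
}

# brute-force duplicate search: all same-length pairs, full invariant only
brute_force_pairs <- function(chains, t) {
  n <- length(chains)
  bris <- lapply(chains, compute_bri)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chains[[i]]$m != chains[[j]]$m) next
      if (chains[[i]]$entry_id == chains[[j]]$entry_id) next
      if (bri_distance(bris[[i]], bris[[j]]) <= t) {
        key <- sort(c(paste0(chains[[i]]$entry_id, "_", chains[[i]]$chain_id),
                      paste0(chains[[j]]$entry_id, "_", chains[[j]]$chain_id)))
        out <- c(out, paste(key, collapse = "|"))
      }
    }
  }
  sort(out)
}

pair_keys <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  sort(vapply(seq_len(nrow(pairs)), function(r) {
    key <- sort(c(paste0(pairs$entry1[r], "_", pairs$chain1[r]),
                  paste0(pairs$entry2[r], "_", pairs$chain2[r])))
    paste(key, collapse = "|")
  }, character(1)))
}

# small corpus of in-memory chains with planted duplicates, distinct entries
random_corpus <- function(n_base, seed, t = 0.01) {
  set.seed(seed)
  lens <- sample(10:40, n_base, replace = TRUE)
  chains <- lapply(seq_len(n_base), function(i) {
    ch <- random_chain(lens[i], seed * 1000 + i)
    ch$entry_id <- sprintf("e%04d", i)
    ch
  })
  extra <- list()
  for (i in sample(n_base, max(1, n_base %/% 5))) {
    mode <- sample(c("exact", "rigid_copy", "mirror"), 1)
    dup <- make_duplicate(chains[[i]], mode, seed = seed + i,
                          entry_id = sprintf("d%04d", i))
    extra[[length(extra) + 1]] <- dup
  }
  c(chains, extra)
}
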