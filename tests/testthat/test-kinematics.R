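# Linker windows, torsion application, full-length construction.

test_that("linker_residues selects split windows and rejects overlaps", {
  lay <- domain_layout("A", list(
    list(id = "D1", chain = "A", ranges = list(c(1, 50))),
    list(id = "D2", chain = "A", ranges = list(c(51, 100)))))
  sp <- linker_residues(lay, width = 8)
  expect_equal(sp$windows$from, 47L)
  expect_equal(sp$windows$to, 54L)
  expect_equal(nrow(sp$torsions), 16L)
  expect_equal(sp$n_genes, 16L)

  lay3 <- domain_layout("A", list(
    list(id = "D1", chain = "A", ranges = list(c(1, 40))),
    list(id = "D2", chain = "A", ranges = list(c(41, 80))),
    list(id = "D3", chain = "A", ranges = list(c(81, 120)))))
  sp3 <- linker_residues(lay3, width = 8)
  expect_equal(nrow(sp3$windows), 2L)
  r1 <- seq(sp3$windows$from[1], sp3$windows$to[1])
  r2 <- seq(sp3$windows$from[2], sp3$windows$to[2])
  expect_length(intersect(r1, r2), 0L)

  tiny <- domain_layout("A", list(
    list(id = "D1", chain = "A", ranges = list(c(1, 4))),
    list(id = "D2", chain = "A", ranges = list(c(5, 8))),
    list(id = "D3", chain = "A", ranges = list(c(9, 12)))))
  expect_error(linker_residues(tiny, width = 8),
               class = "domasm_layout_error")
  expect_error(linker_residues(lay, width = 7),
               class = "domasm_validation_error")
})

test_that("apply_torsions: identity, rigid cores, additive group action", {
  tg <- fx_two_domain()
  base <- tg$structure
  sp <- linker_residues(tg$layout, 8)
  same <- apply_torsions(base, sp, numeric(sp$n_genes))
  expect_lt(max(abs(same$ca - base$ca)), 1e-9)
  expect_lt(max(abs(same$n - base$n)), 1e-9)

  set.seed(9)
  v <- runif(sp$n_genes, -pi, pi)
  out <- apply_torsions(base, sp, v)
  # rigid-core invariance: intra-domain distances outside movable windows
  win <- unlist(lapply(seq_len(nrow(sp$windows)), function(b)
    seq(sp$windows$from[b], sp$windows$to[b])))
  for (dom in unique(base$res$domain)) {
    core <- which(base$res$domain == dom & !(base$res$resno %in% win))
    d0 <- dist(base$ca[core, ])
    d1 <- dist(out$ca[core, ])
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  # bond geometry preserved everywhere
  expect_lt(max(abs(sqrt(rowSums((out$c - out$ca)^2)) -
                      sqrt(rowSums((base$c - base$ca)^2)))), 1e-9)
  # additive composition (torsions are internal coordinates)
  w <- runif(sp$n_genes, -0.5, 0.5)
  ab <- apply_torsions(apply_torsions(base, sp, v), sp, w)
  both <- apply_torsions(base, sp, v + w)
  expect_lt(max(abs(ab$ca - both$ca)), 1e-6)
})

test_that("a single phi offset matches an explicit axis-angle rotation", {
  dom <- make_ideal_domain("helix", 12)
  lay <- domain_layout("A", list(
    list(id = "D1", chain = "A", ranges = list(c(1, 6))),
    list(id = "D2", chain = "A", ranges = list(c(7, 12)))))
  b <- dom
  b$res$domain <- layout_residues(lay)$domain
  sp <- linker_residues(lay, 4)  # residues 5-8
  v <- numeric(sp$n_genes)
  tpos <- which(sp$torsions$resno == 5 & sp$torsions$type == "phi")
  v[tpos] <- 60 * pi / 180
  out <- apply_torsions(b, sp, v)
  rows <- which(b$res$resno == 5)
  axis <- b$n[rows, ] - b$ca[rows, ]
  R <- domasm:::rotation_about_axis(axis, 60 * pi / 180)
  p <- b$ca[rows, ]
  rot_pt <- function(x) as.numeric(R %*% (x - p)) + p
  # downstream atoms: C of residue 5 and everything from residue 6 on
  expect_lt(max(abs(out$c[rows, ] - rot_pt(b$c[rows, ]))), 1e-9)
  for (r in which(b$res$resno > 5)) {
    expect_lt(max(abs(out$n[r, ] - rot_pt(b$n[r, ]))), 1e-9)
    expect_lt(max(abs(out$ca[r, ] - rot_pt(b$ca[r, ]))), 1e-9)
  }
  # upstream untouched
  for (r in which(b$res$resno < 5))
    expect_lt(max(abs(out$ca[r, ] - b$ca[r, ])), 1e-12)
  # the phi dihedral itself moved by +60 degrees
  phi0 <- dihedral_angle(b$c[rows - 1, ], b$n[rows, ], b$ca[rows, ], b$c[rows, ])
  phi1 <- dihedral_angle(out$c[rows - 1, ], out$n[rows, ], out$ca[rows, ],
                         out$c[rows, ])
  expect_lt(abs(domasm:::wrap_angle(phi1 - phi0 - 60 * pi / 180)), 1e-9)
})

test_that("initial_full_length builds ideal junctions deterministically", {
  tg <- fx_two_domain()
  # single-domain input is returned unchanged
  lay1 <- domain_layout("A", list(list(id = "D1", chain = "A",
                                       ranges = list(c(1, 30)))))
  dom <- make_ideal_domain("helix", 30)
  one <- initial_full_length(list(D1 = dom), lay1, rng_seed = 4)
  expect_lt(max(abs(one$ca - dom$ca)), 1e-12)

  full <- initial_full_length(tg$domains, tg$layout, rng_seed = 7)
  expect_equal(n_residues(full), 68L)
  # exactly one junction: C(34)-N(35) has ideal peptide bond length
  bond <- sqrt(sum((full$n[35, ] - full$c[34, ])^2))
  expect_lt(abs(bond - 1.329), 1e-6)
  # chain connectivity everywhere
  cn <- sqrt(rowSums((full$n[-1, ] - full$c[-68, ])^2))
  expect_lt(max(abs(cn - 1.329)), 0.01)

  again <- initial_full_length(tg$domains, tg$layout, rng_seed = 7)
  expect_identical(full$ca, again$ca)
  other <- initial_full_length(tg$domains, tg$layout, rng_seed = 8)
  expect_gt(max(abs(other$ca - full$ca)), 0.1)
})

test_that("chain-slot moves are rigid and invert under negation", {
  tg <- fx_two_chain()
  sp <- linker_residues(tg$layout, 8)
  expect_equal(sp$slots, "B")
  expect_equal(sp$n_genes, 6L)
  v <- c(0.4, -0.2, 0.7, 5, -3, 2)
  out <- apply_torsions(tg$structure, sp, v)
  rows <- which(tg$structure$res$chain == "B")
  expect_lt(max(abs(dist(out$ca[rows, ]) - dist(tg$structure$ca[rows, ]))),
            1e-9)
  back <- apply_torsions(out, sp, -v)
  expect_lt(max(abs(back$ca - tg$structure$ca)), 1e-9)
})
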