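# Evolutionary operators, elitist selection, reproducibility.

test_that("uniform crossover obeys boundary cases and gene-origin statistics", {
  tg <- fx_two_domain()
  sp <- linker_residues(tg$layout, 8)
  set.seed(1)
  a <- runif(sp$n_genes, -pi, pi)
  b <- runif(sp$n_genes, -pi, pi)
  expect_identical(crossover_genes(a, a, 0.5), a)
  expect_identical(crossover_genes(a, b, 1.0), a)
  expect_identical(crossover_genes(a, b, 0.0), b)
  expect_error(crossover_genes(a, b[-1]), class = "domasm_validation_error")
  # empirical origin frequency at rate 0.5 over 10,000 gene draws
  set.seed(2)
  n <- 10000L
  aa <- rep(1, n); bb <- rep(0, n)
  freq <- mean(crossover_genes(aa, bb, 0.5))
  expect_lt(abs(freq - 0.5), 0.02)
})

test_that("mutation respects rate, wrapping and perturbation frequency", {
  tg <- fx_two_domain()
  sp <- linker_residues(tg$layout, 8)
  set.seed(3)
  v <- runif(sp$n_genes, -pi, pi)
  expect_identical(mutate_genes(v, sp, rate = 0), v)
  hits <- 0L; total <- 0L
  for (k in 1:625) {  # 625 x 16 = 10,000 gene draws
    m <- mutate_genes(v, sp, rate = 0.1)
    expect_true(all(m >= -pi & m < pi))
    hits <- hits + sum(m != v); total <- total + length(v)
  }
  expect_lt(abs(hits / total - 0.1), 0.01)
})

test_that("init_population is seeded, evaluated, and recognizes the optimum", {
  tg <- fx_two_domain()
  cfg <- assembly_config(pool_size = 6, iterations = 1, top_k = 2,
                         rng_seed = 10)
  pool <- init_population(tg$domains, tg$layout, cfg, tg$map)
  expect_equal(nrow(pool$vectors), 6L)
  expect_true(all(is.finite(pool$energies)))
  pool2 <- init_population(tg$domains, tg$layout, cfg, tg$map)
  expect_identical(pool$vectors, pool2$vectors)
  expect_identical(pool$energies, pool2$energies)

  # inject the target's own torsion offsets: energy ~0 and pool minimum
  prob <- pool$problem
  tors <- function(st, rn, type) {
    r <- which(st$res$resno == rn)
    if (type == "phi")
      dihedral_angle(st$c[r - 1, ], st$n[r, ], st$ca[r, ], st$c[r, ])
    else
      dihedral_angle(st$n[r, ], st$ca[r, ], st$c[r, ], st$n[r + 1, ])
  }
  vstar <- vapply(seq_len(nrow(prob$spec$torsions)), function(t)
    tors(tg$structure, prob$spec$torsions$resno[t], prob$spec$torsions$type[t]) -
      tors(prob$base, prob$spec$torsions$resno[t], prob$spec$torsions$type[t]),
    0)
  estar <- prob$energy(vstar)  # positive offsets add to the dihedrals
  expect_lt(estar, 1e-9)
  expect_lt(estar, min(pool$energies))
})

test_that("evolve_step conserves the pool and never worsens the best energy", {
  tg <- fx_two_domain()
  cfg <- assembly_config(pool_size = 10, iterations = 1, top_k = 2,
                         rng_seed = 11)
  pool <- init_population(tg$domains, tg$layout, cfg, tg$map)
  set.seed(99)
  for (k in 1:5) {
    before <- min(pool$energies)
    pool <- evolve_step(pool)
    expect_equal(nrow(pool$vectors), 10L)
    expect_lte(min(pool$energies), before)
  }
  # degenerate operators: offspring equal parents, pool unchanged
  cfg0 <- assembly_config(pool_size = 10, iterations = 1, top_k = 2,
                          rng_seed = 11, crossover_rate = 1,
                          mutation_rate = 0)
  pool0 <- init_population(tg$domains, tg$layout, cfg0, tg$map)
  v0 <- pool0$vectors
  pool0 <- evolve_step(pool0)
  expect_identical(pool0$vectors, v0)
})

test_that("run_assembly is reproducible, monotone, and honors iterations = 0", {
  tg <- fx_two_domain()
  cfg <- assembly_config(pool_size = 12, iterations = 15, top_k = 3,
                         rng_seed = 5, refine = FALSE)
  r1 <- run_assembly(tg$domains, tg$layout, tg$map, cfg)
  r2 <- run_assembly(tg$domains, tg$layout, tg$map, cfg)
  expect_identical(r1$energies, r2$energies)
  expect_identical(r1$vectors, r2$vectors)
  expect_true(all(diff(r1$trace$best) <= 1e-12))
  expect_length(r1$models, 3L)
  expect_equal(r1$energies, sort(r1$energies))
  # cached energies equal the general-route ACD of the realized models
  for (k in 1:3)
    expect_lt(abs(acd(r1$models[[k]], tg$map) - r1$energies[k]), 1e-9)

  cfg0 <- assembly_config(pool_size = 12, iterations = 0, top_k = 3,
                          rng_seed = 5, refine = FALSE)
  r0 <- run_assembly(tg$domains, tg$layout, tg$map, cfg0)
  expect_equal(nrow(r0$trace), 1L)
  expect_length(r0$models, 3L)
})

test_that("the refinement stage only lowers the best energy and stays reproducible", {
  tg <- fx_two_domain()
  cfg <- assembly_config(pool_size = 8, iterations = 5, top_k = 1,
                         rng_seed = 6, refine = TRUE, refine_rounds = 1)
  ra <- run_assembly(tg$domains, tg$layout, tg$map, cfg)
  rb <- run_assembly(tg$domains, tg$layout, tg$map, cfg)
  expect_identical(ra$energies, rb$energies)
  cfg_off <- assembly_config(pool_size = 8, iterations = 5, top_k = 1,
                             rng_seed = 6, refine = FALSE)
  roff <- run_assembly(tg$domains, tg$layout, tg$map, cfg_off)
  expect_lte(ra$energies[1], roff$energies[1])
})

test_that("writing assembly outputs produces models, energies and trace files", {
  tg <- fx_two_domain()
  cfg <- assembly_config(pool_size = 6, iterations = 3, top_k = 2,
                         rng_seed = 2, refine = FALSE)
  res <- run_assembly(tg$domains, tg$layout, tg$map, cfg)
  d <- withr::local_tempdir()
  write_assembly_result(res, d)
  expect_true(file.exists(file.path(d, "model_01.pdb")))
  expect_true(file.exists(file.path(d, "model_02.pdb")))
  en <- read.delim(file.path(d, "energies.tsv"))
  expect_equal(nrow(en), 2L)
  tr <- read.delim(file.path(d, "trace.tsv"))
  expect_equal(nrow(tr), 4L)  # iteration 0 + 3 steps
})
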