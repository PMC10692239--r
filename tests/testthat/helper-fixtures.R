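# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# standard two-domain helix pair with an 8-residue linker
fx_two_domain <- function() fx_get("two_domain", function() {
  tg <- make_multidomain_target(
    fixture_spec(c("helix", "helix"), c(30, 30), linkers = 8, seed = 1))
  tg$map <- oracle_interactions(tg$structure, tg$layout)
  tg$domains <- stats::setNames(
    lapply(tg$layout$domains, function(d)
      extract_domain(tg$structure, tg$layout, d$id)),
    vapply(tg$layout$domains, `[[`, "", "id"))
  tg
})

# three-domain mixed-topology chain
fx_three_domain <- function() fx_get("three_domain", function() {
  tg <- make_multidomain_target(
    fixture_spec(c("helix", "strand", "mixed"), c(24, 20, 24),
                 linkers = c(8, 8), seed = 2))
  tg$map <- oracle_interactions(tg$structure, tg$layout)
  tg$domains <- stats::setNames(
    lapply(tg$layout$domains, function(d)
      extract_domain(tg$structure, tg$layout, d$id)),
    vapply(tg$layout$domains, `[[`, "", "id"))
  tg
})

# two-chain pseudo-complex
fx_two_chain <- function() fx_get("two_chain", function() {
  tg <- make_multidomain_target(
    fixture_spec(c("helix", "helix"), c(30, 30), chains = c("A", "B"),
                 seed = 3))
  tg$map <- oracle_interactions(tg$structure, tg$layout)
  tg$domains <- stats::setNames(
    lapply(tg$layout$domains, function(d)
      extract_domain(tg$structure, tg$layout, d$id)),
    vapply(tg$layout$domains, `[[`, "", "id"))
  tg
})

# two close 5-residue strands on separate domains (all CA pairs < 40 A)
fx_toy_2x5 <- function() fx_get("toy_2x5", function() {
  s1 <- make_ideal_domain("strand", 8)
  keep <- 1:5
  sub5 <- function(s, resno_start, shift) backbone_structure(
    chain = rep("A", 5), resno = seq(resno_start, length.out = 5),
    aa = s$res$aa[keep],
    n = sweep(s$n[keep, ], 2, shift, "+"),
    ca = sweep(s$ca[keep, ], 2, shift, "+"),
    c = sweep(s$c[keep, ], 2, shift, "+"),
    cb = sweep(s$cb[keep, ], 2, shift, "+"), validate = FALSE)
  a <- sub5(s1, 1, c(0, 0, 0))
  b <- sub5(s1, 6, c(0, 5, 0))
  st <- backbone_structure(
    chain = rep("A", 10), resno = 1:10, aa = c(a$res$aa, b$res$aa),
    n = rbind(a$n, b$n), ca = rbind(a$ca, b$ca), c = rbind(a$c, b$c),
    cb = rbind(a$cb, b$cb), validate = FALSE)
  lay <- domain_layout("A", list(
    list(id = "D1", chain = "A", ranges = list(c(1, 5))),
    list(id = "D2", chain = "A", ranges = list(c(6, 10)))))
  list(structure = st, layout = lay)
})

# hand-written minimal PDB text
write_tiny_pdb <- function(path, drop_ca2 = FALSE) {
  at <- function(no, name, resno, x, y, z)
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            no, name, resno, x, y, z, substr(name, 1, 1))
  lines <- c(
    at(1, "N", 1, 0, 1.4, 0), at(2, "CA", 1, 0, 0, 0), at(3, "C", 1, 1.5, 0, 0),
    at(4, "N", 2, 2.2, 1.0, 0),
    if (!drop_ca2) at(5, "CA", 2, 3.6, 1.0, 0.2),
    at(6, "C", 2, 4.3, 2.2, 0.4),
    at(7, "N", 3, 5.6, 2.2, 0.5), at(8, "CA", 3, 6.4, 3.3, 0.7),
    at(9, "C", 3, 7.9, 3.0, 0.8),
    "END")
  writeLines(lines, path)
  path
}
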