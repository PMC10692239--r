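# Interaction maps: oracle generation, binning/decoding, TSV round trips.

test_that("oracle r equals the CA-CA distance and respects r_max", {
  tg <- fx_two_domain()
  m <- tg$map
  s <- tg$structure
  gk <- paste(m$index$chain, m$index$resno)
  sk <- paste(s$res$chain, s$res$resno)
  rows <- match(gk, sk)
  i <- rows[match(m$pairs$i, m$index$gidx)]
  j <- rows[match(m$pairs$j, m$index$gidx)]
  d <- sqrt(rowSums((s$ca[i, ] - s$ca[j, ])^2))
  expect_lt(max(abs(m$mode[, "r"] - d)), 1e-9)
  expect_lte(max(m$mode[, "r"]), 40)
  # both orderings present
  expect_true(all(paste(m$pairs$j, m$pairs$i) %in% paste(m$pairs$i, m$pairs$j)))
  expect_error(oracle_interactions(tg$structure, tg$layout, r_max = 0),
               class = "domasm_degenerate_error")
})

test_that("oracle pair count on a toy 2x5 two-domain structure is 50", {
  toy <- fx_toy_2x5()
  m <- oracle_interactions(toy$structure, toy$layout, r_max = 40)
  expect_equal(n_pairs(m), 2L * 5L * 5L)  # brute-force enumeration
})

test_that("discretize produces normalized distributions with bounded quantization", {
  tg <- fx_two_domain()
  m <- tg$map
  d0 <- discretize_targets(m, blur_sd = 0)
  # delta: probability 1 in the containing bin
  r1 <- m$mode[1, "r"]
  b <- findInterval(r1, d0$scheme$r$edges)
  expect_equal(d0$dist$r[1, b], 1)
  for (el in c("alpha", "beta", "gamma", "r", "theta", "phi")) {
    expect_lt(max(abs(rowSums(d0$dist[[el]]) - 1)), 1e-6)
    expect_gte(min(d0$dist[[el]]), 0)
  }
  dec <- decode_distributions(d0)
  # decode returns midpoints: error at most half a bin width per element
  expect_lte(max(abs(dec$mode[, "r"] - m$mode[, "r"])), 0.5 + 1e-9)
  for (el in c("alpha", "gamma", "phi", "theta", "beta"))
    expect_lte(max(abs(dec$mode[, el] - m$mode[, el])),
               7.5 * pi / 180 + 1e-9)

  db <- discretize_targets(m, blur_sd = c(alpha = 15, beta = 15, gamma = 15,
                                          r = 1, theta = 15, phi = 15) *
                             c(rep(pi / 180, 3), 1, pi / 180, pi / 180))
  for (el in c("alpha", "beta", "gamma", "r", "theta", "phi")) {
    expect_lt(max(abs(rowSums(db$dist[[el]]) - 1)), 1e-6)
    expect_gte(min(db$dist[[el]]), -1e-12)
  }
  decb <- decode_distributions(db)  # overflow pairs may be dropped
  keep <- match(paste(decb$pairs$i, decb$pairs$j),
                paste(m$pairs$i, m$pairs$j))
  expect_lte(mean(abs(decb$mode[, "r"] - m$mode[keep, "r"])), 1)

  expect_error(discretize_targets(dec, blur_sd = -1),
               class = "domasm_validation_error")
})

test_that("decode breaks ties toward the lowest bin and drops overflow pairs", {
  tg <- fx_two_domain()
  d0 <- discretize_targets(tg$map, blur_sd = 0)
  nr <- ncol(d0$dist$r)
  d0$dist$r[1, ] <- 1 / nr                    # uniform over r bins
  d0$dist$r[2, ] <- c(rep(0, nr - 1), 1)      # all mass in overflow
  dec <- decode_distributions(d0)
  expect_equal(unname(dec$mode[1, "r"]), 2.5) # lowest bin midpoint
  expect_equal(n_pairs(dec), n_pairs(d0) - 1L)
  d0$dist$alpha[3, 1] <- -0.5
  expect_error(decode_distributions(d0), class = "domasm_validation_error")
})

test_that("interaction files round-trip in both dialects", {
  tg <- fx_two_domain()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(tg$map, p)
  m2 <- read_interactions(p)
  expect_equal(m2$dialect, "mode")
  expect_equal(m2$pairs, tg$map$pairs)
  expect_lt(max(abs(m2$mode - tg$map$mode)), 1e-6)
  expect_equal(m2$index$chain, tg$map$index$chain)

  db <- discretize_targets(tg$map, blur_sd = c(alpha = 15, beta = 15,
                                               gamma = 15, r = 1, theta = 15,
                                               phi = 15) *
                             c(rep(pi / 180, 3), 1, pi / 180, pi / 180))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(db, p2)
  d2 <- read_interactions(p2)
  expect_equal(d2$dialect, "dist")
  # sparse rows (omitted zero bins) reconstruct the full distributions
  for (el in c("alpha", "r", "theta"))
    expect_lt(max(abs(d2$dist[[el]] - db$dist[[el]])), 2e-6)

  # empty map: header-only file, read back as empty
  empty <- tg$map
  empty$pairs <- empty$pairs[0, , drop = FALSE]
  empty$mode <- empty$mode[0, , drop = FALSE]
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(empty, p3)
  e2 <- read_interactions(p3)
  expect_equal(n_pairs(e2), 0L)

  # malformed row reports its line number
  lines <- readLines(p)
  lines[length(lines)] <- "1\t2\tbroken"
  writeLines(lines, p)
  expect_error(read_interactions(p), "line", class = "domasm_format_error")
})
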