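# Ideal-geometry synthetic multi-domain targets with ground truth:
# stand-ins for experimental structures so the whole engine is testable
# with zero data dependencies.

IDEAL_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                       strand = c(phi = -120, psi = 120))

# sequential internal-to-Cartesian build of one chain from per-residue
# phi/psi (radians); phi[1] and psi[L] are not used.
build_chain_from_torsions <- function(phi, psi, chain = "A",
                                      resno_start = 1L, aa = "ALA") {
  L <- length(phi)
  g <- IDEAL_GEOM
  d2r <- pi / 180
  n <- ca <- cc <- matrix(NA_real_, L, 3)
  n[1, ] <- c(0, 0, 0)
  ca[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- pi - g$a_n_ca_c * d2r
  cc[1, ] <- ca[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(L - 1L)) {
    n[i + 1L, ] <- nerf_place(n[i, ], ca[i, ], cc[i, ],
                              g$b_c_n, g$a_ca_c_n * d2r, psi[i])
    ca[i + 1L, ] <- nerf_place(ca[i, ], cc[i, ], n[i + 1L, ],
                               g$b_n_ca, g$a_c_n_ca * d2r, pi)
    cc[i + 1L, ] <- nerf_place(cc[i, ], n[i + 1L, ], ca[i + 1L, ],
                               g$b_ca_c, g$a_n_ca_c * d2r, phi[i + 1L])
  }
  backbone_structure(chain = rep(chain, L),
                     resno = seq.int(resno_start, length.out = L),
                     aa = rep(aa, L), n = n, ca = ca, c = cc,
                     cb = virtual_cbeta(n, ca, cc), validate = FALSE)
}

# ideal per-residue torsions for a domain kind
domain_torsions <- function(kind, length) {
  d2r <- pi / 180
  if (kind == "mixed") {
    h <- ceiling(length / 2)
    list(phi = c(rep(IDEAL_TORSIONS$helix["phi"], h),
                 rep(IDEAL_TORSIONS$strand["phi"], length - h)) * d2r,
         psi = c(rep(IDEAL_TORSIONS$helix["psi"], h),
                 rep(IDEAL_TORSIONS$strand["psi"], length - h)) * d2r)
  } else if (kind %in% names(IDEAL_TORSIONS)) {
    list(phi = rep(IDEAL_TORSIONS[[kind]]["phi"] * d2r, length),
         psi = rep(IDEAL_TORSIONS[[kind]]["psi"] * d2r, length))
  } else stop_validation("unknown domain kind: %s", kind)
}

#' Ideal-geometry single domain
#'
#' Builds a backbone from ideal internal coordinates (helix
#' phi = -57, psi = -47 degrees; strand phi = -120, psi = +120;
#' "mixed" = helix half then strand half; omega = 180, ideal bond
#' lengths/angles) by sequential atom placement.  Deterministic; the
#' `seed` argument is accepted for interface symmetry and ignored.
#'
#' @param kind One of `"helix"`, `"strand"`, `"mixed"`.
#' @param length Number of residues (>= 8).
#' @param seed Ignored (the construction is deterministic).
#' @return A `"backbone"` structure (poly-alanine with ideal CB).
#' @export
make_ideal_domain <- function(kind, length, seed = 0) {
  if (length < 8L) stop_validation("domain length must be >= 8")
  tt <- domain_torsions(kind, length)
  build_chain_from_torsions(tt$phi, tt$psi)
}

#' Synthetic multi-domain fixture specification
#'
#' @param kinds Character vector of per-domain secondary-structure kinds
#'   (`"helix"`, `"strand"`, `"mixed"`).
#' @param lengths Integer per-domain residue counts (each >= 8).
#' @param linkers Integer linker lengths between consecutive same-chain
#'   domains (length `length(kinds) - 1`; entries at chain changes are
#'   ignored).
#' @param chains Per-domain chain ids (default: all on chain `"A"`).
#' @param seed Integer seed controlling linker torsions and inter-chain
#'   placement.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(kinds, lengths, linkers = integer(0),
                         chains = rep("A", length(kinds)), seed = 0) {
  if (length(kinds) != length(lengths) || length(kinds) != length(chains))
    stop_validation("kinds, lengths and chains must have equal length")
  if (any(lengths < 8L)) stop_validation("domain lengths must be >= 8")
  nd <- length(kinds)
  # one linker per pair of consecutive same-chain domains
  nlink <- if (nd > 1L) sum(chains[-1L] == chains[-nd]) else 0L
  if (length(linkers) == 1L && nlink > 1L) linkers <- rep(linkers, nlink)
  if (length(linkers) != nlink)
    stop_validation("need %d linker length(s)", nlink)
  if (nlink > 0L && any(linkers < 1L))
    stop_validation("linker lengths must be >= 1")
  tot <- sum(lengths) + sum(linkers)
  if (tot > 500L) stop_validation("fixture too large (%d residues > 500)", tot)
  structure(list(kinds = kinds, lengths = as.integer(lengths),
                 linkers = as.integer(linkers), chains = as.character(chains),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Synthetic multi-domain target with ground truth
#'
#' Concatenates ideal-geometry domains with flexible linkers whose
#' torsions are fixed, seed-determined random draws; redraws (up to 100
#' times) until the target is clash-free (minimum inter-domain CA-CA
#' distance >= 3.5 Angstrom).  Linker residues are assigned half to the
#' preceding and half to the following domain, so the default movable
#' window of [linker_residues()] brackets each junction.  Additional
#' chains are placed at a seeded random orientation a few Angstrom from
#' the anchor chain.
#'
#' @param spec A `"fixture_spec"`.
#' @return List with elements `structure` (a `"backbone"` with domain
#'   labels) and `layout` (a `"domain_layout"`).
#' @export
make_multidomain_target <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop_validation("need a fixture_spec")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  nd <- length(spec$kinds)
  chains_u <- unique(spec$chains)
  # layout bookkeeping: contiguous residue numbering per chain; each
  # linker is split between its flanking domains (first half to the
  # preceding domain) so the movable window brackets the junction
  doms <- list()
  linker_of <- cumsum(c(FALSE, spec$chains[-1L] == spec$chains[-nd]))
  for (ch in chains_u) {
    di <- which(spec$chains == ch)
    pos <- 1L
    for (q in seq_along(di)) {
      k <- di[q]
      pre <- if (q > 1L) {
        l <- spec$linkers[linker_of[k]]
        l - floor(l / 2)
      } else 0L
      post <- if (q < length(di)) floor(spec$linkers[linker_of[di[q + 1L]]] / 2) else 0L
      len <- pre + spec$lengths[k] + post
      doms[[k]] <- list(id = sprintf("D%d", k), chain = ch,
                        ranges = list(c(pos, pos + len - 1L)))
      pos <- pos + len
    }
  }
  layout <- domain_layout(chains_u, doms[order(match(
    vapply(doms, `[[`, "", "chain"), chains_u))])
  for (attempt in seq_len(100L)) {
    built <- list()
    for (ch in chains_u) {
      di <- which(spec$chains == ch)
      phi <- numeric(0); psi <- numeric(0)
      for (q in seq_along(di)) {
        k <- di[q]
        tt <- domain_torsions(spec$kinds[k], spec$lengths[k])
        phi <- c(phi, tt$phi); psi <- c(psi, tt$psi)
        if (q < length(di)) {
          nl <- spec$linkers[linker_of[di[q + 1L]]]
          phi <- c(phi, stats::runif(nl, -pi, pi))
          psi <- c(psi, stats::runif(nl, -pi, pi))
        }
      }
      built[[ch]] <- build_chain_from_torsions(phi, psi, chain = ch)
    }
    s <- built[[1L]]
    if (length(built) > 1L) for (ci in 2:length(built)) {
      cc <- built[[ci]]
      a_ctr <- colMeans(s$ca)
      a_rad <- sqrt(max(rowSums(sweep(s$ca, 2L, a_ctr)^2)))
      c_ctr <- colMeans(cc$ca)
      c_rad <- sqrt(max(rowSums(sweep(cc$ca, 2L, c_ctr)^2)))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_about_axis(ax, stats::runif(1, -pi, pi))
      shift <- a_ctr + (a_rad + c_rad + 10) * u
      tx <- function(m) if (is.null(m)) NULL else
        sweep(sweep(m, 2L, c_ctr) %*% t(R), 2L, shift, "+")
      s <- backbone_structure(
        chain = c(s$res$chain, cc$res$chain),
        resno = c(s$res$resno, cc$res$resno),
        aa = c(s$res$aa, cc$res$aa),
        n = rbind(s$n, tx(cc$n)), ca = rbind(s$ca, tx(cc$ca)),
        c = rbind(s$c, tx(cc$c)), cb = rbind(s$cb, tx(cc$cb)),
        validate = FALSE)
    }
    s <- assign_domains(s, layout)
    dmin <- min_interdomain_ca(s)
    if (dmin >= 3.5) return(list(structure = s, layout = layout))
  }
  domasm_stop("generation", "no clash-free target in 100 attempts")
}

min_interdomain_ca <- function(s) {
  dm <- as.matrix(stats::dist(s$ca))
  inter <- outer(s$res$domain, s$res$domain, "!=")
  min(dm[inter])
}

#' Perturbed start from a target
#'
#' Applies uniform random torsion offsets in `[-magnitude, +magnitude]`
#' (degrees) to the movable linker windows (and, for multi-chain
#' targets, rotation-vector offsets of the same magnitude plus
#' translations up to `magnitude / 10` Angstrom to the chain slots).
#' The drawn gene vector is recorded in the `"perturbation"` attribute;
#' applying its negation restores the single-chain target exactly.
#'
#' @param target Target `"backbone"` structure.
#' @param layout A `"domain_layout"`.
#' @param magnitude_deg Maximum torsion offset in degrees (>= 0).
#' @param seed Integer seed.
#' @param width Movable window width (residues).
#' @return The perturbed `"backbone"` with attribute `"perturbation"`.
#' @export
perturbed_start <- function(target, layout, magnitude_deg, seed = 0,
                            width = 8) {
  if (magnitude_deg < 0) stop_validation("magnitude must be >= 0")
  spec <- linker_residues(layout, width)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mag <- magnitude_deg * pi / 180
  nt <- nrow(spec$torsions)
  v <- numeric(spec$n_genes)
  if (nt > 0L) v[seq_len(nt)] <- stats::runif(nt, -mag, mag)
  if (length(spec$slots) > 0L) for (sidx in seq_along(spec$slots)) {
    v[nt + 6L * (sidx - 1L) + 1:6] <- c(stats::runif(3, -mag, mag),
                                        stats::runif(3, -magnitude_deg / 10,
                                                     magnitude_deg / 10))
  }
  out <- apply_torsions(assign_domains(target, layout), spec, v)
  attr(out, "perturbation") <- v
  out
}

#' Write the standard synthetic fixture suite
#'
#' Writes three seed-fixed targets -- a two-domain helix pair, a
#' three-domain mixed-topology chain, and a two-chain pseudo-complex --
#' each as a target PDB, per-domain PDBs, a layout JSON, and oracle
#' interaction files in both dialects (exact mode targets and blurred
#' binned distributions).  Regeneration is bit-identical for the TSV and
#' JSON artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed for the suite.
#' @param blur_sd Blur widths for the dist-dialect files (see
#'   [discretize_targets()]); default 15 degrees on angles, 1 Angstrom
#'   on distances.
#' @return Invisibly, a data.frame cataloguing the written files.
#' @export
fixture_suite <- function(out_dir, seed = 0,
                          blur_sd = c(alpha = 15, beta = 15, gamma = 15,
                                      r = 1, theta = 15, phi = 15) *
                            c(rep(pi / 180, 3), 1, pi / 180, pi / 180)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    two_domain = fixture_spec(c("helix", "helix"), c(30, 30), linkers = 8,
                              seed = seed + 1L),
    three_domain = fixture_spec(c("helix", "strand", "mixed"),
                                c(24, 20, 24), linkers = c(8, 8),
                                seed = seed + 2L),
    two_chain = fixture_spec(c("helix", "helix"), c(30, 30),
                             chains = c("A", "B"), seed = seed + 3L))
  cat_rows <- list()
  for (nm in names(specs)) {
    tg <- make_multidomain_target(specs[[nm]])
    p <- function(suffix) file.path(out_dir, paste0(nm, "_", suffix))
    write_pdb(tg$structure, p("target.pdb"))
    write_domain_layout(tg$layout, p("layout.json"))
    for (d in tg$layout$domains)
      write_pdb(extract_domain(tg$structure, tg$layout, d$id),
                p(sprintf("domain_%s.pdb", d$id)))
    m <- oracle_interactions(tg$structure, tg$layout)
    write_interactions(m, p("interactions_mode.tsv"))
    write_interactions(discretize_targets(m, blur_sd = blur_sd),
                       p("interactions_dist.tsv"))
    cat_rows[[nm]] <- data.frame(
      fixture = nm, residues = n_residues(tg$structure),
      domains = length(tg$layout$domains), pairs = n_pairs(m),
      stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, cat_rows))
}
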