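# Torsion-space kinematics: decision variables are phi/psi offsets of the
# movable linker residues around each domain boundary (plus one rigid
# 6-DoF slot per non-anchor chain); domains move as rigid bodies.

# ideal backbone internal coordinates (Angstrom / degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7
)

# rotate rows `idx` of coordinate matrix m about point p (rotation given
# as its transpose tR for right-multiplication), then optionally shift
rotate_rows <- function(m, idx, tR, p, shift = NULL) {
  if (is.null(m) || length(idx) == 0L) return(m)
  x <- m[idx, , drop = FALSE]
  x[, 1] <- x[, 1] - p[1]; x[, 2] <- x[, 2] - p[2]; x[, 3] <- x[, 3] - p[3]
  x <- x %*% tR
  if (is.null(shift)) shift <- c(0, 0, 0)
  x[, 1] <- x[, 1] + p[1] + shift[1]
  x[, 2] <- x[, 2] + p[2] + shift[2]
  x[, 3] <- x[, 3] + p[3] + shift[3]
  m[idx, ] <- x
  m
}

# rotation matrix about unit axis u by angle (Rodrigues)
rotation_about_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Dihedral angle of four points
#'
#' Signed torsion angle a-b-c-d in radians, in `[-pi, pi)`.
#'
#' @param a,b,c,d Length-3 coordinate vectors (Angstrom).
#' @return Angle in radians.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# place atom D given A, B, C with bond |C-D|, angle B-C-D and dihedral
# A-B-C-D (radians); the standard internal-to-Cartesian step.
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ---- linker specification ---------------------------------------------------

#' Movable linker residues of a layout
#'
#' Selects, for every intra-chain boundary between consecutive domains,
#' a window of `width` movable residues split evenly across the junction
#' (`width/2` on each side).  Each window residue contributes a phi and a
#' psi decision variable; every non-anchor chain additionally contributes
#' one rigid 6-DoF slot (3 rotation angles, 3 translations).
#'
#' @param layout A `"domain_layout"`.
#' @param width Even window width in residues (default 8).
#' @return An object of class `"linker_spec"` with elements `torsions`
#'   (`data.frame(chain, resno, type)` in kinematic order), `windows`,
#'   `slots` (non-anchor chain ids) and `n_genes`.
#' @export
#' @examples
#' lay <- domain_layout("A", list(
#'   list(id = "D1", chain = "A", ranges = list(c(1, 50))),
#'   list(id = "D2", chain = "A", ranges = list(c(51, 100)))))
#' linker_residues(lay, width = 8)$windows  # residues 47-54
linker_residues <- function(layout, width = 8) {
  if (width < 2 || width %% 2 != 0)
    stop_validation("linker width must be an even number >= 2")
  w2 <- width %/% 2
  bd <- layout_boundaries(layout)
  lr <- layout_residues(layout)
  tor <- list(); win <- list()
  used <- character(0)
  if (nrow(bd) > 0L) for (b in seq_len(nrow(bd))) {
    ch <- bd$chain[b]
    rn <- lr$resno[lr$chain == ch]
    p <- match(bd$resno_before[b], rn)
    if (p - w2 + 1L < 1L || p + w2 > length(rn))
      stop_layout("linker window extends past chain %s bounds", ch)
    pos <- seq.int(p - w2 + 1L, p + w2)
    key <- paste(ch, rn[pos])
    if (any(key %in% used))
      stop_layout("linker windows of adjacent boundaries overlap on chain %s", ch)
    used <- c(used, key)
    win[[b]] <- data.frame(boundary = b, chain = ch,
                           from = rn[pos[1]], to = rn[pos[width]],
                           stringsAsFactors = FALSE)
    tor[[b]] <- data.frame(chain = ch, resno = rep(rn[pos], each = 2L),
                           type = rep(c("phi", "psi"), width),
                           stringsAsFactors = FALSE)
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else
    data.frame(chain = character(), resno = integer(), type = character(),
               stringsAsFactors = FALSE)
  # kinematic order: chain order, then position, phi before psi
  torsions <- torsions[order(match(torsions$chain, layout$chains),
                             torsions$resno, match(torsions$type,
                                                   c("phi", "psi"))), ,
                       drop = FALSE]
  rownames(torsions) <- NULL
  slots <- setdiff(layout$chains, layout$chains[1])
  structure(list(torsions = torsions,
                 windows = if (length(win)) do.call(rbind, win) else
                   data.frame(boundary = integer(), chain = character(),
                              from = integer(), to = integer()),
                 slots = slots, width = width,
                 n_genes = nrow(torsions) + 6L * length(slots)),
            class = "linker_spec")
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("<linker spec> %d movable torsion(s), %d chain slot(s), %d gene(s)\n",
              nrow(x$torsions), length(x$slots), x$n_genes))
  invisible(x)
}

# ---- torsion application ----------------------------------------------------

#' Apply a torsion offset vector to a structure
#'
#' Offsets are processed N-to-C: a phi offset rotates all downstream
#' atoms (the residue's own C/O/CB and every later residue of the chain)
#' about the residue's N-CA axis; a psi offset rotates the residue's O
#' and every later residue about CA-C.  Bond lengths, bond angles and
#' all geometry outside the movable windows are exactly preserved; chain
#' slots then apply a rigid transform (a rotation-vector rotation about
#' the chain's current CA centroid, plus a translation) to each
#' non-anchor chain.  The zero vector is an exact identity; torsion
#' offsets compose additively, and negating a slot's genes exactly
#' undoes its move.
#'
#' @param base A `"backbone"` structure.
#' @param spec A `"linker_spec"` for the same layout.
#' @param v Numeric gene vector of length `spec$n_genes`: torsion offsets
#'   in radians (wrapped to `[-pi, pi)`), then per chain slot a rotation
#'   vector (axis times angle, radians) and a translation
#'   `(tx, ty, tz)` in Angstrom.
#' @return The transformed `"backbone"` structure.
#' @export
apply_torsions <- function(base, spec, v) {
  v <- as.numeric(v)
  if (length(v) != spec$n_genes)
    stop_validation("gene vector has length %d, expected %d",
                    length(v), spec$n_genes)
  if (any(!is.finite(v))) stop_validation("gene vector must be finite")
  nt <- nrow(spec$torsions)
  if (nt > 0L) v[seq_len(nt)] <- wrap_angle(v[seq_len(nt)])
  blocks <- c("n", "ca", "c", "o", "cb")
  xyz <- lapply(blocks, function(b) base[[b]])
  names(xyz) <- blocks
  key <- paste(base$res$chain, base$res$resno)
  if (nt > 0L) for (t in seq_len(nt)) {
    ang <- v[t]
    if (ang == 0) next
    ch <- spec$torsions$chain[t]
    rt <- match(paste(ch, spec$torsions$resno[t]), key)
    if (is.na(rt)) stop_validation("structure lacks torsion residue %s %d",
                                   ch, spec$torsions$resno[t])
    chain_rows <- which(base$res$chain == ch)
    down <- chain_rows[chain_rows > rt]
    if (spec$torsions$type[t] == "phi") {
      p0 <- xyz$n[rt, ]; p1 <- xyz$ca[rt, ]
      own <- list(c = rt, o = rt, cb = rt)
    } else {
      p0 <- xyz$ca[rt, ]; p1 <- xyz$c[rt, ]
      own <- list(o = rt)
    }
    # axis points from the bond's distal atom back toward the backbone N
    # terminus so a positive offset increases the conventional dihedral
    tR <- t(rotation_about_axis(p0 - p1, ang))
    for (b in blocks) xyz[[b]] <- rotate_rows(xyz[[b]], down, tR, p1)
    for (b in names(own)) xyz[[b]] <- rotate_rows(xyz[[b]], own[[b]], tR, p1)
  }
  if (length(spec$slots) > 0L) for (sidx in seq_along(spec$slots)) {
    g <- v[nt + 6L * (sidx - 1L) + 1:6]
    if (all(g == 0)) next
    ch <- spec$slots[sidx]
    rows <- which(base$res$chain == ch)
    if (length(rows) == 0L) stop_validation("structure lacks chain %s", ch)
    ang <- sqrt(sum(g[1:3]^2))
    tR <- if (ang < 1e-12) diag(3) else t(rotation_about_axis(g[1:3], ang))
    ctr <- colMeans(xyz$ca[rows, , drop = FALSE])
    for (b in blocks) {
      if (is.null(xyz[[b]])) next
      xyz[[b]] <- rotate_rows(xyz[[b]], rows, tR, ctr, shift = g[4:6])
    }
  }
  backbone_structure(chain = base$res$chain, resno = base$res$resno,
                     aa = base$res$aa, n = xyz$n, ca = xyz$ca, c = xyz$c,
                     o = xyz$o, cb = xyz$cb, domain = base$res$domain,
                     validate = FALSE)
}

# ---- full-length model construction ----------------------------------------

# deterministic concatenation of rigid domains: each intra-chain junction
# rebuilt with ideal peptide geometry (C-N 1.329 A, omega 180 deg) at
# baseline torsions psi = 150, phi = -150 deg; non-anchor chains placed at
# a neutral offset along +x from the anchor chain.
assemble_base <- function(domains, layout) {
  if (!is.null(names(domains)) && all(nzchar(names(domains)))) {
    ids <- vapply(layout$domains, `[[`, "", "id")
    if (!all(ids %in% names(domains)))
      stop_layout("missing domain structure(s): %s",
                  paste(setdiff(ids, names(domains)), collapse = ", "))
    domains <- domains[ids]
  } else if (length(domains) != length(layout$domains)) {
    stop_layout("need one structure per layout domain")
  }
  d2r <- pi / 180
  g <- IDEAL_GEOM
  chain_built <- list()
  for (ch in layout$chains) {
    idx <- which(vapply(layout$domains, `[[`, "", "chain") == ch)
    if (length(idx) == 0L) next
    starts <- vapply(idx, function(k) min(layout$domains[[k]]$ranges[, 1]), 0)
    idx <- idx[order(starts)]
    parts <- lapply(idx, function(k) {
      d <- domains[[k]]
      want <- sort(unlist(apply(layout$domains[[k]]$ranges, 1L,
                                function(r) seq.int(r[1], r[2]),
                                simplify = FALSE)))
      rows <- match(want, d$res$resno[d$res$chain == ch])
      drow <- which(d$res$chain == ch)[rows]
      if (any(is.na(drow)))
        stop_layout("domain %s structure does not cover its ranges",
                    layout$domains[[k]]$id)
      sub <- function(m) if (is.null(m)) NULL else m[drow, , drop = FALSE]
      backbone_structure(chain = rep(ch, length(drow)), resno = want,
                         aa = d$res$aa[drow], n = sub(d$n), ca = sub(d$ca),
                         c = sub(d$c), o = sub(d$o), cb = sub(d$cb),
                         domain = rep(layout$domains[[k]]$id, length(drow)),
                         validate = FALSE)
    })
    acc <- parts[[1]]
    if (length(parts) > 1L) for (k in 2:length(parts)) {
      nxt <- parts[[k]]
      last <- nrow(acc$res)
      # NeRF targets for the next domain's first residue
      nN <- nerf_place(acc$n[last, ], acc$ca[last, ], acc$c[last, ],
                       g$b_c_n, g$a_ca_c_n * d2r, 150 * d2r)
      nCA <- nerf_place(acc$ca[last, ], acc$c[last, ], nN,
                        g$b_n_ca, g$a_c_n_ca * d2r, pi)
      nC <- nerf_place(acc$c[last, ], nN, nCA,
                       g$b_ca_c, g$a_n_ca_c * d2r, -150 * d2r)
      fit <- kabsch(rbind(nxt$n[1, ], nxt$ca[1, ], nxt$c[1, ]),
                    rbind(nN, nCA, nC))
      tx <- function(m) if (is.null(m)) NULL else
        sweep(m %*% t(fit$rotation), 2L, fit$translation, "+")
      acc <- backbone_structure(
        chain = c(acc$res$chain, nxt$res$chain),
        resno = c(acc$res$resno, nxt$res$resno),
        aa = c(acc$res$aa, nxt$res$aa),
        n = rbind(acc$n, tx(nxt$n)), ca = rbind(acc$ca, tx(nxt$ca)),
        c = rbind(acc$c, tx(nxt$c)),
        o = if (!is.null(acc$o) && !is.null(nxt$o)) rbind(acc$o, tx(nxt$o)),
        cb = if (!is.null(acc$cb) && !is.null(nxt$cb)) rbind(acc$cb, tx(nxt$cb)),
        domain = c(acc$res$domain, nxt$res$domain), validate = FALSE)
    }
    chain_built[[ch]] <- acc
  }
  anchor <- chain_built[[layout$chains[1]]]
  a_ctr <- colMeans(anchor$ca)
  a_rad <- sqrt(max(rowSums(sweep(anchor$ca, 2L, a_ctr)^2)))
  out <- anchor
  for (ch in setdiff(names(chain_built), layout$chains[1])) {
    cc <- chain_built[[ch]]
    c_ctr <- colMeans(cc$ca)
    c_rad <- sqrt(max(rowSums(sweep(cc$ca, 2L, c_ctr)^2)))
    shift <- a_ctr + c(a_rad + c_rad + 20, 0, 0) - c_ctr
    tx <- function(m) if (is.null(m)) NULL else sweep(m, 2L, shift, "+")
    out <- backbone_structure(
      chain = c(out$res$chain, cc$res$chain),
      resno = c(out$res$resno, cc$res$resno),
      aa = c(out$res$aa, cc$res$aa),
      n = rbind(out$n, tx(cc$n)), ca = rbind(out$ca, tx(cc$ca)),
      c = rbind(out$c, tx(cc$c)),
      o = if (!is.null(out$o) && !is.null(cc$o)) rbind(out$o, tx(cc$o)),
      cb = if (!is.null(out$cb) && !is.null(cc$cb)) rbind(out$cb, tx(cc$cb)),
      domain = c(out$res$domain, cc$res$domain), validate = FALSE)
  }
  out
}

# random gene vector: torsion offsets uniform on [-pi, pi); chain slots
# get a uniform random orientation and a translation landing the chain
# centroid uniformly inside the anchor's bounding sphere inflated by 30 A.
random_gene_vector <- function(base, spec, layout) {
  nt <- nrow(spec$torsions)
  v <- numeric(spec$n_genes)
  if (nt > 0L) v[seq_len(nt)] <- stats::runif(nt, -pi, pi)
  if (length(spec$slots) > 0L) {
    anchor_rows <- which(base$res$chain == layout$chains[1])
    a_ctr <- colMeans(base$ca[anchor_rows, , drop = FALSE])
    a_rad <- sqrt(max(rowSums(sweep(base$ca[anchor_rows, , drop = FALSE],
                                    2L, a_ctr)^2))) + 30
    for (sidx in seq_along(spec$slots)) {
      # uniform random orientation as a rotation vector (axis * angle)
      q <- stats::rnorm(4)
      q <- q / sqrt(sum(q^2))
      if (q[1] < 0) q <- -q
      vn <- sqrt(sum(q[2:4]^2))
      rotvec <- if (vn < 1e-12) c(0, 0, 0) else
        (2 * atan2(vn, q[1])) * q[2:4] / vn
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) break
      }
      target <- a_ctr + a_rad * p
      rows <- which(base$res$chain == spec$slots[sidx])
      ctr <- colMeans(base$ca[rows, , drop = FALSE])
      v[nt + 6L * (sidx - 1L) + 1:6] <- c(rotvec, target - ctr)
    }
  }
  v
}

#' Random initial full-length model
#'
#' Concatenates the rigid domains N-to-C along each chain with ideal
#' peptide junction geometry (C-N 1.329 Angstrom, omega = 180 degrees),
#' then draws the movable linker phi/psi uniformly from `[-pi, pi)`;
#' chains beyond the anchor are placed with a random rigid transform
#' (uniform orientation, centroid inside the anchor's bounding sphere
#' inflated by 30 Angstrom).  Deterministic given `rng_seed`.
#'
#' @param domains List of single-domain `"backbone"` structures, named by
#'   domain id or in layout order.
#' @param layout A `"domain_layout"`.
#' @param rng_seed Integer seed.
#' @param linker_width Movable window width (residues, even).
#' @return A full-length `"backbone"` structure.
#' @export
initial_full_length <- function(domains, layout, rng_seed = 0,
                                linker_width = 8) {
  base <- assemble_base(domains, layout)
  spec <- linker_residues(layout, linker_width)
  if (spec$n_genes == 0L) return(base)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(rng_seed) %% .Machine$integer.max)
  apply_torsions(base, spec, random_gene_vector(base, spec, layout))
}
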