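# Interaction maps: per inter-domain residue pair, either a 6D point
# target ("mode" dialect) or six binned categorical distributions ("dist"
# dialect), plus a structure-derived oracle and TSV file I/O.

ELEMENTS <- c("alpha", "beta", "gamma", "r", "theta", "phi")

#' Binning scheme for 6D interaction distributions
#'
#' Default bins: `r` on \[2, 40\] Angstrom at 1 Angstrom width plus one
#' overflow "no interaction" bin; `alpha`, `gamma`, `phi` on
#' \[-180, 180) degrees at 15 degrees; `beta` on \[-90, 90\] and `theta`
#' on \[0, 180\] at 15 degrees.  Angles are held in radians internally;
#' the decode value of a finite bin is its midpoint.
#'
#' @param r_max Upper edge of the last finite distance bin (Angstrom).
#' @param r_min Lower edge of the first distance bin (Angstrom).
#' @param r_width Distance bin width (Angstrom).
#' @param angle_width Angular bin width (degrees).
#' @return An object of class `"bin_scheme"`: per element, a list with
#'   `edges` (radians / Angstrom), `periodic` and `overflow` flags.
#' @export
bin_scheme <- function(r_max = 40, r_min = 2, r_width = 1, angle_width = 15) {
  d2r <- pi / 180
  if (r_max <= r_min || r_width <= 0 || angle_width <= 0 ||
      (r_max - r_min) %% r_width > 1e-9)
    stop_validation("inconsistent bin scheme parameters")
  el <- function(lo, hi, w, periodic = FALSE, overflow = FALSE)
    list(edges = seq(lo, hi, by = w), periodic = periodic, overflow = overflow)
  structure(list(
    alpha = el(-pi, pi, angle_width * d2r, periodic = TRUE),
    beta  = el(-pi / 2, pi / 2, angle_width * d2r),
    gamma = el(-pi, pi, angle_width * d2r, periodic = TRUE),
    r     = el(r_min, r_max, r_width, overflow = TRUE),
    theta = el(0, pi, angle_width * d2r),
    phi   = el(-pi, pi, angle_width * d2r, periodic = TRUE)
  ), class = "bin_scheme")
}

# number of categories (finite bins + optional overflow)
scheme_ncat <- function(sch, element) {
  e <- sch[[element]]
  length(e$edges) - 1L + as.integer(isTRUE(e$overflow))
}

scheme_midpoints <- function(sch, element) {
  e <- sch[[element]]
  (e$edges[-1] + e$edges[-length(e$edges)]) / 2
}

new_interaction_map <- function(pairs, dialect, scheme, index,
                                mode = NULL, dist = NULL,
                                provenance = "external", r_max = NULL) {
  structure(list(pairs = pairs, dialect = dialect, mode = mode, dist = dist,
                 scheme = scheme, index = index, provenance = provenance,
                 r_max = r_max),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction map> %d ordered pair(s), dialect '%s', %s\n",
              nrow(x$pairs), x$dialect, x$provenance))
  invisible(x)
}

#' Number of ordered pairs in an interaction map
#' @param m An `"interaction_map"`.
#' @return Integer pair count.
#' @export
n_pairs <- function(m) nrow(m$pairs)

# ---- oracle ----------------------------------------------------------------

#' Structure-derived ("true") inter-domain interaction targets
#'
#' The offline stand-in for a learned interaction predictor: for every
#' ordered inter-domain residue pair (i, j) with CA-CA distance at most
#' `r_max`, emits the exact 6D transform between the two residues' local
#' frames (see [relative_transform()]).  Both (i, j) and (j, i) are
#' emitted.  Scoring a structure against its own oracle map gives an ACD
#' energy of zero.
#'
#' @param ref Reference `"backbone"` structure.
#' @param layout A `"domain_layout"` covering `ref`.
#' @param r_max Distance cutoff in Angstrom (> 0).
#' @param scheme `"bin_scheme"` recorded for downstream discretization.
#' @return A mode-dialect `"interaction_map"` with provenance `"oracle"`.
#' @export
oracle_interactions <- function(ref, layout, r_max = 40,
                                scheme = bin_scheme(r_max = r_max)) {
  if (r_max <= 0) stop_degenerate("r_max must be positive")
  s <- assign_domains(ref, layout)
  nr <- nrow(s$res)
  dom <- s$res$domain
  ca <- s$ca
  dmat <- as.matrix(stats::dist(ca))
  inter <- outer(dom, dom, "!=")
  sel <- which(inter & dmat <= r_max, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop_degenerate("no inter-domain residue pair within r_max = %g A", r_max)
  i <- sel[, 1]; j <- sel[, 2]
  fr <- frames_batch(s$n, s$ca, s$c)
  mode <- rel_transform_batch(fr, i, j)
  ord <- order(i, j)
  pairs <- data.frame(i = i[ord] - 1L, j = j[ord] - 1L)  # 0-based global idx
  new_interaction_map(pairs, "mode", scheme,
                      index = data.frame(gidx = seq_len(nr) - 1L,
                                         chain = s$res$chain,
                                         resno = s$res$resno,
                                         domain = dom,
                                         stringsAsFactors = FALSE),
                      mode = mode[ord, , drop = FALSE],
                      provenance = "oracle", r_max = r_max)
}

# batched relative 6D transforms for row indices i, j into frames fr
rel_transform_batch <- function(fr, i, j) {
  R9i <- fr$R9[i, , drop = FALSE]
  R9j <- fr$R9[j, , drop = FALSE]
  c1 <- rot_t_apply(R9i, R9j[, 1:3, drop = FALSE])
  c2 <- rot_t_apply(R9i, R9j[, 4:6, drop = FALSE])
  c3 <- rot_t_apply(R9i, R9j[, 7:9, drop = FALSE])
  sb <- pmax(-1, pmin(1, -c1[, 3]))
  beta <- asin(sb)
  alpha <- atan2(c2[, 3], c3[, 3])
  gamma <- atan2(c1[, 2], c1[, 1])
  lock <- abs(cos(beta)) < 1e-8
  if (any(lock)) {
    alpha[lock] <- 0
    gamma[lock] <- atan2(-c2[lock, 1], c2[lock, 2])
  }
  tr <- rot_t_apply(R9i, fr$t[j, , drop = FALSE] - fr$t[i, , drop = FALSE])
  r <- sqrt(rowSums(tr^2))
  theta <- acos(pmax(-1, pmin(1, tr[, 3] / pmax(r, 1e-300))))
  phi <- atan2(tr[, 2], tr[, 1])
  m <- cbind(alpha = wrap_angle(alpha), beta = beta,
             gamma = wrap_angle(gamma), r = r,
             theta = theta, phi = wrap_angle(phi))
  zero <- r < 1e-12
  if (any(zero)) { m[zero, "theta"] <- 0; m[zero, "phi"] <- 0 }
  m
}

# ---- discretize / decode ----------------------------------------------------

#' Discretize point targets into binned distributions
#'
#' Emulates a predictor's output: each 6D element becomes a categorical
#' distribution over the bin scheme -- a delta on the containing bin when
#' `blur_sd` is zero, otherwise a discretized Gaussian (wrapped for
#' periodic angles) renormalized over the bins.  Distance mass beyond
#' the last finite bin goes to the overflow ("no interaction") bin.
#'
#' @param m A mode-dialect `"interaction_map"`.
#' @param scheme A `"bin_scheme"` (defaults to the map's own).
#' @param blur_sd Per-element Gaussian widths, a named numeric vector over
#'   `alpha, beta, gamma, r, theta, phi` (radians / Angstrom), a single
#'   number recycled, or 0 for deltas.
#' @return A dist-dialect `"interaction_map"`.
#' @export
discretize_targets <- function(m, scheme = m$scheme, blur_sd = 0) {
  if (m$dialect != "mode") stop_validation("need a mode-dialect map")
  if (length(blur_sd) == 1L) blur_sd <- stats::setNames(rep(blur_sd, 6), ELEMENTS)
  blur_sd <- blur_sd[ELEMENTS]
  if (any(is.na(blur_sd)) || any(blur_sd < 0))
    stop_validation("blur_sd must be named non-negative widths")
  dist <- stats::setNames(vector("list", 6L), ELEMENTS)
  for (el in ELEMENTS) {
    e <- scheme[[el]]
    v <- m$mode[, el]
    ncat <- scheme_ncat(scheme, el)
    nfin <- length(e$edges) - 1L
    lo <- e$edges[1]; hi <- e$edges[length(e$edges)]
    if (!e$overflow && (any(v < lo - 1e-9) || any(v > hi + 1e-9)))
      stop_validation("%s value outside bin scheme domain", el)
    if (e$overflow && any(v < lo - 1e-9))
      stop_validation("%s value below first bin edge", el)
    p <- matrix(0, nrow(m$mode), ncat)
    if (blur_sd[[el]] == 0) {
      b <- findInterval(pmin(pmax(v, lo), hi), e$edges,
                        rightmost.closed = TRUE)
      if (e$overflow) b[v > hi] <- nfin + 1L
      p[cbind(seq_along(b), b)] <- 1
    } else {
      sd <- blur_sd[[el]]
      cdf_at <- function(x) {
        if (e$periodic) {
          out <- 0
          for (k in -2:2) out <- out + stats::pnorm(x, v + 2 * pi * k, sd)
          out
        } else stats::pnorm(x, v, sd)
      }
      cum <- vapply(e$edges, cdf_at, numeric(nrow(m$mode)))
      if (nrow(m$mode) == 1L) cum <- matrix(cum, nrow = 1L)
      p[, seq_len(nfin)] <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
      if (e$overflow) {
        p[, nfin + 1L] <- 1 - cum[, ncol(cum)]   # mass beyond last edge
        p[, 1L] <- p[, 1L] + cum[, 1L]           # sub-range mass lumped low
      } else if (!e$periodic) {
        # bounded non-periodic element: tails lumped into terminal bins
        p[, 1L] <- p[, 1L] + cum[, 1L]
        p[, nfin] <- p[, nfin] + 1 - cum[, ncol(cum)]
      }
      # periodic elements: the image-summed bin masses already total 1
    }
    p <- p / rowSums(p)
    dist[[el]] <- p
  }
  new_interaction_map(m$pairs, "dist", scheme, m$index, dist = dist,
                      provenance = m$provenance, r_max = m$r_max)
}

#' Decode binned distributions to point targets
#'
#' Per element, takes the bin with the maximum probability (ties broken
#' toward the lowest bin index) and returns its midpoint.  Pairs whose
#' distance arg-max falls in the overflow bin are treated as
#' non-interacting and dropped from the map.
#'
#' @param m A dist-dialect `"interaction_map"`.
#' @param scheme A `"bin_scheme"` (defaults to the map's own).
#' @return A mode-dialect `"interaction_map"`.
#' @export
decode_distributions <- function(m, scheme = m$scheme) {
  if (m$dialect != "dist") stop_validation("need a dist-dialect map")
  np <- nrow(m$pairs)
  vals <- matrix(NA_real_, np, 6L, dimnames = list(NULL, ELEMENTS))
  drop <- rep(FALSE, np)
  for (el in ELEMENTS) {
    p <- m$dist[[el]]
    if (any(p < -1e-9)) stop_validation("negative probability mass in %s", el)
    if (any(abs(rowSums(p) - 1) > 1e-6))
      stop_validation("%s distributions do not sum to 1", el)
    b <- apply(p, 1L, which.max)  # first max: ties -> lowest bin
    mid <- scheme_midpoints(scheme, el)
    if (scheme[[el]]$overflow) {
      over <- b > length(mid)
      drop <- drop | over
      b[over] <- 1L
    }
    vals[, el] <- mid[b]
  }
  keep <- !drop
  if (!any(keep)) stop_degenerate("all pairs decode to the no-interaction bin")
  new_interaction_map(m$pairs[keep, , drop = FALSE], "mode", scheme, m$index,
                      mode = vals[keep, , drop = FALSE],
                      provenance = m$provenance, r_max = m$r_max)
}

# coerce any map to mode dialect
as_mode_map <- function(m) if (m$dialect == "dist") decode_distributions(m) else m

# ---- file I/O ---------------------------------------------------------------

#' Write / read interaction maps as TSV
#'
#' UTF-8 TSV with `#`-prefixed header lines recording format version,
#' dialect, bin scheme and the global-residue-index mapping.  Mode rows
#' are `i, j, alpha, beta, gamma, r, theta, phi` (degrees / Angstrom);
#' dist rows are `i, j, element, bin_index, probability` with
#' zero-probability bins omitted (bin indices 0-based, the last distance
#' index being the overflow bin).  `read_interactions()` auto-detects the
#' dialect and round-trips values to 1e-6.
#'
#' @param m An `"interaction_map"`.
#' @param path File path.
#' @return `read_interactions()`: an `"interaction_map"`;
#'   `write_interactions()`: invisibly, `path`.
#' @export
write_interactions <- function(m, path) {
  r2d <- 180 / pi
  sch <- m$scheme
  fmt_el <- function(el) {
    e <- sch[[el]]
    u <- if (el == "r") 1 else r2d
    sprintf("%s %g %g %g", el, e$edges[1] * u, e$edges[length(e$edges)] * u,
            (e$edges[2] - e$edges[1]) * u)
  }
  hdr <- c("# domasm-interactions 1",
           sprintf("# dialect: %s", m$dialect),
           sprintf("# provenance: %s", m$provenance),
           sprintf("# r_max: %g", if (is.null(m$r_max)) NA else m$r_max),
           sprintf("# scheme: %s", paste(vapply(ELEMENTS, fmt_el, ""),
                                         collapse = "; ")),
           sprintf("# residue %d %s %d %s", m$index$gidx, m$index$chain,
                   m$index$resno, m$index$domain))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_io("cannot write %s", path))
  on.exit(close(con))
  writeLines(hdr, con)
  if (m$dialect == "mode") {
    writeLines("i\tj\talpha\tbeta\tgamma\tr\ttheta\tphi", con)
    if (nrow(m$pairs) > 0L) {
      v <- m$mode
      writeLines(sprintf("%d\t%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f",
                         m$pairs$i, m$pairs$j,
                         v[, "alpha"] * r2d, v[, "beta"] * r2d,
                         v[, "gamma"] * r2d, v[, "r"],
                         v[, "theta"] * r2d, v[, "phi"] * r2d), con)
    }
  } else {
    writeLines("i\tj\telement\tbin_index\tprobability", con)
    for (el in ELEMENTS) {
      p <- m$dist[[el]]
      nz <- which(p > 1e-9, arr.ind = TRUE)
      if (nrow(nz) == 0L) next
      ord <- order(nz[, 1], nz[, 2])
      nz <- nz[ord, , drop = FALSE]
      writeLines(sprintf("%d\t%d\t%s\t%d\t%.6f",
                         m$pairs$i[nz[, 1]], m$pairs$j[nz[, 1]], el,
                         nz[, 2] - 1L, p[nz]), con)
    }
  }
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_io("cannot read interaction file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1], "# domasm-interactions"))
    stop_format("%s: missing interaction file signature (line 1)", path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_hdr <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) == 0L) stop_format("%s: missing '# %s:' header", path, key)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  dialect <- get_hdr("dialect")
  if (!dialect %in% c("mode", "dist"))
    stop_format("%s: unknown dialect '%s'", path, dialect)
  provenance <- get_hdr("provenance")
  r_max <- suppressWarnings(as.numeric(get_hdr("r_max")))
  sch_txt <- strsplit(get_hdr("scheme"), ";")[[1]]
  sch_parts <- lapply(sch_txt, function(s) strsplit(trimws(s), " +")[[1]])
  names(sch_parts) <- vapply(sch_parts, `[[`, "", 1L)
  num <- function(el, k) as.numeric(sch_parts[[el]][k + 1L])
  scheme <- tryCatch(
    bin_scheme(r_max = num("r", 2), r_min = num("r", 1), r_width = num("r", 3),
               angle_width = num("alpha", 3)),
    error = function(e) stop_format("%s: unparseable scheme header", path))
  res_ln <- grep("^# residue ", hdr, value = TRUE)
  idx <- if (length(res_ln) > 0L) {
    f <- do.call(rbind, strsplit(sub("^# residue ", "", res_ln), " +"))
    data.frame(gidx = as.integer(f[, 1]), chain = f[, 2],
               resno = as.integer(f[, 3]), domain = f[, 4],
               stringsAsFactors = FALSE)
  } else data.frame(gidx = integer(), chain = character(), resno = integer(),
                    domain = character(), stringsAsFactors = FALSE)
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop_format("%s: missing column header row", path)
  body <- body[-1L]  # column names
  if (length(body) == 0L) {
    return(new_interaction_map(data.frame(i = integer(), j = integer()),
                               "mode", scheme, idx,
                               mode = matrix(numeric(), 0, 6,
                                             dimnames = list(NULL, ELEMENTS)),
                               provenance = provenance, r_max = r_max))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- if (dialect == "mode") 8L else 5L
  badln <- which(lengths(fields) != nfield)
  if (length(badln) > 0L)
    stop_format("%s: malformed row at line %d", path,
                which(!is_hdr)[badln[1] + 1L])
  f <- do.call(rbind, fields)
  d2r <- pi / 180
  if (dialect == "mode") {
    v <- apply(f[, 3:8, drop = FALSE], 2L, as.numeric)
    if (length(body) == 1L) v <- matrix(v, nrow = 1L)
    if (any(is.na(v))) stop_format("%s: non-numeric value in body", path)
    mode <- cbind(alpha = v[, 1] * d2r, beta = v[, 2] * d2r,
                  gamma = v[, 3] * d2r, r = v[, 4],
                  theta = v[, 5] * d2r, phi = v[, 6] * d2r)
    pairs <- data.frame(i = as.integer(f[, 1]), j = as.integer(f[, 2]))
    new_interaction_map(pairs, "mode", scheme, idx, mode = mode,
                        provenance = provenance, r_max = r_max)
  } else {
    i <- as.integer(f[, 1]); j <- as.integer(f[, 2])
    el <- f[, 3]; bin <- as.integer(f[, 4]); prob <- as.numeric(f[, 5])
    if (any(is.na(i)) || any(is.na(bin)) || any(is.na(prob)) ||
        any(!el %in% ELEMENTS))
      stop_format("%s: malformed dist row", path)
    key <- paste(i, j)
    ukey <- unique(key)
    pr <- match(key, ukey)
    pairs_i <- i[!duplicated(pr)]; pairs_j <- j[!duplicated(pr)]
    dist <- stats::setNames(vector("list", 6L), ELEMENTS)
    for (e in ELEMENTS) {
      p <- matrix(0, length(ukey), scheme_ncat(scheme, e))
      sel <- el == e
      if (any(bin[sel] < 0L | bin[sel] >= ncol(p)))
        stop_format("%s: bin index out of range for %s", path, e)
      p[cbind(pr[sel], bin[sel] + 1L)] <- prob[sel]
      rs <- rowSums(p)
      if (any(abs(rs - 1) > 1e-3))
        stop_format("%s: %s distribution mass far from 1 (row %d)",
                    path, e, which(abs(rs - 1) > 1e-3)[1])
      p <- p / rs  # renormalize away the 6-decimal file precision
      dist[[e]] <- p
    }
    new_interaction_map(data.frame(i = pairs_i, j = pairs_j), "dist",
                        scheme, idx, dist = dist,
                        provenance = provenance, r_max = r_max)
  }
}
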