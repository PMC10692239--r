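# Model evaluation: optimal rigid superposition (Kabsch), TM-score with
# the standard fragment-seeded iterative search, and the inter-domain
# distance error of a predicted interaction map.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid superposition of point set `a` onto `b` with a
#' proper rotation enforced (no reflection), via SVD of the covariance.
#'
#' @param a,b Matched n x 3 point sets (Angstrom), n >= 3.
#' @return An object of class `"superposition"`: list with `rotation`
#'   (3x3), `translation` (length 3; the fit is
#'   `a %*% t(rotation) + translation`), `n` and `rmsd` (Angstrom).
#' @export
kabsch <- function(a, b) {
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop_validation("point sets must be matched n x 3 matrices")
  if (nrow(a) < 3L) stop_validation("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2L, ca), sweep(b, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- sweep(sweep(a, 2L, ca) %*% t(R), 2L, cb, "+")
  structure(list(rotation = R, translation = as.numeric(cb - R %*% ca),
                 n = nrow(a),
                 rmsd = sqrt(mean(rowSums((fit - b)^2)))),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, RMSD %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' @rdname kabsch
#' @export
kabsch_rmsd <- function(a, b) kabsch(a, b)$rmsd

# CA coordinates of residues common to two structures, matched on
# (chain, residue number) in reference order
matched_ca <- function(model, reference) {
  mk <- paste(model$res$chain, model$res$resno)
  rk <- paste(reference$res$chain, reference$res$resno)
  common <- intersect(rk, mk)
  list(model = model$ca[match(common, mk), , drop = FALSE],
       ref = reference$ca[match(common, rk), , drop = FALSE])
}

#' CA RMSD between two structures
#'
#' Kabsch-superposed RMSD over CA atoms of residues common to both
#' structures (matched on chain and residue number).
#'
#' @param model,reference `"backbone"` structures.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model, reference) {
  m <- matched_ca(model, reference)
  if (nrow(m$ref) < 3L) stop_validation("fewer than 3 common residues")
  kabsch_rmsd(m$model, m$ref)
}

#' TM-score of a model against a reference
#'
#' Length-normalized topological similarity in (0, 1]:
#' `TM = max over superpositions of (1/L_ref) sum_i 1 / (1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8` (clamped below at 0.5).
#' The maximization uses the standard search: superpositions seeded on
#' all fragments of lengths `L, L/2, L/4, ..., >= 4`, each refined by
#' iteratively re-superposing on the residues within a distance cutoff
#' until the selected set converges.
#'
#' @param model,reference `"backbone"` structures with >= 15 common
#'   residues (matched on chain and residue number).
#' @return TM-score (numeric scalar) with attributes `d0` and `n_common`.
#' @export
tm_score <- function(model, reference) {
  m <- matched_ca(model, reference)
  L <- nrow(m$ref)
  if (L < 15L) stop_validation("need at least 15 common residues for TM-score")
  d0 <- max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  d02 <- d0^2
  score_of <- function(fit) mean(1 / (1 + rowSums((fit - m$ref)^2) / d02))
  fit_on <- function(idx) {
    sp <- kabsch(m$model[idx, , drop = FALSE], m$ref[idx, , drop = FALSE])
    sweep(m$model %*% t(sp$rotation), 2L, sp$translation, "+")
  }
  best <- 0
  frag_lens <- unique(pmax(4L, c(L, L %/% 2L, L %/% 4L, 4L)))
  d_cuts <- c(8, 5.5, 4.25, 3.5, 3)  # shrinking inclusion cutoffs (A)
  for (fl in frag_lens) {
    step <- max(1L, fl %/% 2L)
    starts <- unique(c(seq(1L, L - fl + 1L, by = step), L - fl + 1L))
    for (st in starts) {
      idx <- st:(st + fl - 1L)
      for (dc in d_cuts) {
        prev <- integer(0)
        for (iter in 1:20) {
          fit <- fit_on(idx)
          sc <- score_of(fit)
          if (sc > best) best <- sc
          d2 <- rowSums((fit - m$ref)^2)
          nidx <- which(d2 < max(dc, d0)^2)
          if (length(nidx) < 3L)
            nidx <- order(d2)[seq_len(max(3L, min(L, fl)))]
          if (identical(nidx, idx) || identical(nidx, prev)) break
          prev <- idx
          idx <- nidx
        }
        idx <- st:(st + fl - 1L)  # reseed for the next cutoff
      }
    }
  }
  structure(min(best, 1), d0 = d0, n_common = L)
}

#' Inter-domain distance error of a predicted interaction map
#'
#' Error (Angstrom) between the predicted inter-domain distances and the
#' true CA-CA distances of the reference, over all pairs present in the
#' map (pairs decoded to the no-interaction overflow bin are absent by
#' construction).  Because frame origins are the CA atoms, the 6D `r`
#' element is the predicted CA-CA distance.
#'
#' @param pred An `"interaction_map"` (dist dialect is decoded first).
#' @param ref Reference `"backbone"` structure.
#' @param layout A `"domain_layout"` covering `ref`.
#' @param stat Aggregation over pairs: `"mean"` (default) or `"median"`.
#' @return Error in Angstrom.
#' @export
inter_domain_distance_error <- function(pred, ref, layout,
                                        stat = c("mean", "median")) {
  stat <- match.arg(stat)
  m <- as_mode_map(pred)
  if (nrow(m$pairs) == 0L) stop_degenerate("interaction map has no pairs")
  s <- assign_domains(ref, layout)
  skey <- paste(s$res$chain, s$res$resno)
  gkey <- paste(m$index$chain, m$index$resno)
  rows <- match(gkey, skey)
  i_rows <- rows[match(m$pairs$i, m$index$gidx)]
  j_rows <- rows[match(m$pairs$j, m$index$gidx)]
  if (any(is.na(i_rows)) || any(is.na(j_rows)))
    stop_validation("reference is missing residues named in the map")
  d_true <- sqrt(rowSums((s$ca[i_rows, , drop = FALSE] -
                            s$ca[j_rows, , drop = FALSE])^2))
  err <- abs(m$mode[, "r"] - d_true)
  if (stat == "mean") mean(err) else stats::median(err)
}
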