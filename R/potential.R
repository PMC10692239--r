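# The atomic coordinate deviation (ACD) energy: mean Euclidean deviation,
# over ordered inter-domain residue pairs and backbone atoms
# {N, CA, C, CB}, between atom positions expressed in the partner
# residue's local frame under the conformation's actual relative
# transform versus the targeted one.

ACD_ATOMS <- c("N", "CA", "C", "CB")

#' ACD evaluation context
#'
#' Precomputes, from an interaction map, the per-pair target transforms
#' (rotation + translation rebuilt from the 6D vectors) against which a
#' conformation is scored.  `N_tot = 4 x` (number of ordered pairs): one
#' cumulative term per pair and backbone atom.
#'
#' @param map An `"interaction_map"`; dist-dialect maps are decoded first
#'   (arg-max bin midpoints, overflow pairs dropped).
#' @param clamp Optional per-term clamp in Angstrom (default none, the
#'   potential as defined has no clamp).
#' @param steric_weight Weight of an optional soft steric repulsion over
#'   inter-domain CA pairs closer than 3.6 Angstrom (default 0 = off).
#' @return An object of class `"acd_context"`.
#' @export
acd_context <- function(map, clamp = NULL, steric_weight = 0) {
  m <- as_mode_map(map)
  np <- nrow(m$pairs)
  if (np == 0L) stop_degenerate("interaction map has no pairs")
  Rt <- matrix(NA_real_, np, 9L)
  tt <- matrix(NA_real_, np, 3L)
  for (p in seq_len(np)) {
    a <- affine_from_6d(m$mode[p, ])
    Rt[p, ] <- as.numeric(a$R)  # column-major = frame column layout
    tt[p, ] <- a$t
  }
  structure(list(i = m$pairs$i, j = m$pairs$j, Rt = Rt, tt = tt,
                 index = m$index, n_tot = 4L * np,
                 clamp = clamp, steric_weight = steric_weight),
            class = "acd_context")
}

#' @export
print.acd_context <- function(x, ...) {
  cat(sprintf("<ACD context> %d ordered pair(s), N_tot = %d%s%s\n",
              length(x$i), x$n_tot,
              if (is.null(x$clamp)) "" else sprintf(", clamp %g A", x$clamp),
              if (x$steric_weight > 0)
                sprintf(", steric weight %g", x$steric_weight) else ""))
  invisible(x)
}

# map the context's global indices onto rows of a conformation
ctx_rows <- function(ctx, conf) {
  ckey <- paste(conf$res$chain, conf$res$resno)
  gkey <- paste(ctx$index$chain, ctx$index$resno)
  rows <- match(gkey, ckey)
  i_rows <- rows[match(ctx$i, ctx$index$gidx)]
  j_rows <- rows[match(ctx$j, ctx$index$gidx)]
  if (any(is.na(i_rows)) || any(is.na(j_rows)))
    stop_validation("conformation is missing residues named in the ACD context")
  list(i = i_rows, j = j_rows)
}

# hot path shared by acd() and the optimizer: row indices precomputed
acd_eval <- function(conf, ctx, i_rows, j_rows) {
  fr <- frames_batch(conf$n, conf$ca, conf$c)
  cb <- get_cb(conf)
  R9i <- fr$R9[i_rows, , drop = FALSE]
  R9j <- fr$R9[j_rows, , drop = FALSE]
  ti <- fr$t[i_rows, , drop = FALSE]
  tj <- fr$t[j_rows, , drop = FALSE]
  total <- 0
  for (blk in list(conf$n, conf$ca, conf$c, cb)) {
    x <- blk[j_rows, , drop = FALSE]
    lhs <- rot_t_apply(R9i, x - ti)
    rhs <- rot_apply(ctx$Rt, rot_t_apply(R9j, x - tj)) + ctx$tt
    d <- lhs - rhs
    term <- sqrt(rowSums(d * d))
    if (!is.null(ctx$clamp)) term <- pmin(term, ctx$clamp)
    total <- total + sum(term)
  }
  e <- total / ctx$n_tot
  if (ctx$steric_weight > 0) {
    dca <- sqrt(rowSums((conf$ca[i_rows, , drop = FALSE] -
                           conf$ca[j_rows, , drop = FALSE])^2))
    viol <- pmax(0, 3.6 - dca)
    e <- e + ctx$steric_weight * mean(viol^2)
  }
  e
}

#' Atomic coordinate deviation energy
#'
#' `F_ACD = (1 / N_tot) * sum over ordered pairs (i, j) and atoms k in
#' \{N, CA, C, CB\} of || A_i^-1 x_jk - A_(i,j) A_j^-1 x_jk ||`, where
#' `A_i`, `A_j` are the conformation's current residue frames, `A_(i,j)`
#' the targeted relative transform and `x_jk` the ground-frame position
#' of atom k of residue j.  Zero exactly when every targeted relative
#' transform matches the conformation's; invariant under global rigid
#' motion of the conformation.  Units: Angstrom.
#'
#' @param conf A `"backbone"` conformation (CB virtualized where absent).
#' @param ctx An `"acd_context"` (or an `"interaction_map"`, converted on
#'   the fly).
#' @return Energy in Angstrom (non-negative scalar).
#' @export
acd <- function(conf, ctx) {
  if (inherits(ctx, "interaction_map")) ctx <- acd_context(ctx)
  if (!inherits(ctx, "acd_context")) stop_validation("ctx must be an acd_context")
  rw <- ctx_rows(ctx, conf)
  acd_eval(conf, ctx, rw$i, rw$j)
}

#' Predicted and true ACD
#'
#' `pacd()` scores a conformation against a (decoded) predicted
#' interaction map; `tacd()` against the exact oracle interactions of a
#' reference structure, realizing the "true" inter-domain interactions.
#'
#' @param conf A `"backbone"` conformation.
#' @param predicted_map An `"interaction_map"` (either dialect).
#' @return Energy in Angstrom.
#' @export
pacd <- function(conf, predicted_map) acd(conf, acd_context(predicted_map))

#' @rdname pacd
#' @param reference Reference `"backbone"` structure.
#' @param layout A `"domain_layout"`.
#' @param r_max Oracle distance cutoff (Angstrom).
#' @export
tacd <- function(conf, reference, layout, r_max = 40) {
  acd(conf, acd_context(oracle_interactions(reference, layout, r_max)))
}
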