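# Backbone structures: ordered residues with N/CA/C (+ optional O, CB)
# coordinates, chain and domain labels.  PDB I/O is delegated to bio3d.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Ideal CB position in the residue's local frame (x along CA->C, y from
# Gram-Schmidt on CA->N).  Derived once from ideal internal coordinates:
# |CA-CB| = 1.522 A, N-CA-CB = 110.5 deg, C-CA-CB = 110.1 deg,
# N-CA-C = 111.2 deg; the negative-z branch gives L-amino-acid chirality.
cb_local_ideal <- local({
  d2r <- pi / 180
  a <- cos(110.1 * d2r)
  b <- (cos(110.5 * d2r) - a * cos(111.2 * d2r)) / sin(111.2 * d2r)
  cc <- -sqrt(1 - a^2 - b^2)
  1.522 * c(a, b, cc)
})

#' Backbone structure
#'
#' Ordered protein backbone: one row per residue with chain id, residue
#' number, three-letter amino-acid code, optional domain label, and
#' coordinate matrices (Angstrom) for N, CA, C and optionally O and CB.
#'
#' @param chain Character vector of chain ids (one per residue).
#' @param resno Integer residue numbers, strictly increasing within a chain.
#' @param aa Three-letter amino-acid codes.
#' @param n,ca,c n x 3 coordinate matrices (Angstrom).
#' @param o,cb Optional n x 3 coordinate matrices.
#' @param domain Optional character vector of domain labels.
#' @param validate Run invariant checks (ordering, finiteness; bond-length
#'   sanity is warned about, not rejected)?
#' @return An object of class `"backbone"`.
#' @export
backbone_structure <- function(chain, resno, aa, n, ca, c,
                               o = NULL, cb = NULL, domain = NULL,
                               validate = TRUE) {
  nr <- length(resno)
  as_m <- function(x) {
    if (is.null(x)) return(NULL)
    x <- unname(as.matrix(x))
    if (!is.numeric(x) || ncol(x) != 3L || nrow(x) != nr)
      stop_validation("coordinate block must be an n x 3 numeric matrix")
    x
  }
  s <- structure(list(
    res = data.frame(chain = as.character(chain),
                     resno = as.integer(resno),
                     aa = as.character(aa),
                     domain = if (is.null(domain)) NA_character_
                              else as.character(domain),
                     stringsAsFactors = FALSE),
    n = as_m(n), ca = as_m(ca), c = as_m(c), o = as_m(o), cb = as_m(cb)
  ), class = "backbone")
  if (validate) validate_backbone(s)
  s
}

validate_backbone <- function(s) {
  if (nrow(s$res) == 0L) stop_validation("backbone structure has no residues")
  for (ch in unique(s$res$chain)) {
    rn <- s$res$resno[s$res$chain == ch]
    if (any(diff(rn) <= 0L))
      stop_validation("residue numbers must strictly increase within chain %s", ch)
  }
  for (blk in c("n", "ca", "c")) {
    if (is.null(s[[blk]]) || any(!is.finite(s[[blk]])))
      stop_validation("non-finite or missing %s coordinates", toupper(blk))
  }
  dcac <- sqrt(rowSums((s$c - s$ca)^2))
  dnca <- sqrt(rowSums((s$n - s$ca)^2))
  bad <- dcac <= 1.2 | dcac >= 1.8 | dnca <= 1.2 | dnca >= 1.8
  if (any(bad))
    warning(sprintf("%d residue(s) with unusual N-CA or CA-C bond lengths",
                    sum(bad)), call. = FALSE)
  invisible(s)
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d residues, %d chain(s)%s\n",
              nrow(x$res), length(unique(x$res$chain)),
              if (all(is.na(x$res$domain))) ""
              else sprintf(", %d domain(s)",
                           length(unique(stats::na.omit(x$res$domain))))))
  blocks <- c("N", "CA", "C", if (!is.null(x$o)) "O", if (!is.null(x$cb)) "CB")
  cat("atoms per residue:", paste(blocks, collapse = " "), "\n")
  invisible(x)
}

#' Number of residues in a backbone structure
#' @param s A `"backbone"` structure.
#' @return Integer residue count.
#' @export
n_residues <- function(s) nrow(s$res)

#' Virtual C-beta from backbone atoms
#'
#' Places an ideal C-beta 1.522 Angstrom from CA using tetrahedral
#' L-amino-acid geometry in the residue's local frame; deterministic and
#' rigid-motion equivariant.  Used so the backbone atom set
#' \{N, CA, C, CB\} is uniform across residues, glycine included.
#'
#' @param n,ca,c Length-3 vectors or m x 3 matrices of atom coordinates
#'   (Angstrom).
#' @return Coordinates of the virtual CB, same shape as the inputs.
#' @export
#' @examples
#' virtual_cbeta(c(-0.5, 1.4, 0), c(0, 0, 0), c(1.525, 0, 0))
virtual_cbeta <- function(n, ca, c) {
  if (is.matrix(ca)) {
    fr <- frames_batch(n, ca, c)
    rot_apply(fr$R9, matrix(cb_local_ideal, nrow(ca), 3, byrow = TRUE)) + ca
  } else {
    f <- build_frame(n, ca, c)
    affine_apply(f, cb_local_ideal)
  }
}

#' C-beta coordinates of every residue
#'
#' Stored CB atoms where present, ideal virtual CB (see [virtual_cbeta()])
#' elsewhere.
#'
#' @param s A `"backbone"` structure.
#' @return n x 3 matrix of CB coordinates (Angstrom).
#' @export
get_cb <- function(s) {
  if (!is.null(s$cb)) {
    if (all(is.finite(s$cb[, 1]))) return(s$cb)
    vcb <- virtual_cbeta(s$n, s$ca, s$c)
    keep <- is.finite(s$cb[, 1])
    vcb[keep, ] <- s$cb[keep, , drop = FALSE]
    return(vcb)
  }
  virtual_cbeta(s$n, s$ca, s$c)
}

# ---- PDB I/O ----------------------------------------------------------------

#' Read a backbone structure from a PDB file
#'
#' Parses the first model via bio3d, keeping standard amino-acid ATOM
#' records (altloc blank or 'A').  Residues missing any of N, CA or C are
#' dropped with a warning.  When a [domain_layout()] is supplied, residues
#' are reordered to the layout's chain order and labelled by domain.
#'
#' @param path PDB file path.
#' @param layout Optional `"domain_layout"`.
#' @return A `"backbone"` structure.
#' @export
read_pdb <- function(path, layout = NULL) {
  if (!file.exists(path)) stop_io("cannot read PDB file: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop_format("not parseable as PDB: %s (%s)",
                                    path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% STANDARD_AA, , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  if (nrow(at) == 0L) stop_format("no standard backbone atoms in %s", path)
  at$chain[is.na(at$chain)] <- "A"
  key <- paste(at$chain, at$resno)
  ukey <- unique(key)
  nr <- length(ukey)
  blocks <- list(N = NULL, CA = NULL, C = NULL, O = NULL, CB = NULL)
  for (el in names(blocks)) {
    m <- matrix(NA_real_, nr, 3)
    sel <- at$elety == el
    idx <- match(key[sel], ukey)
    first <- !duplicated(idx)
    m[idx[first], ] <- as.matrix(at[sel, c("x", "y", "z")])[first, , drop = FALSE]
    blocks[[el]] <- m
  }
  meta <- at[match(ukey, key), c("chain", "resno", "resid")]
  complete <- is.finite(blocks$N[, 1]) & is.finite(blocks$CA[, 1]) &
    is.finite(blocks$C[, 1])
  if (!any(complete)) stop_format("no residue with full N/CA/C backbone in %s", path)
  if (any(!complete))
    warning(sprintf("dropped %d residue(s) missing N/CA/C in %s",
                    sum(!complete), basename(path)), call. = FALSE)
  sub <- function(m) m[complete, , drop = FALSE]
  has_any <- function(m) any(is.finite(m[, 1]))
  s <- backbone_structure(
    chain = meta$chain[complete], resno = meta$resno[complete],
    aa = meta$resid[complete],
    n = sub(blocks$N), ca = sub(blocks$CA), c = sub(blocks$C),
    o = if (has_any(sub(blocks$O))) sub(blocks$O),
    cb = if (has_any(sub(blocks$CB))) sub(blocks$CB))
  if (!is.null(layout)) s <- assign_domains(s, layout)
  s
}

#' Write a backbone structure to a PDB file
#'
#' Emits standard ATOM records (fixed-point 8.3 coordinates) with chain
#' ids and residue numbers preserved and TER records between chains.
#'
#' @param s A `"backbone"` structure.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "backbone") || nrow(s$res) == 0L)
    stop_validation("need a non-empty backbone structure")
  elety <- c("N", "CA", "C", if (!is.null(s$o)) "O", if (!is.null(s$cb)) "CB")
  per <- length(elety)
  nr <- nrow(s$res)
  xyz <- matrix(NA_real_, nr * per, 3)
  for (k in seq_along(elety)) {
    blk <- switch(elety[k], N = s$n, CA = s$ca, C = s$c, O = s$o, CB = s$cb)
    xyz[seq(k, by = per, length.out = nr), ] <- blk
  }
  keep <- is.finite(xyz[, 1])
  rep_res <- rep(seq_len(nr), each = per)[keep]
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(xyz[keep, , drop = FALSE])),
                     resno = s$res$resno[rep_res],
                     resid = s$res$aa[rep_res],
                     chain = s$res$chain[rep_res],
                     elety = rep(elety, nr)[keep],
                     eleno = seq_len(sum(keep)),
                     o = rep(1, sum(keep)), b = rep(0, sum(keep)),
                     chainter = TRUE, verbose = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop_io("cannot write PDB file: %s", path)
  invisible(path)
}

# internal: order residues by layout chain order (resno within chain) and
# attach domain labels; errors if layout and structure disagree.
assign_domains <- function(s, layout) {
  lr <- layout_residues(layout)
  skey <- paste(s$res$chain, s$res$resno)
  lkey <- paste(lr$chain, lr$resno)
  if (any(!(lkey %in% skey)))
    stop_layout("layout references %d residue(s) absent from the structure",
                sum(!(lkey %in% skey)))
  if (any(!(skey %in% lkey)))
    stop_layout("%d structure residue(s) not covered by any domain",
                sum(!(skey %in% lkey)))
  ord <- match(lkey, skey)
  sub <- function(m) if (is.null(m)) NULL else m[ord, , drop = FALSE]
  backbone_structure(chain = s$res$chain[ord], resno = s$res$resno[ord],
                     aa = s$res$aa[ord],
                     n = sub(s$n), ca = sub(s$ca), c = sub(s$c),
                     o = sub(s$o), cb = sub(s$cb),
                     domain = lr$domain, validate = FALSE)
}

#' Extract one domain as a stand-alone structure
#'
#' @param s A `"backbone"` structure.
#' @param layout A `"domain_layout"`.
#' @param id Domain id present in `layout`.
#' @return A `"backbone"` structure containing only that domain's residues.
#' @export
extract_domain <- function(s, layout, id) {
  s <- assign_domains(s, layout)
  keep <- which(s$res$domain == id)
  if (length(keep) == 0L) stop_layout("unknown domain id: %s", id)
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  backbone_structure(chain = s$res$chain[keep], resno = s$res$resno[keep],
                     aa = s$res$aa[keep],
                     n = sub(s$n), ca = sub(s$ca), c = sub(s$c),
                     o = sub(s$o), cb = sub(s$cb),
                     domain = s$res$domain[keep], validate = FALSE)
}
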