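#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of paired point sets, proper
#' rotations only (mirror images are rejected by construction: the
#' determinant sign is corrected in the SVD solution, so chirality is
#' never silently flipped). Row convention: the returned transform maps A
#' onto B as `sweep(A %*% rotation, 2, translation, "+")`.
#'
#' @param A,B N x 3 paired coordinate matrices, N >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation`,
#'   `backbone_rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(A, B) {
  A <- .coords_of(A); B <- .coords_of(B)
  if (!all(dim(A) == dim(B))) stop("point sets must be paired (equal shape)")
  if (nrow(A) < 3L) stop("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1e-12)) {
    stop("degenerate (collinear) point configuration")
  }
  dsign <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, dsign))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- cb - drop(ca %*% R)
  fitted <- sweep(A %*% R, 2L, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = tr, backbone_rmsd = rmsd)
}

# apply a superposition result to coordinates
.apply_transform <- function(x, fit) {
  sweep(x %*% fit$rotation, 2L, fit$translation, `+`)
}

#' Active-site alignment of a generated structure against a reference
#'
#' Globally superposes the generated structure onto the reference
#' (C-alpha, paired by residue index), then matches each annotated
#' reference site residue to the nearest generated residue of identical
#' amino-acid type (ties broken by lower residue index). If all site
#' residues have a one-to-one match, the site RMSD over matched C-alpha
#' pairs is reported, with success defined as RMSD below 1 Angstrom; a
#' site residue with no same-type candidate, or a collision in the
#' matching, yields `status = "match_failed"` rather than an error.
#'
#' @param generated,reference lists with `coords` (L x 3) and `tokens`.
#' @param site integer indices of annotated site residues in the
#'   reference (>= 2).
#' @return list with `status` (`"ok"` or `"match_failed"`), `rotation`,
#'   `translation`, `backbone_rmsd`, `site_rmsd`, `residue_matches`
#'   (data frame), `identity_fraction`, `success`.
#' @export
active_site_align <- function(generated, reference, site) {
  stopifnot(length(site) >= 2L)
  gx <- .coords_of(generated$coords); rx <- .coords_of(reference$coords)
  gt <- .tokens_of(generated$tokens); rt <- .tokens_of(reference$tokens)
  if (nrow(gx) != nrow(rx)) {
    stop("index-paired global superposition requires equal lengths")
  }
  fit <- kabsch_superpose(gx, rx)
  gxt <- .apply_transform(gx, fit)
  matches <- data.frame(reference_residue = integer(0),
                        generated_residue = integer(0),
                        distance = numeric(0))
  for (i in site) {
    cand <- which(gt == rt[i])
    if (length(cand) == 0L) {
      return(c(fit, list(status = "match_failed", site_rmsd = NA_real_,
                         residue_matches = matches,
                         identity_fraction = NA_real_, success = FALSE)))
    }
    d <- sqrt(rowSums(sweep(gxt[cand, , drop = FALSE], 2L, rx[i, ])^2))
    best <- cand[order(d, cand)][1L]
    matches <- rbind(matches,
                     data.frame(reference_residue = i,
                                generated_residue = best,
                                distance = min(d)))
  }
  if (anyDuplicated(matches$generated_residue)) {
    return(c(fit, list(status = "match_failed", site_rmsd = NA_real_,
                       residue_matches = matches,
                       identity_fraction = NA_real_, success = FALSE)))
  }
  site_rmsd <- sqrt(mean(matches$distance^2))
  c(fit, list(status = "ok", site_rmsd = site_rmsd,
              residue_matches = matches, identity_fraction = 1,
              success = site_rmsd < 1.0))
}

#' Shell-expansion metrics around an active site
#'
#' For spherical shells of increasing radius around the site centroid of
#' the reference: selects the reference residues inside the shell,
#' re-superposes the generated structure on that selection (index-paired
#' C-alpha), and reports the selection RMSD and the fraction of matching
#' residue identities. Shells with fewer than three residues are marked
#' undefined (NA).
#'
#' @param generated,reference lists with `coords` and `tokens`, equal
#'   length.
#' @param site annotated site residue indices (reference).
#' @param radii shell radii in Angstrom (default 1..18).
#' @return data frame with columns `radius`, `n_residues`, `rmsd`,
#'   `identity_fraction`.
#' @export
shell_metrics <- function(generated, reference, site, radii = 1:18) {
  gx <- .coords_of(generated$coords); rx <- .coords_of(reference$coords)
  gt <- .tokens_of(generated$tokens); rt <- .tokens_of(reference$tokens)
  stopifnot(nrow(gx) == nrow(rx))
  center <- colMeans(rx[site, , drop = FALSE])
  d <- sqrt(rowSums(sweep(rx, 2L, center)^2))
  out <- data.frame(radius = radii, n_residues = NA_integer_,
                    rmsd = NA_real_, identity_fraction = NA_real_)
  for (k in seq_along(radii)) {
    sel <- which(d <= radii[k])
    out$n_residues[k] <- length(sel)
    if (length(sel) == 0L) next
    out$identity_fraction[k] <- mean(gt[sel] == rt[sel])
    if (length(sel) >= 3L) {
      fit <- tryCatch(kabsch_superpose(gx[sel, , drop = FALSE],
                                       rx[sel, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(fit)) out$rmsd[k] <- fit$backbone_rmsd
    }
  }
  out
}

#' Radius-based residue selection
#'
#' Residues whose C-alpha lies within `radius` of `center` (boundary
#' inclusive).
#'
#' @param structure coordinates (L x 3 or `structure_state`).
#' @param center 3-vector (Angstrom).
#' @param radius selection radius (> 0, or 0 for exact coincidence).
#' @return integer residue indices.
#' @export
select_motif_by_radius <- function(structure, center, radius) {
  stopifnot(radius >= 0)
  x <- .coords_of(structure)
  d <- sqrt(rowSums(sweep(x, 2L, center)^2))
  which(d <= radius)
}

#' Midpoint of two residues' C-alpha atoms
#'
#' @param structure coordinates.
#' @param resA,resB residue indices.
#' @return 3-vector.
#' @export
residue_midpoint <- function(structure, resA, resB) {
  x <- .coords_of(structure)
  if (resA < 1L || resA > nrow(x) || resB < 1L || resB > nrow(x)) {
    stop("residue index out of range")
  }
  (x[resA, ] + x[resB, ]) / 2
}

#' Extract a motif by radius around a point
#'
#' Convenience wrapper pairing [select_motif_by_radius()] with
#' [motif_spec()]: the motif carries the selected residues' coordinates
#' and identities at their original indices.
#'
#' @param coords L x 3 coordinates.
#' @param tokens length-L amino-acid tokens.
#' @param center 3-vector.
#' @param radius selection radius (Angstrom).
#' @return a [motif_spec()].
#' @export
motif_from_radius <- function(coords, tokens, center, radius) {
  coords <- .coords_of(coords); tokens <- .tokens_of(tokens)
  idx <- select_motif_by_radius(coords, center, radius)
  if (length(idx) == 0L) stop("no residue within radius")
  motif_spec(idx, coords[idx, , drop = FALSE], tokens[idx])
}
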