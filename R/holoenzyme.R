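# Holoenzyme modelling: place a conformer into an R2C2 template by
# anchor-helix superposition onto one catalytic subunit, then scan for
# steric clashes between the placed appendage and the regulatory
# subunits.

#' Place a conformer into a holoenzyme template
#'
#' The conformer is rigidly superposed (Kabsch over `fit_sel`, typically
#' the E/F anchor-helix backbone) onto chain `template_chain` of the
#' template; that template chain is then replaced by the transformed
#' conformer while every other template chain is retained.
#'
#' @param conformer Structure to place (its chain ids are rewritten to
#'   `template_chain`).
#' @param template multi-chain Structure (regulatory and catalytic
#'   subunits).
#' @param template_chain chain id of the catalytic subunit being replaced.
#' @param fit_sel Selection resolving in both conformer and template
#'   chain; residue numbering must agree between the two (use a
#'   [numbering_map()] upstream if it does not).
#' @param conformer_fit_sel optional distinct Selection for the conformer
#'   side when its chain id differs from `template_chain`.
#' @return List of class `Assembly`: `structure` (merged Structure),
#'   `placed_chain`, `fit_rmsd_A` (post-fit QC RMSD over the fit atoms).
#' @export
place_conformer <- function(conformer, template, template_chain = "C",
                            fit_sel = core_fit_selection(chain = template_chain),
                            conformer_fit_sel = NULL) {
  if (is.null(conformer_fit_sel)) {
    conformer_fit_sel <- fit_sel
    conformer_fit_sel$ranges$chain <- unique(conformer$atoms$chain)[1]
  }
  mob_idx <- select_indices(conformer, conformer_fit_sel)
  tgt <- select_atoms(template, fit_sel)
  mob <- select_atoms(conformer, conformer_fit_sel)
  # pair by (residue, atom); both selections come back in canonical order
  key_t <- paste(tgt$resid, tgt$atom); key_m <- paste(mob$resid, mob$atom)
  common <- intersect(key_t, key_m)
  if (length(common) < 3L) stop("fit selection pairs fewer than 3 atoms")
  A <- as.matrix(mob[match(common, key_m), c("x", "y", "z")])
  B <- as.matrix(tgt[match(common, key_t), c("x", "y", "z")])
  tf <- kabsch(A, B)
  fit_rmsd <- rmsd(apply_transform(A, tf), B)

  moved <- conformer
  moved$coords <- apply_transform(conformer$coords, tf)
  moved$atoms$chain <- template_chain

  keep <- template$atoms$chain != template_chain
  atoms <- rbind(template$atoms[keep, , drop = FALSE], moved$atoms)
  coords <- rbind(template$coords[keep, , drop = FALSE], moved$coords)
  merged <- new_structure(atoms, coords,
                          label = sprintf("%s + placed %s", template$label,
                                          conformer$label))
  structure(list(structure = merged, placed_chain = template_chain,
                 fit_rmsd_A = fit_rmsd),
            class = "Assembly")
}

#' Steric clash scan between two atom groups
#'
#' Reports every heavy-atom pair, one atom from each group, closer than
#' `threshold_A`.  A spatial cell list keeps the scan near-linear; the
#' result is identical to a brute-force all-pairs scan.
#'
#' @param a an `Assembly` or a Structure.
#' @param group1,group2 disjoint Selections (e.g. the placed appendage
#'   residues versus the regulatory-subunit chains).
#' @param threshold_A distance threshold, default 2.5 (hard-sphere
#'   heavy-atom proxy).
#' @param method `"grid"` (cell list) or `"brute"`.
#' @return List of class `ClashReport`: `pair_count`, `min_distance_A`
#'   (over all inter-group pairs, even when no clash), `pairs` (data.frame
#'   ordered by ascending distance), `threshold_A`.
#' @export
clash_scan <- function(a, group1, group2, threshold_A = 2.5,
                       method = c("grid", "brute")) {
  method <- match.arg(method)
  s <- if (inherits(a, "Assembly")) a$structure else a
  i1 <- select_indices(s, group1)
  i2 <- select_indices(s, group2)
  heavy <- !(toupper(s$atoms$element) %in% "H")
  i1 <- i1[heavy[i1]]; i2 <- i2[heavy[i2]]
  if (!length(i1) || !length(i2)) stop("empty group after hydrogen removal")
  if (length(intersect(i1, i2))) stop("clash groups overlap")
  p1 <- s$coords[i1, , drop = FALSE]
  p2 <- s$coords[i2, , drop = FALSE]

  if (method == "brute") {
    d2 <- outer(rowSums(p1^2), rowSums(p2^2), `+`) - 2 * p1 %*% t(p2)
    d2[d2 < 0] <- 0
    dd <- sqrt(d2)
    hit <- which(dd < threshold_A, arr.ind = TRUE)
    pairs <- data.frame(atom1 = i1[hit[, 1]], atom2 = i2[hit[, 2]],
                        distance_A = dd[hit])
    min_d <- min(dd)
  } else {
    cell <- max(threshold_A, 1e-6)
    key <- function(p) {
      g <- floor(p / cell)
      paste(g[, 1], g[, 2], g[, 3])
    }
    k2 <- key(p2)
    buckets <- split(seq_along(i2), k2)
    g1 <- floor(p1 / cell)
    res1 <- integer(0); res2 <- integer(0); resd <- numeric(0)
    min_d <- Inf
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (r in seq_along(i1)) {
      cand <- integer(0)
      for (o in seq_len(nrow(offs))) {
        kk <- paste(g1[r, 1] + offs[o, 1], g1[r, 2] + offs[o, 2],
                    g1[r, 3] + offs[o, 3])
        b <- buckets[[kk]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      if (length(cand)) {
        dd <- sqrt(colSums((t(p2[cand, , drop = FALSE]) - p1[r, ])^2))
        sel <- dd < threshold_A
        res1 <- c(res1, rep(r, sum(sel)))
        res2 <- c(res2, cand[sel])
        resd <- c(resd, dd[sel])
        if (length(dd)) min_d <- min(min_d, min(dd))
      }
    }
    pairs <- data.frame(atom1 = i1[res1], atom2 = i2[res2], distance_A = resd)
    # the cell list only visits nearby pairs; recover the true global
    # minimum distance when nothing fell inside the neighborhood
    if (!is.finite(min_d) || !nrow(pairs)) {
      d2 <- outer(rowSums(p1^2), rowSums(p2^2), `+`) - 2 * p1 %*% t(p2)
      min_d <- sqrt(max(0, min(d2)))
    }
  }
  ord <- order(pairs$distance_A, pairs$atom1, pairs$atom2)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pair_count = nrow(pairs), min_distance_A = min_d,
                 pairs = pairs, threshold_A = threshold_A),
            class = "ClashReport")
}
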