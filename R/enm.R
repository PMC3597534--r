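#' @name enm
#' @title Calpha elastic-network normal-mode analysis
#'
#' @description
#' The elastic network places a Hookean spring of uniform stiffness `k`
#' between every pair of Calpha nodes closer than a distance cutoff
#' (default 8 Angstrom); recorded covalent links always receive a spring
#' regardless of distance. Normal modes are the eigenvectors of the
#' resulting Hessian; the six zero-eigenvalue modes are rigid-body motions,
#' so with 1-based ascending numbering "mode 7" is the first internal mode.
NULL

# Calpha node indices: atoms named CA, or every atom when none is named CA
# (point-atom fixtures are already one node per residue).
ca_node_indices <- function(s) {
  idx <- which(s$atoms$atom_name == "CA")
  if (length(idx) == 0) idx <- seq_len(nrow(s$atoms))
  idx
}

# Map recorded links to node index pairs (the node of the named residue).
link_node_pairs <- function(s, node_idx) {
  if (nrow(s$links) == 0) return(matrix(integer(0), ncol = 2))
  at <- s$atoms[node_idx, ]
  pairs <- matrix(NA_integer_, nrow(s$links), 2)
  for (i in seq_len(nrow(s$links))) {
    a <- which(at$chain_id == s$links$chain_a[i] &
               at$residue_index == s$links$residue_a[i])
    b <- which(at$chain_id == s$links$chain_b[i] &
               at$residue_index == s$links$residue_b[i])
    if (length(a) == 0 || length(b) == 0)
      stop("link residue has no Calpha node: link ", i)
    pairs[i, ] <- c(a[1], b[1])
  }
  pairs
}

# Contact pairs within cutoff (i < j), plus always-on link pairs.
contact_pairs <- function(xyz, cutoff, links = NULL) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  in_cut <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  pairs <- unname(in_cut)
  if (!is.null(links) && nrow(links) > 0) {
    lk <- t(apply(links, 1, sort))
    pairs <- unique(rbind(pairs, lk))
  }
  pairs
}

#' Build the elastic-network Hessian
#'
#' Standard pairwise Hookean super-elements on 3x3 blocks: for a contact
#' pair (i, j) with unit inter-node vector u, the off-diagonal block gets
#' `-k u u^T` and both diagonal blocks accumulate `+k u u^T`. Pairs beyond
#' the cutoff contribute nothing; recorded covalent links always contribute.
#'
#' @param s a `MolecularStructure` (its Calpha atoms are the nodes; for
#'   point-atom fixtures without CA names, every atom is a node).
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @param k uniform spring constant (default 1; mode shapes are
#'   k-independent).
#' @param extra_links optional data.frame of links in the [join_chains()]
#'   format, added to any links already recorded on `s`.
#' @return symmetric positive-semidefinite 3N x 3N matrix.
#' @export
build_hessian <- function(s, cutoff = 8, k = 1, extra_links = NULL) {
  stopifnot(inherits(s, "MolecularStructure"), cutoff > 0, k > 0)
  node_idx <- ca_node_indices(s)
  n <- length(node_idx)
  if (n < 2) stop("need at least 2 Calpha nodes")
  xyz <- coords(s)[node_idx, , drop = FALSE]
  s2 <- s
  if (!is.null(extra_links)) s2$links <- rbind(s$links, extra_links)
  lpairs <- link_node_pairs(s2, node_idx)
  pairs <- contact_pairs(xyz, cutoff, lpairs)
  H <- matrix(0, 3 * n, 3 * n)
  if (nrow(pairs) > 0) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      dv <- xyz[j, ] - xyz[i, ]
      dd <- sqrt(sum(dv^2))
      if (dd < 1e-6)
        stop("degenerate geometry: coincident nodes ", i, " and ", j)
      u <- dv / dd
      blk <- k * tcrossprod(u)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
    }
  }
  H
}

# Connected components of the contact graph (union-find).
network_components <- function(xyz, cutoff, links = NULL) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pairs <- contact_pairs(xyz, cutoff, links)
  if (nrow(pairs) > 0) for (p in seq_len(nrow(pairs))) {
    ri <- find(pairs[p, 1]); rj <- find(pairs[p, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Compute elastic-network normal modes
#'
#' Full symmetric eigendecomposition of the Hessian from [build_hessian()].
#' Eigenvalues are returned ascending and clamped to exactly zero when
#' `|lambda| < zero_tol * lambda_max`; a connected 3-D structure has exactly
#' six zero modes (rigid translations/rotations). A disconnected network
#' raises a warning reporting the component count (six zero modes per rigid
#' component are expected).
#'
#' @inheritParams build_hessian
#' @param zero_tol relative threshold below which an eigenvalue is treated
#'   as a rigid-body zero (default 1e-8 of the largest eigenvalue).
#' @return a `ModeSet`: ascending `values`, orthonormal eigenvector columns
#'   `vectors` (3N x 3N), the node roster, the zero-mode count `n_zero`
#'   and the network component count.
#' @export
compute_modes <- function(s, cutoff = 8, k = 1, extra_links = NULL,
                          zero_tol = 1e-8) {
  node_idx <- ca_node_indices(s)
  xyz <- coords(s)[node_idx, , drop = FALSE]
  s2 <- s
  if (!is.null(extra_links)) s2$links <- rbind(s$links, extra_links)
  ncomp <- max(network_components(xyz, cutoff,
                                  link_node_pairs(s2, node_idx)))
  if (ncomp > 1)
    warning("elastic network has ", ncomp,
            " connected components; extra zero modes expected")
  H <- build_hessian(s, cutoff = cutoff, k = k, extra_links = extra_links)
  eg <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(eg$values))
  values <- eg$values[ord]
  vectors <- eg$vectors[, ord, drop = FALSE]
  lmax <- max(abs(values))
  if (lmax > 0) values[abs(values) < zero_tol * lmax] <- 0
  values[values < 0] <- 0
  structure(list(values = values, vectors = vectors,
                 cutoff = cutoff, spring_constant = k,
                 nodes = s$atoms[node_idx, c("chain_id", "residue_index")],
                 n_zero = sum(values == 0), n_components = ncomp),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf(
    "ModeSet: %d nodes, cutoff %g A, k = %g; %d zero modes (%d component%s)\n",
    nrow(x$nodes), x$cutoff, x$spring_constant, x$n_zero, x$n_components,
    if (x$n_components == 1) "" else "s"))
  invisible(x)
}

#' Per-node displacement vectors of one mode
#'
#' @param m a `ModeSet`.
#' @param i 1-based mode index (mode 7 is the first internal mode of a
#'   connected structure).
#' @return n x 3 matrix of displacement components (unit modal amplitude).
#' @export
mode_displacements <- function(m, i) {
  if (i < 1 || i > length(m$values)) stop("mode index out of range: ", i)
  matrix(m$vectors[, i], ncol = 3, byrow = TRUE)
}

#' Deformation energy of a mode at unit amplitude
#'
#' Energy of displacing the network by one unit along mode `i`:
#' `0.5 * lambda_i`. Zero for rigid-body modes; non-decreasing with mode
#' index, which is why only the first few internal modes contribute visibly
#' to the deformation pattern.
#'
#' @inheritParams mode_displacements
#' @return scalar energy in units of `k * Angstrom^2`.
#' @export
deformation_energy <- function(m, i) {
  if (i < 1 || i > length(m$values)) stop("mode index out of range: ", i)
  0.5 * m$values[i]
}

#' Detect a hinge between two rigid domains in a mode
#'
#' Labels the nodes of a structure as two anti-phase moving domains plus a
#' low-mobility hinge segment lying between them in sequence, from the
#' displacement pattern of one internal mode:
#' (1) per-residue displacement vectors come from the eigenvector;
#' (2) residues with amplitude above the median are split into two direction
#' groups by the sign of their projection onto the first principal axis of
#' the displacement set; (3) the hinge is the residues with amplitude below
#' the `low_quantile` percentile lying sequence-wise between the two groups;
#' (4) the anticorrelation is the cosine between the two groups' mean
#' displacement vectors (close to -1 for clean anti-phase domain motion).
#'
#' When the displacement field is near-parallel (a single rigid block), or
#' no anti-phase split exists, a "no hinge" report is returned rather than
#' an error.
#'
#' @param m a `ModeSet`.
#' @param s the `MolecularStructure` the modes were computed from.
#' @param mode_index mode to analyse (default 7, the first internal mode).
#' @param low_quantile amplitude quantile below which a residue can be a
#'   hinge residue (default 0.25).
#' @param anticorrelation_max largest (most positive) group-mean cosine
#'   still accepted as anti-phase motion (default -0.2).
#' @param min_group_size smallest direction group accepted as a rigid
#'   domain (default 5 residues); below this the structure is treated as
#'   a single rigid block.
#' @return a `HingeReport`: `has_hinge`, per-node `domain_labels` in
#'   `{domain1, domain2, hinge}`, `hinge_residues` (roster rows), the mode
#'   index and the `anticorrelation` cosine.
#' @export
detect_hinge <- function(m, s, mode_index = 7, low_quantile = 0.25,
                         anticorrelation_max = -0.2, min_group_size = 5) {
  stopifnot(inherits(m, "ModeSet"))
  if (mode_index < 1 || mode_index > length(m$values))
    stop("mode index out of range: ", mode_index)
  if (m$values[mode_index] == 0)
    stop("mode ", mode_index, " is a rigid-body mode; pick an internal mode")
  disp <- mode_displacements(m, mode_index)
  n <- nrow(disp)
  amp <- sqrt(rowSums(disp^2))
  no_hinge <- function(reason) {
    structure(list(has_hinge = FALSE, reason = reason,
                   domain_labels = rep("domain1", n),
                   hinge_residues = integer(0), mode_index = mode_index,
                   anticorrelation = NA_real_, nodes = m$nodes),
              class = "HingeReport")
  }
  high <- which(amp > stats::median(amp))
  if (length(high) < 2) return(no_hinge("no high-amplitude residues"))
  hd <- disp[high, , drop = FALSE]
  pc <- eigen(crossprod(scale(hd, center = TRUE, scale = FALSE)),
              symmetric = TRUE)$vectors[, 1]
  proj <- as.vector(disp %*% pc)
  grpA <- high[proj[high] >= 0]
  grpB <- high[proj[high] < 0]
  if (length(grpA) == 0 || length(grpB) == 0)
    return(no_hinge("displacements near-parallel: single rigid block"))
  if (length(grpA) < min_group_size || length(grpB) < min_group_size)
    return(no_hinge("direction groups too small to be rigid domains"))
  meanA <- colMeans(disp[grpA, , drop = FALSE])
  meanB <- colMeans(disp[grpB, , drop = FALSE])
  anticorr <- sum(meanA * meanB) /
    (sqrt(sum(meanA^2)) * sqrt(sum(meanB^2)))
  if (!is.finite(anticorr) || anticorr > anticorrelation_max)
    return(no_hinge("direction groups are not anti-phase"))
  # order the groups along the roster; the hinge can only live in the
  # sequence stretch between them. In a two-domain motion the groups are
  # sequence-segregated; heavy cross-mixing means the mode is not a
  # domain motion (e.g. a torsion, where each cluster contributes both
  # directions): no hinge.
  if (stats::median(grpA) > stats::median(grpB)) { tmp <- grpA; grpA <- grpB; grpB <- tmp }
  crossed <- sum(grpA > stats::median(grpB)) + sum(grpB < stats::median(grpA))
  if (crossed > 0.05 * (length(grpA) + length(grpB)))
    return(no_hinge("direction groups interleave in sequence"))
  lo <- stats::median(grpA); hi <- stats::median(grpB)
  idx <- seq_len(n)
  cand <- which(amp < stats::quantile(amp, low_quantile) & idx > lo & idx < hi)
  if (length(cand) == 0)
    return(no_hinge("no low-mobility residues between the domains"))
  # the hinge is the contiguous low-mobility segment that separates the
  # two groups in sequence (>= 85% of group A before it, >= 85% of group
  # B after it; a few bridge-end residues always ride with a domain);
  # other low-amplitude stretches, e.g. around a domain's own rotation
  # axis, do not separate the groups
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  separates <- vapply(runs, function(r) {
    mean(grpA < min(r)) >= 0.85 && mean(grpB > max(r)) >= 0.85
  }, logical(1))
  if (!any(separates))
    return(no_hinge("no low-mobility segment separates the domains"))
  runs <- runs[separates]
  # if several qualify, take the stillest one
  hinge <- runs[[which.min(vapply(runs, function(r) min(amp[r]),
                                  numeric(1)))]]
  labels <- ifelse(proj >= 0, "domain1", "domain2")
  labels[hinge] <- "hinge"
  structure(list(has_hinge = TRUE, reason = NULL, domain_labels = labels,
                 hinge_residues = hinge, mode_index = mode_index,
                 anticorrelation = anticorr, nodes = m$nodes),
            class = "HingeReport")
}

#' Find the lowest mode exhibiting a clean two-domain hinge
#'
#' The lowest internal mode of a two-domain structure is not always the
#' hinge-bending mode (for a dumbbell it can be a torsion about the
#' inter-domain axis, whose direction groups interleave in sequence).
#' This scans the internal modes in ascending order and returns the first
#' [detect_hinge()] report that finds an anti-phase hinge.
#'
#' @inheritParams detect_hinge
#' @param modes candidate mode indices, ascending (default `7:18`).
#' @return the first hinge-positive `HingeReport`, or the last (no-hinge)
#'   report when no candidate mode qualifies.
#' @export
find_hinge_mode <- function(m, s, modes = 7:18, low_quantile = 0.25,
                            anticorrelation_max = -0.5) {
  modes <- modes[modes <= length(m$values) & modes >= 1]
  modes <- modes[m$values[modes] > 0]
  if (length(modes) == 0) stop("no internal modes among the candidates")
  rep <- NULL
  for (mi in modes) {
    rep <- detect_hinge(m, s, mode_index = mi, low_quantile = low_quantile,
                        anticorrelation_max = anticorrelation_max)
    if (rep$has_hinge) return(rep)
  }
  rep
}

#' @export
print.HingeReport <- function(x, ...) {
  if (!x$has_hinge) {
    cat("HingeReport: no hinge (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "HingeReport: mode %d, %d hinge residues, anticorrelation %.3f\n",
      x$mode_index, length(x$hinge_residues), x$anticorrelation))
  }
  invisible(x)
}

#' Write mode displacements as TSV
#'
#' One row per (node, mode): chain, residue, mode index, dx, dy, dz.
#'
#' @param m a `ModeSet`.
#' @param file output path.
#' @param modes mode indices to write (default the first four internal
#'   modes, 7:10).
#' @return `file`, invisibly.
#' @export
write_modes_tsv <- function(m, file, modes = 7:10) {
  modes <- modes[modes <= length(m$values)]
  rows <- do.call(rbind, lapply(modes, function(i) {
    d <- mode_displacements(m, i)
    data.frame(chain = m$nodes$chain_id, residue = m$nodes$residue_index,
               mode = i, eigenvalue = m$values[i],
               dx = d[, 1], dy = d[, 2], dz = d[, 3])
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
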