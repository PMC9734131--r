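#' Conformational ensemble container
#'
#' An ordered set of coordinate models sharing one atom table.
#'
#' @param models List of \eqn{N \times 3} coordinate matrices (one per
#'   model, same atom order).
#' @param atoms Data frame with columns \code{resno} (author residue
#'   number), \code{resname} (3-letter code), \code{name} (atom name),
#'   one row per atom.
#' @param label Optional ensemble label.
#' @param times Optional per-model time stamps (for trajectories).
#' @return An object of class \code{"conformer_ensemble"}.
#' @export
conformer_ensemble <- function(models, atoms, label = "", times = NULL) {
  if (!length(models)) .stopf("an ensemble needs at least one model")
  req <- c("resno", "resname", "name")
  if (!all(req %in% names(atoms)))
    .stopf("atoms must have columns %s", paste(req, collapse = ", "))
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != n)
      .stopf("model %d is not an %d x 3 coordinate matrix", i, n)
  }
  if (!is.null(times) && length(times) != length(models))
    .stopf("times must have one entry per model")
  structure(list(models = models, atoms = atoms, label = label,
                 times = times),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble%s: %d models, %d atoms, residues %d-%d\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$models), nrow(x$atoms),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens A [conformer_ensemble()].
#' @return Integer.
#' @export
n_models <- function(ens) length(ens$models)

#' Atom selection by residue range and atom class
#'
#' @param residues Integer vector of residue numbers, or a list of
#'   inclusive \code{c(start, end)} ranges.
#' @param atom_filter \code{"CA"}, \code{"backbone"} (N, CA, C, O) or
#'   \code{"all"}.
#' @return An object of class \code{"atom_selection"}.
#' @export
selection <- function(residues, atom_filter = c("CA", "backbone", "all")) {
  atom_filter <- match.arg(atom_filter)
  if (is.list(residues))
    residues <- unlist(lapply(residues, function(r) seq(r[1], r[2])))
  residues <- sort(unique(as.integer(residues)))
  structure(list(residues = residues, atom_filter = atom_filter),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#' @param atoms Atom table of an ensemble.
#' @param sel An [selection()] object, or an integer vector of atom
#'   indices (returned unchanged).
#' @return Integer atom indices.
#' @export
resolve_selection <- function(atoms, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "atom_selection"))
  keep <- atoms$resno %in% sel$residues
  keep <- keep & switch(sel$atom_filter,
                        CA = atoms$name == "CA",
                        backbone = atoms$name %in% c("N", "CA", "C", "O"),
                        all = TRUE)
  idx <- which(keep)
  if (!length(idx))
    .stopf("selection matches no atoms (residues %d-%d, filter %s)",
           min(sel$residues), max(sel$residues), sel$atom_filter)
  idx
}

.rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Kabsch rotation (reflections excluded) mapping mobile points onto
# reference points; rows are points
.kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv_q <- svd(qc)$d
  if (nrow(q) < 3 || sv_q[2] < 1e-8 * max(sv_q[1], 1e-12))
    .stopf("degenerate (collinear or < 3 atoms) superposition selection")
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  w <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = w, center_mobile = cp, center_ref = cq)
}

.apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_mobile) %*% t(tr$rotation), 2,
        tr$center_ref, `+`)
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation + translation (Kabsch, reflections excluded) of a
#' mobile model onto a reference over a selection.
#'
#' @param mobile,reference \eqn{N \times 3} coordinate matrices sharing
#'   the atom order of \code{atoms}.
#' @param sel A [selection()] or integer atom indices; needs at least 3
#'   non-collinear atoms.
#' @param atoms Atom table (required when \code{sel} is a selection).
#' @return List with \code{xyz} (the transformed full mobile model),
#'   \code{rmsd} (over the selection, after transform), and the
#'   transform (\code{rotation}, \code{center_mobile},
#'   \code{center_ref}).
#' @export
superpose <- function(mobile, reference, sel, atoms = NULL) {
  idx <- if (is.numeric(sel)) as.integer(sel) else resolve_selection(atoms, sel)
  if (length(idx) < 3) .stopf("superposition needs at least 3 atoms (got %d)", length(idx))
  tr <- .kabsch(mobile[idx, , drop = FALSE], reference[idx, , drop = FALSE])
  xyz <- .apply_transform(mobile, tr)
  c(list(xyz = xyz, rmsd = .rmsd_xyz(xyz[idx, , drop = FALSE],
                                     reference[idx, , drop = FALSE])), tr)
}

#' RMSD of one region after superposition on another
#'
#' Superposes \code{b} onto \code{a} over \code{fit_sel} and reports the
#' RMSD over \code{measure_sel} — e.g. fit on the rigid core, measure on
#' the mobile segment.
#'
#' @param a,b Coordinate matrices sharing the atom order of \code{atoms}.
#' @param fit_sel,measure_sel [selection()]s or atom index vectors.
#' @param atoms Atom table.
#' @return RMSD in \AA{}.
#' @export
region_rmsd <- function(a, b, fit_sel, measure_sel, atoms = NULL) {
  fit_idx <- if (is.numeric(fit_sel)) as.integer(fit_sel) else resolve_selection(atoms, fit_sel)
  mea_idx <- if (is.numeric(measure_sel)) as.integer(measure_sel) else resolve_selection(atoms, measure_sel)
  sp <- superpose(b, a, fit_idx)
  .rmsd_xyz(sp$xyz[mea_idx, , drop = FALSE], a[mea_idx, , drop = FALSE])
}

#' Pairwise region-RMSD matrix of an ensemble
#'
#' Symmetric matrix of [region_rmsd()] values between every pair of
#' models, the input to [ward_cluster()].
#'
#' @param ens A [conformer_ensemble()] with at least 2 models.
#' @inheritParams region_rmsd
#' @return Symmetric matrix (\AA{}) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ens, fit_sel, measure_sel = fit_sel) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  if (n_models(ens) < 2) .stopf("pairwise RMSD needs at least 2 models")
  fit_idx <- resolve_selection(ens$atoms, fit_sel)
  mea_idx <- resolve_selection(ens$atoms, measure_sel)
  n <- n_models(ens)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in seq((i + 1), n)) {
      v <- region_rmsd(ens$models[[i]], ens$models[[j]], fit_idx, mea_idx)
      m[i, j] <- v
      m[j, i] <- v
    }
  m
}

.mean_silhouette <- function(labels, dmat) {
  sil <- cluster::silhouette(labels, dmatrix = dmat)
  if (length(sil) == 1 && is.na(sil)) return(NA_real_)
  mean(sil[, "sil_width"])
}

#' Hierarchical clustering of a conformational ensemble
#'
#' Ward-linkage (variance minimization) hierarchical clustering on a
#' pairwise RMSD matrix.  When \code{n_clusters} is not given, the
#' cluster number is chosen automatically as the k in 2..\code{k_max}
#' maximizing the mean silhouette width (ties toward smaller k).  Each
#' cluster is summarized by its medoid (member minimizing summed RMSD to
#' co-members) and its spread (mean member-to-medoid RMSD).
#'
#' @param mat Symmetric RMSD matrix, e.g. from [pairwise_rmsd_matrix()].
#' @param n_clusters Optional fixed number of clusters.
#' @param k_max Largest k tried by the automatic choice.
#' @param method Linkage: \code{"ward.D2"} (default) or
#'   \code{"average"}.
#' @param height_cutoff With \code{method = "average"}, cut the tree at
#'   this height instead of choosing k by silhouette.
#' @return An object of class \code{"ensemble_clusters"}: \code{labels},
#'   \code{n_clusters}, \code{centroids} (medoid model indices),
#'   \code{spreads} (\AA{}), \code{silhouette}, and the \code{hclust}
#'   linkage record.
#' @export
ward_cluster <- function(mat, n_clusters = NULL, k_max = 10,
                         method = c("ward.D2", "average"),
                         height_cutoff = NULL) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) .stopf("clustering needs at least 2 models")
  if (max(abs(mat - t(mat))) > 1e-9 || any(abs(diag(mat)) > 1e-9))
    .stopf("mat must be symmetric with a zero diagonal")
  sil <- NA_real_
  if (max(mat) < 1e-10 && is.null(n_clusters)) {
    labels <- rep(1L, n)
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(mat), method = method)
    if (!is.null(n_clusters)) {
      if (n_clusters < 1 || n_clusters > n) .stopf("n_clusters out of range")
      labels <- stats::cutree(hc, k = n_clusters)
    } else if (!is.null(height_cutoff)) {
      labels <- stats::cutree(hc, h = height_cutoff)
    } else {
      ks <- seq(2, max(2, min(k_max, n - 1)))
      sils <- vapply(ks, function(k)
        .mean_silhouette(stats::cutree(hc, k = k), mat), numeric(1))
      best <- ks[which.max(sils)]  # which.max takes the first (smallest k) tie
      sil <- max(sils, na.rm = TRUE)
      labels <- stats::cutree(hc, k = best)
    }
  }
  cl <- sort(unique(labels))
  centroids <- integer(length(cl))
  spreads <- numeric(length(cl))
  for (c_i in seq_along(cl)) {
    members <- which(labels == cl[c_i])
    sums <- rowSums(mat[members, members, drop = FALSE])
    med <- members[which.min(sums)]
    centroids[c_i] <- med
    spreads[c_i] <- mean(mat[members, med])
  }
  structure(list(labels = as.integer(labels), n_clusters = length(cl),
                 centroids = centroids, spreads = spreads,
                 silhouette = sil, hclust = hc, method = method),
            class = "ensemble_clusters")
}

#' @export
print.ensemble_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) over %d models (%s linkage)\n",
              x$n_clusters, length(x$labels), x$method))
  for (i in seq_len(x$n_clusters))
    cat(sprintf("  cluster %d: %d members, medoid model %d, spread %.3g A\n",
                i, sum(x$labels == i), x$centroids[i], x$spreads[i]))
  invisible(x)
}

#' Representative (medoid) model of an ensemble
#'
#' The member minimizing summed RMSD to all other members, computed on a
#' selection (all atoms by default).
#'
#' @param ens A [conformer_ensemble()].
#' @param fit_sel Selection used both to fit and to measure.
#' @return Model index.
#' @export
representative_model <- function(ens, fit_sel = NULL) {
  if (n_models(ens) == 1L) return(1L)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(ens$atoms))
  m <- pairwise_rmsd_matrix(ens, fit_sel, fit_sel)
  which.min(rowSums(m))
}

#' Per-residue root-mean-square fluctuation
#'
#' Models are superposed on the mean structure over \code{fit_sel}
#' (computed once against model 1, then refined once against the mean),
#' and per-residue RMSF is the root mean squared deviation of the
#' residue's filtered atoms from their mean positions.
#'
#' @param ens A [conformer_ensemble()] (or trajectory) with \eqn{\ge} 2
#'   models.
#' @param fit_sel Superposition selection.
#' @param atom_filter Which atoms enter the per-residue average:
#'   \code{"CA"}, \code{"backbone"} or \code{"all"}.
#' @return Data frame with columns \code{resno}, \code{rmsf} (\AA{}).
#' @export
rmsf_profile <- function(ens, fit_sel, atom_filter = c("CA", "backbone", "all")) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  atom_filter <- match.arg(atom_filter)
  if (n_models(ens) < 2) .stopf("RMSF needs at least 2 models")
  fit_idx <- resolve_selection(ens$atoms, fit_sel)
  fitted1 <- lapply(ens$models, function(m) superpose(m, ens$models[[1]], fit_idx)$xyz)
  mean1 <- Reduce(`+`, fitted1) / length(fitted1)
  fitted2 <- lapply(ens$models, function(m) superpose(m, mean1, fit_idx)$xyz)
  mean2 <- Reduce(`+`, fitted2) / length(fitted2)
  dev2 <- Reduce(`+`, lapply(fitted2, function(m) rowSums((m - mean2)^2))) /
    length(fitted2)
  keep <- switch(atom_filter,
                 CA = ens$atoms$name == "CA",
                 backbone = ens$atoms$name %in% c("N", "CA", "C", "O"),
                 all = rep(TRUE, nrow(ens$atoms)))
  resno <- sort(unique(ens$atoms$resno[keep]))
  rmsf <- vapply(resno, function(r)
    sqrt(mean(dev2[keep & ens$atoms$resno == r])), numeric(1))
  data.frame(resno = resno, rmsf = rmsf)
}
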